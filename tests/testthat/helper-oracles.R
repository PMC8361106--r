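# Independent oracles used across tests. These deliberately take different
# algorithmic routes from the package implementation.

# All compositions n1+...+ns = k of k atoms among s isotopes, with the
# multinomial probability and total mass shift of each: exhaustive
# enumeration of isotope assignments for one element.
oracle_element_dist <- function(k, shifts, probs) {
  s <- length(shifts)
  if (k == 0) return(1)
  grids <- rep(list(0:k), s)
  combos <- as.matrix(expand.grid(grids))
  combos <- combos[rowSums(combos) == k, , drop = FALSE]
  out <- numeric(k * max(shifts) + 1)
  for (r in seq_len(nrow(combos))) {
    n <- combos[r, ]
    logp <- lgamma(k + 1) - sum(lgamma(n + 1)) +
      sum(ifelse(n > 0, n * log(probs), 0))
    shift <- sum(n * shifts)
    out[shift + 1] <- out[shift + 1] + exp(logp)
  }
  out
}

# full polynomial-expansion distribution of a formula's natural mass
# shifts, truncated to length m
oracle_natural_mid <- function(formula, m, elements = element_table()) {
  f <- parse_formula(formula)
  total <- 1
  for (sym in names(f)) {
    sub <- elements[elements$symbol == sym, ]
    d <- oracle_element_dist(f[[sym]], sub$isotope_shift, sub$abundance)
    new <- numeric(length(total) + length(d) - 1)
    for (i in seq_along(total))
      for (j in seq_along(d))
        new[i + j - 1] <- new[i + j - 1] + total[i] * d[j]
    total <- new
  }
  out <- numeric(m)
  n <- min(m, length(total))
  out[seq_len(n)] <- total[seq_len(n)]
  out
}

# correction-matrix column by enumeration: j labeled carbon positions are a
# pseudo-element with isotope probs (1-p, p), combined with the remaining
# atoms' enumerated natural distribution
oracle_correction_matrix <- function(fragment, n, purity = 1,
                                     elements = element_table()) {
  f <- parse_formula(fragment)
  A <- matrix(0, n + 1, n + 1)
  for (j in 0:n) {
    rest <- stats::setNames(as.integer(f), names(f))
    rest["C"] <- rest["C"] - j
    rest_str <- paste0(names(rest)[rest > 0], rest[rest > 0], collapse = "")
    nat <- if (rest_str == "") 1 else
      oracle_natural_mid(rest_str, n + 1, elements)
    lab <- if (j == 0) 1 else
      oracle_element_dist(j, c(0, 1), c(1 - purity, purity))
    col <- numeric(2 * (n + 1))
    for (i in seq_along(lab))
      for (k in seq_along(nat))
        col[i + k - 1] <- col[i + k - 1] + lab[i] * nat[k]
    A[, j + 1] <- col[1:(n + 1)]
  }
  A
}

# Benjamini-Hochberg step-up written out directly
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * p[ord[i]] / i)
    adj[ord[i]] <- running
  }
  adj
}

# run raw MIDs from a labeling experiment through correction + MPE +
# contribution
pipeline_contribution <- function(lab, n = 5) {
  A <- lab$truth$A
  mcols <- paste0("M", 0:n)
  mpe_of <- function(cond) {
    sub <- lab$mids[lab$mids$condition == cond, mcols, drop = FALSE]
    apply(sub, 1, function(r) mpe(correct_mid(as.numeric(r), A)))
  }
  contribution(mpe_of("control"), mpe_of("supplemented"))
}

# planted feature table used by several detection tests
planted_features <- function() {
  data.frame(
    mz = c(159.0296, 173.0455, 131.0350, 200.1000, 250.2000,
           300.3000, 350.4000, 400.5000, 450.6000, 500.7000),
    rt = c(3.9, 5.0, 7.1, 9.0, 11.0, 13.0, 15.0, 17.0, 19.0, 21.0),
    intensity = c(2e6, 1e6, 5e5, 8e5, 3e6, 2e5, 4e5, 6e5, 9e5, 1.5e6))
}
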