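#' Tracer specification
#'
#' Describes the isotopic tracer whose labeled positions shift the mass of
#' a traced metabolite, e.g. uniformly 13C-labeled glutamine for carbon
#' tracing. Isotopic purity is the probability that a nominally labeled
#' position actually carries the heavy isotope.
#'
#' @param element Traced element symbol (only carbon is supported).
#' @param purity Isotopic purity in (0, 1]. Commercial 13C tracers are
#'   typically ~0.99; the default of 1.0 reproduces analyses that do not
#'   model purity, and lower values support sensitivity analysis.
#' @param n_positions Number of labeled positions per tracer molecule
#'   (metadata only; e.g. 5 for 13C5-glutamine).
#' @return A list of class `"tracer_spec"`.
#' @export
tracer_spec <- function(element = "C", purity = 1.0, n_positions = 5L) {
  if (element != "C") stop("only carbon tracing is supported")
  if (!(purity > 0 && purity <= 1)) stop("purity must be in (0, 1]")
  structure(list(element = element, purity = purity,
                 n_positions = as.integer(n_positions)),
            class = "tracer_spec")
}

# convolution of two shift-probability vectors truncated to length m
conv_trunc <- function(a, b, m) {
  n <- min(m, length(a) + length(b) - 1)
  out <- numeric(m)
  for (i in seq_along(a)) {
    jmax <- min(length(b), m - i + 1)
    if (jmax >= 1) {
      idx <- i:(i + jmax - 1)
      out[idx] <- out[idx] + a[i] * b[1:jmax]
    }
  }
  out
}

#' Natural isotopologue distribution of a formula (truncated)
#'
#' Probability of mass shifts +0 ... +(length-1) Da arising from natural
#' isotope abundance, computed by convolving the single-atom shift
#' distribution of every atom in the formula. The vector is truncated, not
#' renormalized, so it sums to <= 1: the missing mass lies beyond the
#' requested window.
#'
#' @inheritParams monoisotopic_mass
#' @param length Number of entries (window M+0 .. M+length-1); >= 1.
#' @return Numeric vector of shift probabilities.
#' @export
#' @examples
#' natural_mid("C1", 2)  # ~ c(0.9893, 0.0107)
natural_mid <- function(f, length, elements = element_table()) {
  stopifnot(length >= 1)
  f <- as_formula_counts(f, elements)
  v <- 1
  for (sym in names(f)) {
    p <- element_shift_dist(sym, elements)
    for (i in seq_len(f[[sym]])) v <- conv_trunc(v, p, length)
  }
  out <- numeric(length)
  out[seq_along(v)] <- v
  out
}

#' Build a natural-abundance correction matrix
#'
#' Constructs the (n+1) x (n+1) matrix `A` that maps a true (corrected)
#' mass isotopologue distribution onto the measured one. Column `j`
#' (0-based) is the mass-shift distribution of a molecule with `j`
#' tracer-labeled carbon positions: each labeled position adds +1 with
#' probability `purity` (else +0), convolved with the natural-abundance
#' distribution of all remaining atoms of the fragment (the full formula
#' minus `j` carbons), truncated to shifts 0..n. For GC-MS the fragment
#' must be the complete derivatized fragment formula — silicon and the
#' methoxime N contribute heavily to the natural pattern.
#'
#' @param fragment Formula of the measured fragment ion (string or
#'   [formula_counts()]); must contain at least `n` carbons.
#' @param n Number of traceable carbons (MID length is n+1).
#' @param tracer A [tracer_spec()]; only its `purity` enters the matrix.
#' @param elements Element table.
#' @return Matrix of class `"correction_matrix"` with attributes
#'   `fragment` (formula string) and `purity`.
#' @export
#' @examples
#' # fragment of the KG methoxime di-TBDMS derivative after tert-butyl loss
#' A <- build_correction_matrix("C14H28NO5Si2", 5)
#' colSums(A)  # column-substochastic
build_correction_matrix <- function(fragment, n, tracer = tracer_spec(),
                                    elements = element_table()) {
  fragment <- as_formula_counts(fragment, elements)
  n <- as.integer(n)
  nC <- if ("C" %in% names(fragment)) fragment[["C"]] else 0L
  if (n > nC)
    stop("n (", n, ") exceeds the fragment's carbon count (", nC, ")")
  p <- tracer$purity
  A <- matrix(0, n + 1, n + 1)
  for (j in 0:n) {
    rest <- unclass(fragment)
    rest["C"] <- rest["C"] - j
    nat <- natural_mid(formula_counts(rest), n + 1, elements)
    lab <- stats::dbinom(0:j, j, p)
    A[, j + 1] <- conv_trunc(lab, nat, n + 1)
  }
  structure(A, class = c("correction_matrix", "matrix", "array"),
            fragment = format(fragment), purity = p)
}

#' @export
print.correction_matrix <- function(x, ...) {
  cat("<correction_matrix> fragment:", attr(x, "fragment"),
      " purity:", attr(x, "purity"), "\n")
  print(round(unclass(x), 5))
  invisible(x)
}

#' Correct a measured MID for natural isotope abundance
#'
#' Solves `min || A x - raw ||` subject to `x >= 0` by non-negative least
#' squares and renormalizes the solution to a simplex vector. NNLS (rather
#' than matrix inversion) avoids the negative fractions inversion produces
#' on noisy data.
#'
#' @param raw Measured (uncorrected) MID vector, length n+1; normalized
#'   internally.
#' @param A A [build_correction_matrix()] result of matching dimension.
#' @return Corrected MID vector summing to 1.
#' @export
#' @examples
#' A <- build_correction_matrix("C5H6O5", 5)
#' raw <- as.numeric(A %*% c(0.3, 0, 0, 0, 0, 0.7))
#' round(correct_mid(raw, A), 6)
correct_mid <- function(raw, A) {
  if (length(raw) != nrow(A))
    stop("raw MID length (", length(raw), ") does not match matrix dimension (",
         nrow(A), ")")
  if (any(raw < 0)) stop("raw MID has negative entries")
  s <- sum(raw)
  if (s <= 0) stop("raw MID is all zero; metabolite not detected")
  raw <- raw / s
  x <- pracma::lsqnonneg(unclass(A), raw)$x
  if (sum(x) <= 0) stop("degenerate correction: NNLS solution is zero")
  x / sum(x)
}

#' Mole percent enrichment of a MID
#'
#' The weighted average of the mass isotopologue distribution,
#' `100 * sum(i * M_i) / n`: the percentage of traceable carbon atoms that
#' carry label. The denominator is the fixed carbon count `n`, so appending
#' zero isotopologues beyond n changes the value — the MID must have
#' exactly n+1 entries.
#'
#' @param m MID vector (M0..Mn); normalized internally.
#' @param n Number of traceable carbons; defaults to `length(m) - 1`.
#' @return MPE in percent (0-100).
#' @export
#' @examples
#' mpe(c(0.25, 0, 0, 0, 0, 0.75))  # 75
mpe <- function(m, n = length(m) - 1) {
  if (n < 1) stop("MPE is undefined for zero traceable carbons")
  if (length(m) != n + 1)
    stop("MID must have n + 1 = ", n + 1, " entries")
  if (any(m < 0)) stop("MID has negative entries")
  s <- sum(m)
  if (s <= 0) stop("MID is all zero")
  m <- m / s
  100 * sum((0:n) * m) / n
}
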