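#' Parse a molecular formula string
#'
#' Parses a Hill-style formula such as `"C6H8O5"` or `"C13H25NO5Si"` into a
#' named integer vector of element counts. Multi-digit counts and repeated
#' element tokens (counts are summed) are supported.
#'
#' @param text A single formula string.
#' @param elements Element table (see [element_table()]); symbols not in the
#'   table are rejected.
#' @return A named integer vector of class `"formula_counts"`.
#' @export
#' @examples
#' parse_formula("C6H8O5")
#' parse_formula("H2O")
parse_formula <- function(text, elements = element_table()) {
  stopifnot(is.character(text), length(text) == 1, !is.na(text))
  text <- trimws(text)
  if (text == "") return(formula_counts(integer(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text) || any(m < 0))
    stop("malformed formula: '", text, "'")
  syms <- sub("[0-9]*$", "", tokens)
  cnts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                            sub("^[A-Za-z]+", "", tokens), "1"))
  known <- unique(elements$symbol)
  bad <- setdiff(syms, known)
  if (length(bad) > 0)
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  counts <- tapply(cnts, factor(syms, levels = unique(syms)), sum)
  formula_counts(stats::setNames(as.integer(counts), names(counts)))
}

#' Construct a formula (element count) object
#'
#' @param counts Named integer vector of atom counts (may be empty).
#' @return A named integer vector of class `"formula_counts"`.
#' @export
formula_counts <- function(counts) {
  counts <- counts[counts != 0]
  if (length(counts) > 0 && (is.null(names(counts)) || any(names(counts) == "")))
    stop("counts must be named by element symbol")
  if (any(counts < 0)) stop("negative atom counts are not allowed")
  structure(as.integer(counts), names = names(counts),
            class = "formula_counts")
}

#' @export
format.formula_counts <- function(x, ...) {
  if (length(x) == 0) return("")
  # Hill order: C, H, then alphabetical
  syms <- names(x)
  ord <- order(match(syms, c("C", "H"), nomatch = 3L), syms)
  paste0(syms[ord], ifelse(x[ord] == 1, "", x[ord]), collapse = "")
}

#' @export
print.formula_counts <- function(x, ...) {
  cat("<formula> ", format(x), "\n", sep = "")
  invisible(x)
}

as_formula_counts <- function(f, elements = element_table()) {
  if (inherits(f, "formula_counts")) return(f)
  if (is.character(f)) return(parse_formula(f, elements))
  if (is.numeric(f)) return(formula_counts(stats::setNames(as.integer(f), names(f))))
  stop("cannot interpret object as a molecular formula")
}

#' Monoisotopic mass of a formula
#'
#' Sum over elements of atom count times the principal-isotope mass.
#'
#' @param f Formula string, [formula_counts()] object, or named count vector.
#' @param elements Element table.
#' @return Mass in Da (0 for the empty formula).
#' @export
#' @examples
#' monoisotopic_mass("C6H8O5")
monoisotopic_mass <- function(f, elements = element_table()) {
  f <- as_formula_counts(f, elements)
  if (length(f) == 0) return(0)
  mono <- elements$monoisotopic_mass[!duplicated(elements$symbol)]
  names(mono) <- elements$symbol[!duplicated(elements$symbol)]
  if (any(!names(f) %in% names(mono)))
    stop("unknown element symbol(s): ",
         paste(setdiff(names(f), names(mono)), collapse = ", "))
  sum(unclass(f) * mono[names(f)])
}

#' Nominal (integer) mass of a formula
#'
#' @inheritParams monoisotopic_mass
#' @return Integer mass in Da.
#' @export
#' @examples
#' nominal_mass("C4H9")  # the tert-butyl radical lost in [M-57] fragments
nominal_mass <- function(f, elements = element_table()) {
  f <- as_formula_counts(f, elements)
  if (length(f) == 0) return(0L)
  nom <- elements$nominal_mass[!duplicated(elements$symbol)]
  names(nom) <- elements$symbol[!duplicated(elements$symbol)]
  if (any(!names(f) %in% names(nom)))
    stop("unknown element symbol(s): ",
         paste(setdiff(names(f), names(nom)), collapse = ", "))
  as.integer(sum(unclass(f) * nom[names(f)]))
}

# hydrogen-atom, proton and electron masses (Da)
.m_H <- 1.00782503207
.m_e <- 0.00054857990907
.m_proton <- .m_H - .m_e

#' Theoretical [M+H]+ / [M-H]- m/z of a neutral formula
#'
#' Two reporting conventions are provided. `"physical"` (the default, used
#' for all peak matching) is exact ion physics: the negative ion is the
#' neutral monoisotopic mass minus one proton, the positive ion plus one
#' proton, so electron bookkeeping is correct. `"reported"` reproduces the
#' three-decimal values printed in published texts for this compound family: neutral mass
#' minus/plus one hydrogen atom (electron neglected), rounded to four
#' decimals and then truncated to three — the rule that regenerates all the
#' printed values (159.029, 173.045, 131.034, 129.018) exactly.
#'
#' @inheritParams monoisotopic_mass
#' @param mode `"negative"` for [M-H]-, `"positive"` for [M+H]+.
#' @param convention `"physical"` (exact, full precision) or `"reported"`
#'   (printed three-decimal reporting).
#' @return m/z value.
#' @export
#' @examples
#' theoretical_mz("C6H8O5", "negative", "reported")  # mono-methyl-KG, 159.029
#' theoretical_mz("C6H8O5", "negative", "physical")
theoretical_mz <- function(f, mode = c("negative", "positive"),
                           convention = c("physical", "reported"),
                           elements = element_table()) {
  mode <- match.arg(mode)
  convention <- match.arg(convention)
  f <- as_formula_counts(f, elements)
  if (length(f) == 0) stop("empty formula has no ion m/z")
  M <- monoisotopic_mass(f, elements)
  sign <- if (mode == "negative") -1 else 1
  if (convention == "physical") {
    M + sign * .m_proton
  } else {
    trunc3(round(M + sign * .m_H, 4))
  }
}

# truncate toward zero at 3 decimals, guarding against representation error
trunc3 <- function(x) floor(x * 1000 + 1e-6) / 1000

#' Derivatization specification for GC-MS
#'
#' Describes methoximation (keto groups converted to methoximes) and TBDMS
#' silylation (acidic protons replaced by tert-butyldimethylsilyl) counts
#' applied during standard methoxyamine + MTBSTFA derivatization.
#'
#' @param n_methoxime Number of keto groups methoximated (each applies net
#'   +C +3H +N; the keto oxygen is replaced by N-OCH3 so O is unchanged).
#' @param n_tbdms Number of acidic protons replaced (each applies net
#'   -H +C6H15Si).
#' @return A list of class `"derivative_spec"`.
#' @export
#' @examples
#' derivative_spec(1, 2)  # e.g. alpha-ketoglutarate: one ketone, two acids
derivative_spec <- function(n_methoxime = 0, n_tbdms = 0) {
  stopifnot(n_methoxime >= 0, n_tbdms >= 0)
  structure(list(n_methoxime = as.integer(n_methoxime),
                 n_tbdms = as.integer(n_tbdms)),
            class = "derivative_spec")
}

#' @export
print.derivative_spec <- function(x, ...) {
  cat("<derivative_spec> methoxime:", x$n_methoxime,
      " TBDMS:", x$n_tbdms, "\n")
  invisible(x)
}

#' Apply a methoxime/TBDMS derivative to a neutral formula
#'
#' Each methoximation applies net +C +3H +N; each TBDMS substitution applies
#' net -H +C6H15Si. The caller asserts the molecule has enough keto groups
#' and exchangeable protons.
#'
#' @inheritParams monoisotopic_mass
#' @param d A [derivative_spec()].
#' @return The derivatized [formula_counts()].
#' @export
#' @examples
#' # mono-methyl-KG -> its methoxime mono-TBDMS derivative C13H25NO5Si
#' apply_derivative("C6H8O5", derivative_spec(1, 1))
apply_derivative <- function(f, d, elements = element_table()) {
  f <- as_formula_counts(f, elements)
  stopifnot(inherits(d, "derivative_spec"))
  delta <- c(C = d$n_methoxime + 6L * d$n_tbdms,
             H = 3L * d$n_methoxime + 14L * d$n_tbdms,
             N = d$n_methoxime,
             Si = d$n_tbdms)
  out <- stats::setNames(as.integer(f), names(f))
  for (sym in names(delta)) {
    out[sym] <- ifelse(is.na(out[sym]), 0L, out[sym]) + delta[[sym]]
  }
  out <- out[!is.na(out)]
  if (any(out < 0)) stop("derivatization yields negative atom counts")
  formula_counts(out)
}

#' Nominal m/z of a fragment ion formed by neutral loss
#'
#' Nominal mass of the derivatized molecule minus the nominal mass of the
#' lost group, e.g. loss of tert-butyl (C4H9) gives the diagnostic [M-57]
#' fragment of TBDMS derivatives.
#'
#' @param derivative Formula of the intact (derivatized) molecule.
#' @param loss Formula of the neutral loss (element-wise no greater than
#'   `derivative`); the empty formula gives the intact nominal mass.
#' @param elements Element table.
#' @return Integer nominal m/z.
#' @export
#' @examples
#' mkg_deriv <- apply_derivative("C6H8O5", derivative_spec(1, 1))
#' fragment_nominal_mz(mkg_deriv, "C4H9")  # 246
fragment_nominal_mz <- function(derivative, loss = "",
                                elements = element_table()) {
  derivative <- as_formula_counts(derivative, elements)
  loss <- as_formula_counts(loss, elements)
  for (sym in names(loss)) {
    have <- if (sym %in% names(derivative)) derivative[[sym]] else 0L
    if (loss[[sym]] > have)
      stop("loss ", format(loss), " exceeds atoms available in ",
           format(derivative))
  }
  nominal_mass(derivative, elements) - nominal_mass(loss, elements)
}

#' Signed parts-per-million mass difference
#'
#' @param observed Observed m/z.
#' @param theoretical Theoretical m/z (must be positive).
#' @return Signed ppm: `(observed - theoretical) / theoretical * 1e6`.
#' @export
#' @examples
#' ppm_diff(159.0302, 159.02935)
ppm_diff <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  (observed - theoretical) / theoretical * 1e6
}
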