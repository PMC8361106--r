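#' Element mass and natural-abundance table
#'
#' Returns the table of monoisotopic masses, nominal (integer) masses and
#' natural isotopic abundances used by all mass and isotopologue
#' computations. One row per isotope: `symbol`, `monoisotopic_mass` (Da, the
#' lightest/principal isotope, repeated across rows of the element),
#' `nominal_mass` (integer Da), `isotope_shift` (integer mass shift relative
#' to the principal isotope, starting at 0) and `abundance` (natural
#' fractional abundance; abundances of an element sum to 1).
#'
#' Values are the IUPAC recommended isotopic abundances and atomic-mass
#' evaluation monoisotopic masses. The same table ships as editable
#' delimited text in `inst/extdata/isotopes.tsv` and can be re-read (after
#' editing) with [read_element_table()].
#'
#' @param path Optional path to a delimited element table to use instead of
#'   the built-in values.
#' @return A `data.frame` with the five columns described above.
#' @seealso [read_element_table()], [monoisotopic_mass()], [natural_mid()]
#' @export
#' @examples
#' head(element_table())
element_table <- function(path = NULL) {
  if (!is.null(path)) return(read_element_table(path))
  .kgtrace_elements
}

# Principal-isotope monoisotopic masses (Da), nominal masses, and isotope
# shift/abundance pairs. Shifts are integer Da relative to the principal
# isotope; abundances per element sum to 1.
.kgtrace_elements <- local({
  rows <- list(
    list("H",  1.00782503207,  1, c(0, 1), c(0.999885, 0.000115)),
    list("C",  12.0,          12, c(0, 1), c(0.9893, 0.0107)),
    list("N",  14.0030740048, 14, c(0, 1), c(0.99636, 0.00364)),
    list("O",  15.9949146196, 16, c(0, 1, 2), c(0.99757, 0.00038, 0.00205)),
    list("Si", 27.9769265325, 28, c(0, 1, 2), c(0.92223, 0.04685, 0.03092)),
    list("S",  31.9720710015, 32, c(0, 1, 2, 4), c(0.9499, 0.0075, 0.0425, 0.0001)),
    list("P",  30.9737616320, 31, 0, 1),
    list("F",  18.9984031630, 19, 0, 1),
    list("Na", 22.9897692809, 23, 0, 1),
    list("K",  38.9637064864, 39, c(0, 1, 2), c(0.932581, 0.000117, 0.067302)),
    list("Cl", 34.9688526800, 35, c(0, 2), c(0.7576, 0.2424))
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(symbol = r[[1]], monoisotopic_mass = r[[2]],
               nominal_mass = r[[3]], isotope_shift = as.integer(r[[4]]),
               abundance = r[[5]], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
})

#' Read an element mass/abundance table from delimited text
#'
#' Expects tab-delimited text with header columns `symbol`,
#' `monoisotopic_mass`, `nominal_mass`, `isotope_shift`, `abundance` (one
#' row per isotope), as written in `inst/extdata/isotopes.tsv`.
#'
#' @param path File path.
#' @return A validated element table `data.frame`.
#' @export
read_element_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_element_table(tab)
  tab
}

validate_element_table <- function(tab) {
  needed <- c("symbol", "monoisotopic_mass", "nominal_mass",
              "isotope_shift", "abundance")
  if (!all(needed %in% names(tab)))
    stop("element table must have columns: ", paste(needed, collapse = ", "))
  if (any(tab$monoisotopic_mass <= 0) || any(tab$nominal_mass <= 0))
    stop("element masses must be positive")
  for (sym in unique(tab$symbol)) {
    sub <- tab[tab$symbol == sym, ]
    if (abs(sum(sub$abundance) - 1) > 1e-6)
      stop("abundances for ", sym, " do not sum to 1")
    sh <- sub$isotope_shift
    if (sh[1] != 0 || any(diff(sh) <= 0))
      stop("isotope shifts for ", sym,
           " must start at 0 and be strictly increasing")
  }
  invisible(tab)
}

# shift/abundance vectors for one element, as a probability vector over
# integer shifts 0..max(shift)
element_shift_dist <- function(symbol, elements = element_table()) {
  sub <- elements[elements$symbol == symbol, ]
  if (nrow(sub) == 0) stop("unknown element symbol: ", symbol)
  p <- numeric(max(sub$isotope_shift) + 1)
  p[sub$isotope_shift + 1] <- sub$abundance
  p
}
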