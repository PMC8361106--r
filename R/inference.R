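#' Stable-isotope dilution contribution estimate
#'
#' Under a steady tracer (e.g. 13C5-glutamine labeling intracellular KG),
#' an unlabeled carbon source dilutes the label it reaches. Its percent
#' contribution to the pool is the drop in mole percent enrichment:
#' `MPE_control - MPE_treated`. The `"unlabeled"` mode phrases the same
#' quantity as the difference in percent unlabeled carbon,
#' `(100 - MPE_treated) - (100 - MPE_control)` — algebraically identical in
#' magnitude. Dispersion is the standard error of the difference of means,
#' `sqrt(sd1^2/n1 + sd2^2/n2)`.
#'
#' @param control Replicate MPE values (percent, 0-100) for the control
#'   (tracer only) condition.
#' @param treated Replicate MPE values for the supplemented condition.
#' @param mode `"mpe"` (difference of %MPE) or `"unlabeled"` (difference of
#'   %(100-MPE)); both return the same contribution value.
#' @return A list of class `"contribution_estimate"`: `mpe_control`,
#'   `mpe_treated` (means), `contribution` (percent, clamped to
#'   [-100, 100]; small negative values are reported, not zeroed), `se`,
#'   `n_control`, `n_treated`, `mode`.
#' @export
#' @examples
#' contribution(c(90, 91, 89), c(75, 74, 76))
contribution <- function(control, treated, mode = c("mpe", "unlabeled")) {
  mode <- match.arg(mode)
  if (length(control) == 0 || length(treated) == 0)
    stop("empty replicate set")
  if (any(control < 0 | control > 100 | treated < 0 | treated > 100))
    stop("MPE values must lie in [0, 100]")
  n1 <- length(control); n2 <- length(treated)
  diff <- mean(control) - mean(treated)
  v1 <- if (n1 > 1) stats::var(control) else 0
  v2 <- if (n2 > 1) stats::var(treated) else 0
  se <- sqrt(v1 / n1 + v2 / n2)
  structure(list(mpe_control = mean(control), mpe_treated = mean(treated),
                 contribution = max(-100, min(100, diff)), se = se,
                 n_control = n1, n_treated = n2, mode = mode),
            class = "contribution_estimate")
}

#' @export
print.contribution_estimate <- function(x, ...) {
  lab <- if (x$mode == "mpe") "delta %MPE" else "delta %(100-MPE)"
  cat(sprintf("<contribution_estimate> %.2f%% (%s, se %.3f)\n",
              x$contribution, lab, x$se))
  cat(sprintf("  MPE control %.2f%% (n=%d)  treated %.2f%% (n=%d)\n",
              x$mpe_control, x$n_control, x$mpe_treated, x$n_treated))
  invisible(x)
}

#' Percent unlabeled carbon
#'
#' `100 - MPE`: the share of traceable carbon not carrying tracer label,
#' i.e. the share supplied by unlabeled sources.
#'
#' @param mpe MPE value(s) in percent (0-100).
#' @return `100 - mpe`.
#' @export
unlabeled_fraction <- function(mpe) {
  if (any(mpe < 0 | mpe > 100)) stop("MPE values must lie in [0, 100]")
  100 - mpe
}

#' Compartment-specific contribution via the 2-HG reporter
#'
#' Mutant IDH1-R132H (cytosolic) or IDH2-R172K (mitochondrial) produce
#' 2-hydroxyglutarate from the KG pool of their own compartment, so the
#' labeling of 2-HG (5-carbon backbone) reports compartment-specific KG
#' labeling. The contribution arithmetic is identical to [contribution()],
#' tagged with the compartment implied by the construct.
#'
#' @param construct `"IDH1-R132H"` or `"IDH2-R172K"`; any other label is an
#'   error.
#' @param control_mids,treated_mids Lists of replicate 2-HG MID vectors
#'   (length 6, M0..M5) for control and supplemented conditions.
#' @param mode Passed to [contribution()].
#' @return A `"contribution_estimate"` with an added `compartment` field
#'   (`"cytosolic"` or `"mitochondrial"`).
#' @export
compartment_contribution <- function(construct, control_mids, treated_mids,
                                     mode = c("unlabeled", "mpe")) {
  mode <- match.arg(mode)
  compartment <- switch(construct,
                        "IDH1-R132H" = "cytosolic",
                        "IDH2-R172K" = "mitochondrial",
                        stop("unknown reporter construct: ", construct))
  ctl <- vapply(control_mids, mpe, numeric(1), n = 5)
  trt <- vapply(treated_mids, mpe, numeric(1), n = 5)
  est <- contribution(ctl, trt, mode)
  est$compartment <- compartment
  est$construct <- construct
  est
}

#' Internal-standard absolute quantitation
#'
#' A known amount of co-extracted isotopically labeled internal standard
#' (e.g. 5 nmol of 2H6-KG in the quench solvent) converts a signal ratio
#' into an absolute amount: `amount = (analyte / IS) * is_amount`, and the
#' concentration in the sampled aliquot is `amount / aliquot volume`
#' (nmol/ul = mM).
#'
#' @param analyte Analyte signal (>= 0).
#' @param is_signal Internal-standard signal (> 0).
#' @param is_amount_nmol Spiked internal-standard amount (nmol).
#' @param aliquot_ul Sampled aliquot volume (ul).
#' @return Concentration in mM.
#' @export
#' @examples
#' absolute_quant(1e6, 1e6, is_amount_nmol = 5, aliquot_ul = 5)  # 1 mM
absolute_quant <- function(analyte, is_signal, is_amount_nmol = 5,
                           aliquot_ul = 5) {
  if (any(is_signal <= 0)) stop("internal-standard signal must be positive")
  if (any(analyte < 0)) stop("analyte signal must be >= 0")
  (analyte / is_signal) * is_amount_nmol / aliquot_ul
}

#' Normalize signals to a reference compound
#'
#' Ratio to a co-measured reference (e.g. the norvaline extraction
#' standard), removing sample-to-sample extraction and loading variation.
#'
#' @param analyte Analyte signal(s).
#' @param reference Reference signal(s) (> 0).
#' @return `analyte / reference`.
#' @export
normalize_to_reference <- function(analyte, reference) {
  if (any(reference <= 0)) stop("reference signal must be positive")
  analyte / reference
}

#' Normalize a rate series to its baseline
#'
#' Expresses each measurement as a percentage of the mean of the first
#' `n_basal` (baseline) measurements, as done for plate-respirometry OCR
#' and ECAR traces normalized to the three basal readings.
#'
#' @param series Ordered measurements.
#' @param n_basal Number of leading baseline measurements (default 3).
#' @return Percent-of-baseline series.
#' @export
baseline_normalize <- function(series, n_basal = 3) {
  if (length(series) <= n_basal)
    stop("series must be longer than the baseline")
  basal <- mean(series[seq_len(n_basal)])
  if (basal <= 0) stop("baseline mean must be positive")
  series * 100 / basal
}

#' Vehicle background subtraction of aligned series
#'
#' Element-wise subtraction of a vehicle series from experimental series at
#' aligned time points, then mean and standard deviation across replicates
#' — the processing used for cell-free acidification (mpH) traces.
#'
#' @param experimental Numeric vector, or matrix with replicates in rows
#'   and time points in columns.
#' @param vehicle Numeric vector (time points) or matrix aligned with
#'   `experimental`.
#' @return For vector input, the delta series. For matrix input, a list
#'   with `delta` (replicate x time matrix), `mean` and `sd` per time
#'   point.
#' @export
background_subtract <- function(experimental, vehicle) {
  if (is.matrix(experimental)) {
    veh <- if (is.matrix(vehicle)) colMeans(vehicle) else vehicle
    if (ncol(experimental) != length(veh))
      stop("experimental and vehicle series are misaligned")
    delta <- sweep(experimental, 2, veh)
    list(delta = delta, mean = colMeans(delta),
         sd = apply(delta, 2, stats::sd))
  } else {
    if (length(experimental) != length(vehicle))
      stop("experimental and vehicle series are misaligned")
    experimental - vehicle
  }
}

#' Group-wise differential statistics with the volcano rule
#'
#' Per-metabolite two-sided Welch (unequal-variance) t-tests between two
#' groups of samples, log2 fold change of group means, Benjamini-Hochberg
#' adjusted p-values, and the volcano significance rule
#' `|log2FC| >= lfc_cut & adjusted p < alpha` (defaults 1 and 0.05). Blank
#' policy substitution is expected to have been applied upstream. Rows
#' with non-positive group means get `NA` fold change and are flagged in
#' `fc_computed`.
#'
#' @param mat Numeric matrix, metabolites in rows, samples in columns.
#' @param groups Factor/character of length `ncol(mat)` with two levels.
#' @param control,treated Level names; fold change is treated over control.
#' @param lfc_cut Absolute log2 fold-change cutoff.
#' @param alpha Adjusted-p cutoff.
#' @return A `data.frame` with `metabolite`, `log2fc`, `p`, `p_adj`,
#'   `significant`, `fc_computed`.
#' @export
group_stats <- function(mat, groups, control, treated, lfc_cut = 1,
                        alpha = 0.05) {
  stopifnot(is.matrix(mat), length(groups) == ncol(mat))
  ctl <- mat[, groups == control, drop = FALSE]
  trt <- mat[, groups == treated, drop = FALSE]
  if (ncol(ctl) < 2 || ncol(trt) < 2)
    stop("need >= 2 replicates per group")
  nms <- if (is.null(rownames(mat))) as.character(seq_len(nrow(mat))) else
    rownames(mat)
  res <- t(vapply(seq_len(nrow(mat)), function(i) {
    x <- ctl[i, ]; y <- trt[i, ]
    p <- if (stats::var(x) == 0 && stats::var(y) == 0 &&
             mean(x) == mean(y)) 1 else
      stats::t.test(y, x, var.equal = FALSE)$p.value
    mx <- mean(x); my <- mean(y)
    lfc <- if (mx > 0 && my > 0) log2(my / mx) else NA_real_
    c(lfc, p)
  }, numeric(2)))
  p_adj <- stats::p.adjust(res[, 2], method = "BH")
  data.frame(metabolite = nms, log2fc = res[, 1], p = res[, 2],
             p_adj = p_adj,
             significant = !is.na(res[, 1]) & abs(res[, 1]) >= lfc_cut &
               p_adj < alpha,
             fc_computed = !is.na(res[, 1]))
}

#' Injection stock concentration for port loading
#'
#' A plate-respirometry injection of `inject_ul` into a well holding
#' `well_ul` dilutes the stock by `(well_ul + inject_ul) / inject_ul`; the
#' stock concentration achieving a final concentration is that multiple
#' (e.g. 25 ul into 150 ul for 1 mM final requires a 7 mM, 7x stock).
#'
#' @param final_mM Desired final concentration (mM).
#' @param well_ul Volume already in the well (ul).
#' @param inject_ul Injected volume (ul).
#' @return Stock concentration in mM.
#' @export
injection_stock <- function(final_mM, well_ul = 150, inject_ul = 25) {
  if (inject_ul <= 0 || well_ul < 0) stop("invalid volumes")
  final_mM * (well_ul + inject_ul) / inject_ul
}

#' Read an experimental design table
#'
#' Tab-delimited text with header columns `sample`, `condition`, `tracer`,
#' `supplement`, `replicate`, `is_blank`.
#'
#' @param path File path.
#' @return A `data.frame`.
#' @export
read_design <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("sample", "condition", "tracer", "supplement", "replicate",
              "is_blank")
  if (!all(needed %in% names(tab)))
    stop("design must have columns: ", paste(needed, collapse = ", "))
  tab$is_blank <- as.logical(tab$is_blank)
  tab
}
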