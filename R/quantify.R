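#' Read a compound library from delimited text
#'
#' Expects tab-delimited text with header columns `name`, `formula`, `mox`,
#' `tbdms`, `mode`, `n_carbons`, `expected_rt_min`, `fragment_loss`.
#' `mox`/`tbdms` are the methoxime and TBDMS counts of the GC-MS derivative
#' (0 for LC-MS entries); `fragment_loss` is the neutral-loss formula of the
#' quantified fragment (empty for intact ions).
#'
#' @param path File path.
#' @return A `data.frame` with the columns above.
#' @export
read_compound_library <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = character(0))
  needed <- c("name", "formula", "mox", "tbdms", "mode", "n_carbons",
              "expected_rt_min", "fragment_loss")
  if (!all(needed %in% names(tab)))
    stop("library must have columns: ", paste(needed, collapse = ", "))
  tab
}

#' Targeted quantitation against an accurate-mass / retention-time library
#'
#' For each library entry the target ion m/z is computed from its neutral
#' formula under the physically exact convention (see [theoretical_mz()]).
#' Candidate peaks lie within `lib_ppm` of the target m/z and
#' `lib_rt_window_min` of the expected retention time; the per-sample apex
#' is the most intense candidate. The consensus apex retention time is the
#' median per-sample apex time, and a sample's apex is accepted only within
#' `apex_tol_s` seconds of that consensus. Entries whose formula cannot be
#' parsed are reported in the `errors` attribute rather than aborting the
#' run.
#'
#' @param peaklists List of [peaklist()] objects.
#' @param library Compound library `data.frame` (see
#'   [read_compound_library()]); columns `name`, `formula`, `mode`,
#'   `expected_rt_min` are used here.
#' @param params A [detection_params()].
#' @param elements Element table.
#' @return A `data.frame` (one row per entry x sample) with columns `name`,
#'   `sample`, `intensity`, `apex_rt`, `detected`, plus attribute `errors`
#'   (data.frame of per-entry failures).
#' @export
quantify_library <- function(peaklists, library,
                             params = detection_params(),
                             elements = element_table()) {
  samples <- vapply(peaklists, sample_id, character(1))
  rows <- list()
  errors <- data.frame(name = character(0), error = character(0))
  for (k in seq_len(nrow(library))) {
    entry <- library[k, ]
    target <- tryCatch(
      theoretical_mz(entry$formula, entry$mode, "physical", elements),
      error = function(e) e)
    if (inherits(target, "error")) {
      errors <- rbind(errors,
                      data.frame(name = entry$name,
                                 error = conditionMessage(target)))
      next
    }
    apex_int <- apex_rt <- rep(NA_real_, length(samples))
    for (i in seq_along(peaklists)) {
      pl <- peaklists[[i]]
      cand <- which(abs(ppm_diff(pl$mz, target)) <= params$lib_ppm &
                      abs(pl$rt - entry$expected_rt_min) <=
                        params$lib_rt_window_min)
      if (length(cand) == 0) next
      apex <- cand[which.max(pl$intensity[cand])]
      apex_int[i] <- pl$intensity[apex]
      apex_rt[i] <- pl$rt[apex]
    }
    consensus <- stats::median(apex_rt, na.rm = TRUE)
    accept <- !is.na(apex_rt) &
      abs(apex_rt - consensus) <= params$apex_tol_s / 60
    rows[[length(rows) + 1]] <- data.frame(
      name = entry$name, sample = samples,
      intensity = ifelse(accept, apex_int, NA_real_),
      apex_rt = apex_rt, detected = accept)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(name = character(0), sample = character(0),
               intensity = numeric(0), apex_rt = numeric(0),
               detected = logical(0))
  rownames(out) <- NULL
  attr(out, "errors") <- errors
  out
}

#' Blank correction of quantified intensities
#'
#' For each analyte the detection threshold is
#' `max(blank_mult * mean(blank intensities), blank_floor)`. Non-blank
#' samples whose intensity falls below the threshold are flagged
#' undetected and their value replaced by the threshold (default policy,
#' used for group-wise comparisons) or by zero (`policy = "zero"`, used
#' when downstream models treat non-detects as absent). Missing
#' intensities are treated as zero signal.
#'
#' @param rows Quantitation `data.frame` with columns `name`, `sample`,
#'   `intensity` (as from [quantify_library()]).
#' @param blank_samples Character vector of blank sample ids (may be
#'   empty: the floor alone then sets the threshold).
#' @param params A [detection_params()].
#' @param policy `"threshold"` or `"zero"` replacement for non-detects.
#' @return The corrected `data.frame` with `detected` and `threshold`
#'   columns updated/added; blank rows are dropped.
#' @export
blank_correct <- function(rows, blank_samples = character(0),
                          params = detection_params(),
                          policy = c("threshold", "zero")) {
  policy <- match.arg(policy)
  stopifnot(all(c("name", "sample", "intensity") %in% names(rows)))
  is_blank <- rows$sample %in% blank_samples
  out <- list()
  for (nm in unique(rows$name)) {
    sub <- rows[rows$name == nm & !is_blank, , drop = FALSE]
    bl <- rows$intensity[rows$name == nm & is_blank]
    bl[is.na(bl)] <- 0
    blank_mean <- if (length(bl) > 0) mean(bl) else 0
    threshold <- max(params$blank_mult * blank_mean, params$blank_floor)
    val <- sub$intensity
    val[is.na(val)] <- 0
    det <- val >= threshold
    sub$intensity <- ifelse(det, val,
                            if (policy == "threshold") threshold else 0)
    sub$detected <- det
    sub$threshold <- threshold
    out[[nm]] <- sub
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract a raw mass isotopologue distribution from a peak list
#'
#' Sums intensity in m/z windows centred at the base (M0) ion and its
#' +1..+n isotopologues within a retention-time window, and normalizes to
#' a fraction vector. `"nominal"` spacing (1 Da, absolute `mz_tol` window)
#' suits unit-resolution GC-MS fragments; `"accurate"` spacing uses the
#' 13C-12C mass difference with a ppm window for high-resolution LC-MS.
#'
#' @param pl A [peaklist()].
#' @param base_mz m/z of the M0 ion.
#' @param n Number of traceable carbons (vector length n+1).
#' @param rt Expected retention time (minutes).
#' @param rt_window Retention-time half-width (minutes).
#' @param mode `"nominal"` or `"accurate"`.
#' @param mz_tol Absolute m/z half-width for `"nominal"` mode.
#' @param ppm_tol ppm half-width for `"accurate"` mode.
#' @return Numeric vector M0..Mn summing to 1.
#' @export
extract_mid <- function(pl, base_mz, n, rt, rt_window = 0.5,
                        mode = c("nominal", "accurate"),
                        mz_tol = 0.3, ppm_tol = 5) {
  mode <- match.arg(mode)
  spacing <- if (mode == "nominal") 1 else 1.00335483507
  in_rt <- abs(pl$rt - rt) <= rt_window
  v <- vapply(0:n, function(i) {
    center <- base_mz + i * spacing
    tol <- if (mode == "nominal") mz_tol else center * ppm_tol / 1e6
    sum(pl$intensity[in_rt & abs(pl$mz - center) <= tol])
  }, numeric(1))
  if (sum(v) <= 0)
    stop("metabolite not detected: no signal in the extraction windows")
  v / sum(v)
}
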