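#' Detection and quantitation parameters
#'
#' Parameters of MS1 feature detection, library quantitation and blank
#' correction. Defaults are the operating values of the emulated
#' processing: 20 ppm m/z discrimination, 1e5 minimum intensity, minimum
#' S/N of 10 and a 2-minute retention-time co-grouping threshold for
#' untargeted detection; +/-5 ppm and +/-0.5 min library search windows
#' with a +/-7.5 s per-sample apex tolerance; and 3x blank correction with
#' a 1e5 floor.
#'
#' @param group_ppm m/z co-grouping half-width for feature detection (ppm).
#' @param min_intensity Minimum apex intensity for a feature seed.
#' @param min_snr Minimum signal-to-noise ratio for a feature seed.
#' @param rt_group_min Retention-time co-grouping half-width (minutes).
#' @param lib_ppm Library accurate-mass tolerance (ppm).
#' @param lib_rt_window_min Initial library retention-time window (minutes).
#' @param apex_tol_s Per-sample apex retention-time tolerance (seconds).
#' @param blank_mult Blank multiplier for the detection threshold.
#' @param blank_floor Detection threshold floor.
#' @param snr_ppm Half-width of the m/z slice used by the noise estimator
#'   (ppm).
#' @param snr_rt_excl_min Retention-time half-width excluded around the
#'   candidate when estimating noise (minutes).
#' @return A list of class `"detection_params"`.
#' @export
detection_params <- function(group_ppm = 20, min_intensity = 1e5,
                             min_snr = 10, rt_group_min = 2,
                             lib_ppm = 5, lib_rt_window_min = 0.5,
                             apex_tol_s = 7.5, blank_mult = 3,
                             blank_floor = 1e5, snr_ppm = 50,
                             snr_rt_excl_min = 0.2) {
  p <- list(group_ppm = group_ppm, min_intensity = min_intensity,
            min_snr = min_snr, rt_group_min = rt_group_min,
            lib_ppm = lib_ppm, lib_rt_window_min = lib_rt_window_min,
            apex_tol_s = apex_tol_s, blank_mult = blank_mult,
            blank_floor = blank_floor, snr_ppm = snr_ppm,
            snr_rt_excl_min = snr_rt_excl_min)
  if (any(unlist(p) <= 0)) stop("all detection parameters must be positive")
  structure(p, class = "detection_params")
}

#' Estimate signal-to-noise ratio of a candidate peak
#'
#' The noise level is the median intensity of peaks within `snr_ppm` of the
#' candidate m/z across the full run, excluding `snr_rt_excl_min` minutes
#' either side of the candidate retention time (so the candidate's own
#' chromatographic peak does not inflate the noise). S/N is candidate
#' intensity over that noise; when the slice is empty or the median is
#' zero, `Inf` is returned.
#'
#' @param mz,rt,intensity Candidate peak coordinates.
#' @param host A [peaklist()] containing the candidate's run.
#' @param params A [detection_params()].
#' @return Signal-to-noise ratio (possibly `Inf`).
#' @export
estimate_snr <- function(mz, rt, intensity, host,
                         params = detection_params()) {
  slice <- host$intensity[abs(ppm_diff(host$mz, mz)) <= params$snr_ppm &
                            abs(host$rt - rt) > params$snr_rt_excl_min]
  noise <- stats::median(slice)
  if (length(slice) == 0 || is.na(noise) || noise <= 0) return(Inf)
  intensity / noise
}

#' Untargeted MS1 feature detection across samples
#'
#' Greedy intensity-descending seeding, as in the emulated untargeted
#' processing: peaks of all samples are pooled, the most intense unassigned
#' peak that passes the minimum-intensity and S/N rules seeds a feature,
#' and all unassigned peaks within `group_ppm` (m/z) and `rt_group_min`
#' (retention time) of the seed are absorbed. Features are disjoint over
#' peaks; each sample contributes its apex (maximum) member intensity.
#' Ties in seed intensity are broken by lower m/z, then earlier retention
#' time, for determinism.
#'
#' @param peaklists List of [peaklist()] objects sharing one polarity.
#' @param params A [detection_params()].
#' @return A list of class `"feature_set"`: `features` (data.frame with
#'   `feature_id`, consensus `mz` (intensity-weighted mean), consensus `rt`,
#'   `n_peaks`), `intensity` / `apex_rt` / `detected` matrices (features x
#'   samples; `detected` requires the sample apex to reach
#'   `min_intensity`), and `assignment` (per pooled peak, the feature index
#'   or NA).
#' @export
detect_features <- function(peaklists, params = detection_params()) {
  stopifnot(is.list(peaklists))
  samples <- vapply(peaklists, sample_id, character(1))
  empty <- feature_set(data.frame(feature_id = integer(0), mz = numeric(0),
                                  rt = numeric(0), n_peaks = integer(0)),
                       matrix(NA_real_, 0, length(samples),
                              dimnames = list(NULL, samples)),
                       matrix(NA_real_, 0, length(samples),
                              dimnames = list(NULL, samples)),
                       matrix(FALSE, 0, length(samples),
                              dimnames = list(NULL, samples)),
                       integer(0))
  if (length(peaklists) == 0) return(empty)
  pols <- unique(vapply(peaklists, polarity, character(1)))
  if (length(pols) > 1) stop("peak lists mix polarities")
  pool <- do.call(rbind, lapply(seq_along(peaklists), function(i) {
    pl <- peaklists[[i]]
    if (nrow(pl) == 0) return(NULL)
    data.frame(sample = samples[i], sample_idx = i,
               rt = pl$rt, mz = pl$mz, intensity = pl$intensity,
               row.names = NULL)
  }))
  if (is.null(pool) || nrow(pool) == 0) return(empty)

  ord <- order(-pool$intensity, pool$mz, pool$rt)
  assigned <- rep(NA_integer_, nrow(pool))
  feat_mz <- feat_rt <- numeric(0)
  members <- list()
  n_feat <- 0L
  for (i in ord) {
    if (!is.na(assigned[i])) next
    if (pool$intensity[i] < params$min_intensity) break
    snr <- estimate_snr(pool$mz[i], pool$rt[i], pool$intensity[i],
                        peaklists[[pool$sample_idx[i]]], params)
    if (snr < params$min_snr) next
    hit <- which(is.na(assigned) &
                   abs(ppm_diff(pool$mz, pool$mz[i])) <= params$group_ppm &
                   abs(pool$rt - pool$rt[i]) <= params$rt_group_min)
    n_feat <- n_feat + 1L
    assigned[hit] <- n_feat
    members[[n_feat]] <- hit
    feat_mz[n_feat] <- stats::weighted.mean(pool$mz[hit], pool$intensity[hit])
    feat_rt[n_feat] <- stats::weighted.mean(pool$rt[hit], pool$intensity[hit])
  }
  if (n_feat == 0) return(empty)

  ns <- length(samples)
  intensity <- apex_rt <- matrix(NA_real_, n_feat, ns,
                                 dimnames = list(NULL, samples))
  detected <- matrix(FALSE, n_feat, ns, dimnames = list(NULL, samples))
  for (f in seq_len(n_feat)) {
    sub <- pool[members[[f]], ]
    for (s in unique(sub$sample_idx)) {
      ss <- sub[sub$sample_idx == s, ]
      apex <- which.max(ss$intensity)
      intensity[f, s] <- ss$intensity[apex]
      apex_rt[f, s] <- ss$rt[apex]
      detected[f, s] <- ss$intensity[apex] >= params$min_intensity
    }
  }
  feats <- data.frame(feature_id = seq_len(n_feat), mz = feat_mz,
                      rt = feat_rt,
                      n_peaks = vapply(members, length, integer(1)))
  feature_set(feats, intensity, apex_rt, detected, assigned)
}

feature_set <- function(features, intensity, apex_rt, detected, assignment) {
  structure(list(features = features, intensity = intensity,
                 apex_rt = apex_rt, detected = detected,
                 assignment = assignment),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("<feature_set> ", nrow(x$features), " features x ",
      ncol(x$intensity), " samples\n", sep = "")
  if (nrow(x$features) > 0) print(utils::head(x$features, 10))
  invisible(x)
}
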