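#' Generate synthetic centroided MS1 peak lists with planted features
#'
#' Emulates the statistical structure of per-sample centroided peak tables:
#' planted features (true m/z, retention time, apex intensity) observed in
#' every sample with configurable ppm, retention-time and intensity jitter,
#' plus uniform low-intensity background peaks. The ground truth (planted
#' coordinates, per-sample apexes, seed and noise settings) is returned
#' alongside the data, and regeneration from the same seed is identical.
#'
#' @param n_samples Number of samples.
#' @param features `data.frame` with columns `mz`, `rt`, `intensity` (true
#'   apex); must lie within `scan_range` and `rt_range`.
#' @param ppm_sd m/z jitter (ppm standard deviation).
#' @param rt_sd Retention-time jitter (minutes sd).
#' @param intensity_cv Multiplicative intensity noise (coefficient of
#'   variation).
#' @param n_background Background peaks per sample.
#' @param bg_intensity_range Uniform background intensity range (kept below
#'   the 1e5 detection floor by default).
#' @param scan_range Acquisition m/z range.
#' @param rt_range Retention-time range (minutes).
#' @param pol Polarity of the emulated acquisition.
#' @param seed Integer seed; all randomness derives from it.
#' @return A list: `peaklists` (named list of [peaklist()]), `truth`
#'   (planted features, per-sample apex matrix, generator settings).
#' @export
gen_peaklists <- function(n_samples = 3, features, ppm_sd = 0, rt_sd = 0,
                          intensity_cv = 0, n_background = 0,
                          bg_intensity_range = c(1e3, 5e4),
                          scan_range = c(67, 1000), rt_range = c(0, 30),
                          pol = "negative", seed = 1) {
  stopifnot(all(c("mz", "rt", "intensity") %in% names(features)))
  if (any(features$mz < scan_range[1] | features$mz > scan_range[2]))
    stop("planted features outside declared scan range")
  if (any(features$rt < rt_range[1] | features$rt > rt_range[2]))
    stop("planted features outside retention-time range")
  set.seed(seed)
  nf <- nrow(features)
  apex <- matrix(NA_real_, nf, n_samples,
                 dimnames = list(NULL, paste0("S", seq_len(n_samples))))
  pls <- lapply(seq_len(n_samples), function(s) {
    mz <- features$mz * (1 + stats::rnorm(nf, 0, ppm_sd) / 1e6)
    rt <- pmin(pmax(features$rt + stats::rnorm(nf, 0, rt_sd),
                    rt_range[1]), rt_range[2])
    int <- features$intensity *
      pmax(1 + stats::rnorm(nf, 0, intensity_cv), 0)
    apex[, s] <<- int
    if (n_background > 0) {
      mz <- c(mz, stats::runif(n_background, scan_range[1], scan_range[2]))
      rt <- c(rt, stats::runif(n_background, rt_range[1], rt_range[2]))
      int <- c(int, stats::runif(n_background, bg_intensity_range[1],
                                 bg_intensity_range[2]))
    }
    peaklist(paste0("S", s), rt, mz, int, pol, scan_range)
  })
  names(pls) <- paste0("S", seq_len(n_samples))
  list(peaklists = pls,
       truth = list(features = features, apex = apex, seed = seed,
                    ppm_sd = ppm_sd, rt_sd = rt_sd,
                    intensity_cv = intensity_cv,
                    n_background = n_background))
}

#' Generate a synthetic stable-isotope dilution labeling experiment
#'
#' Emulates the study design in which intracellular metabolites are
#' labeled by a uniformly 13C tracer and an unlabeled supplement dilutes
#' the label by its fractional contribution `c` to the pool. The true
#' corrected MID is a mixture of unlabeled (`c + (1-c)(1-e)`) and fully
#' labeled (`(1-c)e`) species — or a user-supplied pattern — which is
#' forward-distorted by the natural-abundance correction matrix of the
#' derivatized fragment, perturbed by multiplicative noise per
#' isotopologue, and renormalized. Control (`c = 0`) and supplemented
#' conditions are both generated; ground truth is recorded.
#'
#' Defaults mirror the central scenario: the 5-carbon KG backbone measured
#' as its methoxime di-TBDMS [M-57] fragment, full tracer enrichment, three
#' replicates, 2% multiplicative noise.
#'
#' @param formula Neutral metabolite formula (default KG, `"C5H6O5"`).
#' @param n_carbons Traceable carbons (default 5).
#' @param derivative [derivative_spec()] of the GC-MS derivative.
#' @param fragment_loss Neutral-loss formula of the quantified fragment.
#' @param enrichment Tracer labeling extent `e` of the pool in the control
#'   condition, in [0, 1].
#' @param contribution True fractional contribution `c` of the unlabeled
#'   supplement, in [0, 1].
#' @param replicates Replicates per condition.
#' @param cv Multiplicative noise per isotopologue.
#' @param tracer A [tracer_spec()].
#' @param true_mid Optional user-supplied true labeled-pool MID (length
#'   n_carbons + 1) replacing the two-component mixture for the labeled
#'   fraction of the pool.
#' @param seed Integer seed.
#' @param elements Element table.
#' @return A list: `mids` (data.frame `condition`, `replicate`, `M0..Mn`),
#'   `truth` (true MIDs, `c`, `e`, expected delta-MPE, fragment formula,
#'   correction matrix, seed).
#' @export
gen_labeling_experiment <- function(formula = "C5H6O5", n_carbons = 5,
                                    derivative = derivative_spec(1, 2),
                                    fragment_loss = "C4H9",
                                    enrichment = 1, contribution = 0,
                                    replicates = 3, cv = 0.02,
                                    tracer = tracer_spec(),
                                    true_mid = NULL, seed = 1,
                                    elements = element_table()) {
  e <- enrichment; cc <- contribution
  if (e < 0 || e > 1 || cc < 0 || cc > 1)
    stop("enrichment and contribution must lie in [0, 1]")
  if (cv < 0) stop("cv must be >= 0")
  deriv <- apply_derivative(formula, derivative, elements)
  loss <- as_formula_counts(fragment_loss, elements)
  frag <- unclass(deriv)
  for (sym in names(loss)) frag[sym] <- frag[sym] - loss[[sym]]
  fragment <- formula_counts(frag)
  A <- build_correction_matrix(fragment, n_carbons, tracer, elements)

  labeled_pattern <- if (is.null(true_mid)) {
    x <- numeric(n_carbons + 1); x[n_carbons + 1] <- 1; x
  } else {
    if (length(true_mid) != n_carbons + 1)
      stop("true_mid must have n_carbons + 1 entries")
    true_mid / sum(true_mid)
  }
  unlab <- numeric(n_carbons + 1); unlab[1] <- 1
  true_x <- function(c_frac) {
    (c_frac + (1 - c_frac) * (1 - e)) * unlab +
      (1 - c_frac) * e * labeled_pattern
  }
  x_ctl <- true_x(0)
  x_trt <- true_x(cc)

  set.seed(seed)
  gen_cond <- function(x, cond) {
    raw0 <- as.numeric(unclass(A) %*% x)
    do.call(rbind, lapply(seq_len(replicates), function(r) {
      raw <- raw0 * pmax(1 + stats::rnorm(length(raw0), 0, cv), 0)
      raw <- raw / sum(raw)
      out <- as.data.frame(as.list(stats::setNames(
        raw, paste0("M", 0:n_carbons))))
      cbind(data.frame(condition = cond, replicate = r), out)
    }))
  }
  mids <- rbind(gen_cond(x_ctl, "control"), gen_cond(x_trt, "supplemented"))
  list(mids = mids,
       truth = list(contribution = cc, enrichment = e,
                    expected_delta_mpe = 100 * cc * e,
                    x_control = x_ctl, x_treated = x_trt,
                    fragment = format(fragment), A = A, seed = seed,
                    cv = cv, replicates = replicates))
}

#' Generate a noisy synthetic hydrolysis time course
#'
#' Evaluates the consecutive first-order model and applies multiplicative
#' noise per observation; ground truth (parameters and noiseless curves)
#' is recorded.
#'
#' @param E0,k1,k2 True model parameters (see [simulate_consecutive()]).
#' @param times Sampling times (hours).
#' @param cv Multiplicative noise coefficient of variation.
#' @param replicates Replicates per time point.
#' @param seed Integer seed.
#' @return A list: `data` (data.frame `species`, `time_h`, `conc_mM`,
#'   `replicate`), `truth` (parameters, noiseless curves, seed).
#' @export
gen_timecourse <- function(E0 = 1, k1 = 5, k2 = 0.02,
                           times = c(0, 0.25, 0.5, 1, 2, 4, 8, 24, 48, 72),
                           cv = 0.05, replicates = 3, seed = 1) {
  sim <- simulate_consecutive(E0, k1, k2, times)
  set.seed(seed)
  long <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    do.call(rbind, lapply(c("ester", "monoester", "acid"), function(sp) {
      conc <- sim[[sp]] * pmax(1 + stats::rnorm(length(times), 0, cv), 0)
      data.frame(species = sp, time_h = times, conc_mM = conc,
                 replicate = r)
    }))
  }))
  rownames(long) <- NULL
  list(data = long,
       truth = list(params = c(E0 = E0, k1 = k1, k2 = k2),
                    curves = sim, cv = cv, replicates = replicates,
                    seed = seed))
}
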