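#' Consecutive first-order hydrolysis model
#'
#' Closed-form concentrations for the two-step hydrolysis
#' di-ester -> monoester -> free acid (e.g. DMKG -> 5MKG -> KG) with rate
#' constants `k1`, `k2`:
#' `E(t) = E0 exp(-k1 t)`,
#' `M(t) = E0 k1/(k2-k1) (exp(-k1 t) - exp(-k2 t))`,
#' `P(t) = E0 - E(t) - M(t)`. The equal-rate limit
#' `M(t) = E0 k1 t exp(-k1 t)` is used when `|k2 - k1|` is numerically
#' small, via an `expm1`-based form that is continuous through `k2 = k1`.
#' Mass is conserved at every time point.
#'
#' @param E0 Initial di-ester concentration (mM, > 0).
#' @param k1 First (proximal, fast) hydrolysis rate constant (1/h, >= 0).
#' @param k2 Second (distal, slow) hydrolysis rate constant (1/h, >= 0).
#' @param times Time points (hours, >= 0).
#' @return A `data.frame` with columns `time_h`, `ester`, `monoester`,
#'   `acid`.
#' @export
#' @examples
#' simulate_consecutive(1, 5, 0.02, c(0, 1, 24, 72))
simulate_consecutive <- function(E0, k1, k2, times) {
  if (E0 <= 0) stop("E0 must be positive")
  if (k1 < 0 || k2 < 0) stop("rate constants must be >= 0")
  if (any(times < 0)) stop("times must be >= 0")
  E <- E0 * exp(-k1 * times)
  d <- k2 - k1
  # M = E0 k1 (e^{-k1 t} - e^{-k2 t}) / (k2 - k1), with the equal-rate
  # limit E0 k1 t e^{-k1 t} when the rates are numerically indistinguishable
  M <- ifelse(abs(d) * pmax(times, 1) < 1e-12,
              E0 * k1 * times * exp(-k1 * times),
              E0 * k1 * (exp(-k1 * times) - exp(-k2 * times)) / d)
  M[is.nan(M)] <- 0
  P <- E0 - E - M
  data.frame(time_h = times, ester = E, monoester = M, acid = P)
}

#' Single-step first-order hydrolysis model
#'
#' Mono-ester hydrolysis (e.g. 1-octyl-KG -> KG): exponential ester decay
#' and complementary product rise.
#'
#' @param E0 Initial ester concentration (mM, > 0).
#' @param k Hydrolysis rate constant (1/h, >= 0).
#' @param times Time points (hours).
#' @return A `data.frame` with columns `time_h`, `ester`, `acid`.
#' @export
simulate_single <- function(E0, k, times) {
  if (E0 <= 0) stop("E0 must be positive")
  if (k < 0) stop("rate constant must be >= 0")
  if (any(times < 0)) stop("times must be >= 0")
  E <- E0 * exp(-k * times)
  data.frame(time_h = times, ester = E, acid = E0 - E)
}

#' Fit the consecutive hydrolysis model to time-course data
#'
#' Least-squares fit of `(E0, k1, k2)` to measured concentrations of any
#' subset of the three species, by Levenberg-Marquardt. Confidence
#' intervals come from the parameter covariance (residual variance times
#' the inverse of the Jacobian cross-product).
#'
#' @param data A `data.frame` with columns `species` (`"ester"`,
#'   `"monoester"`, `"acid"`), `time_h`, `conc_mM`, and optionally
#'   `replicate`. Each observed species needs >= 3 distinct time points.
#' @param start Named start values for `E0`, `k1`, `k2`; defaults to the
#'   maximum observed concentration and (1, 0.1) 1/h.
#' @param weights Optional observation weights (same length as rows of
#'   `data`).
#' @param conf_level Confidence level for the intervals.
#' @return A list of class `"rate_fit"`: `params` (named vector), `se`,
#'   `ci` (matrix), `cov`, `fitted`, `residuals`, `deviance`,
#'   `convergence` (info code and message from the optimizer).
#' @export
fit_consecutive <- function(data, start = NULL, weights = NULL,
                            conf_level = 0.95) {
  stopifnot(all(c("species", "time_h", "conc_mM") %in% names(data)))
  if (!all(data$species %in% c("ester", "monoester", "acid")))
    stop("species must be ester/monoester/acid")
  for (sp in unique(data$species)) {
    if (length(unique(data$time_h[data$species == sp])) < 3)
      stop("need >= 3 distinct time points for species ", sp)
  }
  if (is.null(weights)) weights <- rep(1, nrow(data))
  if (is.null(start))
    start <- c(E0 = max(data$conc_mM), k1 = 1, k2 = 0.1)
  model_vals <- function(par) {
    sim <- simulate_consecutive(par[["E0"]], par[["k1"]], par[["k2"]],
                                data$time_h)
    vals <- numeric(nrow(data))
    for (sp in c("ester", "monoester", "acid")) {
      sel <- data$species == sp
      vals[sel] <- sim[[sp]][sel]
    }
    vals
  }
  resid_fn <- function(par) {
    par <- pmax(par, c(1e-9, 0, 0))
    sqrt(weights) * (model_vals(c(E0 = par[1], k1 = par[2], k2 = par[3])) -
                       data$conc_mM)
  }
  fit <- minpack.lm::nls.lm(par = unname(start), fn = resid_fn,
                            lower = c(1e-9, 0, 0),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  if (!(fit$info %in% 1:4))
    stop("fit did not converge (info ", fit$info, "): ", fit$message)
  par <- stats::setNames(fit$par, c("E0", "k1", "k2"))
  dof <- max(nrow(data) - 3, 1)
  s2 <- fit$deviance / dof
  # nls.lm's hessian slot is the Jacobian cross-product J'J
  cov <- tryCatch(s2 * solve(fit$hessian),
                  error = function(e) matrix(NA_real_, 3, 3))
  se <- sqrt(pmax(diag(cov), 0))
  tq <- stats::qt(1 - (1 - conf_level) / 2, dof)
  ci <- cbind(lower = par - tq * se, upper = par + tq * se)
  names(se) <- names(par)
  structure(list(params = par, se = se, ci = ci, cov = cov,
                 fitted = model_vals(par),
                 residuals = model_vals(par) - data$conc_mM,
                 deviance = fit$deviance,
                 convergence = list(info = fit$info, message = fit$message,
                                    niter = fit$niter)),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat("<rate_fit> consecutive first-order hydrolysis\n")
  tab <- cbind(estimate = x$params, se = x$se, x$ci)
  print(signif(tab, 5))
  cat("residual deviance:", signif(x$deviance, 5), "\n")
  invisible(x)
}

#' Buffer + polyprotic acid system
#'
#' Describes an aqueous system of a monoprotic buffer (e.g. 5 mM HEPES,
#' pKa ~7.55) at a known initial pH, to which a neutral polyprotic acid
#' (e.g. alpha-ketoglutaric acid, pKa1 ~2.5, pKa2 ~4.7, released by ester
#' hydrolysis) is added.
#'
#' @param buffer_mM Total buffer concentration (mM, >= 0).
#' @param buffer_pka Buffer pKa.
#' @param acid_mM Added neutral acid concentration (mM, >= 0).
#' @param acid_pkas Ascending pKa values of the added acid.
#' @param ph_initial Initial (pre-addition) pH.
#' @return A list of class `"buffer_system"`.
#' @export
buffer_system <- function(buffer_mM = 5, buffer_pka = 7.55, acid_mM = 0,
                          acid_pkas = c(2.5, 4.7), ph_initial = 7.4) {
  if (buffer_mM < 0 || acid_mM < 0) stop("concentrations must be >= 0")
  if (is.unsorted(acid_pkas, strictly = TRUE) && length(acid_pkas) > 1)
    stop("acid pKa list must be ascending")
  structure(list(buffer_mM = buffer_mM, buffer_pka = buffer_pka,
                 acid_mM = acid_mM, acid_pkas = acid_pkas,
                 ph_initial = ph_initial),
            class = "buffer_system")
}

# mean charge (protons removed per molecule) of a polyprotic acid at [H+] (M)
polyprotic_mean_charge <- function(h, pkas) {
  ka <- 10^(-pkas)
  m <- length(ka)
  # unnormalized species weights: [H_m A] ~ 1, successive deprotonations
  # multiply by Ka_i / h
  w <- matrix(0, length(h), m + 1)
  w[, 1] <- 1
  for (i in seq_len(m)) w[, i + 1] <- w[, i] * ka[i] / h
  (w %*% (0:m)) / rowSums(w)
}

# charge-balance residual (mM): strong cation + [H+] - [OH-] - buffer anion
# - acid anions; Cb is the fixed strong-ion difference
charge_balance <- function(ph, b, Cb) {
  h <- 10^(-ph)
  oh <- 1e-14 / h
  buf_anion <- b$buffer_mM * 10^(-b$buffer_pka) /
    (10^(-b$buffer_pka) + h)
  acid_anion <- if (b$acid_mM > 0)
    b$acid_mM * as.numeric(polyprotic_mean_charge(h, b$acid_pkas)) else
      rep(0, length(h))
  Cb + 1000 * h - 1000 * oh - buf_anion - acid_anion
}

#' Equilibrium pH after adding a polyprotic acid to a buffered medium
#'
#' Solves the proton condition of the buffer + polyprotic acid + water
#' system by bracketed root finding on pH in [0, 14]. The strong-ion
#' difference is first calibrated so the acid-free system sits at
#' `ph_initial`; the neutral acid is then added and the charge balance
#' re-solved. Returns the new pH and the change in milli-pH units,
#' `1000 * (pH_after - pH_initial)` (negative for acidification). CO2 /
#' bicarbonate chemistry is deliberately out of model scope (intended for
#' bicarbonate-free HEPES media).
#'
#' @param b A [buffer_system()].
#' @param tol Root-finding tolerance on pH.
#' @return A list: `ph_initial`, `ph_after`, `delta_mph`.
#' @export
#' @examples
#' ph_after_acid_addition(buffer_system(acid_mM = 1))
ph_after_acid_addition <- function(b, tol = 1e-9) {
  stopifnot(inherits(b, "buffer_system"))
  # strong-ion difference that places the acid-free system at ph_initial
  b0 <- b; b0$acid_mM <- 0
  Cb <- -charge_balance(b$ph_initial, b0, 0)
  f <- function(ph) charge_balance(ph, b, Cb)
  if (b$acid_mM == 0)
    return(list(ph_initial = b$ph_initial, ph_after = b$ph_initial,
                delta_mph = 0))
  if (f(0) * f(14) > 0) stop("no root in pH bracket [0, 14]")
  root <- stats::uniroot(f, c(0, 14), tol = tol)$root
  list(ph_initial = b$ph_initial, ph_after = root,
       delta_mph = 1000 * (root - b$ph_initial))
}

#' Read a hydrolysis time-course table
#'
#' Tab-delimited text with header columns `species`, `time_h`, `conc_mM`
#' and optionally `replicate`.
#'
#' @param path File path.
#' @return A `data.frame`.
#' @export
read_timecourse <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("species", "time_h", "conc_mM")
  if (!all(needed %in% names(tab)))
    stop("time course must have columns: ", paste(needed, collapse = ", "))
  tab
}
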