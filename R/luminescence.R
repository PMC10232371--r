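#' Fit a single-exponential luminescence decay
#'
#' Least squares of `I(t) = A * exp(-t / tau) + baseline` to a decay trace.
#' Time arrives in microseconds (the usual instrument grid); the lifetime
#' is returned in milliseconds, the unit assumed by the hydration-number
#' constants. A non-decaying trace is flagged as a failed fit.
#'
#' @param data a data frame with columns `time_us` and `counts`.
#' @param baseline include a constant baseline term (default `TRUE`).
#' @return an object of class `decay_fit` with `tau_ms`, `amplitude`,
#'   `baseline`, `converged`, `failed`, `reason` and `data` (with fitted
#'   values).
#' @export
fit_decay <- function(data, baseline = TRUE) {
  data <- as_tibble(data)
  check_columns(data, c("time_us", "counts"), "decay trace")
  t_us <- data$time_us
  y <- data$counts
  if (length(t_us) < 10) abort("need at least 10 trace points.")
  if (is.unsorted(t_us, strictly = TRUE)) abort("time must be strictly increasing.")
  if (any(y < 0)) abort("intensities must be non-negative.")
  fail <- function(reason) {
    structure(list(tau_ms = NA_real_, amplitude = NA_real_,
                   baseline = NA_real_, converged = FALSE, failed = TRUE,
                   reason = reason,
                   data = mutate(data, fitted = NA_real_)),
              class = "decay_fit")
  }
  # crude decay check: early-window mean must exceed late-window mean
  k <- max(3L, length(y) %/% 5L)
  if (mean(utils::head(y, k)) <= mean(utils::tail(y, k)) ||
      diff(range(y)) == 0) {
    return(fail("trace does not decay"))
  }
  b0 <- if (baseline) min(y) else 0
  pos <- y - b0 > 0
  lmfit <- lm(log(y[pos] - b0 + 0.5) ~ t_us[pos])
  rate0 <- max(-coef(lmfit)[[2]], 1e-6)  # per us
  a0 <- max(y) - b0
  form <- if (baseline) y ~ a * exp(-t_us * r) + b else y ~ a * exp(-t_us * r)
  start <- if (baseline) list(a = a0, r = rate0, b = b0) else list(a = a0, r = rate0)
  fit <- tryCatch(
    minpack.lm::nlsLM(form, start = start,
                      lower = if (baseline) c(0, 1e-9, -Inf) else c(0, 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(fail("nonlinear fit did not converge"))
  est <- coef(fit)
  tau_ms <- (1 / est[["r"]]) / 1000  # us -> ms
  structure(
    list(tau_ms = tau_ms, amplitude = est[["a"]],
         baseline = if (baseline) est[["b"]] else 0,
         converged = TRUE, failed = FALSE, reason = NA_character_,
         data = mutate(data, fitted = predict(fit))),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$failed) {
    cat("<decay_fit> FAILED:", x$reason, "\n")
  } else {
    cat(sprintf("<decay_fit> tau = %.4g ms, A = %.4g, baseline = %.4g\n",
                x$tau_ms, x$amplitude, x$baseline))
  }
  invisible(x)
}

#' Decay-rate slope versus D2O fraction
#'
#' Ordinary least squares of the decay rate `1/tau` (ms^-1) on the solvent
#' D2O fraction (0-1). Returns the slope `m`, the intercept (the rate in
#' pure H2O) and the extrapolated rate at fraction 1 (pure D2O), the two
#' rates entering the hydration-number equation.
#'
#' @param data a data frame with columns `d2o_fraction` (0-1; percentages
#'   > 1 are accepted and divided by 100) and `tau_ms`.
#' @return an object of class `solvent_slope` with `m` (ms^-1 per unit
#'   fraction), `tau_h2o_inv`, `tau_d2o_inv` (ms^-1) and `data`.
#' @export
solvent_slope <- function(data) {
  data <- as_tibble(data)
  check_columns(data, c("d2o_fraction", "tau_ms"), "solvent series")
  f <- data$d2o_fraction
  if (any(f > 1)) f <- f / 100
  tau <- data$tau_ms
  if (any(tau <= 0)) abort("lifetimes must be positive.")
  if (length(unique(f)) < 2) abort("need at least 2 distinct D2O fractions.")
  rate <- 1 / tau
  fit <- lm(rate ~ f)
  m <- coef(fit)[[2]]
  intercept <- coef(fit)[[1]]
  structure(
    list(m = m, tau_h2o_inv = intercept, tau_d2o_inv = intercept + m,
         data = tibble(d2o_fraction = f, tau_ms = tau, rate = rate,
                       fitted = predict(fit))),
    class = "solvent_slope"
  )
}

#' @export
print.solvent_slope <- function(x, ...) {
  cat(sprintf(
    "<solvent_slope> m = %.4g ms^-1, tau_H2O^-1 = %.4g, tau_D2O^-1 (extrap.) = %.4g ms^-1\n",
    x$m, x$tau_h2o_inv, x$tau_d2o_inv))
  invisible(x)
}

#' Hydration number from H2O/D2O luminescence lifetimes
#'
#' The number of metal-coordinated water molecules, from the difference of
#' the reciprocal lifetimes in H2O and D2O (ms^-1) corrected for other
#' exchangeable oscillators:
#' `q = 1.11 * (tau_H2O^-1 - tau_D2O^-1 - 0.31 + 0.45*n_OH + 0.99*n_NH +
#' 0.075*n_OCNH)`.
#'
#' @param tau_h2o_inv,tau_d2o_inv reciprocal lifetimes in ms^-1 (`tau_d2o_inv`
#'   typically extrapolated from the solvent series; see [solvent_slope()]).
#' @param n_oh,n_nh,n_ocnh counts of exchangeable alcohol OH, amine NH and
#'   amide O=C-NH oscillators coordinated to the metal.
#' @return the hydration number `q` (dimensionless; may be slightly
#'   negative at q ~ 0 from measurement noise — reported, not clamped).
#' @export
q_value <- function(tau_h2o_inv, tau_d2o_inv, n_oh = 0, n_nh = 0,
                    n_ocnh = 1) {
  1.11 * (tau_h2o_inv - tau_d2o_inv - 0.31 +
            0.45 * n_oh + 0.99 * n_nh + 0.075 * n_ocnh)
}

#' Hydration number directly from the solvent-series slope
#'
#' With the D2O axis expressed as a fraction 0-1, the slope `m` of `1/tau`
#' versus fraction equals `tau_D2O^-1 - tau_H2O^-1`, so the hydration
#' number simplifies to `q = 1.11 * (-m - 0.31 + 0.45*n_OH + 0.99*n_NH +
#' 0.075*n_OCNH)` (with the default amide-only oscillator counts,
#' `q = 1.11 * (-m - 0.31 + 0.075)`).
#'
#' @param m slope of `1/tau` (ms^-1) versus D2O fraction, or a
#'   [solvent_slope()] object.
#' @inheritParams q_value
#' @return the hydration number `q`.
#' @export
q_from_slope <- function(m, n_oh = 0, n_nh = 0, n_ocnh = 1) {
  if (inherits(m, "solvent_slope")) m <- m$m
  q_value(-m, 0, n_oh = n_oh, n_nh = n_nh, n_ocnh = n_ocnh)
}
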