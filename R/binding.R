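#' Free metal concentration in a 1:1 chelator buffer
#'
#' Solves the mass balance for a metal M and chelator L forming a 1:1
#' complex ML with conditional stability constant `k_cond` (L/mol):
#' `K*x^2 - (K*M_T + K*L_T + 1)*x + K*M_T*L_T = 0` with `x = [ML]`, taking
#' the physical root, and returns `[M] = M_T - x`, evaluated through the
#' equivalent stable quadratic in the free metal itself so that very large
#' and very small `K` behave correctly; conservation holds to better than
#' 1e-10 relative (see [buffer_speciation()] for all three species).
#'
#' @param total_metal total metal, mol/L (vectorized).
#' @param total_chelator total chelator, mol/L.
#' @param k_cond conditional 1:1 stability constant, L/mol (pH-specific).
#' @return free metal concentration(s), mol/L.
#' @export
free_metal <- function(total_metal, total_chelator, k_cond) {
  speciate_quadratic(total_metal, total_chelator, k_cond)
}

# positive root of K*y^2 + (K*(other - self) + 1)*y - self = 0, the free
# concentration of `self` in a 1:1 buffer; both branch forms avoid
# catastrophic cancellation
#' @noRd
speciate_quadratic <- function(self, other, k) {
  check_number(self, "total concentration", lower = 0)
  check_number(other, "total concentration", lower = 0)
  check_number(k, "k_cond", lower = 0)
  args <- vctrs_recycle(self, other, k)
  s <- args[[1]]; o <- args[[2]]; kk <- args[[3]]
  b <- kk * (o - s) + 1
  disc <- sqrt(b^2 + 4 * kk * s)
  y <- ifelse(b >= 0, 2 * s / (b + disc), (disc - b) / (2 * kk))
  y <- ifelse(kk == 0, s, y)
  if (any(!is.finite(y) | y < 0 | y > s * (1 + 1e-9))) {
    abort("no physical complexation root found.")
  }
  pmin(y, s)
}

#' Full speciation of a 1:1 metal/chelator buffer
#'
#' Returns all three species of the 1:1 complexation equilibrium, each
#' computed from its own numerically stable quadratic so that the mass
#' balances `[M] + [ML] = M_T` and `[L] + [ML] = L_T` close to near
#' machine precision even in strongly one-sided regimes.
#'
#' @inheritParams free_metal
#' @return a tibble with `total_metal`, `total_chelator`, `k_cond`,
#'   `free_metal`, `free_chelator` and `complex` (all mol/L).
#' @export
buffer_speciation <- function(total_metal, total_chelator, k_cond) {
  fm <- speciate_quadratic(total_metal, total_chelator, k_cond)
  fl <- speciate_quadratic(total_chelator, total_metal, k_cond)
  args <- vctrs_recycle(total_metal, total_chelator, k_cond)
  m <- args[[1]]; l <- args[[2]]; k <- args[[3]]
  b <- k * (m + l) + 1
  x <- 2 * k * m * l / (b + sqrt(pmax(b^2 - 4 * k^2 * m * l, 0)))
  tibble(total_metal = m, total_chelator = l, k_cond = k,
         free_metal = fm, free_chelator = fl, complex = x)
}

#' @noRd
vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, rep_len, length.out = n)
}

#' Total metal needed to buffer a target free concentration
#'
#' Inverse of [free_metal()]: given the desired free metal `free`, the
#' chelator total and the conditional constant, returns the total metal to
#' add, `M_T = x * (1 + K*L_T / (1 + K*x))` (closed form of the 1:1 mass
#' balance). Used to design chelator-buffered titration schedules.
#'
#' @param free target free metal, mol/L (vectorized).
#' @inheritParams free_metal
#' @return total metal, mol/L.
#' @export
buffered_total_metal <- function(free, total_chelator, k_cond) {
  check_number(free, "free", lower = 0)
  free * (1 + k_cond * total_chelator / (1 + k_cond * free))
}

#' Hill response of a cooperative binding transition
#'
#' `S(x) = S0 + (S1 - S0) * x^n / (K^n + x^n)` with `x` the free metal
#' concentration, `K` the apparent dissociation constant and `n` the Hill
#' coefficient.
#'
#' @param x free metal concentration(s), mol/L.
#' @param kd apparent dissociation constant, mol/L.
#' @param n Hill coefficient.
#' @param s0,s1 baseline and plateau signals.
#' @return signal value(s).
#' @export
hill_signal <- function(x, kd, n, s0 = 0, s1 = 1) {
  check_number(x, "x", lower = 0)
  check_number(kd, "kd", lower = 0, allow_zero = FALSE)
  t <- (x / kd)^n
  s0 + (s1 - s0) * t / (1 + t)
}

#' Fit the Hill model to a titration
#'
#' Nonlinear least squares of the Hill response on a log-spaced free-metal
#' axis. For chelator-buffered titrations (`buffered = TRUE`) the free
#' metal is first computed per point from the buffer composition via
#' [free_metal()]. Standard errors come from seeded residual-resampling
#' bootstrap. Initialization: `K` at the concentration nearest the signal
#' midpoint, `n = 1`; bounds `n` in \[0.3, 4\] and `K` within the data
#' range times \[1e-2, 1e2\]. Monotone-decreasing (desorption-shaped) data
#' are flagged as a failed fit rather than fitted backwards.
#'
#' @param data a data frame. Unbuffered: columns `conc` (free metal, mol/L)
#'   and `signal`. Buffered: columns `total_metal`, `total_chelator`,
#'   `k_cond` and `signal`.
#' @param buffered whether `data` describes a chelator-buffered schedule.
#' @param n_boot bootstrap replicates for standard errors (default 200; 0
#'   disables).
#' @param seed seed for the bootstrap resampling.
#' @return an object of class `hill_fit` with elements `kd`, `n`, `s0`,
#'   `s1`, `se` (named vector), `converged`, `failed`, `reason`, `data`
#'   (tibble with `free`, `signal`, `fitted`) and `n_boot`.
#' @export
fit_hill <- function(data, buffered = FALSE, n_boot = 200, seed = 1) {
  data <- as_tibble(data)
  if (buffered) {
    check_columns(data, c("total_metal", "total_chelator", "k_cond", "signal"),
                  "buffered titration data")
    free <- free_metal(data$total_metal, data$total_chelator, data$k_cond)
  } else {
    check_columns(data, c("conc", "signal"), "titration data")
    free <- data$conc
  }
  y <- data$signal
  if (length(free) < 5) abort("need at least 5 titration points.")
  if (is.unsorted(free, strictly = TRUE)) {
    ord <- order(free)
    free <- free[ord]; y <- y[ord]
    if (anyDuplicated(free)) abort("concentrations must be distinct.")
  }
  if (any(free <= 0)) abort("free metal must be positive for a log-axis fit.")

  # direction guard: a binding transition rises with concentration
  rho <- suppressWarnings(cor(log10(free), y, method = "spearman"))
  if (is.na(rho) || rho < 0) {
    return(new_hill_fit(failed = TRUE, reason = "signal not increasing with concentration",
                        free = free, signal = y))
  }
  fit <- hill_nls(free, y)
  if (is.null(fit)) {
    return(new_hill_fit(failed = TRUE, reason = "nonlinear fit did not converge",
                        free = free, signal = y))
  }
  est <- coef(fit)
  kd <- 10^est[["lk"]]
  at_bound <- abs(est[["lk"]] - log10(min(free)) + 2) < 1e-6 ||
    abs(est[["lk"]] - log10(max(free)) - 2) < 1e-6
  fitted <- hill_signal(free, kd, est[["n"]], est[["s0"]], est[["s1"]])
  se <- c(kd = NA_real_, n = NA_real_, s0 = NA_real_, s1 = NA_real_)
  if (n_boot > 0) {
    se <- hill_bootstrap(free, fitted, y - fitted, n_boot, seed)
  }
  new_hill_fit(
    kd = kd, n = est[["n"]], s0 = est[["s0"]], s1 = est[["s1"]],
    se = se, converged = TRUE, failed = at_bound,
    reason = if (at_bound) "K at parameter bound" else NA_character_,
    free = free, signal = y, fitted = fitted, n_boot = n_boot
  )
}

#' @noRd
hill_nls <- function(free, y) {
  lk0 <- log10(free[which.min(abs(y - (min(y) + max(y)) / 2))])
  start <- c(lk = lk0, n = 1, s0 = min(y), s1 = max(y))
  span <- diff(range(y))
  lower <- c(lk = log10(min(free)) - 2, n = 0.3,
             s0 = min(y) - span, s1 = min(y))
  upper <- c(lk = log10(max(free)) + 2, n = 4,
             s0 = max(y), s1 = max(y) + span)
  tryCatch(
    minpack.lm::nlsLM(
      y ~ s0 + (s1 - s0) * (free / 10^lk)^n / (1 + (free / 10^lk)^n),
      start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
}

#' @noRd
hill_bootstrap <- function(free, fitted, residuals, n_boot, seed) {
  boots <- with_seed(seed, {
    map(seq_len(n_boot), function(b) {
      yb <- fitted + sample(residuals, replace = TRUE)
      fb <- hill_nls(free, yb)
      if (is.null(fb)) return(NULL)
      cb <- coef(fb)
      c(kd = 10^cb[["lk"]], n = cb[["n"]], s0 = cb[["s0"]], s1 = cb[["s1"]])
    })
  })
  boots <- do.call(rbind, purrr::compact(boots))
  if (is.null(boots) || nrow(boots) < 10) {
    return(c(kd = NA_real_, n = NA_real_, s0 = NA_real_, s1 = NA_real_))
  }
  apply(boots, 2, sd)
}

#' @noRd
new_hill_fit <- function(kd = NA_real_, n = NA_real_, s0 = NA_real_,
                         s1 = NA_real_, se = NULL, converged = FALSE,
                         failed = FALSE, reason = NA_character_,
                         free = numeric(), signal = numeric(),
                         fitted = rep(NA_real_, length(free)), n_boot = 0) {
  structure(
    list(
      kd = kd, n = n, s0 = s0, s1 = s1,
      se = se %||% c(kd = NA_real_, n = NA_real_, s0 = NA_real_, s1 = NA_real_),
      converged = converged, failed = failed, reason = reason,
      data = tibble(free = free, signal = signal, fitted = fitted),
      n_boot = n_boot
    ),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<hill_fit> FAILED:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("<hill_fit> K_d,app = %.4g M (se %.2g), n = %.3g (se %.2g)%s\n",
              x$kd, x$se[["kd"]], x$n, x$se[["n"]],
              if (x$failed) paste0(" [flag: ", x$reason, "]") else ""))
  invisible(x)
}

#' Fit a four-parameter logistic desorption curve
#'
#' Fits `S = post + (pre - post) / (1 + 10^(slope * (log10(c) - log10(mid))))`
#' to signal versus chelator concentration, returning the desorption
#' midpoint (the chelator concentration at 50% desorption). The signal may
#' fall or rise with concentration; a fit whose plateaus are not separated
#' is flagged as failed.
#'
#' @param data a data frame with columns `conc` (chelator, mol/L) and
#'   `signal`.
#' @param n_boot,seed bootstrap settings as in [fit_hill()].
#' @return an object of class `desorption_fit` with `midpoint` (mol/L),
#'   `slope`, `pre`, `post`, `se`, `converged`, `failed`, `reason`, `data`.
#' @export
fit_desorption <- function(data, n_boot = 200, seed = 1) {
  data <- as_tibble(data)
  check_columns(data, c("conc", "signal"), "desorption data")
  x <- data$conc; y <- data$signal
  if (length(x) < 5) abort("need at least 5 points.")
  if (any(x <= 0)) abort("chelator concentrations must be positive.")
  ord <- order(x); x <- x[ord]; y <- y[ord]
  lx <- log10(x)
  mid0 <- lx[which.min(abs(y - (min(y) + max(y)) / 2))]
  # `pre`/`post` carry the curve direction, so the logistic slope is
  # constrained positive (a negative slope would mirror the same curve)
  start <- c(lmid = mid0, slope = 1, pre = y[1], post = y[length(y)])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ post + (pre - post) / (1 + 10^(slope * (lx - lmid))),
      start = start,
      lower = c(lmid = min(lx), slope = 0.05, pre = min(y) - diff(range(y)),
                post = min(y) - diff(range(y))),
      upper = c(lmid = max(lx), slope = 20, pre = max(y) + diff(range(y)),
                post = max(y) + diff(range(y))),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(structure(list(midpoint = NA_real_, slope = NA_real_,
                          pre = NA_real_, post = NA_real_,
                          se = c(midpoint = NA_real_),
                          converged = FALSE, failed = TRUE,
                          reason = "nonlinear fit did not converge",
                          data = tibble(conc = x, signal = y,
                                        fitted = NA_real_)),
                     class = "desorption_fit"))
  }
  est <- coef(fit)
  fitted <- predict(fit)
  sep <- abs(est[["pre"]] - est[["post"]])
  noise <- sd(y - fitted)
  failed <- sep < 4 * max(noise, .Machine$double.eps)
  se <- c(midpoint = NA_real_)
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      map_dbl(seq_len(n_boot), function(b) {
        yb <- fitted + sample(y - fitted, replace = TRUE)
        fb <- tryCatch(
          minpack.lm::nlsLM(
            yb ~ post + (pre - post) / (1 + 10^(slope * (lx - lmid))),
            start = est,
            control = minpack.lm::nls.lm.control(maxiter = 200)
          ),
          error = function(e) NULL
        )
        if (is.null(fb)) NA_real_ else 10^coef(fb)[["lmid"]]
      })
    })
    se <- c(midpoint = sd(boots, na.rm = TRUE))
  }
  structure(
    list(midpoint = 10^est[["lmid"]], slope = est[["slope"]],
         pre = est[["pre"]], post = est[["post"]], se = se,
         converged = TRUE, failed = failed,
         reason = if (failed) "plateaus not separated" else NA_character_,
         data = tibble(conc = x, signal = y, fitted = fitted)),
    class = "desorption_fit"
  )
}

#' @export
print.desorption_fit <- function(x, ...) {
  if (!x$converged || x$failed) {
    cat("<desorption_fit> FLAGGED:", x$reason, "\n")
    if (!x$converged) return(invisible(x))
  }
  cat(sprintf("<desorption_fit> [chelator]_1/2 = %.4g M, slope = %.3g\n",
              x$midpoint, x$slope))
  invisible(x)
}

#' Selectivity ratio of two desorption midpoints
#'
#' The ratio of chelator concentrations required for 50% desorption of two
#' metals, `midpoint_a / midpoint_b` — a single-number selectivity metric
#' for a desorption scheme.
#'
#' @param fit_a,fit_b converged [fit_desorption()] objects (or bare
#'   midpoint numbers).
#' @return the dimensionless ratio.
#' @export
selectivity_ratio <- function(fit_a, fit_b) {
  m <- function(f) if (inherits(f, "desorption_fit")) f$midpoint else f
  ma <- m(fit_a); mb <- m(fit_b)
  if (!is.finite(ma) || !is.finite(mb)) abort("both fits must have converged.")
  if (mb == 0) abort("denominator midpoint is zero.")
  ma / mb
}
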