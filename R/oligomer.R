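#' Free monomer concentration in a monomer-dimer equilibrium
#'
#' For the dissociation equilibrium D = 2M with `K_dimer = [M]^2 / [D]` and
#' total protein `[P] = [M] + 2[D]` (monomer equivalents), the monomer
#' concentration solves `2[M]^2 + K_dimer*[M] - K_dimer*[P] = 0`, giving the
#' positive root `[M] = (-K + sqrt(K^2 + 8*K*P)) / 4`.
#'
#' @param p_total total protein in monomer equivalents, mol/L (vectorized).
#' @param k_dimer dimer dissociation constant, mol/L.
#' @return free monomer concentration, mol/L, in `[0, p_total]`.
#' @export
monomer_concentration <- function(p_total, k_dimer) {
  check_number(p_total, "p_total", lower = 0)
  check_number(k_dimer, "k_dimer", lower = 0, allow_zero = FALSE)
  args <- vctrs_recycle(p_total, k_dimer)
  p <- args[[1]]; k <- args[[2]]
  # conjugate form of (-K + sqrt(K^2 + 8KP))/4: no cancellation when
  # 8P << K (the fully monomeric limit)
  m <- 2 * k * p / (k + sqrt(k^2 + 8 * k * p))
  pmin(pmax(m, 0), p)
}

#' Monomer/dimer speciation table
#'
#' @inheritParams monomer_concentration
#' @return a tibble with `p_total`, `k_dimer`, `monomer` (`[M]`), `dimer`
#'   (`[D]`) and `monomer_fraction` (`[M]/[P]`, `NA` at `[P] = 0`).
#' @export
dimer_speciation <- function(p_total, k_dimer) {
  m <- monomer_concentration(p_total, k_dimer)
  args <- vctrs_recycle(p_total, k_dimer)
  p <- args[[1]]; k <- args[[2]]
  tibble(
    p_total = p, k_dimer = k, monomer = m, dimer = (p - m) / 2,
    monomer_fraction = ifelse(p > 0, m / p, NA_real_)
  )
}

#' Weight-average molecular weight of a monomer-dimer mixture
#'
#' The mass-weighted mean molecular weight,
#' `M_mono * ([M] + 4[D]) / ([M] + 2[D])`, bounded between the monomer and
#' dimer MWs. This is the quantity SEC-MALS reports for a rapidly
#' interconverting monomer/dimer mixture.
#'
#' @inheritParams monomer_concentration
#' @param m_mono monomer molecular weight, Da.
#' @return weight-average MW, Da. At `p_total = 0` returns `m_mono` with a
#'   warning (no protein, so the average is undefined).
#' @export
weight_average_mw <- function(p_total, k_dimer, m_mono) {
  check_number(m_mono, "m_mono", lower = 0, allow_zero = FALSE)
  sp <- dimer_speciation(p_total, k_dimer)
  if (any(sp$p_total == 0)) {
    warn("p_total = 0: returning the monomer MW.")
  }
  ifelse(sp$p_total > 0,
         m_mono * (sp$monomer + 4 * sp$dimer) / (sp$monomer + 2 * sp$dimer),
         m_mono)
}

#' Standard dilution-ITC injection schedule
#'
#' @param first_ul volume of the first (discarded) pre-injection, ul.
#' @param n_injections number of main injections.
#' @param injection_ul volume of each main injection, ul.
#' @return numeric vector of injection volumes in ul.
#' @export
itc_schedule <- function(first_ul = 0.2, n_injections = 17,
                         injection_ul = 2) {
  c(first_ul, rep(injection_ul, n_injections))
}

#' Forward model for dilution ITC of a dissociating dimer
#'
#' Predicts the heat of each injection when a concentrated, partly dimeric
#' protein stock is injected into buffer. The perfusion cell is treated
#' with the instantaneous-mixing-with-overflow convention: after injecting
#' volume `v` into cell volume `V0`, the cell concentration updates as
#' `P_i = P_{i-1} * (1 - v/V0) + P_syr * v/V0`. The heat of injection `i`
#' is the enthalpy of dissociation (per mole of dimer) times the moles of
#' dimer that dissociate on re-equilibration, relative to the no-reaction
#' mixture of cell carryover plus injected syringe material, plus a
#' constant blank heat:
#' `q_i = dH * (n_D,carryover + n_D,injected - n_D,equilibrated) + q_blank`.
#'
#' @param injections_ul injection volumes, ul (see [itc_schedule()]).
#' @param k_dimer dimer dissociation constant, mol/L.
#' @param dh_diss enthalpy of dissociation, J per mole of dimer
#'   (endothermic dissociation = positive heats).
#' @param syringe_uM syringe protein concentration, uM monomer equivalents.
#' @param cell_ul active cell volume, ul.
#' @param q_blank blank (mixing/dilution) heat per injection, uJ.
#' @param p0_uM initial cell protein concentration, uM (default 0: buffer).
#' @return a tibble with one row per injection: `injection`, `volume_ul`,
#'   `p_before_uM`, `p_after_uM`, `dimer_dissociated_nmol` and `heat_uJ`.
#' @export
itc_forward <- function(injections_ul, k_dimer, dh_diss,
                        syringe_uM = 300, cell_ul = 185,
                        q_blank = 0, p0_uM = 0) {
  check_number(injections_ul, "injections_ul", lower = 0, allow_zero = FALSE)
  check_number(k_dimer, "k_dimer", lower = 0, allow_zero = FALSE)
  core <- itc_core(injections_ul, k_dimer, syringe_uM, cell_ul, p0_uM)
  tibble(
    injection = seq_along(injections_ul),
    volume_ul = injections_ul,
    p_before_uM = core$p_before * 1e6,
    p_after_uM = core$p_after * 1e6,
    dimer_dissociated_nmol = core$n_diss * 1e9,
    heat_uJ = dh_diss * core$n_diss * 1e6 + q_blank
  )
}

# numeric core of the dilution forward model (no data-frame overhead; used
# inside the fitting objective)
#' @noRd
itc_core <- function(injections_ul, k_dimer, syringe_uM, cell_ul, p0_uM) {
  v0 <- cell_ul * 1e-6              # L
  p_syr <- syringe_uM * 1e-6        # M
  p <- p0_uM * 1e-6                 # M
  dimer_conc <- function(ptot) {
    (ptot - monomer_concentration(ptot, k_dimer)) / 2
  }
  d_syr <- dimer_conc(p_syr)
  n <- length(injections_ul)
  p_before <- p_after <- n_diss <- numeric(n)
  for (i in seq_len(n)) {
    v <- injections_ul[i] * 1e-6  # L
    f <- v / v0
    n_d_mix <- v0 * dimer_conc(p) * (1 - f) + v * d_syr
    p_new <- p * (1 - f) + p_syr * f
    n_diss[i] <- n_d_mix - v0 * dimer_conc(p_new)
    p_before[i] <- p
    p_after[i] <- p_new
    p <- p_new
  }
  list(p_before = p_before, p_after = p_after, n_diss = n_diss)
}

#' Fit the dimer-dissociation model to dilution-ITC heats
#'
#' Least-squares fit of (`K_dimer`, `dH_diss`) — and optionally a blank
#' heat per injection — to dilution heats using the forward model of
#' [itc_forward()]. `K_dimer` is fitted in log10 space with bounds
#' log10(K/M) in \[-9, -1\]. The first injection (typically a small
#' pre-injection) is excluded from the residuals by default but still
#' advances the concentration ledger. By default the blank is assumed
#' already subtracted (a buffer-into-buffer control is standard practice);
#' a free blank constant is nearly collinear with the tail of the
#' dissociation curve and substantially inflates the uncertainty of
#' `K_dimer`, so it is only fitted on request. Thermodynamics at
#' the 1 M standard state: `dG = -RT*ln(K_dimer / 1 M)`,
#' `dS = (dH - dG)/T`. When the fitted `K_dimer` sits at a bound the fit is
#' flagged `bound_only` — the data then only support a one-sided bound (a
#' dimer too tight, or too weak, to observe dissociating at these
#' concentrations). Identifiability is assessed by profiling the residual
#' sum of squares over log10(K) (dH and the blank are linear and profiled
#' out); when the 95% profile interval reaches a box bound, `bound_only`
#' is set and `k_limit` carries the supported one-sided limit.
#'
#' @param data a data frame with columns `volume_ul` and `heat_uJ`, one row
#'   per injection in order.
#' @param syringe_uM,cell_ul,p0_uM experiment geometry as in
#'   [itc_forward()].
#' @param temperature_C cell temperature, Celsius (default 30).
#' @param exclude_first drop the first injection from the fit (default
#'   `TRUE`).
#' @param fit_blank also fit a constant blank heat per injection (default
#'   `FALSE`: blank assumed subtracted, reported as 0).
#' @return an object of class `itc_fit` with `k_dimer` (mol/L), `dh`
#'   (J/mol dimer), `q_blank` (uJ), `dg`, `ds` (J/mol, J/mol/K),
#'   `temperature` (K), `bound_only`, `bound_side`, `k_limit`,
#'   `converged`, `data` (with fitted heats), `rss`.
#' @export
fit_itc <- function(data, syringe_uM = 300, cell_ul = 185,
                    temperature_C = 30, exclude_first = TRUE,
                    fit_blank = FALSE, p0_uM = 0) {
  data <- as_tibble(data)
  check_columns(data, c("volume_ul", "heat_uJ"), "ITC data")
  n_inj <- nrow(data)
  use <- if (exclude_first) seq_len(n_inj)[-1] else seq_len(n_inj)
  if (length(use) < 8) abort("need at least 8 usable injections.")
  heats <- data$heat_uJ
  vols <- data$volume_ul

  # dH and q_blank enter the model linearly, so the fit reduces to a 1-D
  # profile over log10(K): at each K the linear pair is solved exactly and
  # the profiled residual sum of squares is minimized over a grid plus a
  # local polish. This is robust to the near-flat profiles that arise when
  # K lies far from the working concentrations.
  profile_fit <- function(lk) {
    basis <- itc_core(vols, 10^lk, syringe_uM, cell_ul, p0_uM)$n_diss * 1e6
    if (fit_blank) {
      lm(heats[use] ~ basis[use])
    } else {
      lm(heats[use] ~ basis[use] - 1)
    }
  }
  profile_rss <- function(lk) sum(resid(profile_fit(lk))^2)
  lk_grid <- seq(-9, -1, by = 0.1)
  prof <- map_dbl(lk_grid, profile_rss)
  i_best <- which.min(prof)
  lo <- lk_grid[max(i_best - 1, 1)]
  hi <- lk_grid[min(i_best + 1, length(lk_grid))]
  opt <- stats::optimize(profile_rss, c(lo, hi), tol = 1e-7)
  lk <- opt$minimum
  cf <- coef(profile_fit(lk))
  if (fit_blank) {
    dh_hat <- if (length(cf) > 1 && is.finite(cf[[2]])) cf[[2]] else 0
    qb_hat <- cf[[1]]
  } else {
    dh_hat <- if (is.finite(cf[[1]])) cf[[1]] else 0
    qb_hat <- 0
  }
  best <- list(par = c(lk, dh_hat, qb_hat), value = opt$objective,
               convergence = 0)
  # 95% profile interval; if it reaches a box bound the data only support
  # a one-sided bound on K (e.g. a dimer too tight to watch dissociate)
  n_free <- length(use) - (if (fit_blank) 3 else 2)
  rss_min <- min(min(prof), best$value)
  crit <- rss_min * (1 + stats::qf(0.95, 1, n_free) / n_free) +
    1e-12 * max(heats^2)
  in_ci <- prof <= crit
  bound_only <- in_ci[1] || in_ci[length(in_ci)] ||
    lk <= -9 + 1e-3 || lk >= -1 - 1e-3
  bound_side <- if (!bound_only) {
    NA_character_
  } else if (in_ci[1] || lk <= -9 + 1e-3) "upper" else "lower"
  k <- 10^lk
  k_limit <- if (bound_only) {
    if (bound_side == "upper") 10^max(lk_grid[in_ci]) else
      10^min(lk_grid[in_ci])
  } else {
    NA_real_
  }
  t_k <- temperature_C + 273.15
  r_gas <- 8.31446
  dg <- -r_gas * t_k * log(k)
  fitted <- dh_hat * itc_core(vols, k, syringe_uM, cell_ul,
                              p0_uM)$n_diss * 1e6 + qb_hat
  structure(
    list(
      k_dimer = k, dh = best$par[2], q_blank = best$par[3],
      dg = dg, ds = (best$par[2] - dg) / t_k, temperature = t_k,
      bound_only = bound_only, bound_side = bound_side, k_limit = k_limit,
      converged = best$convergence == 0,
      data = mutate(data, fitted_uJ = fitted,
                    used = seq_len(n_inj) %in% use),
      rss = best$value
    ),
    class = "itc_fit"
  )
}

#' @export
print.itc_fit <- function(x, ...) {
  if (x$bound_only) {
    cat(sprintf(
      "<itc_fit> only a one-sided bound is supported: K_dimer %s %.3g M\n",
      if (x$bound_side == "upper") "<" else ">", x$k_limit))
  } else {
    cat(sprintf(
      "<itc_fit> K_dimer = %.4g M, dH = %.4g kJ/mol, dG = %.4g kJ/mol, dS = %.4g J/mol/K (T = %.2f K)\n",
      x$k_dimer, x$dh / 1000, x$dg / 1000, x$ds, x$temperature))
  }
  invisible(x)
}
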