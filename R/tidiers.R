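# broom-style tidy()/glance() methods for the fitted objects

#' @describeIn fit_hill tidy method: one row per parameter with bootstrap
#'   standard errors.
#' @param x a fitted object.
#' @param ... unused.
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble(
    term = c("kd", "n", "s0", "s1"),
    estimate = c(x$kd, x$n, x$s0, x$s1),
    std.error = unname(x$se[c("kd", "n", "s0", "s1")])
  )
}

#' @describeIn fit_hill glance method: one-row fit summary.
#' @export
glance.hill_fit <- function(x, ...) {
  tibble(
    kd = x$kd, hill_n = x$n, converged = x$converged, failed = x$failed,
    reason = x$reason, n_points = nrow(x$data), n_boot = x$n_boot
  )
}

#' @describeIn fit_desorption tidy method.
#' @param x a fitted object.
#' @param ... unused.
#' @export
tidy.desorption_fit <- function(x, ...) {
  tibble(
    term = c("midpoint", "slope", "pre", "post"),
    estimate = c(x$midpoint, x$slope, x$pre, x$post),
    std.error = c(unname(x$se["midpoint"]), NA_real_, NA_real_, NA_real_)
  )
}

#' @describeIn fit_desorption glance method.
#' @export
glance.desorption_fit <- function(x, ...) {
  tibble(midpoint = x$midpoint, slope = x$slope, converged = x$converged,
         failed = x$failed, reason = x$reason, n_points = nrow(x$data))
}

#' @describeIn fit_itc tidy method: thermodynamic parameters.
#' @param x a fitted object.
#' @param ... unused.
#' @export
tidy.itc_fit <- function(x, ...) {
  tibble(
    term = c("k_dimer", "dh", "dg", "ds", "q_blank"),
    estimate = c(x$k_dimer, x$dh, x$dg, x$ds, x$q_blank),
    unit = c("mol/L", "J/mol", "J/mol", "J/mol/K", "uJ")
  )
}

#' @describeIn fit_itc glance method.
#' @export
glance.itc_fit <- function(x, ...) {
  tibble(k_dimer = x$k_dimer, dh = x$dh, dg = x$dg, ds = x$ds,
         temperature = x$temperature, bound_only = x$bound_only,
         bound_side = x$bound_side, converged = x$converged, rss = x$rss)
}

#' @describeIn fit_decay tidy method.
#' @param x a fitted object.
#' @param ... unused.
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(term = c("tau_ms", "amplitude", "baseline"),
         estimate = c(x$tau_ms, x$amplitude, x$baseline))
}

#' @describeIn solvent_slope tidy method.
#' @param x a fitted object.
#' @param ... unused.
#' @export
tidy.solvent_slope <- function(x, ...) {
  tibble(term = c("m", "tau_h2o_inv", "tau_d2o_inv"),
         estimate = c(x$m, x$tau_h2o_inv, x$tau_d2o_inv),
         unit = "ms^-1")
}

#' @describeIn build_ssn tidy method: the edge table.
#' @param x a `lanm_ssn`.
#' @param ... unused.
#' @export
tidy.lanm_ssn <- function(x, ...) x$edges

#' @describeIn build_ssn glance method: node/edge counts.
#' @export
glance.lanm_ssn <- function(x, ...) {
  tibble(n_nodes = length(x$nodes), n_edges = nrow(x$edges),
         threshold = x$threshold, score_floor = x$score_floor,
         n_clusters = length(unique(connected_clusters(x)$cluster)))
}

#' @describeIn coordination_shell tidy method: the donor table.
#' @param x a `metal_sites` object.
#' @param ... unused.
#' @export
tidy.metal_sites <- function(x, ...) x$donors

#' @describeIn coordination_shell glance method: per-site coordination
#'   summary.
#' @export
glance.metal_sites <- function(x, ...) x$sites

#' @describeIn interface_bsa tidy method: per-residue buried area.
#' @param x an `interface_bsa` object.
#' @param ... unused.
#' @export
tidy.interface_bsa <- function(x, ...) x$per_residue

#' @describeIn interface_bsa glance method.
#' @export
glance.interface_bsa <- function(x, ...) {
  tibble(chain_a = x$chains[1], chain_b = x$chains[2],
         buried_total = x$buried_total,
         buried_per_side = x$buried_per_side,
         sasa_a = x$sasa_a, sasa_b = x$sasa_b, sasa_ab = x$sasa_ab)
}
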