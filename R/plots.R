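# ggplot2 autoplot methods for result objects

#' @describeIn fit_hill autoplot method: data and fitted Hill curve on a
#'   log free-metal axis.
#' @param object a fitted object.
#' @export
autoplot.hill_fit <- function(object, ...) {
  d <- object$data
  p <- ggplot(d, aes(x = .data$free, y = .data$signal)) +
    geom_point() +
    scale_x_log10() +
    labs(x = "free metal (M)", y = "signal") +
    theme_bw()
  if (object$converged) {
    grid <- tibble(free = 10^seq(log10(min(d$free)), log10(max(d$free)),
                                 length.out = 200))
    grid$signal <- hill_signal(grid$free, object$kd, object$n, object$s0,
                               object$s1)
    p <- p + geom_line(data = grid) +
      geom_vline(xintercept = object$kd, linetype = 2)
  }
  p
}

#' @describeIn fit_desorption autoplot method: desorption curve with
#'   fitted logistic and midpoint.
#' @param object a fitted object.
#' @export
autoplot.desorption_fit <- function(object, ...) {
  p <- ggplot(object$data, aes(x = .data$conc, y = .data$signal)) +
    geom_point() +
    scale_x_log10() +
    labs(x = "chelator (M)", y = "signal") +
    theme_bw()
  if (object$converged) {
    p <- p + geom_line(aes(y = .data$fitted)) +
      geom_vline(xintercept = object$midpoint, linetype = 2)
  }
  p
}

#' @describeIn fit_itc autoplot method: measured versus fitted injection
#'   heats.
#' @param object a fitted object.
#' @export
autoplot.itc_fit <- function(object, ...) {
  d <- mutate(object$data, injection = row_number())
  ggplot(d, aes(x = .data$injection)) +
    geom_col(aes(y = .data$heat_uJ), fill = "grey80", colour = "grey40") +
    geom_point(aes(y = .data$fitted_uJ)) +
    labs(x = "injection", y = "heat (uJ)") +
    theme_bw()
}

#' @describeIn fit_decay autoplot method: trace and single-exponential
#'   fit.
#' @param object a fitted object.
#' @param ... unused.
#' @export
autoplot.decay_fit <- function(object, ...) {
  p <- ggplot(object$data, aes(x = .data$time_us, y = .data$counts)) +
    geom_point(size = 0.6) +
    labs(x = "time (us)", y = "counts") +
    theme_bw()
  if (!object$failed) p <- p + geom_line(aes(y = .data$fitted))
  p
}

#' @describeIn solvent_slope autoplot method: decay rate versus D2O
#'   fraction with the fitted line.
#' @param object a fitted object.
#' @export
autoplot.solvent_slope <- function(object, ...) {
  ggplot(object$data, aes(x = .data$d2o_fraction, y = .data$rate)) +
    geom_point() +
    geom_line(aes(y = .data$fitted)) +
    labs(x = "D2O fraction", y = "1/tau (ms^-1)") +
    theme_bw()
}

#' Plot an elution profile
#'
#' @param table long elution table (`bed_volume`, `metal`, `conc`).
#' @return a ggplot object.
#' @export
plot_elution <- function(table) {
  ggplot(table, aes(x = .data$bed_volume, y = .data$conc,
                    colour = .data$metal)) +
    geom_line() +
    geom_point(size = 0.8) +
    labs(x = "bed volumes", y = "concentration (M)", colour = "metal") +
    theme_bw()
}
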