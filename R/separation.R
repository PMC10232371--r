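#' Rare-earth distribution ratios with the bead carryover correction
#'
#' For a batch equilibrium of metal-loaded sorbent beads, the distribution
#' ratio of each metal between the protein (sorbent) phase and the solution
#' phase is `D = [M]_LanM / [M]_Liquid` with `[M]_Liquid = [M]_ad` (the
#' supernatant at equilibrium) and the sorbent-phase concentration
#' corrected for free liquid absorbed on the beads:
#' `[M]_LanM = (V_de * [M]_de - V_bead * [M]_ad) / V_de`. With the default
#' volumes (4 ml strip, 1 ml beads) this is the familiar
#' `(4*[M]_de - [M]_ad) / 4`. Corrected concentrations that come out
#' negative (noise near zero) are clamped to 0 with a warning.
#'
#' @param data a data frame with columns `metal`, `m_ad` (solution phase at
#'   equilibrium) and `m_de` (acid strip), concentrations in any common
#'   unit.
#' @param v_de desorption (strip) volume, ml (default 4).
#' @param v_bead bead volume, ml (default 1).
#' @return a tibble with `metal`, `m_liquid`, `m_lanm`, `D` and flags
#'   `clamped` and `infinite` (`m_ad = 0` with metal on the beads gives an
#'   infinite D, flagged rather than an error).
#' @export
distribution_ratio <- function(data, v_de = 4, v_bead = 1) {
  data <- as_tibble(data)
  check_columns(data, c("metal", "m_ad", "m_de"), "batch data")
  check_number(v_de, "v_de", lower = 0, allow_zero = FALSE)
  check_number(v_bead, "v_bead", lower = 0, allow_zero = FALSE)
  if (any(data$m_ad < 0) || any(data$m_de < 0)) {
    abort("concentrations must be non-negative.")
  }
  m_lanm <- (v_de * data$m_de - v_bead * data$m_ad) / v_de
  clamped <- m_lanm < 0
  if (any(clamped)) {
    warn(sprintf("negative corrected sorbent concentration clamped to 0 for: %s",
                 paste(data$metal[clamped], collapse = ", ")))
    m_lanm[clamped] <- 0
  }
  d <- ifelse(data$m_ad > 0, m_lanm / data$m_ad,
              ifelse(m_lanm > 0, Inf, NA_real_))
  tibble(metal = data$metal, m_liquid = data$m_ad, m_lanm = m_lanm,
         D = d, clamped = clamped, infinite = is.infinite(d))
}

#' Separation factor between two metals
#'
#' `SF = D_RE1 / D_RE2`: the single-stage selectivity between two
#' rare-earth elements.
#'
#' @param d1,d2 distribution ratios.
#' @return the separation factor.
#' @export
separation_factor <- function(d1, d2) {
  check_number(d1, "d1", lower = 0)
  check_number(d2, "d2", lower = 0)
  if (any(d2 == 0)) abort("denominator distribution ratio is zero.")
  d1 / d2
}

#' Pairwise separation-factor matrix
#'
#' @param data a data frame with columns `metal` and `D` (e.g. from
#'   [distribution_ratio()]).
#' @return a tibble with `metal_1`, `metal_2` and `sf` for every ordered
#'   pair; the matrix is reciprocal (`sf(a,b) * sf(b,a) = 1`) with unit
#'   diagonal.
#' @export
separation_factors <- function(data) {
  data <- as_tibble(data)
  check_columns(data, c("metal", "D"), "distribution data")
  grid <- tidyr::expand_grid(metal_1 = data$metal, metal_2 = data$metal)
  grid |>
    left_join(rename(data[, c("metal", "D")], d1 = "D"),
              by = c(metal_1 = "metal")) |>
    left_join(rename(data[, c("metal", "D")], d2 = "D"),
              by = c(metal_2 = "metal")) |>
    mutate(sf = .data$d1 / .data$d2) |>
    select("metal_1", "metal_2", "sf")
}

#' Pooled purity and yield over elution windows
#'
#' Pools column fractions over user-specified bed-volume windows and
#' computes, per window and metal, the recovered moles, the purity
#' (`C_RE1 / sum(C_RE)`, as a percentage) and the yield (recovered over
#' loaded, as a percentage). The fraction volume is the bed-volume
#' increment times the bed volume in ml unless an explicit `volume_ml`
#' column is present; the first fraction's increment is taken from its own
#' bed-volume step (difference to the preceding fraction, or to 0).
#'
#' @param table elution data in long form: columns `bed_volume`
#'   (dimensionless, strictly increasing per metal), `metal` and `conc`
#'   (mol/L); optional `volume_ml`.
#' @param windows a data frame with columns `window` (label), `start` and
#'   `end` (bed volumes; a fraction belongs to a window when
#'   `start < bed_volume <= end`). Windows must not overlap.
#' @param loaded named numeric vector of loaded moles per metal.
#' @param bed_volume_ml bed volume in ml (default 0.7).
#' @return a tibble with `window`, `metal`, `moles`, `purity_pct` and
#'   `yield_pct`.
#' @export
purity_yield <- function(table, windows, loaded, bed_volume_ml = 0.7) {
  table <- as_tibble(table)
  check_columns(table, c("bed_volume", "metal", "conc"), "elution table")
  windows <- as_tibble(windows)
  check_columns(windows, c("window", "start", "end"), "windows")
  if (any(windows$end <= windows$start)) abort("window end must exceed start.")
  w <- windows[order(windows$start), ]
  if (nrow(w) > 1 && any(w$start[-1] < w$end[-nrow(w)] - 1e-12)) {
    abort("pooling windows overlap.")
  }
  metals <- unique(table$metal)
  if (!all(metals %in% names(loaded))) {
    abort("`loaded` must name every metal in the table.")
  }
  if (any(loaded[metals] <= 0)) abort("`loaded` must be positive per metal.")

  table <- table |>
    group_by(.data$metal) |>
    arrange(.data$bed_volume, .by_group = TRUE) |>
    mutate(dv = .data$bed_volume - dplyr::lag(.data$bed_volume,
                                              default = 0)) |>
    ungroup()
  if (any(table$dv <= 0)) abort("bed_volume must be strictly increasing.")
  vol_l <- if ("volume_ml" %in% names(table)) {
    table$volume_ml / 1000
  } else {
    table$dv * bed_volume_ml / 1000
  }
  table$moles <- table$conc * vol_l

  out <- map(seq_len(nrow(w)), function(i) {
    sel <- table$bed_volume > w$start[i] & table$bed_volume <= w$end[i]
    pooled <- table[sel, ] |>
      group_by(.data$metal) |>
      summarise(moles = sum(.data$moles), .groups = "drop")
    pooled <- left_join(tibble(metal = metals), pooled, by = "metal") |>
      mutate(moles = ifelse(is.na(.data$moles), 0, .data$moles))
    total <- sum(pooled$moles)
    tibble(
      window = w$window[i], metal = pooled$metal, moles = pooled$moles,
      purity_pct = if (total > 0) 100 * pooled$moles / total else NA_real_,
      yield_pct = 100 * pooled$moles / unname(loaded[pooled$metal])
    )
  })
  list_rbind(out)
}

#' Breakthrough point of a loading profile
#'
#' Finds, per metal, the first bed volume at which the effluent
#' concentration reaches a threshold fraction of the feed, interpolating
#' linearly between fractions.
#'
#' @param table elution data in long form (`bed_volume`, `metal`, `conc`).
#' @param feed_conc named numeric vector of feed concentrations per metal.
#' @param threshold_fraction effluent/feed ratio defining breakthrough
#'   (default 0.1).
#' @return a tibble with `metal`, `breakthrough_bv` (`NA` when the
#'   threshold is never reached) and `found`.
#' @export
breakthrough_point <- function(table, feed_conc, threshold_fraction = 0.1) {
  table <- as_tibble(table)
  check_columns(table, c("bed_volume", "metal", "conc"), "elution table")
  check_number(threshold_fraction, "threshold_fraction", lower = 0)
  metals <- unique(table$metal)
  if (!all(metals %in% names(feed_conc))) {
    abort("`feed_conc` must name every metal in the table.")
  }
  out <- map(metals, function(m) {
    d <- table[table$metal == m, ]
    d <- d[order(d$bed_volume), ]
    target <- threshold_fraction * feed_conc[[m]]
    above <- which(d$conc >= target)
    if (length(above) == 0) {
      return(tibble(metal = m, breakthrough_bv = NA_real_, found = FALSE))
    }
    i <- above[1]
    bv <- if (i == 1 || d$conc[i] == target || d$conc[i - 1] == 0) {
      # no prior signal to interpolate from (a sharp front arriving
      # within this fraction): report the fraction's bed volume
      d$bed_volume[i]
    } else {
      # linear interpolation across the crossing fraction
      x0 <- d$bed_volume[i - 1]; x1 <- d$bed_volume[i]
      y0 <- d$conc[i - 1]; y1 <- d$conc[i]
      x0 + (target - y0) / (y1 - y0) * (x1 - x0)
    }
    tibble(metal = m, breakthrough_bv = bv, found = TRUE)
  })
  list_rbind(out)
}
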