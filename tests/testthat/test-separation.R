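# distribution ratios, separation factors, purity/yield and breakthrough

test_that("distribution ratios apply the bead carryover correction", {
  # pure carryover (strip = ad/4): correction exactly cancels -> D = 0
  pure <- tibble::tibble(metal = "Nd", m_ad = 1e-3, m_de = 2.5e-4)
  expect_equal(distribution_ratio(pure)$D, 0)

  # direct evaluation of the printed correction
  d <- distribution_ratio(tibble::tibble(metal = "Nd", m_ad = 1e-3,
                                         m_de = 1e-3))
  expect_equal(d$m_lanm, 7.5e-4)
  expect_equal(d$D, 0.75)

  # homogeneity: doubling both concentrations leaves D unchanged
  d2 <- distribution_ratio(tibble::tibble(metal = "Nd", m_ad = 2e-3,
                                          m_de = 2e-3))
  expect_equal(d2$D, d$D)

  # generalized volumes reduce to the printed default
  dg <- distribution_ratio(tibble::tibble(metal = "Nd", m_ad = 1e-3,
                                          m_de = 1e-3),
                           v_de = 8, v_bead = 2)
  expect_equal(dg$D, 0.75)

  # noise below zero clamps with a warning
  expect_warning(
    dneg <- distribution_ratio(tibble::tibble(metal = "Dy", m_ad = 1e-3,
                                              m_de = 1e-5)),
    "clamped")
  expect_equal(dneg$D, 0)
  expect_true(dneg$clamped)

  # metal only on the beads -> infinite-D flag, not a crash
  dinf <- distribution_ratio(tibble::tibble(metal = "La", m_ad = 0,
                                            m_de = 1e-3))
  expect_true(dinf$infinite)
})

test_that("separation factors are ratios with reciprocal consistency", {
  expect_equal(separation_factor(0.5, 0.5), 1)
  expect_equal(separation_factor(0.75, 0.25), 3)
  expect_equal(separation_factor(0.2, 0.8) * separation_factor(0.8, 0.2), 1)
  expect_error(separation_factor(1, 0), "zero")

  sf <- separation_factors(tibble::tibble(metal = c("Nd", "Dy", "La"),
                                          D = c(0.9, 0.2, 1.5)))
  m <- tidyr::pivot_wider(sf, names_from = "metal_2", values_from = "sf")
  mat <- as.matrix(m[, -1])
  expect_equal(diag(mat), rep(1, 3), ignore_attr = TRUE)
  expect_equal(mat * t(mat), matrix(1, 3, 3), ignore_attr = TRUE)
})

test_that("pooled purities and yields follow the molar definitions", {
  # disjoint peaks: each pool is pure and quantitative
  peaks <- tibble::tibble(metal = c("Dy", "Nd"), center = c(5, 20),
                          width = c(0.8, 0.8),
                          loaded_nmol = c(50, 950))
  run <- gen_elution(peaks, noise = 0, seed = 1)
  out <- purity_yield(run$table,
                      windows = tibble::tibble(window = c("dy", "nd"),
                                               start = c(0, 12),
                                               end = c(12, 30)),
                      loaded = run$loaded * 1e9 * 1e-9)
  dy <- out[out$window == "dy" & out$metal == "Dy", ]
  nd <- out[out$window == "nd" & out$metal == "Nd", ]
  expect_equal(dy$purity_pct, 100, tolerance = 1e-6)
  expect_equal(nd$purity_pct, 100, tolerance = 1e-6)
  expect_equal(dy$yield_pct, 100, tolerance = 1e-6)
  expect_equal(nd$yield_pct, 100, tolerance = 1e-6)

  # two-metal purities in any pool sum to 100
  overlap <- gen_elution(tibble::tibble(metal = c("Dy", "Nd"),
                                        center = c(8, 11),
                                        width = c(1.5, 1.5),
                                        loaded_nmol = c(50, 950)),
                         noise = 0, seed = 2)
  pool <- purity_yield(overlap$table,
                       windows = tibble::tibble(window = "w",
                                                start = 4, end = 10),
                       loaded = overlap$loaded)
  expect_equal(sum(pool$purity_pct), 100)

  # yields over exhaustive disjoint pooling close to 100 per metal
  full <- purity_yield(overlap$table,
                       windows = tibble::tibble(window = c("a", "b", "c"),
                                                start = c(0, 10, 20),
                                                end = c(10, 20, 30)),
                       loaded = overlap$loaded)
  tot <- dplyr::summarise(dplyr::group_by(full, metal),
                          y = sum(yield_pct))
  expect_equal(tot$y, c(100, 100), tolerance = 1e-9)

  # overlapping windows are rejected
  expect_error(
    purity_yield(overlap$table,
                 windows = tibble::tibble(window = c("a", "b"),
                                          start = c(0, 5), end = c(10, 20)),
                 loaded = overlap$loaded),
    "overlap")
})

test_that("fraction-based purity matches a continuous trapezoid oracle", {
  centers <- c(8, 11); widths <- c(1.5, 1.5); loads <- c(50, 950) * 1e-9
  bvs <- seq(0.25, 30, by = 0.25)  # fine fractions approach the continuum
  run <- gen_elution(tibble::tibble(metal = c("Dy", "Nd"),
                                    center = centers, width = widths,
                                    loaded_nmol = c(50, 950)),
                     bed_volumes = bvs, noise = 0, seed = 3)
  out <- purity_yield(run$table,
                      windows = tibble::tibble(window = "w", start = 4,
                                               end = 10),
                      loaded = run$loaded)
  # continuous model: Gaussian density integrated over the window
  xs <- seq(4, 10, length.out = 4000)
  dens <- function(j) loads[j] * stats::dnorm(xs, centers[j], widths[j])
  m_or <- c(trapz(xs, dens(1)), trapz(xs, dens(2)))
  purity_oracle <- 100 * m_or[1] / sum(m_or)
  got <- out$purity_pct[out$metal == "Dy"]
  expect_lt(abs(got - purity_oracle), 0.1)
})

test_that("purity and yield are invariant to concentration rescaling", {
  run <- gen_elution(tibble::tibble(metal = c("Dy", "Nd"),
                                    center = c(8, 12), width = c(1, 1),
                                    loaded_nmol = c(100, 900)),
                     noise = 0.02, seed = 4)
  w <- tibble::tibble(window = "w", start = 5, end = 11)
  a <- purity_yield(run$table, w, run$loaded)
  scaled <- run$table
  scaled$conc <- scaled$conc * 1e6
  b <- purity_yield(scaled, w, run$loaded * 1e6)
  expect_equal(a$purity_pct, b$purity_pct)
  expect_equal(a$yield_pct, b$yield_pct)
})

test_that("breakthrough detection interpolates the crossing fraction", {
  # step profile rising at 10 bed volumes
  step <- tibble::tibble(bed_volume = 1:20, metal = "Nd",
                         conc = ifelse(1:20 >= 10, 1e-3, 0))
  bt <- breakthrough_point(step, c(Nd = 1e-3))
  expect_equal(bt$breakthrough_bv, 10)

  # linear ramp: closed-form crossing of the 10% threshold
  ramp <- tibble::tibble(bed_volume = 0:20, metal = "Nd",
                         conc = pmax(0:20 - 5, 0) / 15 * 1e-3)
  bt2 <- breakthrough_point(ramp, c(Nd = 1e-3), threshold_fraction = 0.1)
  # conc = (bv - 5)/15 mM crosses 0.1 mM at bv = 6.5
  expect_equal(bt2$breakthrough_bv, 6.5)

  # all-zero effluent -> none found
  zero <- tibble::tibble(bed_volume = 1:10, metal = "Dy", conc = 0)
  bt3 <- breakthrough_point(zero, c(Dy = 1e-3))
  expect_false(bt3$found)
  expect_true(is.na(bt3$breakthrough_bv))
})
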