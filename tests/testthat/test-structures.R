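# structure parsing, coordination spheres, denticity and interface area

minimal_model <- function() {
  new_structure_model(tibble::tibble(
    elety = c("OD1", "OD2", "LA"),
    resid = c("ASP", "ASP", "LA"),
    chain = "A", resno = c(1, 1, 99),
    x = c(2.5, 2.6, 0), y = c(0, 1.2, 0), z = 0,
    type = c("ATOM", "ATOM", "HETATM"),
    element = c("O", "O", "LA")
  ))
}

test_that("PDB writer/reader round-trips a minimal fixture", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(minimal_model(), path)
  m <- load_structure(path)
  expect_equal(nrow(m$atoms), 3)
  expect_equal(m$atoms$element, c("O", "O", "LA"))
  expect_equal(m$atoms$x, c(2.5, 2.6, 0), tolerance = 1e-3)

  site <- gen_metal_site(seed = 12, path = withr::local_tempfile(
    fileext = ".pdb"))
  back <- load_structure(site$path)
  expect_equal(nrow(back$atoms), nrow(site$model$atoms))
  expect_equal(back$atoms$x, site$model$atoms$x, tolerance = 1e-3)
  expect_equal(back$atoms$element, site$model$atoms$element)
})

test_that("malformed structure files raise parse errors", {
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  GLY A   1      ", "garbage"), bad)
  expect_error(load_structure(bad), "parse|coordinates|atoms")
  expect_error(load_structure("no/such/file.pdb"), "no such file")
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  OD1AASP A   1       1.000   0.000   0.000  0.40  0.00           O",
    "ATOM      2  OD1BASP A   1       2.000   0.000   0.000  0.60  0.00           O",
    "ATOM      3  OD2AASP A   1       3.000   0.000   0.000  0.50  0.00           O",
    "ATOM      4  OD2BASP A   1       4.000   0.000   0.000  0.50  0.00           O",
    "END"), path)
  m <- load_structure(path)
  expect_equal(nrow(m$atoms), 2)
  # highest occupancy wins; ties go to altloc A
  expect_equal(m$atoms$x[m$atoms$elety == "OD1"], 2)
  expect_equal(m$atoms$x[m$atoms$elety == "OD2"], 3)
})

test_that("metal sites are located by element and occupancy", {
  atoms <- tibble::tibble(
    elety = c("LA", "LA", "LA", "NA", "O"),
    resid = c("LA", "LA", "LA", "NA", "HOH"),
    chain = c("A", "A", "B", "B", "A"),
    resno = c(101, 102, 101, 103, 200),
    x = c(0, 10, 20, 30, 40), y = 0, z = 0,
    type = c(rep("HETATM", 5)),
    element = c("LA", "LA", "LA", "NA", "O")
  )
  m <- new_structure_model(atoms)
  sites <- find_metal_sites(m)
  expect_equal(nrow(sites), 4)
  expect_equal(sort(table(sites$element), decreasing = TRUE),
               sort(table(c("LA", "LA", "LA", "NA")), decreasing = TRUE),
               ignore_attr = TRUE)

  # metal-free model -> empty list
  empty <- new_structure_model(atoms[5, ])
  expect_equal(nrow(find_metal_sites(empty)), 0)

  # low-occupancy metals are excluded by default
  atoms$occupancy <- c(1, 0.3, 1, 1, 1)
  expect_equal(nrow(find_metal_sites(new_structure_model(atoms))), 3)
})

test_that("coordination shells count donors within the cutoff", {
  site <- gen_metal_site(cn_target = 10, n_decoys = 3, seed = 21)
  shell <- coordination_shell(site$model)
  expect_equal(shell$sites$coordination_number, 10)
  expect_equal(shell$sites$n_water, 0)
  # donors sorted by distance, all within cutoff
  expect_true(all(diff(shell$donors$distance) >= 0))
  expect_true(all(shell$donors$distance <= 3.0))

  # brute-force all-pairs oracle agrees
  s <- find_metal_sites(site$model)
  expect_equal(shell$sites$coordination_number,
               brute_cn(site$model, s[1, ]))

  # waters are counted and tagged
  wet <- gen_metal_site(cn_target = 9, n_waters = 2, seed = 22)
  shell_w <- coordination_shell(wet$model)
  expect_equal(shell_w$sites$coordination_number, 9)
  expect_equal(shell_w$sites$n_water, 2)

  # empty neighbourhood -> CN 0
  lone <- new_structure_model(tibble::tibble(
    elety = "LA", resid = "LA", chain = "A", resno = 1,
    x = 0, y = 0, z = 0, type = "HETATM", element = "LA"))
  expect_equal(coordination_shell(lone)$sites$coordination_number, 0)
})

test_that("carboxylate denticity classifies by the two-oxygen rule", {
  site <- gen_metal_site(
    cn_target = 9,
    denticity_plan = c("bidentate", "bidentate", "monodentate"),
    seed = 23)
  dent <- carboxylate_denticity(site$model)
  expect_equal(dent$mode, site$truth$denticity$mode)
  mono <- dent[dent$mode == "monodentate", ]
  expect_true(mono$d1 <= 3.0 && mono$d2 > 3.0)

  # explicit distances: one O at 2.4 A, the other at 3.6 A -> monodentate
  m <- minimal_model()
  m$atoms$x <- c(2.4, 3.6, 0); m$atoms$y <- 0
  expect_equal(carboxylate_denticity(m)$mode, "monodentate")
  # both at 2.5ish -> bidentate
  expect_equal(carboxylate_denticity(minimal_model())$mode, "bidentate")
})

test_that("denticity is invariant under rigid motion", {
  site <- gen_metal_site(
    cn_target = 10,
    denticity_plan = c("bidentate", "monodentate", "bidentate"),
    seed = 24)
  a <- carboxylate_denticity(site$model)
  b <- carboxylate_denticity(rotate_model(site$model))
  expect_equal(b$mode, a$mode)
  expect_equal(b$d1, a$d1, tolerance = 1e-9)
  expect_equal(b$d2, a$d2, tolerance = 1e-9)
  # coordination number too
  expect_equal(
    coordination_shell(rotate_model(site$model))$sites$coordination_number,
    coordination_shell(site$model)$sites$coordination_number)
})

test_that("pair distances honour selection and mode", {
  atoms <- tibble::tibble(
    elety = c("NH1", "NH2", "OE1"), resid = c("ARG", "ARG", "GLU"),
    chain = c("C", "C", "A"), resno = c(100, 100, 91),
    x = c(0, 0, 0), y = c(0, 1, 0), z = c(0, 0, 3),
    element = c("N", "N", "O"))
  m <- new_structure_model(atoms)
  d <- pair_distance(m, list(resno = 100, elety = c("NH1", "NH2", "NE")),
                     list(resno = 91, elety = c("OE1", "OE2")))
  expect_equal(d$distance, 3)
  dmax <- pair_distance(m, list(resno = 100), list(resno = 91),
                        mode = "max")
  expect_equal(dmax$distance, sqrt(1 + 9))
  # a selection against itself reports the distinct-pair distance
  self <- pair_distance(m, list(resno = 100), list(resno = 100))
  expect_equal(self$distance, 1)
  expect_error(pair_distance(m, list(resno = 1), list(resno = 91)),
               "no atoms")
})

test_that("buried interface area matches the two-sphere analytic oracle", {
  two <- function(d) new_structure_model(tibble::tibble(
    elety = "C", resid = "GLY", chain = c("A", "B"), resno = c(1, 2),
    x = c(0, d), y = 0, z = 0, element = "C"))
  r_exp <- 1.70 + 1.4
  for (d in c(1.0, 2.0, 4.0)) {
    bsa <- interface_bsa(two(d), "A", "B", n_points = 2000)
    analytic <- 2 * 2 * pi * r_exp * (r_exp - d / 2)
    expect_equal(bsa$buried_total, analytic,
                 tolerance = 0.02)
  }
  # far-apart chains bury nothing
  expect_equal(interface_bsa(two(100), "A", "B")$buried_total, 0)
})

test_that("interface area is symmetric and converged in point count", {
  site <- gen_metal_site(seed = 31)
  # build a small two-chain contact from two copies of the site shell
  a <- site$model$atoms
  b <- a
  b$chain <- "B"
  b$x <- b$x + 4.5
  m <- new_structure_model(dplyr::bind_rows(a, b))
  ab <- interface_bsa(m, "A", "B", n_points = 960)
  ba <- interface_bsa(m, "B", "A", n_points = 960)
  expect_equal(ab$buried_total, ba$buried_total, tolerance = 1e-12)
  expect_gt(ab$buried_total, 0)
  fine <- interface_bsa(m, "A", "B", n_points = 4000)
  expect_lt(abs(fine$buried_total - ab$buried_total) /
              max(fine$buried_total, 1), 0.01)
  # per-residue contributions sum to the total
  expect_equal(sum(ab$per_residue$buried), ab$buried_total,
               tolerance = 1e-9)
})

test_that("site comparison flags carboxylate shifts and CN changes", {
  ref <- gen_metal_site(
    cn_target = 10,
    denticity_plan = c("bidentate", "bidentate", "bidentate"),
    jitter = 0, seed = 41)
  # identical models: no deltas, no shifts
  same <- site_comparison(ref$model, ref$model)
  expect_equal(same$sites$delta_cn, 0)
  expect_equal(same$sites$n_shifts, 0)

  # move one carboxylate oxygen past the cutoff: one shift, CN down by one
  shifted <- ref$model
  i <- which(shifted$atoms$resid == "GLU" &
               shifted$atoms$elety == "OE2")[1]
  v <- c(shifted$atoms$x[i], shifted$atoms$y[i], shifted$atoms$z[i])
  v <- v / sqrt(sum(v^2)) * 3.6
  shifted$atoms$x[i] <- v[1]
  shifted$atoms$y[i] <- v[2]
  shifted$atoms$z[i] <- v[3]
  cmp <- site_comparison(ref$model, shifted)
  expect_equal(cmp$sites$delta_cn, -1)
  expect_equal(cmp$sites$n_shifts, 1)
  shift_row <- cmp$denticity[cmp$denticity$shifted, ]
  expect_equal(shift_row$mode_a, "bidentate")
  expect_equal(shift_row$mode_b, "monodentate")
})
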