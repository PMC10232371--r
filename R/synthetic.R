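# Seeded generators emulating every input the pipeline consumes. Each
# generator seeds its own RNG stream from its `seed` argument (restoring the
# caller's stream afterwards), so adding a generator never perturbs the
# output of another, and identical arguments reproduce identical output.

# background alphabet excludes D and N so that a background residue can
# never satisfy the position-1 class of the default EF-hand loop pattern,
# making planted loops the only matches by construction
BACKGROUND_AA <- c("A", "G", "K", "L", "V", "F", "I", "R", "Q", "H", "M",
                   "W", "Y")

#' @noRd
random_background <- function(n) {
  paste(sample(BACKGROUND_AA, n, replace = TRUE), collapse = "")
}

#' @noRd
make_loop <- function(p2 = TRUE) {
  # canonical lanmodulin-style loop: N1, D3, D5, T7 (backbone carbonyl
  # position), E9, E12; remaining positions from the background alphabet
  loop <- sample(BACKGROUND_AA, 12, replace = TRUE)
  loop[1] <- "N"; loop[3] <- "D"; loop[5] <- "D"; loop[7] <- "T"
  loop[9] <- "E"; loop[12] <- "E"
  loop[2] <- if (p2) "P" else "A"
  paste(loop, collapse = "")
}

#' Generate synthetic LanM-like sequences with planted EF-hand loops
#'
#' Builds `n` sequences: a fraction are true candidates with `n_hands`
#' planted 12-residue EF-hand loops at the requested spacings, the rest are
#' decoys in which each planted loop has its constrained position 12
#' residue replaced by a background residue (so the loop no longer matches
#' the scanner pattern). The background alphabet excludes Asp/Asn, making
#' planted loops the only possible matches. A truth table records every
#' planted offset and the expected verdict.
#'
#' @param n number of sequences.
#' @param n_hands EF hands per true sequence (default 4).
#' @param spacings residues between consecutive loops (recycled to
#'   `n_hands - 1`; default 12).
#' @param p2 proline at loop position 2 (single flag or per-hand vector).
#' @param n_term,c_term lengths of the flanking background segments.
#' @param decoy_fraction fraction of decoy sequences (default 0).
#' @param seed RNG seed.
#' @return a list with `records` (tibble `id`, `sequence`), `truth` (tibble
#'   `id`, `is_decoy`, `n_hands_planted`, `loop_starts` as comma string,
#'   `expected_verdict`) and `seed`.
#' @export
gen_lanm_sequences <- function(n = 10, n_hands = 4, spacings = 12,
                               p2 = TRUE, n_term = 10, c_term = 10,
                               decoy_fraction = 0, seed = 1) {
  if (any(spacings < 0)) abort("spacings must be non-negative.")
  spacings <- rep_len(spacings, max(n_hands - 1, 0))
  p2 <- rep_len(p2, n_hands)
  with_seed(seed, {
    is_decoy <- seq_len(n) <= round(n * decoy_fraction)
    is_decoy <- sample(is_decoy)
    recs <- map(seq_len(n), function(i) {
      loops <- map_chr(seq_len(n_hands), function(h) make_loop(p2[h]))
      if (is_decoy[i]) {
        # break the constrained position 12 so the loop cannot match
        loops <- map_chr(loops, function(l) {
          substr(l, 12, 12) <- sample(BACKGROUND_AA, 1)
          l
        })
      }
      starts <- integer(n_hands)
      seq <- random_background(n_term)
      for (h in seq_len(n_hands)) {
        starts[h] <- nchar(seq) + 1L
        seq <- paste0(seq, loops[h])
        if (h < n_hands) seq <- paste0(seq, random_background(spacings[h]))
      }
      seq <- paste0(seq, random_background(c_term))
      list(id = sprintf("synth%03d", i), sequence = seq,
           starts = starts, decoy = is_decoy[i])
    })
    records <- tibble(id = map_chr(recs, "id"),
                      sequence = map_chr(recs, "sequence"))
    truth <- tibble(
      id = map_chr(recs, "id"),
      is_decoy = map_lgl(recs, "decoy"),
      n_hands_planted = n_hands,
      loop_starts = map_chr(recs, function(r) {
        paste(r$starts, collapse = ",")
      }),
      expected_verdict = ifelse(
        map_lgl(recs, "decoy") | n_hands < 4 | !any(p2) |
          (length(spacings) > 0 && min(spacings) > 13) |
          nchar(records$sequence) >= 200,
        "fail", "pass")
    )
    list(records = records, truth = truth, seed = seed)
  })
}

#' Generate a synthetic (optionally chelator-buffered) Hill titration
#'
#' Samples the Hill response on a log-uniform free-metal grid and applies
#' multiplicative Gaussian noise. For a buffered titration the generator
#' designs the chelator-buffer schedule that produces those free
#' concentrations (via [buffered_total_metal()]), so a downstream fit must
#' recompute the free metal from the mass balance.
#'
#' @param kd true apparent dissociation constant, mol/L.
#' @param hill_n true Hill coefficient.
#' @param n_points number of titration points (default 12).
#' @param conc_range free-metal range, mol/L (default `kd * c(1e-2, 1e2)`).
#' @param s0,s1 baseline and plateau signals.
#' @param noise multiplicative Gaussian noise level (s.d. as a fraction of
#'   the signal; default 0).
#' @param buffered design a chelator-buffered schedule (default `FALSE`).
#' @param total_chelator,k_cond buffer composition used when `buffered`.
#' @param seed RNG seed.
#' @return a list with `data` (tibble ready for [fit_hill()]) and `truth`
#'   (list of the generating parameters).
#' @export
gen_titration <- function(kd, hill_n, n_points = 12,
                          conc_range = kd * c(1e-2, 1e2),
                          s0 = 0, s1 = 1, noise = 0, buffered = FALSE,
                          total_chelator = 5e-3, k_cond = 1e7, seed = 1) {
  check_number(kd, "kd", lower = 0, allow_zero = FALSE)
  free <- 10^seq(log10(conc_range[1]), log10(conc_range[2]),
                 length.out = n_points)
  signal <- hill_signal(free, kd, hill_n, s0, s1)
  with_seed(seed, {
    if (noise > 0) signal <- signal * (1 + rnorm(n_points, 0, noise))
    data <- if (buffered) {
      tibble(
        total_metal = buffered_total_metal(free, total_chelator, k_cond),
        total_chelator = total_chelator, k_cond = k_cond, signal = signal
      )
    } else {
      tibble(conc = free, signal = signal)
    }
    list(
      data = data,
      truth = list(kd = kd, hill_n = hill_n, s0 = s0, s1 = s1,
                   free = free, noise = noise, buffered = buffered,
                   seed = seed)
    )
  })
}

#' Generate a synthetic chelator-desorption curve
#'
#' Four-parameter logistic on log10 chelator concentration with
#' multiplicative Gaussian noise; emulates a fluorescence-reported
#' desorption titration.
#'
#' @param midpoint chelator concentration at 50% desorption, mol/L.
#' @param slope logistic slope (default 1).
#' @param conc_range titrated range, mol/L.
#' @param pre,post plateau signals before/after desorption.
#' @param n_points,noise,seed as in [gen_titration()].
#' @return a list with `data` (tibble `conc`, `signal`) and `truth`.
#' @export
gen_desorption <- function(midpoint, slope = 1,
                           conc_range = midpoint * c(1e-2, 1e2),
                           pre = 1, post = 0, n_points = 12, noise = 0,
                           seed = 1) {
  conc <- 10^seq(log10(conc_range[1]), log10(conc_range[2]),
                 length.out = n_points)
  signal <- post + (pre - post) /
    (1 + 10^(slope * (log10(conc) - log10(midpoint))))
  with_seed(seed, {
    if (noise > 0) signal <- signal * (1 + rnorm(n_points, 0, noise))
    list(data = tibble(conc = conc, signal = signal),
         truth = list(midpoint = midpoint, slope = slope, pre = pre,
                      post = post, noise = noise, seed = seed))
  })
}

#' Generate synthetic dilution-ITC heats from the dimer-dissociation model
#'
#' Runs the forward model of [itc_forward()] over an injection schedule and
#' applies multiplicative Gaussian noise to the per-injection heats.
#'
#' @param k_dimer true dimer dissociation constant, mol/L.
#' @param dh_diss true enthalpy of dissociation, J per mole of dimer.
#' @param injections_ul injection schedule, ul (default [itc_schedule()]).
#' @param syringe_uM,cell_ul,q_blank,p0_uM geometry as in [itc_forward()].
#' @param noise multiplicative Gaussian noise level.
#' @param seed RNG seed.
#' @return a list with `data` (tibble `volume_ul`, `heat_uJ`) and `truth`.
#' @export
gen_itc <- function(k_dimer, dh_diss, injections_ul = itc_schedule(),
                    syringe_uM = 300, cell_ul = 185, q_blank = 0,
                    p0_uM = 0, noise = 0, seed = 1) {
  fwd <- itc_forward(injections_ul, k_dimer, dh_diss,
                     syringe_uM = syringe_uM, cell_ul = cell_ul,
                     q_blank = q_blank, p0_uM = p0_uM)
  with_seed(seed, {
    heats <- fwd$heat_uJ
    if (noise > 0) heats <- heats * (1 + rnorm(length(heats), 0, noise))
    list(
      data = tibble(volume_ul = fwd$volume_ul, heat_uJ = heats),
      truth = list(k_dimer = k_dimer, dh_diss = dh_diss,
                   q_blank = q_blank, syringe_uM = syringe_uM,
                   cell_ul = cell_ul, noise = noise, seed = seed)
    )
  })
}

#' Generate synthetic luminescence decays across a D2O series
#'
#' Builds per-fraction lifetimes from the linear rate model
#' `1/tau(f) = 1/tau_h2o + m * f` (rates in ms^-1, `f` the D2O fraction),
#' then synthesizes a decay trace for each fraction on a microsecond grid
#' with either multiplicative Gaussian or Poisson counting noise.
#'
#' @param tau_h2o_ms lifetime in pure H2O, ms.
#' @param m rate slope versus D2O fraction, ms^-1 (negative: D2O slows
#'   quenching).
#' @param fractions D2O fractions (default `c(0, 0.25, 0.5, 0.75)`).
#' @param span_us trace window, us (default 2500).
#' @param n_t points per trace (default 250).
#' @param amplitude peak counts (default 5000).
#' @param baseline constant offset counts.
#' @param noise relative Gaussian noise on counts; ignored when
#'   `poisson = TRUE`.
#' @param poisson use Poisson counting noise instead (default `FALSE`).
#' @param seed RNG seed.
#' @return a list with `traces` (tibble `d2o_fraction`, `time_us`,
#'   `counts`), `series` (tibble `d2o_fraction`, `tau_ms` of the true
#'   lifetimes) and `truth` (including the implied hydration number
#'   `q = 1.11 * (-m - 0.31 + 0.075)` for the default amide-only
#'   oscillator counts).
#' @export
gen_decay_series <- function(tau_h2o_ms, m,
                             fractions = c(0, 0.25, 0.5, 0.75),
                             span_us = 2500, n_t = 250, amplitude = 5000,
                             baseline = 0, noise = 0, poisson = FALSE,
                             seed = 1) {
  check_number(tau_h2o_ms, "tau_h2o_ms", lower = 0, allow_zero = FALSE)
  rates <- 1 / tau_h2o_ms + m * fractions  # ms^-1
  if (any(rates <= 0)) abort("rate model gives non-positive rates.")
  taus_ms <- 1 / rates
  t_us <- seq(0, span_us, length.out = n_t)
  with_seed(seed, {
    traces <- map(seq_along(fractions), function(i) {
      ideal <- amplitude * exp(-t_us / (taus_ms[i] * 1000)) + baseline
      counts <- if (poisson) {
        rpois(n_t, ideal)
      } else if (noise > 0) {
        pmax(ideal * (1 + rnorm(n_t, 0, noise)), 0)
      } else {
        ideal
      }
      tibble(d2o_fraction = fractions[i], time_us = t_us, counts = counts)
    })
    list(
      traces = list_rbind(traces),
      series = tibble(d2o_fraction = fractions, tau_ms = taus_ms),
      truth = list(tau_h2o_ms = tau_h2o_ms, m = m,
                   q = q_from_slope(m), fractions = fractions,
                   noise = noise, poisson = poisson, seed = seed)
    )
  })
}

#' Generate a synthetic two-metal elution profile
#'
#' Gaussian elution peaks per metal over a bed-volume grid. Each fraction
#' carries the exact integral of the peak over its bed-volume interval,
#' normalized so the eluted moles equal the loaded moles (mass-balance
#' closure), with optional multiplicative noise on the concentrations.
#'
#' @param peaks a tibble with one row per metal: `metal`, `center` (bed
#'   volumes), `width` (s.d. in bed volumes), `loaded_nmol`.
#' @param bed_volumes sampling grid (fraction upper edges).
#' @param bed_volume_ml bed volume, ml (default 0.7).
#' @param noise relative Gaussian noise on concentrations.
#' @param seed RNG seed.
#' @return a list with `table` (long tibble `bed_volume`, `metal`, `conc`
#'   in mol/L), `loaded` (named vector, mol) and `truth`.
#' @export
gen_elution <- function(peaks, bed_volumes = seq(0.5, 30, by = 0.5),
                        bed_volume_ml = 0.7, noise = 0, seed = 1) {
  peaks <- as_tibble(peaks)
  check_columns(peaks, c("metal", "center", "width", "loaded_nmol"),
                "`peaks`")
  dv <- diff(c(0, bed_volumes))
  if (any(dv <= 0)) abort("bed_volumes must be strictly increasing.")
  vol_l <- dv * bed_volume_ml / 1000
  with_seed(seed, {
    rows <- map(seq_len(nrow(peaks)), function(i) {
      edges <- c(0, bed_volumes)
      cdf <- stats::pnorm(edges, peaks$center[i], peaks$width[i])
      shape <- diff(cdf)
      moles <- shape / sum(shape) * peaks$loaded_nmol[i] * 1e-9
      conc <- moles / vol_l
      if (noise > 0) conc <- pmax(conc * (1 + rnorm(length(conc), 0, noise)), 0)
      tibble(bed_volume = bed_volumes, metal = peaks$metal[i], conc = conc)
    })
    list(
      table = list_rbind(rows),
      loaded = setNames(peaks$loaded_nmol * 1e-9, peaks$metal),
      truth = list(peaks = peaks, bed_volume_ml = bed_volume_ml,
                   noise = noise, seed = seed)
    )
  })
}

#' Generate an idealized metal coordination site
#'
#' Places a metal ion at the origin and donor oxygens on a sphere of the
#' requested shell radius (with optional jitter), following a denticity
#' plan for carboxylate residues (bidentate: both oxygens inside the
#' cutoff; monodentate: the second oxygen displaced outside), plus
#' optional waters, decoy atoms beyond the cutoff, and Asn OD1 donors.
#' Returns both an in-memory model and, optionally, a valid minimal PDB
#' file.
#'
#' @param cn_target total donor count inside the shell (oxygens; made up
#'   of the carboxylate plan plus monodentate Asn/water donors).
#' @param denticity_plan character vector over carboxylate residues, each
#'   `"bidentate"` or `"monodentate"` (default two bidentate Asp + one
#'   bidentate Glu).
#' @param n_waters waters inside the shell (default 0).
#' @param n_decoys oxygen atoms placed beyond the cutoff (default 2).
#' @param shell_radius donor distance, A (default 2.5).
#' @param outer_radius distance for displaced/decoy atoms, A (default 3.6).
#' @param jitter s.d. of radial jitter, A (default 0.05).
#' @param metal element symbol (default `"LA"`).
#' @param path optional path to also write a PDB file.
#' @param seed RNG seed.
#' @return a list with `model` (a `structure_model`), `truth` (expected
#'   coordination number, waters and per-residue denticity table) and
#'   `path` (or `NULL`).
#' @export
gen_metal_site <- function(cn_target = 10,
                           denticity_plan = c("bidentate", "bidentate",
                                              "bidentate"),
                           n_waters = 0, n_decoys = 2, shell_radius = 2.5,
                           outer_radius = 3.6, jitter = 0.05,
                           metal = "LA", path = NULL, seed = 1) {
  n_carbox_o <- sum(ifelse(denticity_plan == "bidentate", 2L, 1L))
  n_rest <- cn_target - n_carbox_o - n_waters
  if (n_rest < 0) {
    abort("denticity plan plus waters exceeds the target coordination number.")
  }
  with_seed(seed, {
    # deterministic, well-spread shell directions
    n_shell <- cn_target + length(denticity_plan) + n_decoys
    dirs <- sphere_points(max(n_shell, 4))
    k <- 0
    next_dir <- function() {
      k <<- k + 1
      dirs[k, ]
    }
    rad <- function(r) max(r + rnorm(1, 0, jitter), 0.1)
    atoms <- list()
    add_atom <- function(elety, resid, chain, resno, pos, type = "ATOM",
                         element = substr(elety, 1, 1)) {
      atoms[[length(atoms) + 1]] <<- tibble(
        type = type, elety = elety, resid = resid, chain = chain,
        resno = resno, x = unname(pos[1]), y = unname(pos[2]),
        z = unname(pos[3]), element = element
      )
    }
    resno <- 0
    dent_truth <- list()
    for (mode in denticity_plan) {
      resno <- resno + 1
      resid <- if (resno %% 2 == 1) "ASP" else "GLU"
      o1 <- if (resid == "ASP") "OD1" else "OE1"
      o2 <- if (resid == "ASP") "OD2" else "OE2"
      d1 <- next_dir() * rad(shell_radius)
      add_atom(o1, resid, "A", resno, d1)
      if (mode == "bidentate") {
        # second oxygen close to the first, still inside the cutoff
        d2 <- d1 + next_dir() * 0.8
        d2 <- d2 / sqrt(sum(d2^2)) * rad(shell_radius + 0.1)
      } else {
        d2 <- d1 / sqrt(sum(d1^2)) * rad(outer_radius)
      }
      add_atom(o2, resid, "A", resno, d2)
      dent_truth[[length(dent_truth) + 1]] <-
        tibble(resno = resno, resid = resid, mode = mode)
    }
    for (i in seq_len(max(n_rest, 0))) {
      resno <- resno + 1
      add_atom("OD1", "ASN", "A", resno, next_dir() * rad(shell_radius))
    }
    for (i in seq_len(n_waters)) {
      resno <- resno + 1
      add_atom("O", "HOH", "A", 500 + i, next_dir() * rad(shell_radius),
               type = "HETATM")
    }
    for (i in seq_len(n_decoys)) {
      resno <- resno + 1
      add_atom("OD1", "ASN", "A", resno, next_dir() * rad(outer_radius))
    }
    add_atom(metal, metal, "A", 999, c(0, 0, 0), type = "HETATM",
             element = metal)
    model <- new_structure_model(list_rbind(atoms), source = "gen_metal_site")
    if (!is.null(path)) write_structure(model, path)
    list(
      model = model,
      truth = list(
        coordination_number = cn_target,
        n_waters = n_waters,
        denticity = list_rbind(dent_truth),
        metal = metal, seed = seed
      ),
      path = path
    )
  })
}
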