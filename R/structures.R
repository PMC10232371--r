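# Lanthanide coordination-site geometry from macromolecular structures.
# Parsing is delegated to bio3d; all geometric analysis is done on a plain
# atom tibble so synthetic fixtures and deposited structures share one path.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
VDW_DEFAULT <- 1.80
WATER_RESIDS <- c("HOH", "WAT", "DOD", "H2O")

#' Load a macromolecular structure into an atom table
#'
#' Reads a PDB or mmCIF file (by extension) and applies the alternate
#' location policy: for each (chain, residue, atom name) the highest
#' occupancy conformer is kept, ties going to altloc `"A"` (alphabetically
#' first).
#'
#' @param path path to a `.pdb`/`.ent` or `.cif` file.
#' @return an object of class `structure_model`: a list with `atoms` (a
#'   tibble with columns `type`, `eleno`, `elety`, `alt`, `resid`, `chain`,
#'   `resno`, `x`, `y`, `z`, `occupancy`, `element`) and `source`.
#' @export
load_structure <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    suppressWarnings(
      if (is_cif) bio3d::read.cif(path) else
        bio3d::read.pdb(path, rm.alt = FALSE)
    ),
    error = function(e) {
      abort(sprintf("failed to parse %s: %s", path, conditionMessage(e)))
    }
  )
  atoms <- as_tibble(pdb$atom)
  if (nrow(atoms) == 0) abort(sprintf("no atoms parsed from %s", path))
  atoms <- tibble(
    type = atoms$type,
    eleno = atoms$eleno,
    elety = toupper(trimws(atoms$elety)),
    alt = ifelse(is.na(atoms$alt) | atoms$alt == "", "", atoms$alt),
    resid = toupper(trimws(atoms$resid)),
    chain = ifelse(is.na(atoms$chain), "", atoms$chain),
    resno = atoms$resno,
    x = atoms$x, y = atoms$y, z = atoms$z,
    occupancy = ifelse(is.na(atoms$o), 1, atoms$o),
    element = toupper(trimws(ifelse(is.na(atoms$elesy) | atoms$elesy == "",
                                    substr(trimws(atoms$elety), 1, 1),
                                    atoms$elesy)))
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    bad <- which(!is.finite(atoms$x) | !is.finite(atoms$y) |
                   !is.finite(atoms$z))[1]
    abort(sprintf("non-finite coordinates at atom record %d of %s",
                  bad, path))
  }
  atoms <- apply_altloc_policy(atoms)
  new_structure_model(atoms, source = path)
}

#' @noRd
apply_altloc_policy <- function(atoms) {
  atoms |>
    group_by(.data$chain, .data$resno, .data$resid, .data$elety) |>
    arrange(desc(.data$occupancy), .data$alt, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    arrange(.data$eleno)
}

#' Construct a structure model from an atom table
#'
#' Used by the synthetic fixture generator and anywhere an atom tibble is
#' assembled in code. Missing optional columns are filled with defaults.
#'
#' @param atoms a data frame with at least `elety`, `resid`, `chain`,
#'   `resno`, `x`, `y`, `z`; optional `type`, `eleno`, `alt`, `occupancy`,
#'   `element`.
#' @param source provenance label.
#' @return a `structure_model`.
#' @export
new_structure_model <- function(atoms, source = "in-memory") {
  atoms <- as_tibble(atoms)
  check_columns(atoms, c("elety", "resid", "chain", "resno", "x", "y", "z"),
                "`atoms`")
  n <- nrow(atoms)
  defaults <- list(
    type = rep("ATOM", n), eleno = seq_len(n), alt = rep("", n),
    occupancy = rep(1, n),
    element = toupper(substr(trimws(atoms$elety), 1, 1))
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(atoms)) atoms[[nm]] <- defaults[[nm]]
  }
  atoms <- atoms[, c("type", "eleno", "elety", "alt", "resid", "chain",
                     "resno", "x", "y", "z", "occupancy", "element")]
  structure(list(atoms = atoms, source = source), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms, %d chain(s) [%s]\n",
              nrow(x$atoms), length(unique(x$atoms$chain)), x$source))
  invisible(x)
}

#' Write a structure model as a minimal PDB file
#'
#' Emits standard fixed-column ATOM/HETATM records (plus END). The writer
#' is exact to 3 decimal places in the coordinates, which round-trips
#' through [load_structure()].
#'
#' @param model a `structure_model` (or bare atom tibble).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  atoms <- if (inherits(model, "structure_model")) model$atoms else
    new_structure_model(model)$atoms
  name_field <- function(elety, element) {
    # atom names start in column 14 unless 4 characters or a 2-letter element
    ifelse(nchar(elety) >= 4 | nchar(element) == 2,
           formatC(elety, width = -4),
           paste0(" ", formatC(elety, width = -3)))
  }
  lines <- sprintf(
    "%-6s%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    atoms$type, atoms$eleno %% 100000L,
    name_field(atoms$elety, atoms$element),
    ifelse(nzchar(atoms$alt), substr(atoms$alt, 1, 1), " "),
    atoms$resid,
    ifelse(nzchar(atoms$chain), substr(atoms$chain, 1, 1), " "),
    atoms$resno, atoms$x, atoms$y, atoms$z, atoms$occupancy, 0,
    atoms$element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Locate metal ion sites in a structure
#'
#' Finds heteroatom records whose element matches the requested set (by
#' default the lanthanides studied here plus the Na and Ca ions that can
#' occupy EF hands) and with occupancy at or above `min_occupancy`.
#'
#' @param model a `structure_model`.
#' @param elements element symbols to treat as metal sites.
#' @param min_occupancy minimum occupancy for a site (default 0.5).
#' @return a tibble with one row per site, ordered by chain then residue:
#'   `site` (index), `chain`, `resno`, `resid`, `element`, `x`, `y`, `z`,
#'   `occupancy`.
#' @export
find_metal_sites <- function(model,
                             elements = c("LA", "DY", "ND", "EU", "NA", "CA"),
                             min_occupancy = 0.5) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  sel <- a$type == "HETATM" & a$element %in% toupper(elements) &
    a$occupancy >= min_occupancy
  sites <- a[sel, ] |>
    arrange(.data$chain, .data$resno) |>
    mutate(site = row_number()) |>
    select("site", "chain", "resno", "resid", "element",
           "x", "y", "z", "occupancy")
  sites
}

#' @noRd
dist_to_point <- function(atoms, px, py, pz) {
  sqrt((atoms$x - px)^2 + (atoms$y - py)^2 + (atoms$z - pz)^2)
}

#' First coordination sphere of metal sites
#'
#' For each metal site, collects all oxygen and nitrogen atoms (protein or
#' solvent; the metal's own record excluded) within `cutoff` of the metal,
#' reporting distances and a donor class. The coordination number is the
#' donor count; waters are tagged so solvent-excluded and solvent-bearing
#' sites can be compared explicitly.
#'
#' @param model a `structure_model`.
#' @param sites site table from [find_metal_sites()] (default: computed).
#' @param cutoff donor distance cutoff in Angstrom (default 3.0; typical
#'   Ln-O bonds are 2.3-2.7 A).
#' @return an object of class `metal_sites`: a list with `sites` (the site
#'   table plus `coordination_number` and `n_water`) and `donors` (tibble
#'   `site`, `chain`, `resno`, `resid`, `elety`, `element`, `distance`,
#'   `class` in protein_O/protein_N/water/other, sorted by distance within
#'   site).
#' @export
coordination_shell <- function(model, sites = find_metal_sites(model),
                               cutoff = 3.0) {
  stopifnot(inherits(model, "structure_model"))
  check_number(cutoff, "cutoff", lower = 0, allow_zero = FALSE)
  a <- model$atoms
  donors <- map(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    cand <- a[a$element %in% c("O", "N"), ]
    # exclude the metal's own residue record
    cand <- cand[!(cand$chain == s$chain & cand$resno == s$resno &
                     cand$resid == s$resid), ]
    d <- dist_to_point(cand, s$x, s$y, s$z)
    keep <- d <= cutoff
    if (!any(keep)) return(NULL)
    cand <- cand[keep, ]
    tibble(
      site = s$site, chain = cand$chain, resno = cand$resno,
      resid = cand$resid, elety = cand$elety, element = cand$element,
      distance = d[keep],
      class = dplyr::case_when(
        cand$resid %in% WATER_RESIDS ~ "water",
        cand$type == "ATOM" & cand$element == "O" ~ "protein_O",
        cand$type == "ATOM" & cand$element == "N" ~ "protein_N",
        TRUE ~ "other"
      )
    ) |>
      arrange(.data$distance)
  })
  donors <- list_rbind(purrr::compact(donors))
  if (nrow(sites) == 0 || is.null(donors) || nrow(donors) == 0) {
    donors <- tibble(site = integer(), chain = character(),
                     resno = integer(), resid = character(),
                     elety = character(), element = character(),
                     distance = numeric(), class = character())
  }
  counts <- donors |>
    group_by(.data$site) |>
    summarise(coordination_number = n(),
              n_water = sum(.data$class == "water"), .groups = "drop")
  sites <- left_join(sites, counts, by = "site") |>
    mutate(
      coordination_number = ifelse(is.na(.data$coordination_number), 0L,
                                   .data$coordination_number),
      n_water = ifelse(is.na(.data$n_water), 0L, .data$n_water)
    )
  structure(list(sites = sites, donors = donors, cutoff = cutoff),
            class = "metal_sites")
}

#' @export
print.metal_sites <- function(x, ...) {
  cat(sprintf("<metal_sites> %d site(s), cutoff %.2f A\n",
              nrow(x$sites), x$cutoff))
  print(x$sites)
  invisible(x)
}

#' Carboxylate denticity at metal sites
#'
#' Groups coordinating carboxylate oxygens by their parent Asp (OD1/OD2) or
#' Glu (OE1/OE2) residue and classifies each as bidentate (both oxygens
#' within `cutoff` of the metal), monodentate (exactly one) or
#' non-coordinating. Asp/Glu residues are reported when at least one
#' carboxylate oxygen lies within `cutoff + slack` of the metal, so that a
#' carboxylate shifted just past the cutoff still appears (as monodentate
#' or non-coordinating) rather than silently vanishing.
#'
#' @inheritParams coordination_shell
#' @param slack extra margin for reporting near-miss carboxylates (default
#'   1.0 A).
#' @return a tibble with `site`, `chain`, `resno`, `resid`, `o1`, `o2`
#'   (atom names), `d1`, `d2` (distances, A) and `mode`.
#' @export
carboxylate_denticity <- function(model, sites = find_metal_sites(model),
                                  cutoff = 3.0, slack = 1.0) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  carbox <- a[(a$resid == "ASP" & a$elety %in% c("OD1", "OD2")) |
                (a$resid == "GLU" & a$elety %in% c("OE1", "OE2")), ]
  out <- map(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    if (nrow(carbox) == 0) return(NULL)
    d <- dist_to_point(carbox, s$x, s$y, s$z)
    cand <- mutate(carbox, distance = d)
    calls <- cand |>
      group_by(.data$chain, .data$resno, .data$resid) |>
      summarise(
        o1 = .data$elety[which.min(.data$distance)],
        d1 = min(.data$distance),
        o2 = .data$elety[which.max(.data$distance)],
        d2 = max(.data$distance),
        n_atoms = n(), .groups = "drop"
      ) |>
      filter(.data$n_atoms == 2, .data$d1 <= cutoff + slack) |>
      mutate(
        site = s$site,
        mode = dplyr::case_when(
          .data$d1 <= cutoff & .data$d2 <= cutoff ~ "bidentate",
          .data$d1 <= cutoff ~ "monodentate",
          TRUE ~ "non-coordinating"
        )
      ) |>
      select("site", "chain", "resno", "resid", "o1", "o2", "d1", "d2",
             "mode")
    if (nrow(calls) == 0) NULL else calls
  })
  out <- list_rbind(purrr::compact(out))
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble(site = integer(), chain = character(), resno = integer(),
                  resid = character(), o1 = character(), o2 = character(),
                  d1 = numeric(), d2 = numeric(), mode = character())
  }
  arrange(out, .data$site, .data$chain, .data$resno)
}

#' Select atoms of a structure by chain/residue/atom name
#'
#' @param model a `structure_model`.
#' @param chain,resno,resid,elety,element optional vectors; an atom is
#'   selected when it matches all supplied filters.
#' @return the matching rows of the atom table.
#' @export
atom_select <- function(model, chain = NULL, resno = NULL, resid = NULL,
                        elety = NULL, element = NULL) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(resid)) keep <- keep & a$resid %in% toupper(resid)
  if (!is.null(elety)) keep <- keep & a$elety %in% toupper(elety)
  if (!is.null(element)) keep <- keep & a$element %in% toupper(element)
  a[keep, ]
}

#' Distance between two atom selections
#'
#' @param model a `structure_model`.
#' @param sel1,sel2 atom tables (e.g. from [atom_select()]) or lists of
#'   arguments to [atom_select()].
#' @param mode `"min"` (default), `"max"` or `"all"` (full pair table).
#' @return for `"min"`/`"max"`, a one-row tibble with the distance and the
#'   two atoms involved; for `"all"`, a tibble of all pairs. Atoms common
#'   to both selections are excluded as pairs of an atom with itself.
#' @export
pair_distance <- function(model, sel1, sel2, mode = c("min", "max", "all")) {
  mode <- match.arg(mode)
  resolve <- function(sel, name) {
    if (is.data.frame(sel)) return(sel)
    if (is.list(sel)) return(do.call(atom_select, c(list(model), sel)))
    abort(sprintf("`%s` must be an atom table or a selection list.", name))
  }
  a1 <- resolve(sel1, "sel1")
  a2 <- resolve(sel2, "sel2")
  if (nrow(a1) == 0) abort("`sel1` selects no atoms.")
  if (nrow(a2) == 0) abort("`sel2` selects no atoms.")
  pairs <- tidyr::expand_grid(i = seq_len(nrow(a1)), j = seq_len(nrow(a2)))
  pairs <- pairs[a1$eleno[pairs$i] != a2$eleno[pairs$j], ]
  if (nrow(pairs) == 0) abort("selections contain no distinct atom pairs.")
  d <- sqrt((a1$x[pairs$i] - a2$x[pairs$j])^2 +
              (a1$y[pairs$i] - a2$y[pairs$j])^2 +
              (a1$z[pairs$i] - a2$z[pairs$j])^2)
  tab <- tibble(
    atom_1 = paste0(a1$chain[pairs$i], a1$resno[pairs$i], ":",
                    a1$elety[pairs$i]),
    atom_2 = paste0(a2$chain[pairs$j], a2$resno[pairs$j], ":",
                    a2$elety[pairs$j]),
    distance = d
  )
  switch(mode,
         all = tab,
         min = tab[which.min(tab$distance), ],
         max = tab[which.max(tab$distance), ])
}

#' @noRd
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' @noRd
atom_radii <- function(element) {
  r <- VDW_RADII[element]
  r[is.na(r)] <- VDW_DEFAULT
  unname(r)
}

# Shrake-Rupley solvent-accessible surface area: deterministic sphere
# sampling with a golden-spiral point set.
#' @noRd
shrake_rupley <- function(atoms, probe = 1.4, n_points = 960) {
  n <- nrow(atoms)
  if (n == 0) return(numeric(0))
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  rad <- atom_radii(atoms$element) + probe
  pts <- sphere_points(n_points)
  d2 <- as.matrix(stats::dist(xyz))^2
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    p <- sweep(pts * rad[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & dj > rad[j]^2
    }
    sasa[i] <- 4 * pi * rad[i]^2 * mean(acc)
  }
  sasa
}

#' Buried surface area of a two-chain interface
#'
#' Numerical solvent-accessible surface area (Shrake-Rupley sphere
#' sampling, deterministic for a given point count) of each chain alone and
#' of the pair together; the buried area is
#' `SASA_A + SASA_B - SASA_AB` (total over both chains; half of that is
#' the conventional per-side value, reported alongside). Hydrogens and
#' waters are excluded.
#'
#' @param model a `structure_model`.
#' @param chain_a,chain_b chain identifiers.
#' @param probe probe radius, A (default 1.4).
#' @param n_points sphere sample points per atom (default 960).
#' @return an object of class `interface_bsa`: a list with `buried_total`,
#'   `buried_per_side`, `sasa_a`, `sasa_b`, `sasa_ab` (A^2) and
#'   `per_residue` (tibble of per-residue buried area contributions).
#' @export
interface_bsa <- function(model, chain_a, chain_b, probe = 1.4,
                          n_points = 960) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  a <- a[!(a$resid %in% WATER_RESIDS) & a$element != "H", ]
  at_a <- a[a$chain == chain_a, ]
  at_b <- a[a$chain == chain_b, ]
  if (nrow(at_a) == 0) abort(sprintf("chain %s not present.", chain_a))
  if (nrow(at_b) == 0) abort(sprintf("chain %s not present.", chain_b))
  sasa_a <- shrake_rupley(at_a, probe, n_points)
  sasa_b <- shrake_rupley(at_b, probe, n_points)
  ab <- bind_rows(at_a, at_b)
  sasa_ab <- shrake_rupley(ab, probe, n_points)
  buried_atom <- c(sasa_a, sasa_b) - sasa_ab
  per_residue <- ab |>
    mutate(buried = buried_atom) |>
    group_by(.data$chain, .data$resno, .data$resid) |>
    summarise(buried = sum(.data$buried), .groups = "drop") |>
    filter(abs(.data$buried) > 1e-9) |>
    arrange(desc(.data$buried))
  structure(
    list(
      buried_total = sum(sasa_a) + sum(sasa_b) - sum(sasa_ab),
      buried_per_side = (sum(sasa_a) + sum(sasa_b) - sum(sasa_ab)) / 2,
      sasa_a = sum(sasa_a), sasa_b = sum(sasa_b), sasa_ab = sum(sasa_ab),
      chains = c(chain_a, chain_b), per_residue = per_residue,
      probe = probe, n_points = n_points
    ),
    class = "interface_bsa"
  )
}

#' @export
print.interface_bsa <- function(x, ...) {
  cat(sprintf(
    "<interface_bsa> chains %s/%s: buried %.1f A^2 total (%.1f per side)\n",
    x$chains[1], x$chains[2], x$buried_total, x$buried_per_side))
  invisible(x)
}

#' Compare metal sites between two structures
#'
#' Pairs metal sites across two models (by order within the site tables, or
#' via an explicit mapping), and reports coordination-number deltas and
#' carboxylate denticity changes; any denticity change is flagged as a
#' carboxylate shift.
#'
#' @param model_a,model_b `structure_model` objects.
#' @param mapping optional tibble with columns `site_a`, `site_b` (site
#'   indices as in [find_metal_sites()]); default pairs sites in order,
#'   leaving any excess unpaired.
#' @param cutoff donor cutoff, A.
#' @return a list with `sites` (tibble: per pair `site_a`, `site_b`,
#'   `cn_a`, `cn_b`, `delta_cn`, `n_shifts`, `shift_residues`) and
#'   `denticity` (tibble of per-residue mode pairs), and `unpaired`
#'   (site indices without a partner).
#' @export
site_comparison <- function(model_a, model_b, mapping = NULL, cutoff = 3.0) {
  sa <- find_metal_sites(model_a)
  sb <- find_metal_sites(model_b)
  shell_a <- coordination_shell(model_a, sa, cutoff)
  shell_b <- coordination_shell(model_b, sb, cutoff)
  dent_a <- carboxylate_denticity(model_a, sa, cutoff)
  dent_b <- carboxylate_denticity(model_b, sb, cutoff)
  if (is.null(mapping)) {
    k <- min(nrow(sa), nrow(sb))
    mapping <- tibble(site_a = sa$site[seq_len(k)],
                      site_b = sb$site[seq_len(k)])
  }
  dent_pairs <- map(seq_len(nrow(mapping)), function(i) {
    da <- dent_a[dent_a$site == mapping$site_a[i], ]
    db <- dent_b[dent_b$site == mapping$site_b[i], ]
    dplyr::full_join(
      select(da, "resno", "resid", mode_a = "mode", d1_a = "d1", d2_a = "d2"),
      select(db, "resno", "resid", mode_b = "mode", d1_b = "d1", d2_b = "d2"),
      by = c("resno", "resid")
    ) |>
      mutate(site_a = mapping$site_a[i], site_b = mapping$site_b[i],
             shifted = !is.na(.data$mode_a) & !is.na(.data$mode_b) &
               .data$mode_a != .data$mode_b)
  })
  dent_pairs <- list_rbind(dent_pairs)
  sites <- map(seq_len(nrow(mapping)), function(i) {
    ca <- shell_a$sites$coordination_number[shell_a$sites$site ==
                                              mapping$site_a[i]]
    cb <- shell_b$sites$coordination_number[shell_b$sites$site ==
                                              mapping$site_b[i]]
    dp <- dent_pairs[dent_pairs$site_a == mapping$site_a[i] &
                       dent_pairs$site_b == mapping$site_b[i], ]
    tibble(
      site_a = mapping$site_a[i], site_b = mapping$site_b[i],
      cn_a = ca, cn_b = cb, delta_cn = cb - ca,
      n_shifts = sum(dp$shifted),
      shift_residues = paste(dp$resno[dp$shifted], collapse = ",")
    )
  })
  list(
    sites = list_rbind(sites),
    denticity = dent_pairs,
    unpaired = list(a = setdiff(sa$site, mapping$site_a),
                    b = setdiff(sb$site, mapping$site_b))
  )
}
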