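#' Default EF-hand loop pattern for LanM scanning
#'
#' EF hands carry a 12-residue metal-coordinating loop. In lanmodulins the
#' loop donates a monodentate Asn or Asp at position 1, carboxylates at
#' positions 3, 5, 9 and 12, and a backbone carbonyl at position 7; position
#' 2 is often proline (a LanM hallmark). Because only side-chain identity at
#' a subset of positions is diagnostic, the scanner matches a configurable
#' position-class table. The default constrains positions 1, 3, 5 and 12 to
#' the residue classes compatible with lanmodulin-style coordination and
#' leaves the remaining positions free. `X` never matches a constrained
#' position.
#'
#' @param p1,p3,p5,p12 character vectors of allowed residues at the
#'   constrained loop positions.
#' @param extra optional named list of additional constraints, e.g.
#'   `list("9" = c("D","E"))`; names are loop positions 1-12.
#' @return an object of class `ef_pattern`: a length-12 list of allowed
#'   residue vectors (`NULL` = unconstrained).
#' @export
ef_hand_pattern <- function(p1 = c("D", "N"),
                            p3 = c("D", "N", "E"),
                            p5 = c("D", "N", "E", "S", "T"),
                            p12 = c("D", "E"),
                            extra = NULL) {
  pat <- vector("list", 12)
  pat[[1]] <- p1
  pat[[3]] <- p3
  pat[[5]] <- p5
  pat[[12]] <- p12
  if (!is.null(extra)) {
    for (nm in names(extra)) {
      i <- as.integer(nm)
      if (is.na(i) || i < 1 || i > 12) abort("`extra` names must be positions 1-12.")
      pat[[i]] <- extra[[nm]]
    }
  }
  structure(pat, class = "ef_pattern")
}

#' @noRd
pattern_regex <- function(pattern) {
  stopifnot(inherits(pattern, "ef_pattern"))
  parts <- map_chr(pattern, function(cls) {
    if (is.null(cls)) "[A-WYZ]" else sprintf("[%s]", paste(cls, collapse = ""))
  })
  # unconstrained positions accept any canonical residue or X; constrained
  # positions list explicit residues, so X never matches there
  parts[map_lgl(pattern, is.null)] <- "."
  paste(parts, collapse = "")
}

# canonical side-chain ligand classes used to annotate which loop positions
# look like metal ligands, independent of what the scan constrained
LIGAND_CLASSES <- list(
  `1` = c("D", "N"),
  `3` = c("D", "N", "E"),
  `5` = c("D", "N", "E", "S", "T"),
  `9` = c("D", "E", "N", "Q", "S", "T"),
  `12` = c("D", "E")
)

#' Scan protein sequences for EF-hand metal-binding loops
#'
#' Finds all non-overlapping, left-greedy matches of a 12-residue EF-hand
#' loop pattern in each sequence. Matching is leftmost-first: after a hit at
#' position `s`, scanning resumes at `s + 12`.
#'
#' @param records protein records: a tibble with `id` and `sequence`
#'   columns, a named character vector, or an `AAStringSet`.
#' @param pattern an [ef_hand_pattern()] position-class table.
#' @return a tibble with one row per hit: `id`, `loop_start` (1-based index
#'   of loop position 1), `loop_seq` (the 12 loop residues), `p2` (`TRUE`
#'   if loop position 2 is proline), and `ligand_positions` (comma-separated
#'   subset of positions 1,3,5,9,12 whose residue falls in the canonical
#'   ligand class for that position).
#' @export
scan_ef_hands <- function(records, pattern = ef_hand_pattern()) {
  records <- as_protein_records(records)
  rx <- pattern_regex(pattern)
  hits <- map2(records$id, records$sequence, function(id, seq) {
    if (nchar(seq) < 12) {
      return(NULL)
    }
    m <- gregexpr(rx, seq, perl = TRUE)[[1]]
    if (m[1] == -1) {
      return(NULL)
    }
    starts <- as.integer(m)
    loops <- substring(seq, starts, starts + 11L)
    tibble(
      id = id,
      loop_start = starts,
      loop_seq = loops,
      p2 = substring(loops, 2, 2) == "P",
      ligand_positions = map_chr(loops, annotate_ligands)
    )
  })
  out <- list_rbind(purrr::compact(hits))
  if (nrow(out) == 0) {
    out <- tibble(id = character(), loop_start = integer(),
                  loop_seq = character(), p2 = logical(),
                  ligand_positions = character())
  }
  arrange(out, .data$id, .data$loop_start)
}

#' @noRd
annotate_ligands <- function(loop) {
  pos <- names(LIGAND_CLASSES)
  ok <- map_lgl(pos, function(p) {
    substring(loop, as.integer(p), as.integer(p)) %in% LIGAND_CLASSES[[p]]
  })
  paste(pos[ok], collapse = ",")
}

#' Apply LanM curation criteria to scanned sequences
#'
#' Classifies each record as a LanM candidate using the curation rules:
#' (a) sequence shorter than `max_length` residues, (b) at least (or, with
#' `exact_hands = TRUE`, exactly) `min_hands` EF hands, (c) at least one
#' adjacent pair of EF hands separated by at most `max_spacing` residues
#' (spacing counts the residues strictly between one loop's position 12 and
#' the next loop's position 1), and (d) optionally at least one hand with
#' proline at loop position 2. Failing verdicts are results, not errors.
#'
#' @param records protein records (see [scan_ef_hands()]).
#' @param hits EF-hand hit table; defaults to scanning `records`.
#' @param max_length maximum sequence length, exclusive (default 200).
#' @param min_hands required number of EF hands (default 4).
#' @param exact_hands if `TRUE`, require exactly `min_hands` hands.
#' @param max_spacing maximum inter-loop spacing, inclusive (default 13,
#'   i.e. "separated by fewer than 14 residues").
#' @param require_p2 require at least one proline-2 hand (default `TRUE`;
#'   the hallmark is reported separately in `has_p2` regardless).
#' @return a tibble with one row per record: `id`, `length`, `n_ef_hands`,
#'   `min_spacing` (NA with fewer than two hands), `has_p2`, `length_ok`,
#'   `verdict` (`"pass"`/`"fail"`) and `reasons` (comma-separated failed
#'   criteria, empty on pass).
#' @export
classify_lanm <- function(records, hits = scan_ef_hands(records),
                          max_length = 200, min_hands = 4,
                          exact_hands = FALSE, max_spacing = 13,
                          require_p2 = TRUE) {
  records <- as_protein_records(records)
  per <- map(seq_len(nrow(records)), function(i) {
    id <- records$id[i]
    len <- nchar(records$sequence[i])
    h <- hits[hits$id == id, , drop = FALSE]
    h <- h[order(h$loop_start), , drop = FALSE]
    n_hands <- nrow(h)
    spacing <- if (n_hands >= 2) {
      s <- h$loop_start
      min(s[-1] - (s[-n_hands] + 12L))
    } else {
      NA_integer_
    }
    has_p2 <- n_hands > 0 && any(h$p2)
    reasons <- character()
    length_ok <- len < max_length
    if (!length_ok) reasons <- c(reasons, "length")
    hands_ok <- if (exact_hands) n_hands == min_hands else n_hands >= min_hands
    if (!hands_ok) reasons <- c(reasons, "n_ef_hands")
    spacing_ok <- !is.na(spacing) && spacing <= max_spacing
    if (!spacing_ok) reasons <- c(reasons, "spacing")
    if (require_p2 && !has_p2) reasons <- c(reasons, "p2")
    tibble(
      id = id, length = len, n_ef_hands = n_hands,
      min_spacing = as.integer(spacing), has_p2 = has_p2,
      length_ok = length_ok,
      verdict = if (length(reasons) == 0) "pass" else "fail",
      reasons = paste(reasons, collapse = ",")
    )
  })
  list_rbind(per)
}

# ExPASy-style average residue masses (Da)
AVG_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326,
  X = 110.0000
)
WATER_MASS <- 18.01524

#' Sequence properties: length, average MW and extinction coefficient
#'
#' Computes, per record, the sequence length, the average molecular weight
#' (sum of average residue masses plus one water) and the molar extinction
#' coefficient at 280 nm, `e280 = 5500*nTrp + 1490*nTyr + 125*n_cystine`.
#' Cysteines are assumed reduced by default (`n_cystine = 0`); set
#' `cystines = TRUE` to count Cys pairs as cystines.
#'
#' @param records protein records (see [scan_ef_hands()]).
#' @param cystines count disulfide-paired cysteines (`floor(nCys/2)` pairs)
#'   in the extinction coefficient.
#' @return a tibble with columns `id`, `length`, `mw` (Da), `e280`
#'   (M^-1 cm^-1), `n_trp`, `n_tyr`, `n_cys` and `has_x` (`TRUE` when the
#'   sequence contains unknown residues, in which case `mw` is computed
#'   with a nominal 110 Da placeholder and a warning is raised).
#' @export
sequence_properties <- function(records, cystines = FALSE) {
  records <- as_protein_records(records)
  out <- map(seq_len(nrow(records)), function(i) {
    seq <- records$sequence[i]
    aa <- strsplit(seq, "")[[1]]
    counts <- table(factor(aa, levels = names(AVG_RESIDUE_MASS)))
    has_x <- counts[["X"]] > 0
    mw <- sum(counts * AVG_RESIDUE_MASS) + WATER_MASS
    n_trp <- counts[["W"]]
    n_tyr <- counts[["Y"]]
    n_cys <- counts[["C"]]
    n_cystine <- if (cystines) n_cys %/% 2 else 0
    tibble(
      id = records$id[i], length = nchar(seq), mw = mw,
      e280 = 5500 * n_trp + 1490 * n_tyr + 125 * n_cystine,
      n_trp = n_trp, n_tyr = n_tyr, n_cys = n_cys, has_x = has_x
    )
  })
  out <- list_rbind(out)
  if (any(out$has_x)) {
    warn("sequence(s) contain X residues; MW uses a 110 Da placeholder for X.")
  }
  out
}
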