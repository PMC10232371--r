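#' Global pairwise identity between two protein sequences
#'
#' Performs a deterministic Needleman-Wunsch global alignment (BLOSUM62,
#' affine gaps, default open 11 / extend 1) and reports the percent identity
#' and the alignment score. The identity denominator is the alignment length
#' including internal gap columns but excluding terminal gap runs (the
#' overhangs produced by unequal lengths), so identical sequences score 100
#' regardless of flanking sequence in the partner.
#'
#' @param a,b amino-acid sequences (single strings).
#' @param gap_open,gap_ext affine gap penalties (positive numbers).
#' @param substitution substitution matrix name (default `"BLOSUM62"`).
#' @return a one-row tibble: `percent_identity`, `score`, `n_identical`,
#'   `alignment_length`.
#' @export
global_identity <- function(a, b, gap_open = 11, gap_ext = 1,
                            substitution = "BLOSUM62") {
  if (!is.character(a) || !is.character(b) || !nzchar(a) || !nzchar(b)) {
    abort("`a` and `b` must be non-empty sequences.")
  }
  batch_identity(toupper(a), toupper(b), gap_open, gap_ext, substitution)
}

# vectorized core: aligns many patterns against one subject in a single
# pairwiseAlignment call (per-call dispatch overhead dominates otherwise)
#' @noRd
batch_identity <- function(patterns, subject, gap_open, gap_ext,
                           substitution) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(patterns), subject, type = "global",
    substitutionMatrix = substitution,
    gapOpening = gap_open, gapExtension = gap_ext
  )
  pas <- as.character(Biostrings::alignedPattern(aln))
  pbs <- as.character(Biostrings::alignedSubject(aln))
  scores <- as.numeric(Biostrings::score(aln))
  out <- map(seq_along(pas), function(i) {
    pa <- strsplit(pas[i], "")[[1]]
    pb <- strsplit(pbs[i], "")[[1]]
    gap <- pa == "-" | pb == "-"
    # terminal gap runs: leading/trailing columns where either row is a gap
    non_gap <- which(!gap)
    keep <- if (length(non_gap) == 0) {
      logical(length(pa))
    } else {
      seq_along(pa) >= min(non_gap) & seq_along(pa) <= max(non_gap)
    }
    len <- sum(keep)
    ident <- sum(pa[keep] == pb[keep] & pa[keep] != "-")
    tibble(
      percent_identity = if (len == 0) 0 else 100 * ident / len,
      score = scores[i],
      n_identical = ident,
      alignment_length = len
    )
  })
  list_rbind(out)
}

#' Build an identity-thresholded sequence similarity network
#'
#' Computes all-vs-all global identities (see [global_identity()]) and keeps
#' an undirected edge between two records when their percent identity is at
#' least `threshold` and the alignment score exceeds `score_floor`. The
#' score floor stands in for a database E-value cutoff, which is not
#' reproducible offline.
#'
#' @param records protein records (see [scan_ef_hands()]).
#' @param threshold percent identity threshold in \[0, 100\].
#' @param score_floor minimum alignment score for an edge (default 0).
#' @inheritParams global_identity
#' @return an object of class `lanm_ssn`: a list with `nodes` (character),
#'   `edges` (tibble `from`, `to`, `percent_identity`, `score`),
#'   `threshold` and `score_floor`. All computed pairs are retained in
#'   `all_pairs` so the network can be re-thresholded without realignment
#'   via [rethreshold_ssn()].
#' @export
build_ssn <- function(records, threshold = 65, score_floor = 0,
                      gap_open = 11, gap_ext = 1,
                      substitution = "BLOSUM62") {
  records <- as_protein_records(records)
  check_number(threshold, "threshold", 0, 100)
  if (anyDuplicated(records$id)) abort("record ids must be unique.")
  n <- nrow(records)
  # one vectorized alignment call per subject column of the all-vs-all
  # upper triangle
  all_pairs <- map(seq_len(n)[-1], function(j) {
    gi <- batch_identity(records$sequence[seq_len(j - 1)],
                         records$sequence[j],
                         gap_open, gap_ext, substitution)
    tibble(from = records$id[seq_len(j - 1)], to = records$id[j],
           percent_identity = gi$percent_identity, score = gi$score)
  })
  all_pairs <- if (n >= 2) list_rbind(all_pairs) else NULL
  if (nrow(all_pairs) == 0) {
    all_pairs <- tibble(from = character(), to = character(),
                        percent_identity = numeric(), score = numeric())
  }
  structure(
    list(
      nodes = records$id,
      edges = filter(all_pairs, .data$percent_identity >= threshold,
                     .data$score > score_floor),
      all_pairs = all_pairs,
      threshold = threshold,
      score_floor = score_floor
    ),
    class = "lanm_ssn"
  )
}

#' Re-threshold a sequence similarity network without realigning
#'
#' @param ssn a `lanm_ssn` from [build_ssn()].
#' @param threshold new percent identity threshold in \[0, 100\].
#' @param score_floor new score floor (default: keep the old one).
#' @return a `lanm_ssn` with the same nodes and pair table.
#' @export
rethreshold_ssn <- function(ssn, threshold, score_floor = ssn$score_floor) {
  stopifnot(inherits(ssn, "lanm_ssn"))
  check_number(threshold, "threshold", 0, 100)
  ssn$edges <- filter(ssn$all_pairs, .data$percent_identity >= threshold,
                      .data$score > score_floor)
  ssn$threshold <- threshold
  ssn$score_floor <- score_floor
  ssn
}

#' @export
print.lanm_ssn <- function(x, ...) {
  cat(sprintf(
    "<lanm_ssn> %d nodes, %d edges (identity >= %.1f%%, score > %g)\n",
    length(x$nodes), nrow(x$edges), x$threshold, x$score_floor
  ))
  invisible(x)
}

#' @noRd
ssn_graph <- function(ssn) {
  igraph::graph_from_data_frame(
    ssn$edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = ssn$nodes)
  )
}

#' Connected components of a sequence similarity network
#'
#' @param ssn a `lanm_ssn` from [build_ssn()].
#' @return a tibble with one row per node: `id`, `cluster` (integer index,
#'   1 = largest component; ties broken by first member) and `cluster_size`.
#' @export
connected_clusters <- function(ssn) {
  stopifnot(inherits(ssn, "lanm_ssn"))
  comp <- igraph::components(ssn_graph(ssn))
  membership <- comp$membership[ssn$nodes]
  sizes <- comp$csize[membership]
  # relabel components: largest first, ties by earliest node
  ord <- order(-comp$csize, match(seq_along(comp$csize), membership))
  relabel <- match(membership, ord)
  tibble(id = ssn$nodes, cluster = relabel, cluster_size = sizes) |>
    arrange(.data$cluster, .data$id)
}

#' Write a network edge list as tab-separated values
#'
#' @param ssn a `lanm_ssn`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ssn_edges <- function(ssn, path) {
  stopifnot(inherits(ssn, "lanm_ssn"))
  utils::write.table(ssn$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a network in GraphML format
#'
#' @param ssn a `lanm_ssn`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ssn_graphml <- function(ssn, path) {
  stopifnot(inherits(ssn, "lanm_ssn"))
  g <- igraph::graph_from_data_frame(
    ssn$edges, directed = FALSE, vertices = data.frame(name = ssn$nodes)
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
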