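# internal helpers shared across modules

#' @noRd
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero = TRUE) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite numeric.", name))
  }
  if (any(x < lower) || any(x > upper)) {
    abort(sprintf("`%s` must be in [%s, %s].", name, lower, upper))
  }
  if (!allow_zero && any(x == 0)) {
    abort(sprintf("`%s` must be non-zero.", name))
  }
  invisible(x)
}

#' @noRd
check_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(data)
}

# Records coercion: accept a tibble with id/sequence columns, a named
# character vector, or a Biostrings AAStringSet.
#' @noRd
as_protein_records <- function(records) {
  if (inherits(records, "AAStringSet")) {
    records <- tibble(id = names(records) %||% as.character(seq_along(records)),
                      sequence = as.character(records))
  } else if (is.character(records)) {
    ids <- names(records) %||% paste0("seq", seq_along(records))
    records <- tibble(id = ids, sequence = unname(records))
  }
  if (!is.data.frame(records)) {
    abort("`records` must be a data frame, named character vector or AAStringSet.")
  }
  check_columns(records, c("id", "sequence"), "`records`")
  records <- as_tibble(records)
  records$sequence <- toupper(records$sequence)
  if (any(!nzchar(records$sequence))) {
    abort("all sequences must be non-empty.")
  }
  bad <- grepl(sprintf("[^%s]", paste(AA_LETTERS, collapse = "")),
               records$sequence)
  if (any(bad)) {
    abort(sprintf("invalid amino-acid alphabet in record(s): %s",
                  paste(utils::head(records$id[bad], 5), collapse = ", ")))
  }
  records
}

# 20 canonical residues plus X (unknown).
#' @noRd
AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                "M", "F", "P", "S", "T", "W", "Y", "V", "X")

# Seed fan-out: each generator call derives an independent stream from its
# own seed so that adding generators never perturbs existing fixtures.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Read a multi-FASTA file into a protein record table
#'
#' @param path path to a FASTA file of amino-acid sequences.
#' @return a tibble with columns `id` (first word of the header) and
#'   `sequence` (uppercase one-letter codes).
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  tibble(id = ids, sequence = unname(toupper(as.character(aa))))
}

#' Write a protein record table to a multi-FASTA file
#'
#' @param records tibble with columns `id` and `sequence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(records, path) {
  records <- as_protein_records(records)
  aa <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
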