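# EF-hand scanning, LanM curation, sequence properties and similarity
# networks

loop12 <- function(p1 = "N", p2 = "P", p3 = "D", p5 = "D", p12 = "E") {
  l <- rep("A", 12)
  l[1] <- p1; l[2] <- p2; l[3] <- p3; l[5] <- p5; l[12] <- p12
  paste(l, collapse = "")
}

test_that("scanner finds planted loops at exact offsets and nothing else", {
  # no ligand residues at all -> no hits
  blank <- tibble::tibble(id = "a", sequence = strrep("A", 200))
  expect_equal(nrow(scan_ef_hands(blank)), 0)

  # two planted canonical loops at offsets 10 and 35
  seq <- paste0(strrep("G", 9), loop12(), strrep("K", 13), loop12(p2 = "A"),
                strrep("G", 5))
  hits <- scan_ef_hands(tibble::tibble(id = "x", sequence = seq))
  expect_equal(hits$loop_start, c(10L, 35L))
  expect_equal(hits$p2, c(TRUE, FALSE))

  # X never matches a constrained position
  seqx <- paste0(strrep("G", 9), sub("^N", "X", loop12()))
  expect_equal(nrow(scan_ef_hands(tibble::tibble(id = "x", sequence = seqx))),
               0)
})

test_that("scanner input validation rejects bad alphabets and short input", {
  expect_error(scan_ef_hands(tibble::tibble(id = "a", sequence = "ABZ1")),
               "alphabet")
  expect_error(scan_ef_hands(tibble::tibble(id = "a", sequence = "")),
               "non-empty")
  short <- scan_ef_hands(tibble::tibble(id = "a", sequence = "NPDAD"))
  expect_equal(nrow(short), 0)
})

test_that("curation applies length, hand count, spacing and P2 rules", {
  # 110-residue record, 4 hands, spacings 12-13, all P2 -> pass
  spacers <- c(12, 13, 12)
  seq <- strrep("G", 10)
  for (i in 1:4) {
    seq <- paste0(seq, loop12())
    if (i < 4) seq <- paste0(seq, strrep("K", spacers[i]))
  }
  seq <- paste0(seq, strrep("G", 110 - nchar(seq)))
  expect_equal(nchar(seq), 110)
  rec <- tibble::tibble(id = "hans", sequence = seq)
  call <- classify_lanm(rec)
  expect_equal(call$verdict, "pass")
  expect_equal(call$n_ef_hands, 4L)
  expect_equal(call$min_spacing, 12L)
  expect_true(call$has_p2)
  expect_equal(call$reasons, "")

  # 250-residue, otherwise valid -> fail on length only
  rec250 <- tibble::tibble(id = "big",
                           sequence = paste0(seq, strrep("G", 140)))
  call250 <- classify_lanm(rec250)
  expect_equal(call250$verdict, "fail")
  expect_equal(call250$reasons, "length")

  # 4 hands all separated by 25 residues -> fail on spacing
  seq25 <- strrep("G", 10)
  for (i in 1:4) {
    seq25 <- paste0(seq25, loop12())
    if (i < 4) seq25 <- paste0(seq25, strrep("K", 25))
  }
  call25 <- classify_lanm(tibble::tibble(id = "wide", sequence = seq25))
  expect_equal(call25$verdict, "fail")
  expect_equal(call25$reasons, "spacing")
  expect_equal(call25$min_spacing, 25L)

  # strict equality toggle
  seq5 <- paste0(strrep("G", 4),
                 paste(rep(paste0(loop12(), strrep("K", 12)), 5),
                       collapse = ""))
  call5 <- classify_lanm(tibble::tibble(id = "five", sequence = seq5),
                         exact_hands = TRUE)
  expect_equal(call5$n_ef_hands, 5L)
  expect_match(call5$reasons, "n_ef_hands")
})

test_that("classification is a pure function of record and criteria", {
  g <- gen_lanm_sequences(n = 5, seed = 11)
  a <- classify_lanm(g$records)
  b <- classify_lanm(g$records)
  expect_identical(a, b)
})

test_that("spacing arithmetic matches hand-placed fixtures", {
  # loops at starts 5 and 30: spacing = 30 - (5 + 12) = 13
  seq <- paste0(strrep("G", 4), loop12(), strrep("K", 13), loop12(),
                strrep("G", 4))
  call <- classify_lanm(tibble::tibble(id = "s", sequence = seq),
                        min_hands = 2)
  expect_equal(call$min_spacing, 13L)
})

test_that("sequence properties reproduce composition formulas", {
  props <- sequence_properties(
    tibble::tibble(id = c("w2", "noar", "gg"),
                   sequence = c("WWAAA", "AAAGG", "GG")))
  expect_equal(props$e280, c(2 * 5500, 0, 0))
  expect_equal(props$mw[3], 132.12, tolerance = 1e-4)
  # cystine counting is opt-in
  withc <- sequence_properties(tibble::tibble(id = "c", sequence = "CCW"),
                               cystines = TRUE)
  expect_equal(withc$e280, 5500 + 125)
  expect_warning(
    px <- sequence_properties(tibble::tibble(id = "x", sequence = "GXG")),
    "X residues")
  expect_true(px$has_x)
  expect_equal(px$e280, 0)
})

test_that("global identity follows the stated alignment conventions", {
  expect_equal(global_identity("MKEIDL", "MKEIDL")$percent_identity, 100)
  expect_equal(global_identity("DDDD", "KKKK")$percent_identity, 0)
  expect_error(global_identity("", "AA"), "non-empty")

  # 20-residue pair with exactly 10 identities on a gap-free optimal path:
  # alternating identity/mismatch columns leave no run that a gap could
  # profitably realign
  a <- "ARNDCQEGHILKMFPSTWYV"
  b <- paste(ifelse(seq_len(20) %% 2 == 1, strsplit(a, "")[[1]], "X"),
             collapse = "")
  gi <- global_identity(a, b)
  expect_equal(gi$alignment_length, 20)
  expect_equal(gi$percent_identity, 50)
  # score agrees with an independent dynamic-programming oracle
  data("BLOSUM62", package = "Biostrings", envir = environment())
  expect_equal(gi$score, nw_align(a, b, BLOSUM62), tolerance = 1e-9)
})

test_that("global identity is symmetric", {
  set.seed(42)
  aas <- c("A", "R", "N", "D", "E", "G", "K", "L", "S", "T", "V")
  for (i in 1:15) {
    a <- paste(sample(aas, sample(10:30, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(10:30, 1), replace = TRUE), collapse = "")
    expect_equal(global_identity(a, b)$percent_identity,
                 global_identity(b, a)$percent_identity, tolerance = 1e-12)
  }
})

test_that("similarity network thresholds edges as specified", {
  base <- "NPDADATAEAAEGGKKLLVVFFRRQQHHMM"
  recs <- tibble::tibble(
    id = c("a", "b", "c"),
    sequence = c(base, base, "WYWYWYWYWYWYWYWYWYWYWYWYWYWYWY")
  )
  ssn <- build_ssn(recs, threshold = 90)
  expect_equal(nrow(ssn$edges), 1)
  expect_setequal(c(ssn$edges$from, ssn$edges$to), c("a", "b"))

  # identical threshold 100 with all-distinct sequences -> 0 edges
  distinct <- tibble::tibble(
    id = c("a", "b"),
    sequence = c("NPDADATAEAAE", "NPDADATAEAAD"))
  expect_equal(nrow(build_ssn(distinct, threshold = 100)$edges), 0)

  expect_error(build_ssn(recs, threshold = 150), "threshold")

  # monotone filtering: edges never increase as the threshold rises
  g <- gen_lanm_sequences(n = 8, decoy_fraction = 0.25, seed = 3)
  ssn8 <- build_ssn(g$records, threshold = 40)
  counts <- sapply(seq(40, 90, by = 5), function(t) {
    nrow(rethreshold_ssn(ssn8, t)$edges)
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("connected components partition the network, largest first", {
  empty5 <- structure(
    list(nodes = letters[1:5],
         edges = tibble::tibble(from = character(), to = character(),
                                percent_identity = numeric(),
                                score = numeric()),
         all_pairs = NULL, threshold = 65, score_floor = 0),
    class = "lanm_ssn")
  cl <- connected_clusters(empty5)
  expect_equal(nrow(cl), 5)
  expect_true(all(cl$cluster_size == 1))

  one_edge <- empty5
  one_edge$edges <- tibble::tibble(from = "a", to = "b",
                                   percent_identity = 95, score = 50)
  one_edge$nodes <- c("a", "b", "c")
  cl2 <- connected_clusters(one_edge)
  expect_equal(sort(unique(cl2$cluster_size), decreasing = TRUE), c(2, 1))
  expect_equal(cl2$cluster[cl2$id %in% c("a", "b")], c(1L, 1L))
})

test_that("a planted two-block set resolves into two clusters at 65%", {
  # two families: within-block near-identity, between-block unrelated
  block1 <- "NPDADATAEAAEGGKKLLVVFFRRQQHHMMAA"
  block2 <- "WYWYHHRRQQMMKKLLVVGGFFAAWYWYHHRR"
  mutate_seq <- function(s, pos, to) {
    substr(s, pos, pos) <- to
    s
  }
  recs <- tibble::tibble(
    id = paste0("s", 1:6),
    sequence = c(block1, mutate_seq(block1, 3, "A"),
                 mutate_seq(block1, 7, "G"),
                 block2, mutate_seq(block2, 5, "A"),
                 mutate_seq(block2, 9, "G"))
  )
  ssn <- build_ssn(recs, threshold = 65)
  cl <- connected_clusters(ssn)
  expect_equal(length(unique(cl$cluster)), 2)
  expect_equal(as.vector(table(cl$cluster)), c(3L, 3L))
})

test_that("FASTA round trip preserves records", {
  g <- gen_lanm_sequences(n = 4, seed = 9)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_protein_fasta(g$records, path)
  back <- read_protein_fasta(path)
  expect_equal(back, g$records)
})
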