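make_msa <- function(per_label, width = 20) {
  # per_label: named list label -> list of named residue overrides
  base <- strrep("K", width)
  seqs <- character(0); labels <- character(0)
  for (g in names(per_label)) {
    for (i in 1:3) {
      s <- base
      for (p in names(per_label[[g]])) {
        substr(s, as.integer(p), as.integer(p)) <- per_label[[g]][[p]]
      }
      seqs <- c(seqs, s); labels <- c(labels, g)
    }
  }
  list(seqs = seqs, labels = labels)
}

test_that("a residue fixed in one group and absent elsewhere is called", {
  m <- make_msa(list(A = list(`10` = "W"), B = list(), C = list()))
  calls <- column_signatures(m$seqs, m$labels)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$column, 10L)
  expect_equal(calls$label, "A")
  expect_equal(calls$residue, "W")

  # identical columns across labels fail tau_out and are never called
  m2 <- make_msa(list(A = list(), B = list(), C = list()))
  expect_equal(nrow(column_signatures(m2$seqs, m2$labels)), 0L)
})

test_that("gap-majority and thin columns are uncallable", {
  seqs <- c("KWKK", "K-KK", "--KK",   # A: col2 1/3 gaps, col1 2/3... varied
            "KAKK", "KAKK", "KAKK")   # B
  labels <- c("A", "A", "A", "B", "B", "B")
  calls <- column_signatures(seqs, labels, tau_in = 0.9, tau_out = 0.1)
  # col 2 for A has 1 ungapped residue -> uncallable despite uniqueness
  expect_false(any(calls$label == "A" & calls$column == 2))
})

test_that("signature calls equal the brute-force frequency oracle", {
  withr::with_seed(67, {
    for (rep in 1:5) {
      labels <- rep(c("A", "B", "C"), each = 4)
      seqs <- vapply(seq_along(labels), function(i) {
        paste(sample(c("K", "R", "W", "A", "-"), 15, TRUE,
                     prob = c(0.4, 0.25, 0.15, 0.15, 0.05)), collapse = "")
      }, character(1))
      got <- column_signatures(seqs, labels, tau_in = 0.7, tau_out = 0.3)
      want <- oracle_signatures(seqs, labels, tau_in = 0.7, tau_out = 0.3)
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got[, c("column", "label", "residue")], want)
    }
  })
})

test_that("tightening thresholds never adds a call", {
  withr::with_seed(71, {
    labels <- rep(c("A", "B"), each = 5)
    seqs <- vapply(seq_along(labels), function(i) {
      paste(sample(c("K", "R", "W", "A"), 25, TRUE), collapse = "")
    }, character(1))
  })
  loose <- column_signatures(seqs, labels, tau_in = 0.6, tau_out = 0.4)
  tight_in <- column_signatures(seqs, labels, tau_in = 0.8, tau_out = 0.4)
  tight_out <- column_signatures(seqs, labels, tau_in = 0.6, tau_out = 0.1)
  key <- function(d) paste(d$column, d$label, d$residue)
  expect_true(all(key(tight_in) %in% key(loose)))
  expect_true(all(key(tight_out) %in% key(loose)))
})

test_that("adjacent calls merge into motifs, gaps split them", {
  calls <- data.frame(column = c(36L, 37L), label = "Hox3",
                      residue = c("A", "L"), stringsAsFactors = FALSE)
  m <- merge_motifs(calls)
  expect_equal(nrow(m), 1L)
  expect_equal(m$pattern, "AL")
  expect_equal(c(m$start, m$end), c(36L, 37L))

  calls3 <- data.frame(column = 6:8, label = "G", residue = c("G", "G", "W"),
                       stringsAsFactors = FALSE)
  expect_equal(merge_motifs(calls3)$pattern, "GGW")

  split_calls <- data.frame(column = c(5L, 7L), label = "G",
                            residue = c("A", "A"), stringsAsFactors = FALSE)
  expect_equal(nrow(merge_motifs(split_calls)), 2L)
})

test_that("discovery on noise-free generator alignments recovers the planted signatures", {
  catg <- default_catalog()
  msa <- generate_labeled_msa(catg, n_per_group = 3, mut_rate = 0)
  disc <- discover_signatures(msa$sequences, msa$labels$label)
  key <- paste(disc$motifs$label, disc$motifs$start, disc$motifs$end,
               disc$motifs$pattern)
  # the printed lophotrochozoan AL motif of Hox3
  expect_true("Hox3 36 37 AL" %in% key)
  # consensus residues planted at the catalog's placeholder positions
  expect_true("Hox1 6 8 GGW" %in% key)
  expect_true("Hox1 29 29 V" %in% key)
  expect_true("Hox1 56 56 C" %in% key)
  expect_true("Hox2 24 24 S" %in% key)
  expect_true("Hox2 58 59 GA" %in% key)
  expect_true("Hox3 14 14 P" %in% key)
  # every call sits at a position where exactly one group's consensus differs
  cons <- hd_consensus_set()
  for (i in seq_len(nrow(disc$calls))) {
    cl <- disc$calls[i, ]
    res <- substr(cons[[cl$label]], cl$column, cl$column)
    expect_equal(res, cl$residue)
    others <- vapply(setdiff(names(cons), cl$label), function(g)
      substr(cons[[g]], cl$column, cl$column), character(1))
    expect_false(any(others == cl$residue))
  }
  # emitted features are valid catalog descriptors
  expect_true(all(vapply(disc$features, function(f)
    f$region == "HD_POS" && !f$placeholder, logical(1))))
})

test_that("discovered signatures can fill catalog placeholders and classify", {
  catg <- default_catalog()
  msa <- generate_labeled_msa(catg, n_per_group = 3, mut_rate = 0)
  disc <- discover_signatures(msa$sequences, msa$labels$label)
  # graft the discovered Hox1 motif into the catalog in place of scoring
  f <- disc$features[["hox1_disc_6_8"]]
  catg$groups$Hox1$features <- c(catg$groups$Hox1$features, list(f))
  spec <- generator_spec(default_mix())
  p <- generate_protein("Hox1", catg, spec, seed = 3)
  r <- classify(p$peptide, default_profile(), catg)
  expect_equal(r$label, "Hox1")
  expect_equal(unname(r$scores["Hox1"]), 2)  # predicate + discovered motif
})
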