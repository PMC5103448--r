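catg <- default_catalog()

test_that("a planted CDS yields one candidate in its frame at truth coordinates", {
  spec <- generator_spec(c(Antp = 3L), seed = 31)
  tx <- generate_transcriptome(spec, catg)
  for (i in seq_len(nrow(tx$truth))) {
    r <- tx$truth[i, ]
    orfs <- enumerate_orfs(tx$transcripts$residues[i], 50L,
                           id = r$transcript_id)
    in_frame <- orfs[orfs$frame == r$frame, ]
    expect_equal(nrow(in_frame), 1L)
    expect_equal(in_frame$nt_start, r$cds_start)
    expect_equal(in_frame$nt_end, r$cds_end)
    expect_equal(in_frame$peptide, r$peptide)
  }
})

test_that("the >50 aa filter is strict: 51 aa passes, 50 aa is rejected", {
  withr::with_seed(17, {
    p50 <- paste0("M", random_aa(49))
    p51 <- paste0("M", random_aa(50))
  })
  t50 <- embed_cds(p50, seed = 2)
  t51 <- embed_cds(p51, seed = 2)
  expect_equal(nrow(enumerate_orfs(t50$transcript, 50L)), 0L)
  o51 <- enumerate_orfs(t51$transcript, 50L)
  expect_equal(nrow(o51), 1L)
  expect_equal(o51$aa_length, 51L)
})

test_that("N inside a codon translates to X without disturbing stops", {
  p <- paste0("M", random_aa(60))
  tr <- embed_cds(p, seed = 5)$transcript
  # corrupt one base in the middle of the CDS
  pos <- 60L + 3L * 30L + 2L
  substr(tr, pos, pos) <- "N"
  o <- enumerate_orfs(tr, 50L)
  o <- o[o$frame == 1, ]
  expect_equal(nrow(o), 1L)
  expect_equal(o$aa_length, nchar(p))
  expect_true(grepl("X", o$peptide, fixed = TRUE))
})

test_that("enumerate_orfs matches the brute-force start/stop oracle", {
  withr::with_seed(23, seqs <- replicate(25, random_nt(2000)))
  for (s in seqs) {
    got <- enumerate_orfs(s, 50L)
    want <- oracle_orfs(s, 50L)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got[, c("frame", "nt_start", "nt_end", "peptide",
                         "aa_length")], want)
  }
})

test_that("aa/nt coordinates round-trip through codons on both strands", {
  withr::with_seed(29, seqs <- replicate(10, random_nt(1200)))
  for (s in seqs) {
    orfs <- enumerate_orfs(s, 30L)
    for (i in seq_len(nrow(orfs))) {
      o <- orfs[i, ]
      for (p in c(0L, as.integer(o$aa_length) %/% 2L, o$aa_length - 1L)) {
        if (o$frame > 0) {
          codon <- substr(s, o$nt_start + 3 * p + 1, o$nt_start + 3 * p + 3)
        } else {
          codon <- revcomp(substr(s, o$nt_end - 3 * p - 2, o$nt_end - 3 * p))
        }
        expect_equal(translate_nt(codon), substr(o$peptide, p + 1, p + 1))
      }
    }
  }
})

test_that("built-in evidence sources vote as specified", {
  spec <- generator_spec(default_mix(), seed = 41)
  tx <- generate_transcriptome(spec, catg)
  cands <- enumerate_orfs_set(tx$transcripts)
  ev <- collect_evidence(cands, list(profile_evidence_source(),
                                     kmer_evidence_source()))
  expect_equal(ev$evidence_count,
               as.integer(ev$hd_profile) + as.integer(ev$ref_kmer))
  # true CDS candidates (those matching a truth peptide) get both votes
  truth_pep <- tx$truth$peptide
  is_true <- cands$peptide %in% truth_pep
  expect_true(all(ev$evidence_count[is_true] == 2L))

  # no sources configured -> all zero
  ev0 <- collect_evidence(cands, list())
  expect_true(all(ev0$evidence_count == 0L))
})

test_that("external TSV evidence honours the 1e-06 e-value cutoff", {
  cands <- data.frame(transcript_id = "t1", orf_index = 1:2,
                      candidate_id = c("t1|orf1", "t1|orf2"),
                      peptide = c(random_aa(60), random_aa(60)),
                      stringsAsFactors = FALSE)
  hits <- data.frame(query_id = c("t1|orf1", "t1|orf2", "t9|orf9"),
                     source_name = "blastp", subject_id = "P1",
                     e_value = c(1e-06, 1e-05, 1e-30), bit_score = 50,
                     stringsAsFactors = FALSE)
  expect_warning(
    src <- tsv_evidence_source(hits, candidate_ids = cands$candidate_id),
    "unknown candidate id")
  ev <- collect_evidence(cands, list(src))
  expect_equal(ev$evidence_count, c(1L, 0L))  # 1e-05 fails the cutoff
})

test_that("select_cds picks the evidence argmax with documented tie-breaks", {
  cands <- data.frame(
    transcript_id = "t1", orf_index = 1:3,
    frame = c(1L, 2L, -1L), nt_start = c(10L, 40L, 80L),
    nt_end = c(10L + 3 * 121, 40L + 3 * 101, 80L + 3 * 61),
    peptide = c(random_aa(120), random_aa(100), random_aa(60)),
    aa_length = c(120L, 100L, 60L), stringsAsFactors = FALSE)
  cands$candidate_id <- paste0("t1|orf", cands$orf_index)
  ev <- data.frame(candidate_id = cands$candidate_id,
                   evidence_count = c(1L, 3L, 0L))
  sel <- select_cds(cands, ev)
  expect_equal(nrow(sel), 1L)
  expect_equal(sel$orf_index, 2L)

  # tie at equal counts: longer peptide wins
  ev$evidence_count <- c(2L, 2L, 0L)
  expect_equal(select_cds(cands, ev)$orf_index, 1L)

  # equal count and length: 5'-most start wins
  cands2 <- cands
  cands2$aa_length <- c(100L, 100L, 60L)
  cands2$peptide[1] <- substr(cands2$peptide[1], 1, 100)
  expect_equal(select_cds(cands2, ev)$orf_index, 1L)

  # zero evidence everywhere: dropped by default, kept+flagged by policy
  ev0 <- data.frame(candidate_id = cands$candidate_id,
                    evidence_count = c(0L, 0L, 0L))
  expect_equal(nrow(select_cds(cands, ev0)), 0L)
  kept <- select_cds(cands, ev0, keep_longest = TRUE)
  expect_equal(kept$orf_index, 1L)
  expect_true(kept$zero_evidence)

  expect_error(select_cds(cands, ev[1:2, ]), "does not cover")
})

test_that("selection is a partial function: at most one CDS per transcript", {
  spec <- generator_spec(default_mix(), decoy_rate = 0.25,
                         n_transcripts = 20L, seed = 43)
  tx <- generate_transcriptome(spec, catg)
  cands <- enumerate_orfs_set(tx$transcripts)
  ev <- collect_evidence(cands, list(profile_evidence_source(),
                                     kmer_evidence_source()))
  sel <- select_cds(cands, ev)
  expect_false(anyDuplicated(sel$transcript_id) > 0)
  expect_true(all(sel$transcript_id %in% tx$transcripts$id))
})
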