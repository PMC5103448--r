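catg <- default_catalog()
prof <- default_profile()

feature_by_id <- function(catalog, group, id) {
  fs <- catalog$groups[[group]]$features
  fs[[which(vapply(fs, `[[`, character(1), "id") == id)]]
}

test_that("the default catalog carries the printed diagnostic features", {
  expect_equal(catalog_labels(catg, "hox"),
               c("Hox1", "Hox2", "Hox3", "Hox4", "Hox5", "Lox5", "Antp",
                 "Lox4", "Lox2", "Post2", "Post1"))
  expect_equal(catalog_labels(catg, "parahox"), c("Gsx", "Xlox", "Cdx"))

  hiaknm <- feature_by_id(catg, "Hox5", "hox5_cflank_hiaknm")
  expect_equal(hiaknm$offset, 1L)
  expect_equal(hiaknm$scope, "molluscan")

  lrtcd <- feature_by_id(catg, "Gsx", "gsx_cflank_lrtcd")
  expect_equal(lrtcd$pattern, "LRTCD")
  expect_equal(lrtcd$scope, "lophotrochozoan")

  al <- feature_by_id(catg, "Hox3", "hox3_hd_al_36_37")
  expect_equal(al$positions, c(36L, 37L))
  expect_equal(al$pattern, "AL")

  # placeholders are present but inert
  expect_true(feature_by_id(catg, "Hox1", "hox1_hd_motif_6_8")$placeholder)
  expect_equal(length(scoring_features(catg, "Post1")), 0L)
})

test_that("match_feature tests residues in homeodomain coordinates", {
  spec <- generator_spec(default_mix())
  p1 <- generate_protein("Hox1", catg, spec, seed = 8)
  f23 <- feature_by_id(catg, "Hox1", "hox1_hd_nonbasic_2_3")
  m <- match_feature(p1$peptide, p1$hd_start_aa, f23)
  expect_equal(m$residues, "AS")  # both non-basic
  expect_equal(m$start_aa, p1$hd_start_aa + 1L)

  # a basic residue at position 2 defeats the predicate
  p_other <- generate_protein("Antp", catg, spec, seed = 8)
  expect_null(match_feature(p_other$peptide, p_other$hd_start_aa, f23))

  p5 <- generate_protein("Hox5", catg, spec, seed = 8)
  fhia <- feature_by_id(catg, "Hox5", "hox5_cflank_hiaknm")
  m5 <- match_feature(p5$peptide, p5$hd_start_aa, fhia)
  expect_equal(m5$start_aa, p5$hd_start_aa + 60L)  # offset +1
  expect_equal(m5$residues, "HIAKNM")

  fypwm <- feature_by_id(catg, "Hox4", "hox4_nflank_ypwm")
  expect_null(match_feature(p_other$peptide, p_other$hd_start_aa, fypwm))

  # X never matches, even where the consensus residue would
  px <- p5$peptide
  substr(px, p5$hd_start_aa + 61L, p5$hd_start_aa + 61L) <- "X"
  expect_null(match_feature(px, p5$hd_start_aa, fhia))

  # feature window past the peptide end is a no-match, not an error
  trunc <- substr(p5$peptide, 1, p5$hd_start_aa + 62L)
  expect_null(match_feature(trunc, p5$hd_start_aa, fhia))
})

test_that("classification follows the printed motif logic", {
  spec <- generator_spec(default_mix())
  r4 <- classify(generate_protein("Hox4", catg, spec, 12)$peptide, prof, catg)
  expect_equal(r4$status, "assigned")
  expect_equal(r4$label, "Hox4")
  expect_equal(unname(r4$scores["Hox4"]), 2)

  # YPWM alone cannot separate groups 4 and 5
  p5 <- generate_protein("Hox5", catg, spec, 12)
  pep_ypwm_only <- p5$peptide
  # overwrite the HIAKNM with random residues
  substr(pep_ypwm_only, p5$hd_start_aa + 61L, p5$hd_start_aa + 66L) <-
    "GDEGDE"
  r45 <- classify(pep_ypwm_only, prof, catg)
  expect_equal(r45$status, "AMBIGUOUS")
  expect_setequal(r45$candidates, c("Hox4", "Hox5"))

  rg <- classify(generate_protein("Gsx", catg, spec, 12)$peptide, prof, catg)
  expect_equal(rg$label, "Gsx")

  # no homeodomain -> UNCLASSIFIED
  r_no <- classify(random_aa(120), prof, catg)
  expect_equal(r_no$status, "UNCLASSIFIED")
  expect_true("Post1" %in% r_no$unassignable_groups)

  # determinism
  expect_identical(classify(p5$peptide, prof, catg),
                   classify(p5$peptide, prof, catg))
})

test_that("the shared position-4 predicate is resolved by feature coverage", {
  spec <- generator_spec(default_mix())
  r2 <- classify(generate_protein("Hox2", catg, spec, 19)$peptide, prof, catg)
  expect_equal(r2$label, "Hox2")   # Hox2 matched 1/1, Hox3 only 1/2
  r3 <- classify(generate_protein("Hox3", catg, spec, 19)$peptide, prof, catg)
  expect_equal(r3$label, "Hox3")   # AL at 36-37 breaks the tie by score
  expect_equal(unname(r3$scores["Hox3"]), 2)
})

test_that("adding a matched non-required feature never lowers a group score", {
  spec <- generator_spec(default_mix())
  pg <- generate_protein("Gsx", catg, spec, 23)
  before <- classify(pg$peptide, prof, catg)$scores["Gsx"]
  catg2 <- catg
  # a feature matching the Gsx consensus homeodomain start
  extra <- hoxminer:::.validate_feature(list(
    id = "gsx_extra", region = "HD_POS", positions = list(1L),
    pattern = substr(hd_consensus_set()[["Gsx"]], 1, 1), weight = 1),
    group = "Gsx")
  catg2$groups$Gsx$features <- c(catg2$groups$Gsx$features, list(extra))
  after <- classify(pg$peptide, prof, catg2)$scores["Gsx"]
  expect_gte(after, before)
})

test_that("noise-free generator output classifies to the planted label", {
  spec <- generator_spec(default_mix(), hd_mut_rate = 0)
  for (g in SEPARABLE_LABELS) {
    for (s in 1:3) {
      p <- generate_protein(g, catg, spec, seed = 100 * s + match(g, SEPARABLE_LABELS))
      r <- classify(p$peptide, prof, catg)
      expect_equal(r$status, "assigned", info = g)
      expect_equal(r$label, g)
    }
  }
})
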