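mk_feat <- function(type, desc, start = 1L, end = 10L,
                    acc = "P1", id = "F1") {
  data.frame(accession = acc, feature_id = id, feature_type = type,
             description = desc, start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

test_that("the short-feature rule reads 'shorter than 30' strictly", {
  cfg <- pros_config()
  expect_true(is_short(mk_feat("region_of_interest", "x", 368, 387), cfg))
  expect_true(is_short(mk_feat("region_of_interest", "x", 1, 29), cfg))
  expect_false(is_short(mk_feat("region_of_interest", "x", 1, 30), cfg))
})

test_that("multi-interval features use the non-redundant residue count", {
  f <- rbind(mk_feat("region_of_interest", "x", 1, 20),
             mk_feat("region_of_interest", "x", 10, 35))
  expect_identical(feature_lengths(f)$length, 35L)
  # overlapping intervals are not double-counted: 35 residues, short fails
  expect_false(any(is_short(f)))
})

test_that("keyword rules keep inflected positives and drop negations", {
  cfg <- pros_config()
  kept_region <- select_binding_features(
    mk_feat("region_of_interest", "Interaction with USP7"), cfg)
  expect_identical(kept_region$selection_reason, "keyword_region")
  kept_mut <- select_binding_features(
    mk_feat("mutagenesis_site", "Loss of interactions with MDM2"), cfg)
  expect_identical(kept_mut$selection_reason, "keyword_mutagenesis")
  dropped <- select_binding_features(
    mk_feat("mutagenesis_site", "Does not abolish binding to X"), cfg)
  expect_identical(nrow(dropped), 0L)
  # "no" must not fire inside "nuclear"
  motif_free_region <- select_binding_features(
    mk_feat("region_of_interest", "Nuclear export region"), cfg)
  expect_identical(nrow(motif_free_region), 0L)
  kept_nuc <- select_binding_features(
    mk_feat("mutagenesis_site", "Impairs nuclear binding"), cfg)
  expect_identical(nrow(kept_nuc), 1L)
  # motifs need no keyword; other types are never selected
  expect_identical(select_binding_features(
    mk_feat("short_sequence_motif", "TAD I"), cfg)$selection_reason,
    "motif_class")
  expect_identical(nrow(select_binding_features(
    mk_feat("variant", "Interaction with X"), cfg)), 0L)
})

test_that("selection agrees with a token-based oracle on random text", {
  set.seed(201)
  cfg <- pros_config()
  words <- c("interaction", "binding", "motif", "loss", "of", "with",
             "no", "not", "does", "nuclear", "abolishes", "effect",
             "region", "X", "MDM2", "phosphorylation")
  types <- c(SELECTABLE_FEATURE_TYPES, "variant", "modified_residue")
  feats <- do.call(rbind, lapply(1:500, function(i) {
    mk_feat(sample(types, 1),
            paste(sample(words, sample(2:6, 1), replace = TRUE),
                  collapse = " "),
            id = sprintf("F%03d", i))
  }))
  got <- select_binding_features(feats, cfg)
  want <- feats[bf_select(feats, cfg), , drop = FALSE]
  expect_identical(got$feature_id, want$feature_id)
})

test_that("selection is permutation-equivariant and keyword-monotone", {
  set.seed(202)
  cfg <- pros_config()
  feats <- do.call(rbind, lapply(1:60, function(i) {
    mk_feat(sample(c(SELECTABLE_FEATURE_TYPES, "variant"), 1),
            sample(c("Interaction with X", "No binding", "Motif-like",
                     "Loss of binding", "plain text"), 1),
            id = sprintf("F%03d", i))
  }))
  base_ids <- select_binding_features(feats, cfg)$feature_id
  perm <- feats[sample.int(nrow(feats)), , drop = FALSE]
  expect_setequal(select_binding_features(perm, cfg)$feature_id, base_ids)
  # more positive keywords never removes a selection
  wider <- pros_config(positive_keywords_region =
                         c("interact", "bind", "motif", "loss"))
  expect_true(all(base_ids %in%
                    select_binding_features(feats, wider)$feature_id))
  # more negation tokens never adds one
  narrower <- pros_config(negation_tokens = c("no", "not", "loss"))
  expect_true(all(select_binding_features(feats, narrower)$feature_id %in%
                    base_ids))
})
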