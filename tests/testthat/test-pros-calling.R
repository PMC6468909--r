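test_that("full containment calls a pProS; zero coverage does not", {
  cohort <- make_fixture("p53_like")
  cfg <- pros_config()
  cons <- consensus_idrs(cohort, cfg)
  sel <- select_binding_features(short_features(cohort$features, cfg), cfg)
  pros <- call_pros(sel, cons, cfg)
  tad1 <- pros[pros$description == "TAD I", ]
  expect_identical(nrow(tad1), 1L)
  expect_identical(c(tad1$start, tad1$end), c(15L, 25L))
  expect_equal(tad1$idr_coverage, 1)
  # a feature entirely outside the consensus is never called
  outside <- data.frame(accession = "P04637", feature_id = "FX",
                        feature_type = "region_of_interest",
                        description = "Interaction with Q",
                        start = 150L, end = 160L,
                        selection_reason = "keyword_region")
  expect_identical(nrow(call_pros(outside, cons, cfg)), 0L)
})

test_that("random call sets equal the residue-membership oracle", {
  set.seed(401)
  for (i in 1:60) {
    len <- sample(60:200, 1)
    cons <- cbind(accession = "P1",
                  normalize_intervals(random_intervals(sample(1:4, 1), len)))
    feats <- do.call(rbind, lapply(1:6, function(j) {
      s <- sample.int(len - 10L, 1)
      data.frame(accession = "P1", feature_id = sprintf("F%02d", j),
                 feature_type = "region_of_interest",
                 description = "Interaction with X",
                 start = s, end = min(s + sample(0:9, 1), len),
                 selection_reason = "keyword_region",
                 stringsAsFactors = FALSE)
    }))
    for (thr in c(1, 0.5)) {
      cfg <- pros_config(idr_coverage_threshold = thr)
      got <- unique(call_pros(feats, cons, cfg)$feature_id)
      want <- feats$feature_id[vapply(seq_len(nrow(feats)), function(j) {
        bf_coverage(feats[j, ], cons) >= thr
      }, logical(1))]
      expect_setequal(got, unique(want))
    }
  }
})

test_that("lowering the coverage threshold never removes a call", {
  set.seed(402)
  cohort <- random_cohort(15L)
  cfg1 <- pros_config(idr_coverage_threshold = 1)
  cfg05 <- pros_config(idr_coverage_threshold = 0.5)
  cons <- consensus_idrs(cohort, cfg1)
  sel <- select_binding_features(short_features(cohort$features, cfg1),
                                 cfg1)
  strict <- unique(paste(call_pros(sel, cons, cfg1)$accession,
                         call_pros(sel, cons, cfg1)$feature_id))
  loose <- unique(paste(call_pros(sel, cons, cfg05)$accession,
                        call_pros(sel, cons, cfg05)$feature_id))
  expect_true(all(strict %in% loose))
})

test_that("generic feature-IDR intersection reports point coverage", {
  cons <- data.frame(accession = "P1", start = 10L, end = 40L)
  feats <- data.frame(accession = "P1", feature_id = c("V1", "V2"),
                      feature_type = "variant", description = "",
                      start = c(20L, 60L), end = c(20L, 60L))
  cov <- intersect_features_with_idrs(feats, cons)
  expect_equal(cov$idr_coverage[cov$feature_id == "V1"], 1)
  expect_equal(cov$idr_coverage[cov$feature_id == "V2"], 0)
})

test_that("planted variant in-IDR proportion is recovered", {
  # plant point variants 40% inside true IDRs under faithful tracks
  set.seed(403)
  g <- generate_cohort(cohort_params(n_proteins = 150L,
                                     predictor_agreement = 1, seed = 77L))
  truth <- g$ground_truth$disorder
  cohort <- g$cohort
  rows <- list()
  for (i in seq_len(nrow(cohort$proteins))) {
    acc <- cohort$proteins$accession[i]
    len <- cohort$proteins$length[i]
    tr <- truth[truth$accession == acc, c("start", "end")]
    inside <- bf_residues(tr)
    outside <- setdiff(seq_len(len), inside)
    if (length(inside) == 0L || length(outside) == 0L) next
    pos <- if (runif(1) < 0.4) sample(inside, 1) else sample(outside, 1)
    rows[[length(rows) + 1L]] <- data.frame(
      accession = acc, feature_id = "VAR1", feature_type = "variant",
      description = "", start = pos, end = pos, stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, rows)
  cons <- consensus_idrs(cohort)
  cov <- intersect_features_with_idrs(variants, cons)
  p_hat <- mean(cov$idr_coverage == 1)
  se <- sqrt(0.4 * 0.6 / nrow(variants))
  expect_lt(abs(p_hat - 0.4), 3 * se)
})

test_that("pProS residue accounting is a non-redundant union", {
  mk <- function(id, s, e) {
    data.frame(accession = "P1", feature_id = id,
               feature_type = "region_of_interest",
               selection_reason = "keyword_region", description = "",
               start = s, end = e, idr_coverage = 1,
               stringsAsFactors = FALSE)
  }
  twice <- rbind(mk("F1", 10L, 19L), mk("F2", 10L, 19L))
  expect_identical(pros_residues_per_protein(twice)$pros_residues, 10L)
  disjoint <- rbind(mk("F1", 1L, 5L), mk("F2", 7L, 9L))
  expect_identical(pros_residues_per_protein(disjoint)$pros_residues, 8L)
  set.seed(404)
  for (i in 1:40) {
    n <- sample(1:6, 1)
    pros <- do.call(rbind, lapply(seq_len(n), function(j) {
      s <- sample.int(90L, 1)
      mk(sprintf("F%d", j), s, s + sample(0:15, 1))
    }))
    got <- pros_residues_per_protein(pros)$pros_residues
    expect_identical(got, bf_union_count(pros[, c("start", "end")]))
    expect_lte(got, sum(pros$end - pros$start + 1L))
  }
})
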