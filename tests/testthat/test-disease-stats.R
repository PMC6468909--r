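test_that("half-up rounding behaves at decimal ties", {
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(0.15, 1), 0.2)
  expect_equal(round_half_up(-0.25, 1), -0.3)
  expect_equal(round_half_up(2.578, 1), 2.6)
  expect_equal(round_half_up(27.941, 1), 27.9)
})

test_that("printed-style ratios recompute from their integer inputs", {
  expect_equal(coverage_pct(402, 3378), 11.9)
  expect_equal(coverage_pct(1124, 18450), 6.1)
  expect_equal(coverage_pct(220, 2656), 8.3)
  expect_equal(coverage_pct(479, 14056), 3.4)
  expect_equal(coverage_pct(425, 1740), 24.4)
  expect_equal(coverage_pct(57, 204), 27.9)
  expect_equal(avg_annotations(147, 57), 2.6)
  expect_equal(coverage_pct(40, 687), 5.8)
  expect_equal(avg_annotations(33, 9), 3.7)
  expect_equal(coverage_pct(0, 0), 0)
  expect_equal(avg_annotations(0, 0), 0)
})

test_that("cohort summary counts short annotations and calls by type", {
  cohort <- make_fixture("p53_like")
  cfg <- pros_config()
  res <- run_pipeline(cohort, quiet = TRUE)
  t1 <- res$table1
  expect_identical(t1$statistic[1], "n_proteins")
  expect_identical(t1$all_proteins[1], 1L)
  expect_identical(t1$pros[1], 1L)
  # 11 short annotations, all called
  expect_identical(t1$pros[t1$statistic == "n_short_annotations"], 11L)
  expect_equal(t1$pros_pct[t1$statistic == "n_short_annotations"], 100)
  expect_identical(t1$pros[t1$statistic == "short_sequence_motif"], 5L)
  # a cohort with no calls reports zero percentages
  bare <- pros_cohort(data.frame(accession = "A", length = 100L),
                      diseases = data.frame(accession = "A",
                                            disease_id = "D1",
                                            category = "Can"))
  t1b <- run_pipeline(bare, quiet = TRUE)$table1
  expect_true(all(t1b$pros == 0L))
  expect_true(all(t1b$pros_pct == 0))
})

test_that("category table matches a brute-force recount", {
  set.seed(501)
  for (rep in 1:15) {
    cohort <- random_cohort(20L)
    cfg <- pros_config()
    cons <- consensus_idrs(cohort, cfg)
    sel <- select_binding_features(short_features(cohort$features, cfg),
                                   cfg)
    pros <- call_pros(sel, cons, cfg)
    tab <- category_table(cohort, pros)
    calls <- unique(pros[, c("accession", "feature_id")])
    for (k in seq_len(nrow(tab))) {
      cat_code <- tab$category[k]
      d <- cohort$diseases[cohort$diseases$category == cat_code, ]
      accs <- unique(d$accession)
      n_unique <- 0L; n_with <- 0L; redundant <- 0L
      for (a in accs) {
        cnt <- sum(calls$accession == a)
        n_unique <- n_unique + cnt
        if (cnt > 0) n_with <- n_with + 1L
        redundant <- redundant + cnt * sum(d$accession == a)
      }
      expect_identical(tab$n_proteins[k], length(accs))
      expect_identical(tab$n_unique_pros[k], n_unique)
      expect_identical(tab$n_proteins_with_pros[k], n_with)
      expect_identical(tab$pros_counts_redundant[k], redundant)
      expect_equal(tab$coverage_pct[k], coverage_pct(n_with, length(accs)))
      expect_equal(tab$avg_annotations[k],
                   avg_annotations(n_unique, n_with))
    }
    # redundancy is 1 exactly when no protein repeats a category
    one_dis <- tab$pros_redundancy[!is.na(tab$pros_redundancy)]
    expect_true(all(one_dis <= 1 + 1e-12))
  }
})

test_that("multi-category proteins are counted once per category", {
  cohort <- pros_cohort(
    data.frame(accession = c("A", "B"), length = c(100L, 100L)),
    diseases = data.frame(accession = c("A", "A", "B"),
                          disease_id = c("D1", "D2", "D3"),
                          category = c("Can", "Ner", "Can")))
  tab <- category_table(cohort, data.frame(
    accession = character(0), feature_id = character(0),
    start = integer(0), end = integer(0)))
  expect_identical(sum(tab$n_proteins), 3L)  # A counted in Can and Ner
  expect_true(all(tab$empty_flag))
})

test_that("protein ranking sorts by residues with lexicographic ties", {
  mk_call <- function(acc, s, e) {
    data.frame(accession = acc, feature_id = "F1",
               feature_type = "region_of_interest",
               selection_reason = "keyword_region", description = "",
               start = s, end = e, idr_coverage = 1,
               stringsAsFactors = FALSE)
  }
  cohort <- pros_cohort(
    data.frame(accession = c("A", "B", "C"), length = rep(200L, 3)),
    diseases = data.frame(accession = c("A", "A", "B"),
                          disease_id = c("D1", "D2", "D1"),
                          category = c("Can", "Can", "Ner")))
  pros <- rbind(mk_call("A", 1L, 63L), mk_call("B", 1L, 61L),
                mk_call("C", 1L, 55L))
  rk <- rank_by_pros_residues(cohort, pros)
  expect_identical(rk$accession, c("A", "B", "C"))
  expect_identical(rk$pros_residues, c(63L, 61L, 55L))
  expect_identical(rk$n_diseases, c(2L, 1L, 0L))
  expect_identical(rk$categories[1], "Can")
  # ties break lexicographically
  tie <- rbind(mk_call("B", 1L, 50L), mk_call("A", 1L, 50L))
  expect_identical(rank_by_pros_residues(cohort, tie)$accession,
                   c("A", "B"))
  # ranking equals an order() oracle on random residue counts
  set.seed(502)
  g <- generate_cohort(cohort_params(n_proteins = 60L, seed = 13L))
  res <- run_pipeline(g$cohort, quiet = TRUE)
  rk <- rank_by_pros_residues(g$cohort, res$pros_calls)
  want <- rk[order(-rk$pros_residues, rk$accession), ]
  expect_identical(rk$accession, want$accession)
  res_by <- pros_residues_per_protein(res$pros_calls)
  expect_setequal(rk$accession, res_by$accession)
})
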