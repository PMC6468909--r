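test_that("two of three predictors put a residue in the consensus", {
  tracks <- list(mobidb_lite = data.frame(start = 10L, end = 30L),
                 disopred3 = data.frame(start = integer(0),
                                        end = integer(0)),
                 dichot = data.frame(start = 20L, end = 40L))
  cons <- consensus_intervals(tracks, 100L)
  expect_equal(cons, data.frame(start = 20L, end = 30L))
  # no votes, no consensus
  expect_identical(nrow(consensus_intervals(
    list(a = data.frame(start = integer(0), end = integer(0))), 50L)), 0L)
  expect_error(consensus_intervals(list(), 50L), "at least one")
  expect_error(consensus_intervals(list(a = logical(40)), 50L),
               "does not match protein length")
})

test_that("consensus of identical tracks equals each track", {
  tr <- data.frame(start = c(5L, 40L), end = c(15L, 60L))
  cons <- consensus_intervals(list(a = tr, b = tr, c = tr), 80L)
  expect_equal(cons, tr)
})

test_that("consensus matches per-residue vote counting on random tracks", {
  set.seed(301)
  for (i in 1:200) {
    len <- sample(30:150, 1)
    tracks <- lapply(1:3, function(j) random_intervals(sample(0:4, 1), len))
    names(tracks) <- PREDICTORS
    for (votes in 1:3) {
      cfg <- pros_config(min_predictor_votes = votes)
      got <- bf_residues(consensus_intervals(tracks, len, cfg))
      expect_identical(got, as.integer(bf_consensus_residues(tracks, len,
                                                             votes)))
    }
  }
})

test_that("lowering the vote threshold never shrinks the consensus", {
  set.seed(302)
  for (i in 1:30) {
    len <- sample(50:120, 1)
    tracks <- lapply(1:3, function(j) random_intervals(sample(1:4, 1), len))
    r3 <- bf_residues(consensus_intervals(tracks, len,
                                          pros_config(min_predictor_votes = 3)))
    r2 <- bf_residues(consensus_intervals(tracks, len,
                                          pros_config(min_predictor_votes = 2)))
    r1 <- bf_residues(consensus_intervals(tracks, len,
                                          pros_config(min_predictor_votes = 1)))
    expect_true(all(r3 %in% r2) && all(r2 %in% r1))
  }
})

test_that("IDR fractions follow residue arithmetic", {
  expect_identical(idr_fraction(data.frame(start = 1L, end = 50L), 50L), 1)
  expect_identical(idr_fraction(data.frame(start = integer(0),
                                           end = integer(0)), 50L), 0)
  expect_error(idr_fraction(data.frame(start = 1L, end = 5L), 0L),
               "positive")
  set.seed(303)
  for (i in 1:25) {
    len <- sample(40:200, 1)
    iv <- normalize_intervals(random_intervals(sample(1:5, 1), len))
    expect_equal(idr_fraction(iv, len), length(bf_residues(iv)) / len)
  }
})

test_that("aggregate fraction is residue-weighted and bounded", {
  cohort <- pros_cohort(
    data.frame(accession = c("A", "B"), length = c(100L, 100L)),
    tracks = data.frame(accession = c("A", "A"),
                        predictor_id = c("mobidb_lite", "disopred3"),
                        start = c(1L, 1L), end = c(50L, 50L)))
  cons <- consensus_idrs(cohort)
  agg <- aggregate_idr_fraction(cohort, cons)
  expect_equal(agg$residue_weighted, 0.25)
  expect_equal(agg$mean_per_protein, 0.25)
  single <- aggregate_idr_fraction(cohort, cons, "A")
  expect_equal(single$residue_weighted, idr_fraction(
    cons[cons$accession == "A", c("start", "end")], 100L))
  expect_error(aggregate_idr_fraction(cohort, cons, character(0)),
               "empty")
  # bounded by the per-protein extremes
  g <- generate_cohort(cohort_params(n_proteins = 40L, seed = 8L))
  cons <- consensus_idrs(g$cohort)
  per <- vapply(g$cohort$proteins$accession, function(a) {
    idr_fraction(cons[cons$accession == a, c("start", "end")],
                 g$cohort$proteins$length[
                   g$cohort$proteins$accession == a])
  }, numeric(1))
  agg <- aggregate_idr_fraction(g$cohort, cons)
  expect_gte(agg$residue_weighted, min(per))
  expect_lte(agg$residue_weighted, max(per))
})
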