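test_that("a feature row parses into the expected record", {
  d <- tempfile()
  dir.create(d)
  writeLines(c("accession\tlength\tfeature_type\tdescription\tstart\tend\tfeature_id",
               "P04637\t393\tshort_sequence_motif\tTAD I\t15\t25\tF01"),
             file.path(d, "features.tsv"))
  cohort <- read_cohort(file.path(d, "features.tsv"))
  expect_identical(cohort$proteins$accession, "P04637")
  expect_identical(cohort$proteins$length, 393L)
  expect_identical(cohort$features$feature_type, "short_sequence_motif")
  expect_identical(cohort$features$start, 15L)
  expect_identical(cohort$features$end, 25L)
})

test_that("an empty annotation file yields an empty cohort", {
  f <- tempfile(fileext = ".tsv")
  writeLines("accession\tlength\tfeature_type\tdescription\tstart\tend\tfeature_id",
             f)
  cohort <- read_cohort(f)
  expect_identical(nrow(cohort$proteins), 0L)
  expect_identical(nrow(cohort$features), 0L)
})

test_that("write_cohort then read_cohort reproduces a synthetic cohort", {
  g <- generate_cohort(cohort_params(n_proteins = 50L, seed = 9L))
  d <- tempfile()
  write_cohort(g$cohort, d)
  back <- read_cohort(file.path(d, "features.tsv"),
                      tracks = file.path(d, "tracks.tsv"),
                      diseases = file.path(d, "diseases.tsv"),
                      locations = file.path(d, "locations.tsv"),
                      ppi = file.path(d, "ppi.tsv"))
  expect_identical(unclass(back), unclass(g$cohort))
})

test_that("validation is fail-fast and names the offender", {
  prot <- data.frame(accession = "P1", length = 100L)
  feat_bad <- data.frame(accession = "P1", feature_id = "F1",
                         feature_type = "region_of_interest",
                         description = "Interaction with X",
                         start = 90L, end = 120L)
  expect_error(pros_cohort(prot, features = feat_bad), "F1 on P1")
  expect_error(pros_cohort(data.frame(accession = c("P1", "P1"),
                                      length = c(10L, 10L))),
               "duplicate accession")
  expect_error(pros_cohort(prot, diseases = data.frame(
    accession = "P1", disease_id = "D1", category = "Xyz")),
    "unknown disease category")
  expect_error(pros_cohort(prot, tracks = data.frame(
    accession = "P1", predictor_id = "iupred", start = 1L, end = 5L)),
    "unknown predictor")
})

test_that("report writing is deterministic and order-independent", {
  g <- generate_cohort(cohort_params(n_proteins = 30L, seed = 4L))
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  run_pipeline(g$cohort, out_dir = d1, quiet = TRUE)
  run_pipeline(g$cohort, out_dir = d2, quiet = TRUE)
  # shuffle every table's rows; the constructor re-sorts canonically
  shuffled <- pros_cohort(
    g$cohort$proteins[sample.int(nrow(g$cohort$proteins)), ],
    features = g$cohort$features[sample.int(nrow(g$cohort$features)), ],
    tracks = g$cohort$tracks[sample.int(nrow(g$cohort$tracks)), ],
    diseases = g$cohort$diseases[sample.int(nrow(g$cohort$diseases)), ],
    locations = g$cohort$locations[sample.int(nrow(g$cohort$locations)), ])
  run_pipeline(shuffled, out_dir = d3, quiet = TRUE)
  files <- setdiff(list.files(d1), "manifest.json")
  expect_true(length(files) >= 10)
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d3, f))), label = f)
  }
})
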