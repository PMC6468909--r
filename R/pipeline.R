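# End-to-end orchestration: read -> select -> consensus -> call ->
# statistics -> report. All tables are computed before anything is
# written, so a validation failure never leaves partial output behind.

#' Run the full pProS discovery pipeline
#'
#' Executes every stage on a cohort and (optionally) writes the report
#' tables. `input` is either a directory containing the five input TSVs
#' (features.tsv required; tracks.tsv, diseases.tsv, locations.tsv,
#' ppi.tsv optional) or an in-memory [pros_cohort()].
#'
#' Report files, all with deterministic row and column order:
#' selected_features.tsv, consensus.tsv, pros_calls.tsv, table1.tsv,
#' table2.tsv, table3.tsv, idr_fractions.tsv,
#' localization_enrichment.tsv, ppi_correlation.tsv, ppi_bins.tsv,
#' config.json, and manifest.json. Identical inputs and configuration
#' yield byte-identical report tables and config.json; manifest.json
#' additionally records wall-clock stage timings and is exempt from the
#' byte-identity contract.
#'
#' @param input directory of input TSVs, or a [pros_cohort()].
#' @param out_dir optional report directory; when NULL nothing is
#'   written.
#' @param config a [pros_config()].
#' @param quiet suppress per-stage row-count messages.
#' @return invisibly, a list with the cohort, every intermediate
#'   (`selected`, `consensus`, `pros`), and every report table.
#' @export
run_pipeline <- function(input, out_dir = NULL, config = pros_config(),
                         quiet = FALSE) {
  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0,
                                             units = "secs"))
    t0 <<- Sys.time()
  }
  say <- function(...) if (!quiet) message(...)

  input_paths <- NULL
  if (inherits(input, "pros_cohort")) {
    cohort <- input
  } else {
    stopifnot(is.character(input), length(input) == 1L)
    p <- function(f) {
      path <- file.path(input, f)
      if (file.exists(path)) path else NULL
    }
    features_path <- file.path(input, "features.tsv")
    if (!file.exists(features_path)) {
      stop("features.tsv not found in ", input)
    }
    input_paths <- c(features = features_path,
                     stats::setNames(
                       unlist(lapply(c("tracks.tsv", "diseases.tsv",
                                       "locations.tsv", "ppi.tsv"), p)),
                       NULL))
    cohort <- read_cohort(features_path, tracks = p("tracks.tsv"),
                          diseases = p("diseases.tsv"),
                          locations = p("locations.tsv"),
                          ppi = p("ppi.tsv"))
  }
  say("read: ", nrow(cohort$proteins), " proteins, ",
      nrow(cohort$features), " feature intervals, ",
      nrow(cohort$tracks), " track intervals")
  tick("read")

  short <- short_features(cohort$features, config)
  selected <- select_binding_features(short, config)
  say("select: ", length(unique(paste(selected$accession,
                                      selected$feature_id))),
      " binding-associated short features")
  tick("select")

  consensus <- consensus_idrs(cohort, config)
  say("consensus: ", nrow(consensus), " consensus IDR intervals")
  tick("consensus")

  pros <- call_pros(selected, consensus, config)
  n_pros <- length(unique(paste(pros$accession, pros$feature_id)))
  say("call: ", n_pros, " pProSs")
  tick("call")

  table1 <- table1_stats(cohort, pros, config)
  table2 <- category_table(cohort, pros)
  table3 <- rank_by_pros_residues(cohort, pros)

  dis_acc <- disease_accessions(cohort)
  pros_acc <- unique(pros$accession)
  idr_sets <- list(all_proteins = cohort$proteins$accession,
                   disease_all = dis_acc,
                   disease_pros = intersect(dis_acc, pros_acc),
                   disease_non_pros = setdiff(dis_acc, pros_acc))
  for (cat in intersect(DISEASE_CATEGORIES,
                        unique(cohort$diseases$category))) {
    acc <- unique(cohort$diseases$accession[
      cohort$diseases$category == cat])
    idr_sets[[paste0(cat, "_all")]] <- acc
    idr_sets[[paste0(cat, "_pros")]] <- intersect(acc, pros_acc)
    idr_sets[[paste0(cat, "_non_pros")]] <- setdiff(acc, pros_acc)
  }
  idr_fractions <- do.call(rbind, lapply(names(idr_sets), function(nm) {
    acc <- idr_sets[[nm]]
    if (length(acc) == 0L) {
      return(data.frame(set_name = nm, n_proteins = 0L,
                        residue_weighted_fraction = NA_real_,
                        mean_per_protein_fraction = NA_real_,
                        stringsAsFactors = FALSE))
    }
    f <- aggregate_idr_fraction(cohort, consensus, acc)
    data.frame(set_name = nm, n_proteins = f$n_proteins,
               residue_weighted_fraction = f$residue_weighted,
               mean_per_protein_fraction = f$mean_per_protein,
               stringsAsFactors = FALSE)
  }))

  classes <- location_classes(cohort)
  cls_of <- stats::setNames(classes$location_class, classes$accession)
  background <- unname(cls_of)
  loc_groups <- list(All_pros_containing = intersect(dis_acc, pros_acc),
                     All_non_pros = setdiff(dis_acc, pros_acc))
  for (cat in intersect(DISEASE_CATEGORIES,
                        unique(cohort$diseases$category))) {
    acc <- unique(cohort$diseases$accession[
      cohort$diseases$category == cat])
    loc_groups[[paste0(cat, "_pros_containing")]] <-
      intersect(acc, pros_acc)
    loc_groups[[paste0(cat, "_non_pros")]] <- setdiff(acc, pros_acc)
  }
  loc_rows <- lapply(names(loc_groups), function(nm) {
    acc <- loc_groups[[nm]]
    if (length(acc) == 0L) return(NULL)
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    enr <- location_enrichment(unname(cls_of[acc]), background, config)
    cbind(category = parts[1],
          group = paste(parts[-1], collapse = "_"), enr,
          stringsAsFactors = FALSE)
  })
  localization_enrichment_tab <- do.call(rbind, c(loc_rows, list(
    data.frame(category = character(0), group = character(0),
               location_class = character(0), group_fraction = numeric(0),
               background_fraction = numeric(0), log_ratio = numeric(0),
               flag = character(0)))))

  binned <- suppressMessages(bin_by_disease_count(cohort))
  n_bins_all <- length(unique(binned$n_diseases))
  n_bins_lt10 <- length(unique(binned$n_diseases[binned$n_diseases < 10]))
  corr_row <- function(stat, restriction, method, max_d, n_bins) {
    r <- tryCatch(disease_ppi_correlation(binned, stat = stat,
                                          max_diseases = max_d,
                                          method = method),
                  error = function(e) NA_real_)
    data.frame(stat = stat, restriction = restriction, method = method,
               n_bins = n_bins, r = r,
               flag = ifelse(is.na(r), "undefined", ""),
               stringsAsFactors = FALSE)
  }
  ppi_correlation <- rbind(
    corr_row("mean", "none", "bins", Inf, n_bins_all),
    corr_row("median", "none", "bins", Inf, n_bins_all),
    corr_row("mean", "n_diseases_lt_10", "bins", 10, n_bins_lt10),
    corr_row("median", "n_diseases_lt_10", "bins", 10, n_bins_lt10),
    corr_row("mean", "none", "pairs", Inf, n_bins_all))
  ppi_bins <- if (nrow(binned) > 0L) ppi_bin_summary(binned) else
    data.frame(n_diseases = integer(0), n_proteins = integer(0),
               mean = numeric(0), median = numeric(0), q1 = numeric(0),
               q3 = numeric(0), min = numeric(0), max = numeric(0))
  tick("stats")

  tables <- list(selected_features = selected[, c("accession",
                   "feature_id", "feature_type", "selection_reason",
                   "start", "end", "description")],
                 consensus = consensus,
                 pros_calls = pros[, c("accession", "feature_id",
                   "feature_type", "start", "end", "idr_coverage",
                   "selection_reason", "description")],
                 table1 = table1, table2 = table2, table3 = table3,
                 idr_fractions = idr_fractions,
                 localization_enrichment = localization_enrichment_tab,
                 ppi_correlation = ppi_correlation,
                 ppi_bins = ppi_bins)

  if (!is.null(out_dir)) {
    write_report(tables, out_dir, config)
    manifest <- list(
      package_version = as.character(utils::packageVersion("proseg")),
      config = unclass(config),
      inputs = if (is.null(input_paths)) "in-memory cohort" else
        as.list(tools::md5sum(input_paths)),
      row_counts = list(proteins = nrow(cohort$proteins),
                        feature_intervals = nrow(cohort$features),
                        track_intervals = nrow(cohort$tracks),
                        selected = nrow(selected),
                        consensus_intervals = nrow(consensus),
                        pros_calls = n_pros),
      stage_seconds = timings)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    say("report written to ", out_dir)
  }

  invisible(c(list(cohort = cohort, config = config), tables))
}
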