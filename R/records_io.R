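# Cohort container and the flat TSV dialects.
#
# A cohort is five data frames. features.tsv is the master table: it
# carries the accession and protein length on every row, and a protein
# without any feature is declared by a single row whose feature fields
# are empty. The other four tables attach tracks, disease assignments,
# location terms, and interactor counts by accession. All coordinates
# are 1-based inclusive. Validation is fail-fast: malformed rows raise
# an error naming the accession, nothing is silently dropped.

#' Construct a protein cohort
#'
#' Assembles and validates the five tables of a cohort. Most users will
#' get a cohort from [read_cohort()], [generate_cohort()], or
#' [make_fixture()] instead of calling this directly.
#'
#' @param proteins data frame: `accession`, `length`, optional
#'   `interactor_count` (NA when no interaction data exist).
#' @param features data frame: `accession`, `feature_id`, `feature_type`,
#'   `description`, `start`, `end`. A feature may span several rows (one
#'   per interval) sharing its `feature_id`.
#' @param tracks data frame: `accession`, `predictor_id`, `start`, `end`;
#'   intervals a predictor calls disordered. Residues not covered are
#'   treated as ordered.
#' @param diseases data frame: `accession`, `disease_id`, `category`
#'   (one of [DISEASE_CATEGORIES]).
#' @param locations data frame: `accession`, `location_term`.
#' @return object of class `pros_cohort`.
#' @export
pros_cohort <- function(proteins,
                        features = empty_features(),
                        tracks = empty_tracks(),
                        diseases = empty_diseases(),
                        locations = empty_locations()) {
  proteins <- as.data.frame(proteins, stringsAsFactors = FALSE)
  if (!all(c("accession", "length") %in% names(proteins))) {
    stop("proteins table needs columns accession, length")
  }
  if (is.null(proteins$interactor_count)) {
    proteins$interactor_count <- rep(NA_integer_, nrow(proteins))
  }
  proteins <- proteins[, c("accession", "length", "interactor_count")]
  proteins$accession <- as.character(proteins$accession)
  proteins$length <- as.integer(proteins$length)
  proteins$interactor_count <- as.integer(proteins$interactor_count)

  if (anyNA(proteins$accession) || any(proteins$accession == "")) {
    stop("protein accessions must be non-empty")
  }
  dup <- proteins$accession[duplicated(proteins$accession)]
  if (length(dup) > 0L) {
    stop("duplicate accession in cohort: ", paste(unique(dup), collapse = ", "))
  }
  if (anyNA(proteins$length) || any(proteins$length < 1L)) {
    stop("protein lengths must be positive integers")
  }
  bad_ppi <- !is.na(proteins$interactor_count) & proteins$interactor_count < 0L
  if (any(bad_ppi)) {
    stop("negative interactor_count for ",
         paste(proteins$accession[bad_ppi], collapse = ", "))
  }

  len_of <- stats::setNames(proteins$length, proteins$accession)

  features <- coerce_table(features, empty_features())
  check_text_fields(features, c("feature_type", "description"))
  check_known_accessions(features$accession, len_of, "features")
  for (acc in unique(features$accession)) {
    rows <- features[features$accession == acc, ]
    for (fid in unique(rows$feature_id)) {
      f <- rows[rows$feature_id == fid, ]
      check_intervals(f, context = paste0("feature ", fid, " on ", acc),
                      max_end = len_of[[acc]])
      if (length(unique(f$feature_type)) != 1L) {
        stop("feature ", fid, " on ", acc, " has inconsistent feature_type")
      }
    }
    if (any(rows$feature_id == "")) {
      stop("empty feature_id on ", acc)
    }
  }

  tracks <- coerce_table(tracks, empty_tracks())
  check_known_accessions(tracks$accession, len_of, "tracks")
  bad_pred <- setdiff(unique(tracks$predictor_id), PREDICTORS)
  if (length(bad_pred) > 0L) {
    stop("unknown predictor_id: ", paste(bad_pred, collapse = ", "))
  }
  for (acc in unique(tracks$accession)) {
    rows <- tracks[tracks$accession == acc, ]
    check_intervals(rows, context = paste0("disorder track on ", acc),
                    max_end = len_of[[acc]])
  }

  diseases <- coerce_table(diseases, empty_diseases())
  check_known_accessions(diseases$accession, len_of, "diseases")
  bad_cat <- setdiff(unique(diseases$category), DISEASE_CATEGORIES)
  if (length(bad_cat) > 0L) {
    stop("unknown disease category code: ", paste(bad_cat, collapse = ", "))
  }
  key <- paste(diseases$accession, diseases$disease_id)
  if (anyDuplicated(key)) {
    stop("duplicate disease assignment: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }

  locations <- coerce_table(locations, empty_locations())
  check_text_fields(locations, "location_term")
  check_known_accessions(locations$accession, len_of, "locations")

  out <- list(proteins = sort_reset(proteins, c("accession")),
              features = sort_reset(features,
                                    c("accession", "feature_id", "start")),
              tracks = sort_reset(tracks,
                                  c("accession", "predictor_id", "start")),
              diseases = sort_reset(diseases, c("accession", "disease_id")),
              locations = sort_reset(locations,
                                     c("accession", "location_term")))
  class(out) <- "pros_cohort"
  out
}

empty_features <- function() {
  data.frame(accession = character(0), feature_id = character(0),
              feature_type = character(0), description = character(0),
              start = integer(0), end = integer(0))
}
empty_tracks <- function() {
  data.frame(accession = character(0), predictor_id = character(0),
              start = integer(0), end = integer(0))
}
empty_diseases <- function() {
  data.frame(accession = character(0), disease_id = character(0),
              category = character(0))
}
empty_locations <- function() {
  data.frame(accession = character(0), location_term = character(0))
}

coerce_table <- function(x, template) {
  if (is.null(x)) x <- template
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  missing <- setdiff(names(template), names(x))
  if (length(missing) > 0L) {
    stop("table is missing columns: ", paste(missing, collapse = ", "))
  }
  x <- x[, names(template), drop = FALSE]
  for (col in names(template)) {
    x[[col]] <- if (is.integer(template[[col]])) as.integer(x[[col]])
                else as.character(x[[col]])
  }
  x
}

check_known_accessions <- function(acc, len_of, what) {
  unknown <- setdiff(unique(acc), names(len_of))
  if (length(unknown) > 0L) {
    stop(what, " table references unknown accession: ",
         paste(unknown, collapse = ", "))
  }
}

check_text_fields <- function(x, cols) {
  for (col in cols) {
    v <- x[[col]]
    if (anyNA(v)) stop("missing values in column ", col)
    if (any(grepl("[\t\n\r]", v))) {
      stop("column ", col, " contains tab or newline characters")
    }
  }
}

sort_reset <- function(x, keys) {
  ord <- do.call(order, unname(as.list(x[, keys, drop = FALSE])))
  x <- x[ord, , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' @export
print.pros_cohort <- function(x, ...) {
  cat("pProS cohort:", nrow(x$proteins), "proteins,",
      length(unique(paste(x$features$accession, x$features$feature_id))),
      "features,", nrow(x$tracks), "track intervals,\n ",
      nrow(x$diseases), "disease assignments,",
      nrow(x$locations), "location terms,",
      sum(!is.na(x$proteins$interactor_count)), "interactor counts\n")
  invisible(x)
}

#' Read a cohort from its five TSV tables
#'
#' Reads the documented flat dialects and assembles a validated cohort.
#' `features` is required and defines the cohort membership: every row
#' carries `accession` and `length`, and a protein without features is
#' declared with empty `feature_id`/`feature_type`/`description` and
#' blank coordinates. The optional tables attach disorder tracks, disease
#' assignments, location terms, and interactor counts; a missing table
#' yields empty assignments (and absent interactor counts).
#'
#' Dialects (tab-separated, header row, UTF-8, no quoting):
#' \itemize{
#' \item features.tsv: accession, length, feature_type, description,
#'   start, end, feature_id
#' \item tracks.tsv: accession, predictor_id, start, end
#' \item diseases.tsv: accession, disease_id, category_code
#' \item locations.tsv: accession, location_term
#' \item ppi.tsv: accession, interactor_count
#' }
#'
#' @param features path to features.tsv.
#' @param tracks,diseases,locations,ppi optional paths to the remaining
#'   tables.
#' @return a [pros_cohort()] object.
#' @export
read_cohort <- function(features, tracks = NULL, diseases = NULL,
                        locations = NULL, ppi = NULL) {
  ft <- read_tsv_checked(features,
                         c(accession = "character", length = "integer",
                           feature_type = "character",
                           description = "character",
                           start = "integer", end = "integer",
                           feature_id = "character"))

  lengths <- unique(ft[, c("accession", "length")])
  if (anyDuplicated(lengths$accession)) {
    dup <- lengths$accession[duplicated(lengths$accession)]
    stop("conflicting protein lengths for accession: ",
         paste(unique(dup), collapse = ", "))
  }
  proteins <- lengths

  is_decl <- is.na(ft$start) & is.na(ft$end) &
    trimws(as.character(ft$feature_type)) == ""
  bad <- is.na(ft$start) != is.na(ft$end)
  if (any(bad)) {
    stop("malformed feature row (one endpoint missing) for accession: ",
         paste(unique(ft$accession[bad]), collapse = ", "))
  }
  feat <- ft[!is_decl, c("accession", "feature_id", "feature_type",
                         "description", "start", "end")]
  if (anyNA(feat$start)) {
    stop("feature rows with a feature_type must carry integer coordinates")
  }

  tr <- if (is.null(tracks)) NULL else {
    read_tsv_checked(tracks, c(accession = "character",
                               predictor_id = "character",
                               start = "integer", end = "integer"))
  }
  di <- if (is.null(diseases)) NULL else {
    d <- read_tsv_checked(diseases, c(accession = "character",
                                      disease_id = "character",
                                      category_code = "character"))
    names(d)[names(d) == "category_code"] <- "category"
    d
  }
  lo <- if (is.null(locations)) NULL else {
    read_tsv_checked(locations, c(accession = "character",
                                  location_term = "character"))
  }

  if (!is.null(ppi)) {
    pp <- read_tsv_checked(ppi, c(accession = "character",
                                  interactor_count = "integer"))
    if (anyNA(pp$interactor_count)) {
      stop("ppi table has missing interactor_count values")
    }
    if (anyDuplicated(pp$accession)) {
      stop("duplicate accession in ppi table")
    }
    proteins$interactor_count <-
      pp$interactor_count[match(proteins$accession, pp$accession)]
  }

  pros_cohort(proteins, features = feat, tracks = tr, diseases = di,
              locations = lo)
}

# `spec` is a named character vector: column name -> class.
read_tsv_checked <- function(path, spec) {
  if (!file.exists(path)) stop("input table not found: ", path)
  header <- utils::read.delim(path, sep = "\t", quote = "",
                              comment.char = "", nrows = 1,
                              check.names = FALSE, colClasses = "character")
  missing <- setdiff(names(spec), names(header))
  if (length(missing) > 0L) {
    stop(path, " is missing columns: ", paste(missing, collapse = ", "))
  }
  classes <- stats::setNames(rep("character", ncol(header)), names(header))
  classes[names(spec)] <- spec
  x <- tryCatch(
    utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = classes),
    warning = function(w) stop(path, ": malformed value (",
                               conditionMessage(w), ")"),
    error = function(e) stop(path, ": malformed row (",
                             conditionMessage(e), ")"))
  x[, names(spec), drop = FALSE]
}

#' Write a cohort back to its five TSV tables
#'
#' Inverse of [read_cohort()]: writes features.tsv, tracks.tsv,
#' diseases.tsv, locations.tsv, and ppi.tsv into `dir` in the documented
#' dialects with deterministic row order, such that reading them back
#' reproduces the cohort exactly.
#'
#' @param cohort a [pros_cohort()] object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pros_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  feat <- cohort$features
  ft <- data.frame(accession = feat$accession,
                   length = cohort$proteins$length[
                     match(feat$accession, cohort$proteins$accession)],
                   feature_type = feat$feature_type,
                   description = feat$description,
                   start = feat$start, end = feat$end,
                   feature_id = feat$feature_id,
                   stringsAsFactors = FALSE)
  bare <- setdiff(cohort$proteins$accession, feat$accession)
  if (length(bare) > 0L) {
    ft <- rbind(ft, data.frame(
      accession = bare,
      length = cohort$proteins$length[
        match(bare, cohort$proteins$accession)],
      feature_type = "", description = "",
      start = NA_integer_, end = NA_integer_, feature_id = "",
      stringsAsFactors = FALSE))
  }
  ft <- sort_reset(ft, c("accession", "feature_id", "start"))

  di <- cohort$diseases
  names(di)[names(di) == "category"] <- "category_code"
  pp <- cohort$proteins[!is.na(cohort$proteins$interactor_count),
                        c("accession", "interactor_count")]

  paths <- c(features = file.path(dir, "features.tsv"),
             tracks = file.path(dir, "tracks.tsv"),
             diseases = file.path(dir, "diseases.tsv"),
             locations = file.path(dir, "locations.tsv"),
             ppi = file.path(dir, "ppi.tsv"))
  write_tsv(ft, paths[["features"]])
  write_tsv(cohort$tracks, paths[["tracks"]])
  write_tsv(di, paths[["diseases"]])
  write_tsv(cohort$locations, paths[["locations"]])
  write_tsv(sort_reset(pp, "accession"), paths[["ppi"]])
  invisible(paths)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
}

#' Write report tables plus a configuration sidecar
#'
#' Writes each table of a named list as `<name>.tsv` (tab-separated,
#' header, UTF-8) and the configuration used as `config.json`. Producers
#' of the tables sort rows by documented keys, so identical inputs and
#' configuration yield byte-identical files regardless of input order.
#'
#' @param tables named list of data frames.
#' @param out_dir output directory (created if needed).
#' @param config the [pros_config()] the tables were computed under.
#' @return invisibly, the paths written.
#' @export
write_report <- function(tables, out_dir, config = pros_config()) {
  stopifnot(is.list(tables), !is.null(names(tables)),
            all(names(tables) != ""))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv(tables[[nm]], p)
    paths <- c(paths, p)
  }
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(paths, cfg_path))
}
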