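# Subcellular localization classes and log ratio-of-ratios enrichment.
#
# Four classes are recognized from plain location terms: N (nucleus
# only), C (cytoplasm only), M (membrane only), and CN (both cytoplasm
# and nucleus, the shuttling class). Everything else, including proteins
# with no recognized term, is "other". Matching is case-insensitive
# exact on the trimmed terms "nucleus", "cytoplasm", "membrane".

RECOGNIZED_TERMS <- c(N = "nucleus", C = "cytoplasm", M = "membrane")

#' Classify a protein's location terms
#'
#' @param terms character vector of location terms for one protein.
#' @return one of "N", "C", "M", "CN", "other".
#' @examples
#' classify_location(c("Cytoplasm", "Nucleus"))  # "CN"
#' classify_location("nucleus")                  # "N"
#' classify_location("endoplasmic reticulum")    # "other"
#' @export
classify_location <- function(terms) {
  norm <- unique(tolower(trimws(as.character(terms))))
  rec <- intersect(norm, RECOGNIZED_TERMS)
  if (all(c("cytoplasm", "nucleus") %in% rec)) return("CN")
  if (length(rec) == 1L) {
    return(names(RECOGNIZED_TERMS)[RECOGNIZED_TERMS == rec])
  }
  "other"
}

#' Location class of every protein in a cohort
#'
#' @param cohort a [pros_cohort()].
#' @return data frame `accession`, `location_class`; proteins without
#'   location terms are classed "other".
#' @export
location_classes <- function(cohort) {
  stopifnot(inherits(cohort, "pros_cohort"))
  by_acc <- split(cohort$locations$location_term,
                  cohort$locations$accession)
  cls <- vapply(cohort$proteins$accession, function(acc) {
    terms <- by_acc[[acc]]
    if (is.null(terms)) "other" else classify_location(terms)
  }, character(1))
  data.frame(accession = cohort$proteins$accession,
             location_class = unname(cls), stringsAsFactors = FALSE)
}

#' Per-term tallies of location annotations
#'
#' Raw counts of every normalized location term in a protein set; this
#' is how non-membrane-organelle terms (stress granule, P-body, ...) are
#' surveyed without a dedicated class.
#'
#' @param cohort a [pros_cohort()].
#' @param accessions protein subset; defaults to the whole cohort.
#' @return data frame `location_term`, `n_proteins`, sorted by
#'   decreasing count then term.
#' @export
location_term_counts <- function(cohort, accessions = NULL) {
  loc <- cohort$locations
  if (!is.null(accessions)) {
    loc <- loc[loc$accession %in% accessions, , drop = FALSE]
  }
  loc$location_term <- tolower(trimws(loc$location_term))
  loc <- unique(loc)
  tab <- table(loc$location_term)
  out <- data.frame(location_term = names(tab),
                    n_proteins = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(-out$n_proteins, out$location_term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Localization enrichment as log ratio-of-ratios
#'
#' For each location class, the fraction of the group in that class is
#' divided by the fraction of the background in it, and the logarithm
#' (base `config$enrichment_log_base`, default 2) of the ratio is
#' reported. A class with a zero fraction on either side is flagged and
#' gets no numeric value. Swapping group and background negates every
#' log ratio.
#'
#' @param group_classes character vector of location classes for the
#'   group (e.g. from [location_classes()] rows).
#' @param background_classes location classes of the background set.
#' @param config a [pros_config()].
#' @return data frame `location_class`, `group_fraction`,
#'   `background_fraction`, `log_ratio`, `flag`.
#' @export
location_enrichment <- function(group_classes, background_classes,
                                config = pros_config()) {
  if (length(group_classes) == 0L || length(background_classes) == 0L) {
    stop("group and background must be non-empty")
  }
  lev <- LOCATION_CLASSES
  gf <- as.vector(table(factor(group_classes, levels = lev))) /
    length(group_classes)
  bf <- as.vector(table(factor(background_classes, levels = lev))) /
    length(background_classes)
  ratio <- gf / bf
  lr <- log(ratio, base = config$enrichment_log_base)
  flag <- ifelse(gf == 0 | bf == 0, "zero_fraction", "")
  lr[flag != ""] <- NA_real_
  data.frame(location_class = lev, group_fraction = gf,
             background_fraction = bf, log_ratio = lr, flag = flag,
             stringsAsFactors = FALSE)
}
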