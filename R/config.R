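#' Pipeline thresholds and keyword rules
#'
#' Collects every tunable of the pProS discovery procedure in one object.
#' Defaults encode the standard discovery procedure: features must be shorter than
#' 30 residues (`max_feature_length = 29`), a residue is consensus
#' disordered when at least two of the three predictors call it
#' (`min_predictor_votes = 2`), and a selected feature becomes a pProS
#' when all of its residues lie inside the consensus IDR
#' (`idr_coverage_threshold = 1`). Keyword sets drive description
#' matching: "region of interest" features qualify on interact/bind/motif,
#' "mutagenesis site" features on interact/bind unless the description
#' carries a negation token ("no"/"not" as whole words), and "short
#' sequence motif" features qualify unconditionally.
#'
#' Positive keywords match case-insensitively at word starts (so
#' "interact" hits "Interaction with USP7"); negation tokens match whole
#' words only, so "no" never fires inside "nuclear".
#'
#' @param max_feature_length maximum non-redundant feature length, in
#'   residues, for a feature to count as short (default 29, i.e. strictly
#'   shorter than 30).
#' @param min_predictor_votes minimum number of predictors (1--3) that
#'   must call a residue disordered for it to enter the consensus.
#' @param idr_coverage_threshold fraction of a feature's residues that
#'   must lie inside the consensus IDR, in (0, 1]; 1 demands full
#'   containment.
#' @param positive_keywords_region keywords qualifying a
#'   region_of_interest description.
#' @param positive_keywords_mutagenesis keywords qualifying a
#'   mutagenesis_site description.
#' @param negation_tokens whole words that disqualify a mutagenesis_site
#'   description.
#' @param enrichment_log_base base of the localization enrichment
#'   logarithm.
#' @param random_seed integer seed recorded with reports.
#' @return object of class `pros_config`.
#' @examples
#' cfg <- pros_config()
#' cfg$max_feature_length
#' @export
pros_config <- function(max_feature_length = 29L,
                        min_predictor_votes = 2L,
                        idr_coverage_threshold = 1.0,
                        positive_keywords_region = c("interact", "bind", "motif"),
                        positive_keywords_mutagenesis = c("interact", "bind"),
                        negation_tokens = c("no", "not"),
                        enrichment_log_base = 2,
                        random_seed = 1L) {
  cfg <- list(max_feature_length = as.integer(max_feature_length),
              min_predictor_votes = as.integer(min_predictor_votes),
              idr_coverage_threshold = as.numeric(idr_coverage_threshold),
              positive_keywords_region = as.character(positive_keywords_region),
              positive_keywords_mutagenesis = as.character(positive_keywords_mutagenesis),
              negation_tokens = as.character(negation_tokens),
              enrichment_log_base = as.numeric(enrichment_log_base),
              random_seed = as.integer(random_seed))
  if (cfg$max_feature_length < 1L) {
    stop("max_feature_length must be at least 1")
  }
  if (cfg$min_predictor_votes < 1L || cfg$min_predictor_votes > 3L) {
    stop("min_predictor_votes must be between 1 and 3")
  }
  if (!(cfg$idr_coverage_threshold > 0 && cfg$idr_coverage_threshold <= 1)) {
    stop("idr_coverage_threshold must be in (0, 1]")
  }
  if (cfg$enrichment_log_base <= 0 || cfg$enrichment_log_base == 1) {
    stop("enrichment_log_base must be positive and different from 1")
  }
  structure(cfg, class = "pros_config")
}

#' @export
print.pros_config <- function(x, ...) {
  cat("pProS pipeline configuration\n")
  cat("  max feature length     :", x$max_feature_length, "residues\n")
  cat("  min predictor votes    :", x$min_predictor_votes, "\n")
  cat("  IDR coverage threshold :", x$idr_coverage_threshold, "\n")
  cat("  region keywords        :",
      paste(x$positive_keywords_region, collapse = ", "), "\n")
  cat("  mutagenesis keywords   :",
      paste(x$positive_keywords_mutagenesis, collapse = ", "), "\n")
  cat("  negation tokens        :",
      paste(x$negation_tokens, collapse = ", "), "\n")
  cat("  enrichment log base    :", x$enrichment_log_base, "\n")
  invisible(x)
}
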