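# Length and keyword rules picking candidate binding-associated features.
#
# Selection is a pure function of (feature_type, description, length,
# config). Positive keywords match case-insensitively at word starts, so
# "interact" hits "Interaction with USP7" and "interacts"; negation
# tokens match as whole words only, so "no" does not fire inside
# "nuclear" and "Loss of interaction with MDM2" survives.

escape_regex <- function(words) gsub("([^A-Za-z0-9])", "\\\\\\1", words)

keyword_start_regex <- function(words) {
  paste0("\\b(", paste(escape_regex(words), collapse = "|"), ")")
}

whole_word_regex <- function(words) {
  paste0("\\b(", paste(escape_regex(words), collapse = "|"), ")\\b")
}

has_positive_keyword <- function(description, keywords) {
  if (length(keywords) == 0L) return(rep(FALSE, length(description)))
  grepl(keyword_start_regex(keywords), description,
        ignore.case = TRUE, perl = TRUE)
}

has_negation_token <- function(description, tokens) {
  if (length(tokens) == 0L) return(rep(FALSE, length(description)))
  grepl(whole_word_regex(tokens), description,
        ignore.case = TRUE, perl = TRUE)
}

#' Non-redundant length of each feature
#'
#' A feature's length is the number of distinct residues its location
#' set covers; overlapping intervals of a multi-interval feature are not
#' double-counted.
#'
#' @param features feature data frame (`accession`, `feature_id`,
#'   `start`, `end`, one row per interval).
#' @return data frame with columns `accession`, `feature_id`, `length`.
#' @export
feature_lengths <- function(features) {
  if (nrow(features) == 0L) {
    return(data.frame(accession = character(0), feature_id = character(0),
                      length = integer(0)))
  }
  key <- paste(features$accession, features$feature_id, sep = "\r")
  lens <- vapply(split(features[, c("start", "end")], key),
                 interval_total_length, integer(1))
  first <- !duplicated(key)
  out <- data.frame(accession = features$accession[first],
                    feature_id = features$feature_id[first],
                    stringsAsFactors = FALSE)
  out$length <- as.integer(lens[paste(out$accession, out$feature_id,
                                      sep = "\r")])
  sort_reset(out, c("accession", "feature_id"))
}

#' Is a feature short enough to be a pProS candidate?
#'
#' TRUE when the feature's non-redundant residue count is at most
#' `config$max_feature_length` (default 29, i.e. strictly shorter than
#' 30 residues). Vectorized over the rows of `features`; every interval
#' row of a multi-interval feature receives the feature's decision.
#'
#' @param features feature data frame.
#' @param config a [pros_config()].
#' @return logical vector aligned with `features` rows.
#' @export
is_short <- function(features, config = pros_config()) {
  if (nrow(features) == 0L) return(logical(0))
  fl <- feature_lengths(features)
  lens <- stats::setNames(fl$length,
                          paste(fl$accession, fl$feature_id, sep = "\r"))
  key <- paste(features$accession, features$feature_id, sep = "\r")
  unname(lens[key] <= config$max_feature_length)
}

#' Keep only short features
#'
#' @param features feature data frame.
#' @param config a [pros_config()].
#' @return the rows of `features` whose feature passes [is_short()].
#' @export
short_features <- function(features, config = pros_config()) {
  features[is_short(features, config), , drop = FALSE]
}

#' Select binding-associated features by type and keyword rules
#'
#' Applies the description rules to (already short) features:
#' \itemize{
#' \item `short_sequence_motif`: always selected (`motif_class`);
#' \item `region_of_interest`: selected when the description contains a
#'   positive region keyword (`keyword_region`);
#' \item `mutagenesis_site`: selected when the description contains a
#'   positive mutagenesis keyword and no negation token
#'   (`keyword_mutagenesis`);
#' \item all other feature types: never selected.
#' }
#'
#' @param features feature data frame; callers normally pass the output
#'   of [short_features()].
#' @param config a [pros_config()].
#' @return the selected rows of `features` with an added
#'   `selection_reason` column.
#' @examples
#' f <- data.frame(accession = "P1", feature_id = "F1",
#'                 feature_type = "region_of_interest",
#'                 description = "Interaction with USP7",
#'                 start = 359L, end = 363L)
#' select_binding_features(f)
#' @export
select_binding_features <- function(features, config = pros_config()) {
  if (nrow(features) == 0L) {
    out <- features
    out$selection_reason <- character(0)
    return(out)
  }
  type <- features$feature_type
  desc <- features$description
  reason <- rep(NA_character_, nrow(features))
  reason[type == "short_sequence_motif"] <- "motif_class"
  sel_region <- type == "region_of_interest" &
    has_positive_keyword(desc, config$positive_keywords_region)
  reason[sel_region] <- "keyword_region"
  sel_mut <- type == "mutagenesis_site" &
    has_positive_keyword(desc, config$positive_keywords_mutagenesis) &
    !has_negation_token(desc, config$negation_tokens)
  reason[sel_mut] <- "keyword_mutagenesis"
  out <- features[!is.na(reason), , drop = FALSE]
  out$selection_reason <- reason[!is.na(reason)]
  rownames(out) <- NULL
  out
}
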