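# Intersection of selected features with consensus IDRs.
#
# Each qualifying annotation yields exactly one pProS; overlapping
# annotations stay separate calls ("TAD I" and "Loss of interactions
# with MDM2" are different phenomena on the same residues). Residue
# accounting, by contrast, is always non-redundant.

feature_idr_coverage <- function(features, consensus) {
  if (nrow(features) == 0L) {
    return(data.frame(accession = character(0), feature_id = character(0),
                      feature_type = character(0), idr_coverage = numeric(0)))
  }
  cons_by_acc <- split(consensus[, c("start", "end")], consensus$accession)
  key <- paste(features$accession, features$feature_id, sep = "\r")
  first <- !duplicated(key)
  ids <- data.frame(accession = features$accession[first],
                    feature_id = features$feature_id[first],
                    feature_type = features$feature_type[first],
                    stringsAsFactors = FALSE)
  feat_by_key <- split(features[, c("start", "end")], key)
  cov <- vapply(seq_len(nrow(ids)), function(i) {
    f_ir <- IRanges::reduce(as_iranges(
      feat_by_key[[paste(ids$accession[i], ids$feature_id[i], sep = "\r")]]))
    cons <- cons_by_acc[[ids$accession[i]]]
    if (is.null(cons) || nrow(cons) == 0L) return(0)
    inside <- sum(IRanges::width(IRanges::intersect(f_ir, as_iranges(cons))))
    inside / sum(IRanges::width(f_ir))
  }, numeric(1))
  ids$idr_coverage <- cov
  sort_reset(ids, c("accession", "feature_id"))
}

#' Call pProSs from selected features and consensus IDRs
#'
#' A selected feature becomes a pProS when the fraction of its residues
#' lying inside the consensus IDR reaches
#' `config$idr_coverage_threshold` (default 1: full containment). Calls
#' never merge: one qualifying annotation is one pProS, and a call's
#' intervals are exactly the feature's intervals.
#'
#' @param selected output of [select_binding_features()] (must carry
#'   `selection_reason`).
#' @param consensus cohort-level consensus data frame from
#'   [consensus_idrs()] (`accession`, `start`, `end`).
#' @param config a [pros_config()].
#' @return data frame with one row per called feature interval:
#'   `accession`, `feature_id`, `feature_type`, `selection_reason`,
#'   `description`, `start`, `end`, `idr_coverage`.
#' @export
call_pros <- function(selected, consensus, config = pros_config()) {
  if (is.null(selected$selection_reason)) {
    stop("`selected` must come from select_binding_features()")
  }
  cov <- feature_idr_coverage(selected, consensus)
  eps <- 1e-12
  keep <- cov[cov$idr_coverage >= config$idr_coverage_threshold - eps, ,
              drop = FALSE]
  key <- paste(selected$accession, selected$feature_id, sep = "\r")
  keep_key <- paste(keep$accession, keep$feature_id, sep = "\r")
  out <- selected[key %in% keep_key, , drop = FALSE]
  out$idr_coverage <- keep$idr_coverage[match(
    paste(out$accession, out$feature_id, sep = "\r"), keep_key)]
  out <- out[, c("accession", "feature_id", "feature_type",
                 "selection_reason", "description", "start", "end",
                 "idr_coverage")]
  sort_reset(out, c("accession", "feature_id", "start"))
}

#' IDR coverage of arbitrary feature classes
#'
#' Generic feature-vs-consensus coverage report with no keyword or
#' length filtering; this is the operation behind surveys of variant
#' (mutation) sites and modified residues (e.g. phosphorylation sites)
#' in predicted IDRs.
#'
#' @param features any feature data frame (`accession`, `feature_id`,
#'   `feature_type`, `start`, `end`).
#' @param consensus cohort-level consensus data frame.
#' @return data frame `accession`, `feature_id`, `feature_type`,
#'   `idr_coverage`, one row per feature.
#' @export
intersect_features_with_idrs <- function(features, consensus) {
  feature_idr_coverage(features, consensus)
}

#' Non-redundant pProS residue counts per protein
#'
#' Counts, for each protein with at least one call, the residues covered
#' by any of its pProSs, each residue once. Two annotations at 360--365
#' and 360--362 contribute six residues.
#'
#' @param pros data frame of calls from [call_pros()].
#' @return data frame `accession`, `pros_residues`, sorted by accession.
#' @export
pros_residues_per_protein <- function(pros) {
  if (nrow(pros) == 0L) {
    return(data.frame(accession = character(0), pros_residues = integer(0)))
  }
  res <- vapply(split(pros[, c("start", "end")], pros$accession),
                interval_total_length, integer(1))
  sort_reset(data.frame(accession = names(res),
                        pros_residues = as.integer(res),
                        stringsAsFactors = FALSE), "accession")
}
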