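# Cohort and per-disease-category statistics.
#
# Printed-style percentages and ratios are rounded half-up to one
# decimal; every rounded column sits next to the integer columns it was
# computed from, so each row is recomputable.

#' Round half-up
#'
#' Decimal rounding where ties go away from zero (so 0.25 -> 0.3 at one
#' decimal), unlike base R's round-half-even. Used for all printed-style
#' percentage and ratio columns.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector.
#' @examples
#' round_half_up(c(0.25, 2.578, 27.941), 1)
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  # the 1e-8 nudge rescues decimal .5 ties stored just under .5 in binary
  sign(x) * floor(abs(x) * p + 0.5 + 1e-8) / p
}

#' Protein coverage percentage
#'
#' 100 * k / n rounded half-up to one decimal; the "Protein Coverage"
#' column of the category table (e.g. 57 of 204 -> 27.9).
#'
#' @param k number of pProS-containing proteins.
#' @param n number of proteins.
#' @return numeric vector; 0 where `n` is 0.
#' @export
coverage_pct <- function(k, n) {
  ifelse(n > 0, round_half_up(100 * k / n, 1L), 0)
}

#' Average annotations per pProS-containing protein
#'
#' Unique pProS count divided by pProS-containing protein count, rounded
#' half-up to one decimal (e.g. 147 / 57 -> 2.6). Reported as 0 when no
#' protein in the group carries a pProS.
#'
#' @param n_unique unique pProS count.
#' @param n_with pProS-containing protein count.
#' @return numeric vector.
#' @export
avg_annotations <- function(n_unique, n_with) {
  ifelse(n_with > 0, round_half_up(n_unique / n_with, 1L), 0)
}

disease_accessions <- function(cohort) unique(cohort$diseases$accession)

pros_count_by_protein <- function(pros) {
  if (nrow(pros) == 0L) return(integer(0))
  key <- paste(pros$accession, pros$feature_id, sep = "\r")
  tab <- table(pros$accession[!duplicated(key)])
  stats::setNames(as.integer(tab), names(tab))
}

#' Cohort-level annotation statistics
#'
#' Summarizes the cohort the way the headline annotation table does:
#' protein counts (all / disease-related / disease-related with a pProS)
#' and, for each of the three selectable feature types plus their total,
#' the number of short annotations among all proteins, among
#' disease-related proteins, the number of those called as pProSs, and
#' the pProS percentage (calls / short disease-related annotations,
#' rounded half-up to one decimal). pProS columns are restricted to
#' disease-related proteins.
#'
#' @param cohort a [pros_cohort()].
#' @param pros calls from [call_pros()].
#' @param config a [pros_config()].
#' @return data frame with columns `statistic`, `all_proteins`,
#'   `disease_related`, `pros`, `pros_pct`.
#' @export
table1_stats <- function(cohort, pros, config = pros_config()) {
  dis_acc <- disease_accessions(cohort)
  short <- short_features(cohort$features, config)
  short <- short[short$feature_type %in% SELECTABLE_FEATURE_TYPES, ,
                 drop = FALSE]
  skey <- paste(short$accession, short$feature_id, sep = "\r")
  short1 <- short[!duplicated(skey), , drop = FALSE]

  pkey <- paste(pros$accession, pros$feature_id, sep = "\r")
  pros1 <- pros[!duplicated(pkey), , drop = FALSE]
  pros1 <- pros1[pros1$accession %in% dis_acc, , drop = FALSE]

  n_prot_all <- nrow(cohort$proteins)
  n_prot_dis <- length(dis_acc)
  n_prot_pros <- length(unique(pros1$accession))

  count_type <- function(df, types) sum(df$feature_type %in% types)
  row_for <- function(label, types) {
    all_n <- count_type(short1, types)
    dis_n <- count_type(short1[short1$accession %in% dis_acc, , drop = FALSE],
                        types)
    pros_n <- count_type(pros1, types)
    data.frame(statistic = label, all_proteins = all_n,
               disease_related = dis_n, pros = pros_n,
               pros_pct = coverage_pct(pros_n, dis_n),
               stringsAsFactors = FALSE)
  }

  rbind(
    data.frame(statistic = "n_proteins", all_proteins = n_prot_all,
               disease_related = n_prot_dis, pros = n_prot_pros,
               pros_pct = coverage_pct(n_prot_pros, n_prot_dis),
               stringsAsFactors = FALSE),
    row_for("n_short_annotations", SELECTABLE_FEATURE_TYPES),
    row_for("region_of_interest", "region_of_interest"),
    row_for("mutagenesis_site", "mutagenesis_site"),
    row_for("short_sequence_motif", "short_sequence_motif"))
}

#' Per-disease-category pProS statistics
#'
#' One row per category. A protein assigned to diseases in k categories
#' contributes to each of those k rows; within one category it counts
#' once toward `n_proteins` and `n_proteins_with_pros` and its unique
#' pProS count once toward `n_unique_pros`, but its pProSs count once
#' per disease assignment toward `pros_counts_redundant`.
#' `pros_redundancy` = unique / redundant is 1 exactly when no protein
#' in the category carries several of its diseases.
#'
#' @param cohort a [pros_cohort()].
#' @param pros calls from [call_pros()].
#' @return data frame with columns `category`, `n_unique_pros`,
#'   `n_proteins_with_pros`, `n_proteins`, `coverage_pct`,
#'   `avg_annotations`, `pros_counts_redundant`, `pros_redundancy`,
#'   `empty_flag`, ordered by the canonical category order.
#' @export
category_table <- function(cohort, pros) {
  counts <- pros_count_by_protein(pros)
  cats <- intersect(DISEASE_CATEGORIES, unique(cohort$diseases$category))
  rows <- lapply(cats, function(cat) {
    d <- cohort$diseases[cohort$diseases$category == cat, , drop = FALSE]
    acc <- unique(d$accession)
    per_prot <- stats::setNames(rep(0L, length(acc)), acc)
    hit <- intersect(acc, names(counts))
    per_prot[hit] <- counts[hit]
    n_dis_in_cat <- table(d$accession)
    redundant <- sum(per_prot * as.integer(n_dis_in_cat[acc]))
    n_unique <- sum(per_prot)
    n_with <- sum(per_prot > 0L)
    data.frame(category = cat,
               n_unique_pros = as.integer(n_unique),
               n_proteins_with_pros = as.integer(n_with),
               n_proteins = length(acc),
               coverage_pct = coverage_pct(n_with, length(acc)),
               avg_annotations = avg_annotations(n_unique, n_with),
               pros_counts_redundant = as.integer(redundant),
               pros_redundancy = ifelse(redundant > 0L,
                                        n_unique / redundant, NA_real_),
               empty_flag = n_with == 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank proteins by non-redundant pProS residues
#'
#' Sorts pProS-carrying proteins by their non-redundant pProS residue
#' count, descending; ties break by accession in lexicographic order.
#' Both readings of disease multiplicity are emitted: distinct diseases
#' (`n_diseases`) and distinct disease-category pairs
#' (`n_disease_category_pairs`).
#'
#' @param cohort a [pros_cohort()].
#' @param pros calls from [call_pros()].
#' @param top_n how many rows to keep (default all).
#' @return data frame `accession`, `pros_residues`, `n_diseases`,
#'   `n_disease_category_pairs`, `categories` (comma-joined, canonical
#'   order).
#' @export
rank_by_pros_residues <- function(cohort, pros, top_n = Inf) {
  res <- pros_residues_per_protein(pros)
  if (nrow(res) == 0L) {
    return(data.frame(accession = character(0), pros_residues = integer(0),
                      n_diseases = integer(0),
                      n_disease_category_pairs = integer(0),
                      categories = character(0)))
  }
  d_by_acc <- split(cohort$diseases, cohort$diseases$accession)
  meta <- lapply(res$accession, function(acc) {
    d <- d_by_acc[[acc]]
    if (is.null(d)) {
      return(data.frame(n_diseases = 0L, n_disease_category_pairs = 0L,
                        categories = "", stringsAsFactors = FALSE))
    }
    cats <- intersect(DISEASE_CATEGORIES, unique(d$category))
    data.frame(n_diseases = length(unique(d$disease_id)),
               n_disease_category_pairs =
                 nrow(unique(d[, c("disease_id", "category")])),
               categories = paste(cats, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- cbind(res, do.call(rbind, meta))
  out <- out[order(-out$pros_residues, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, n = if (is.finite(top_n)) top_n else nrow(out))
}
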