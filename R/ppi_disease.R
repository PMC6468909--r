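# Disease multiplicity versus interaction degree.
#
# Proteins are binned by their number of distinct assigned diseases;
# the correlation of interest is between the bin value and the per-bin
# mean (or median) interactor count, matching how a box-plot-per-bin
# figure is summarized. The raw per-protein correlation is available as
# a secondary reading.

#' Bin proteins by disease count
#'
#' Keeps proteins with at least one assigned disease and a known
#' interactor count; proteins with diseases but no interaction data are
#' excluded and reported via a message.
#'
#' @param cohort a [pros_cohort()].
#' @return data frame `accession`, `n_diseases`, `interactor_count`,
#'   sorted by `n_diseases` then accession; the number of excluded
#'   proteins is attached as attribute `n_excluded`.
#' @export
bin_by_disease_count <- function(cohort) {
  stopifnot(inherits(cohort, "pros_cohort"))
  nd <- table(unique(cohort$diseases[, c("accession", "disease_id")])$accession)
  acc <- names(nd)
  ppi <- cohort$proteins$interactor_count[match(acc,
                                                cohort$proteins$accession)]
  excluded <- sum(is.na(ppi))
  if (excluded > 0L) {
    message(excluded, " disease protein(s) lack interactor counts and are ",
            "excluded from disease/PPI binning")
  }
  out <- data.frame(accession = acc, n_diseases = as.integer(nd),
                    interactor_count = as.integer(ppi),
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$interactor_count), , drop = FALSE]
  out <- sort_reset(out, c("n_diseases", "accession"))
  attr(out, "n_excluded") <- excluded
  out
}

#' Per-bin interactor-count summaries
#'
#' Quartile summaries per disease-count bin, the numbers behind a
#' box-plot of interactor counts against disease multiplicity.
#'
#' @param binned output of [bin_by_disease_count()].
#' @return data frame `n_diseases`, `n_proteins`, `mean`, `median`,
#'   `q1`, `q3`, `min`, `max`.
#' @export
ppi_bin_summary <- function(binned) {
  groups <- split(binned$interactor_count, binned$n_diseases)
  out <- data.frame(
    n_diseases = as.integer(names(groups)),
    n_proteins = vapply(groups, length, integer(1)),
    mean = vapply(groups, mean, numeric(1)),
    median = vapply(groups, stats::median, numeric(1)),
    q1 = vapply(groups, function(x) unname(stats::quantile(x, 0.25)),
                numeric(1)),
    q3 = vapply(groups, function(x) unname(stats::quantile(x, 0.75)),
                numeric(1)),
    min = vapply(groups, min, numeric(1)),
    max = vapply(groups, max, numeric(1)))
  rownames(out) <- NULL
  out[order(out$n_diseases), , drop = FALSE]
}

#' Correlation between disease multiplicity and interaction degree
#'
#' Pearson correlation between the number of assigned diseases and the
#' per-bin mean or median interactor count (`method = "bins"`), or
#' between the raw per-protein pairs (`method = "pairs"`). The
#' restriction `max_diseases` keeps bins with strictly fewer diseases
#' (so `max_diseases = 10` reads "less than 10 assigned diseases", i.e.
#' bins 1--9); the default `Inf` keeps everything.
#'
#' @param binned output of [bin_by_disease_count()].
#' @param stat "mean" or "median" (ignored for `method = "pairs"`).
#' @param max_diseases strict upper bound on `n_diseases`.
#' @param method "bins" (default) or "pairs".
#' @return Pearson correlation coefficient.
#' @export
disease_ppi_correlation <- function(binned, stat = c("mean", "median"),
                                    max_diseases = Inf,
                                    method = c("bins", "pairs")) {
  stat <- match.arg(stat)
  method <- match.arg(method)
  keep <- binned[binned$n_diseases < max_diseases, , drop = FALSE]
  if (method == "pairs") {
    if (nrow(keep) < 2L) stop("need at least two proteins for correlation")
    if (stats::var(keep$n_diseases) == 0 ||
        stats::var(keep$interactor_count) == 0) {
      stop("correlation undefined: zero variance in pairs")
    }
    return(stats::cor(keep$n_diseases, keep$interactor_count))
  }
  groups <- split(keep$interactor_count, keep$n_diseases)
  if (length(groups) < 2L) {
    stop("need at least two disease-count bins for correlation")
  }
  x <- as.integer(names(groups))
  y <- vapply(groups, if (stat == "mean") mean else stats::median,
              numeric(1))
  if (stats::var(y) == 0) {
    stop("correlation undefined: per-bin ", stat, " has zero variance")
  }
  stats::cor(x, y)
}
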