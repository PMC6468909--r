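# Consensus IDR calling: a residue is consensus-disordered when at
# least min_predictor_votes of the three predictor tracks call it
# disordered. Votes are counted with IRanges coverage; a predictor with
# no intervals on a protein contributes zero votes everywhere.

#' Consensus IDR intervals for one protein
#'
#' Combines 1--3 predictor tracks into the consensus interval set. Each
#' track may be an interval data frame (`start`, `end`) or a logical
#' per-residue call vector; vectors must match `protein_length` exactly.
#' A residue enters the consensus when at least
#' `config$min_predictor_votes` tracks call it disordered (default 2,
#' the two-of-three rule).
#'
#' @param tracks named list of tracks, one per predictor. An empty
#'   interval data frame is a legitimate track meaning "this predictor
#'   calls no residue disordered"; supplying no tracks at all is an
#'   error.
#' @param protein_length protein length in residues.
#' @param config a [pros_config()].
#' @return normalized interval data frame (`start`, `end`).
#' @examples
#' consensus_intervals(
#'   list(mobidb_lite = data.frame(start = 1, end = 60),
#'        disopred3   = data.frame(start = 40, end = 80),
#'        dichot      = data.frame(start = integer(0), end = integer(0))),
#'   protein_length = 100)
#' @export
consensus_intervals <- function(tracks, protein_length,
                                config = pros_config()) {
  if (!is.list(tracks) || length(tracks) == 0L) {
    stop("consensus requires at least one disorder track")
  }
  if (length(tracks) > 3L) {
    stop("at most three predictor tracks are supported")
  }
  protein_length <- as.integer(protein_length)
  if (is.na(protein_length) || protein_length < 1L) {
    stop("protein_length must be a positive integer")
  }
  irs <- lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    nm <- if (!is.null(names(tracks))) names(tracks)[i] else paste0("track", i)
    if (is.logical(tr)) {
      if (length(tr) != protein_length) {
        stop("track ", nm, ": call vector length ", length(tr),
             " does not match protein length ", protein_length)
      }
      tr <- calls_to_intervals(tr)
    }
    check_intervals(tr, context = paste0("track ", nm),
                    max_end = protein_length)
    IRanges::reduce(as_iranges(tr))
  })
  votes <- IRanges::coverage(do.call(c, irs), width = protein_length)
  iranges_to_df(IRanges::slice(votes, lower = config$min_predictor_votes,
                               rangesOnly = TRUE))
}

#' Consensus IDRs for every protein of a cohort
#'
#' Applies [consensus_intervals()] across the cohort. Proteins without
#' any track rows get an empty consensus: a predictor that reports no
#' disordered interval contributes zero votes, it does not abstain.
#'
#' @param cohort a [pros_cohort()].
#' @param config a [pros_config()].
#' @return data frame `accession`, `start`, `end`, sorted by accession
#'   and start; proteins with empty consensus contribute no rows.
#' @export
consensus_idrs <- function(cohort, config = pros_config()) {
  stopifnot(inherits(cohort, "pros_cohort"))
  tr_by_acc <- split(cohort$tracks, cohort$tracks$accession)
  out <- lapply(cohort$proteins$accession, function(acc) {
    tr <- tr_by_acc[[acc]]
    if (is.null(tr) || nrow(tr) == 0L) return(NULL)
    tracks <- lapply(split(tr[, c("start", "end")], tr$predictor_id),
                     identity)
    cons <- consensus_intervals(tracks,
                                cohort$proteins$length[
                                  cohort$proteins$accession == acc],
                                config)
    if (nrow(cons) == 0L) return(NULL)
    cbind(accession = acc, cons, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(data.frame(accession = character(0),
                                               start = integer(0),
                                               end = integer(0)))))
  sort_reset(out, c("accession", "start"))
}

#' Per-residue predictor vote counts
#'
#' @param tracks named list of tracks as in [consensus_intervals()].
#' @param protein_length protein length in residues.
#' @return integer vector of votes (0--3), one element per residue.
#' @export
predictor_votes <- function(tracks, protein_length) {
  protein_length <- as.integer(protein_length)
  votes <- integer(protein_length)
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    if (is.logical(tr)) tr <- calls_to_intervals(tr)
    votes <- votes + intervals_to_calls(normalize_intervals(tr),
                                        protein_length)
  }
  votes
}

#' Disordered fraction of one protein
#'
#' @param consensus interval data frame of consensus IDRs.
#' @param protein_length protein length in residues (> 0).
#' @return fraction in \[0, 1\]: consensus residues / length.
#' @export
idr_fraction <- function(consensus, protein_length) {
  protein_length <- as.integer(protein_length)
  if (is.na(protein_length) || protein_length < 1L) {
    stop("protein_length must be a positive integer")
  }
  check_intervals(consensus, context = "consensus", max_end = protein_length)
  interval_total_length(consensus) / protein_length
}

#' Aggregate IDR fraction over a set of proteins
#'
#' The primary statistic is residue-weighted: total consensus residues
#' divided by total residues of the subset, matching how a proteome-wide
#' IDR ratio is usually quoted. The unweighted mean of per-protein
#' fractions is returned alongside for comparison.
#'
#' @param cohort a [pros_cohort()].
#' @param consensus cohort-level consensus from [consensus_idrs()].
#' @param accessions subset of proteins to aggregate over; defaults to
#'   the whole cohort. Must be non-empty.
#' @return list with `residue_weighted`, `mean_per_protein`, and
#'   `n_proteins`.
#' @export
aggregate_idr_fraction <- function(cohort, consensus, accessions = NULL) {
  stopifnot(inherits(cohort, "pros_cohort"))
  if (is.null(accessions)) accessions <- cohort$proteins$accession
  accessions <- unique(accessions)
  if (length(accessions) == 0L) {
    stop("cannot aggregate the IDR fraction of an empty protein set")
  }
  unknown <- setdiff(accessions, cohort$proteins$accession)
  if (length(unknown) > 0L) {
    stop("unknown accession: ", paste(unknown, collapse = ", "))
  }
  lens <- cohort$proteins$length[match(accessions,
                                       cohort$proteins$accession)]
  cons <- consensus[consensus$accession %in% accessions, , drop = FALSE]
  per_acc <- vapply(split(IRanges::width(as_iranges(cons)),
                          cons$accession), sum, numeric(1))
  disordered <- stats::setNames(rep(0, length(accessions)), accessions)
  disordered[names(per_acc)] <- per_acc
  list(residue_weighted = sum(disordered) / sum(lens),
       mean_per_protein = mean(disordered / lens),
       n_proteins = length(accessions))
}
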