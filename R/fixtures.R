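# Hand-coded miniature cohorts transcribing well-characterised proteins
# whose short binding annotations sit in predicted IDRs: the p53
# transcription factor (terminal IDRs dense with overlapping
# annotations), the survival of motor neuron protein (an N-terminal
# GEMIN2-binding region longer than 30 residues -- a pseudo-pProS), and
# the LDL receptor adaptor ARH (C-terminal IDR with clathrin and AP-2
# binding, no MobiDB-lite prediction).

fixture_p53_like <- function() {
  acc <- "P04637"
  feats <- data.frame(
    accession = acc,
    feature_id = sprintf("F%02d", 1:11),
    feature_type = c("short_sequence_motif", "mutagenesis_site",
                     "mutagenesis_site", "short_sequence_motif",
                     "short_sequence_motif", "short_sequence_motif",
                     "region_of_interest", "mutagenesis_site",
                     "region_of_interest", "short_sequence_motif",
                     "region_of_interest"),
    description = c("TAD I",
                    "Loss of interactions with MDM2",
                    "Loss of interaction with PPP2R5C, PPP2CA and PPP2R1A",
                    "TAD II",
                    "Bipartite nuclear localization signal",
                    "[KR]-[STA]-K motif",
                    "Interaction with USP7",
                    "Abolishes binding to USP7",
                    "Interaction with BANP",
                    "OD motif",
                    "Basic (interaction with DNA)"),
    start = c(15L, 15L, 15L, 48L, 305L, 370L, 359L, 359L, 359L, 359L, 368L),
    end   = c(25L, 25L, 25L, 56L, 321L, 372L, 363L, 363L, 363L, 363L, 387L),
    stringsAsFactors = FALSE)
  tracks <- rbind(
    data.frame(accession = acc, predictor_id = "mobidb_lite",
               start = c(1L, 280L, 350L), end = c(100L, 330L, 393L)),
    data.frame(accession = acc, predictor_id = "disopred3",
               start = c(1L, 280L, 350L), end = c(100L, 330L, 393L)),
    data.frame(accession = acc, predictor_id = "dichot",
               start = 1L, end = 60L))
  diseases <- data.frame(
    accession = acc,
    disease_id = sprintf("SD%05d", 1:10),
    category = c(rep("Can", 8L), "Ner", "Oth"),
    stringsAsFactors = FALSE)
  pros_cohort(
    proteins = data.frame(accession = acc, length = 393L,
                          interactor_count = 1056L,
                          stringsAsFactors = FALSE),
    features = feats, tracks = tracks, diseases = diseases,
    locations = data.frame(accession = acc,
                           location_term = c("cytoplasm", "nucleus"),
                           stringsAsFactors = FALSE))
}

fixture_smn_like <- function() {
  acc <- "Q16637"
  feats <- data.frame(
    accession = acc,
    feature_id = c("F01", "F02"),
    feature_type = c("region_of_interest", "region_of_interest"),
    description = c("Interaction with GEMIN2",
                    "Interaction with hnRNP Q"),
    start = c(13L, 281L), end = c(44L, 294L),
    stringsAsFactors = FALSE)
  tracks <- rbind(
    data.frame(accession = acc, predictor_id = "mobidb_lite",
               start = c(1L, 235L), end = c(90L, 294L)),
    data.frame(accession = acc, predictor_id = "disopred3",
               start = c(1L, 235L), end = c(90L, 294L)))
  pros_cohort(
    proteins = data.frame(accession = acc, length = 294L,
                          interactor_count = 120L,
                          stringsAsFactors = FALSE),
    features = feats, tracks = tracks,
    diseases = data.frame(accession = acc, disease_id = "SD00101",
                          category = "Ner", stringsAsFactors = FALSE),
    locations = data.frame(accession = acc,
                           location_term = c("cytoplasm", "nucleus"),
                           stringsAsFactors = FALSE))
}

fixture_arh_like <- function() {
  acc <- "Q5SW96"
  feats <- data.frame(
    accession = acc,
    feature_id = c("F01", "F02"),
    feature_type = c("region_of_interest", "region_of_interest"),
    description = c("Clathrin binding", "AP-2 complex binding"),
    start = c(256L, 295L), end = c(260L, 302L),
    stringsAsFactors = FALSE)
  # MobiDB-lite predicts no IDR here; the consensus rests on the other two
  tracks <- rbind(
    data.frame(accession = acc, predictor_id = "disopred3",
               start = c(1L, 250L), end = c(40L, 308L)),
    data.frame(accession = acc, predictor_id = "dichot",
               start = c(1L, 250L), end = c(40L, 308L)))
  pros_cohort(
    proteins = data.frame(accession = acc, length = 308L,
                          interactor_count = 35L,
                          stringsAsFactors = FALSE),
    features = feats, tracks = tracks,
    diseases = data.frame(accession = acc, disease_id = "SD00201",
                          category = "Dme", stringsAsFactors = FALSE),
    locations = data.frame(accession = acc, location_term = "cytoplasm",
                           stringsAsFactors = FALSE))
}

#' Packaged miniature cohorts
#'
#' Small hand-coded cohorts for demonstration and regression testing:
#' \describe{
#' \item{p53_like}{eleven overlapping short annotations on the terminal
#'   and linker IDRs of a 393-residue transcription factor; all become
#'   pProSs, including three distinct annotations on residues 15--25.}
#' \item{smn_like}{a 294-residue snRNP assembly protein whose
#'   N-terminal GEMIN2-interaction region (13--44, 32 residues) sits in
#'   an IDR but exceeds the 29-residue limit -- a pseudo-pProS -- while
#'   the C-terminal hnRNP Q interaction (281--294) is called.}
#' \item{arh_like}{a 308-residue endocytosis adaptor with clathrin- and
#'   AP-2-binding segments on its C-terminal IDR, supported by only two
#'   predictors.}
#' }
#'
#' @param name one of "p53_like", "smn_like", "arh_like".
#' @param out_dir optional directory to write the cohort's input TSVs
#'   to (via [write_cohort()]).
#' @return a [pros_cohort()].
#' @examples
#' cohort <- make_fixture("p53_like")
#' @export
make_fixture <- function(name = c("p53_like", "smn_like", "arh_like"),
                         out_dir = NULL) {
  name <- match.arg(name)
  cohort <- switch(name,
                   p53_like = fixture_p53_like(),
                   smn_like = fixture_smn_like(),
                   arh_like = fixture_arh_like())
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}
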