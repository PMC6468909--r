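# Synthetic cohorts with known ground truth.
#
# The generator emulates the five input tables at the study conditions:
# protein lengths log-normal around a few hundred residues, a ~30%
# disordered proteome with IDRs biased to the termini, three per-residue
# predictor tracks echoing the true disorder state, planted short
# binding annotations inside true IDRs plus decoys (outside IDRs,
# negated, over-long, or keyword-less), ~17% of proteins
# disease-related with power-law disease counts, localization classes
# with the CN (shuttling) class enriched among pProS-containing
# proteins, and interactor counts linear in disease count plus noise.

#' Parameters of the synthetic cohort generator
#'
#' Defaults encode the cohort conditions the pipeline is meant to
#' emulate; see the methods vignette for the rationale behind each
#' value.
#'
#' @param n_proteins cohort size.
#' @param length_meanlog,length_sdlog log-normal protein length
#'   parameters (median 400 residues, sigma 0.6).
#' @param min_length shortest protein emitted, residues (>= 30 so a
#'   sub-30-residue segment always fits).
#' @param target_disorder_fraction mean per-protein disordered fraction.
#' @param disorder_concentration Beta concentration of per-protein
#'   disorder fractions around the target (larger = tighter).
#' @param terminal_idr_bias probability an IDR block is placed at the N
#'   or C terminus rather than internally.
#' @param predictor_agreement per-residue probability that a predictor
#'   echoes the true disorder state (1 = noise-free tracks).
#' @param n_planted_pros Poisson mean of planted binding features per
#'   protein.
#' @param decoy_feature_rate Poisson mean of decoy features per protein.
#' @param p_disease probability a protein is disease-related.
#' @param disease_powerlaw_exponent exponent of the power-law disease
#'   count distribution (P(k) proportional to k^-a).
#' @param max_disease_count largest disease count drawn.
#' @param n_disease_pool number of distinct diseases available.
#' @param loc_probs named probabilities of the five location classes in
#'   non-pProS proteins; must sum to 1.
#' @param cn_enrichment multiplier on the CN class probability in
#'   pProS-containing proteins (other classes rescale to sum 1).
#' @param ppi_intercept,ppi_slope,ppi_noise_sd interactor count model:
#'   count = max(0, round(intercept + slope * n_diseases + N(0, sd))).
#' @param ppi_missing_rate probability a protein lacks interaction data.
#' @param seed integer seed; the generator is fully determined by it.
#' @return object of class `cohort_params`.
#' @export
cohort_params <- function(n_proteins = 500L,
                          length_meanlog = log(400),
                          length_sdlog = 0.6,
                          min_length = 60L,
                          target_disorder_fraction = 0.30,
                          disorder_concentration = 20,
                          terminal_idr_bias = 0.7,
                          predictor_agreement = 0.95,
                          n_planted_pros = 1.2,
                          decoy_feature_rate = 1.0,
                          p_disease = 0.166,
                          disease_powerlaw_exponent = 2.5,
                          max_disease_count = 30L,
                          n_disease_pool = 300L,
                          loc_probs = c(N = 0.20, C = 0.20, M = 0.15,
                                        CN = 0.20, other = 0.25),
                          cn_enrichment = 1.5,
                          ppi_intercept = 40,
                          ppi_slope = 25,
                          ppi_noise_sd = 30,
                          ppi_missing_rate = 0.05,
                          seed = 1L) {
  p <- list(n_proteins = as.integer(n_proteins),
            length_meanlog = length_meanlog, length_sdlog = length_sdlog,
            min_length = as.integer(min_length),
            target_disorder_fraction = target_disorder_fraction,
            disorder_concentration = disorder_concentration,
            terminal_idr_bias = terminal_idr_bias,
            predictor_agreement = predictor_agreement,
            n_planted_pros = n_planted_pros,
            decoy_feature_rate = decoy_feature_rate,
            p_disease = p_disease,
            disease_powerlaw_exponent = disease_powerlaw_exponent,
            max_disease_count = as.integer(max_disease_count),
            n_disease_pool = as.integer(n_disease_pool),
            loc_probs = loc_probs, cn_enrichment = cn_enrichment,
            ppi_intercept = ppi_intercept, ppi_slope = ppi_slope,
            ppi_noise_sd = ppi_noise_sd,
            ppi_missing_rate = ppi_missing_rate,
            seed = as.integer(seed))
  if (p$n_proteins < 1L) stop("n_proteins must be at least 1")
  if (p$min_length < 30L) {
    stop("min_length must be at least 30 residues so that a planted ",
         "sub-30-residue segment always fits inside the protein")
  }
  probs <- c(p$terminal_idr_bias, p$predictor_agreement, p$p_disease,
             p$ppi_missing_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  if (!(p$target_disorder_fraction > 0 && p$target_disorder_fraction < 1)) {
    stop("target_disorder_fraction must lie in (0, 1)")
  }
  if (!setequal(names(p$loc_probs), LOCATION_CLASSES) ||
      any(p$loc_probs < 0) || abs(sum(p$loc_probs) - 1) > 1e-8) {
    stop("loc_probs must be probabilities over ",
         paste(LOCATION_CLASSES, collapse = ", "), " summing to 1")
  }
  if (p$cn_enrichment * p$loc_probs[["CN"]] >= 1) {
    stop("cn_enrichment is infeasible: enriched CN probability >= 1")
  }
  if (p$ppi_noise_sd < 0 || p$disease_powerlaw_exponent <= 0) {
    stop("ppi_noise_sd must be >= 0 and the power-law exponent positive")
  }
  structure(p, class = "cohort_params")
}

# Place `n_blocks` disjoint disordered blocks of total width `total`
# on a chain of length `len`. Terminal placement with probability
# `bias`; internal otherwise. Returns an interval data frame.
place_idr_blocks <- function(len, total, n_blocks, bias) {
  total <- min(total, len)
  if (total <= 0L) return(data.frame(start = integer(0), end = integer(0)))
  widths <- if (n_blocks == 2L && total >= 20L) {
    w1 <- max(10L, round(total * runif(1, 0.3, 0.7)))
    c(w1, total - w1)
  } else total
  widths <- widths[widths > 0L]
  taken <- data.frame(start = integer(0), end = integer(0))
  sides <- sample(c("N", "C"))
  for (i in seq_along(widths)) {
    w <- widths[i]
    placed <- FALSE
    for (attempt in 1:25) {
      terminal <- runif(1) < bias && length(sides) > 0L
      if (terminal) {
        side <- sides[1]
        s <- if (side == "N") 1L else len - w + 1L
      } else {
        if (len - w < 1L) s <- 1L else s <- sample.int(len - w + 1L, 1L)
      }
      e <- s + w - 1L
      clash <- nrow(taken) > 0L &&
        any(pmax(taken$start, s - 5L) <= pmin(taken$end, e + 5L))
      if (!clash) {
        taken <- rbind(taken, data.frame(start = s, end = e))
        if (terminal) sides <- sides[-1]
        placed <- TRUE
        break
      }
    }
    if (!placed) break
  }
  normalize_intervals(taken)
}

power_law_count <- function(n, alpha, kmax) {
  k <- seq_len(kmax)
  sample(k, n, replace = TRUE, prob = k^(-alpha))
}

partner_pool <- sprintf("BP%03d", 1:60)
motif_names <- c("LXXLL motif", "SH3-binding motif", "PDZ-binding motif",
                 "Nuclear localization signal motif", "9aaTAD motif")
positive_templates <- c("Interaction with %s",
                        "Required for binding to %s",
                        "Loss of interaction with %s",
                        "Abolishes binding to %s")
negated_templates <- c("Does not affect binding to %s",
                       "No effect on interaction with %s",
                       "Does not abolish interaction with %s")
plain_descriptions <- c("Disordered linker", "Pro-rich region",
                        "Acidic stretch", "Coiled-coil region")

sample_positive_feature <- function(partner) {
  type <- sample(SELECTABLE_FEATURE_TYPES, 1L)
  desc <- switch(type,
    short_sequence_motif = sample(motif_names, 1L),
    region_of_interest = sprintf(sample(positive_templates[1:2], 1L),
                                 partner),
    mutagenesis_site = sprintf(sample(positive_templates[3:4], 1L),
                               partner))
  list(type = type, description = desc)
}

# Uniform placement of a width-w segment fully inside one of `blocks`
# (which must all have width >= w); NULL when impossible.
place_inside <- function(blocks, w) {
  ok <- blocks[blocks$end - blocks$start + 1L >= w, , drop = FALSE]
  if (nrow(ok) == 0L) return(NULL)
  b <- ok[sample.int(nrow(ok), 1L), ]
  s <- b$start + sample.int(b$end - b$start + 2L - w, 1L) - 1L
  data.frame(start = s, end = s + w - 1L)
}

complement_intervals <- function(blocks, len) {
  calls <- if (nrow(blocks) == 0L) logical(len) else
    intervals_to_calls(blocks, len)
  calls_to_intervals(!calls)
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws a full five-table cohort from [cohort_params()] plus the ground
#' truth needed to score the pipeline against it: every generated
#' feature with its `should_be_called` flag (TRUE for planted binding
#' features inside true IDRs, FALSE for decoys, evaluated under the
#' default configuration and faithful predictor tracks), the true
#' disorder intervals, and each protein's true localization class and
#' pProS group. The output is fully determined by `params$seed`.
#'
#' @param params a [cohort_params()].
#' @param out_dir optional directory; when given, the five input TSVs
#'   plus `ground_truth.tsv` are written there.
#' @return list with elements `cohort` (a [pros_cohort()]),
#'   `ground_truth` (list of data frames `features`, `disorder`,
#'   `proteins`), and `params`.
#' @export
generate_cohort <- function(params = cohort_params(), out_dir = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  n <- params$n_proteins
  acc <- sprintf("SYN%05d", seq_len(n))
  lens <- pmax(params$min_length,
               as.integer(round(rlnorm(n, params$length_meanlog,
                                       params$length_sdlog))))

  a <- params$target_disorder_fraction * params$disorder_concentration
  b <- (1 - params$target_disorder_fraction) * params$disorder_concentration
  frac <- rbeta(n, a, b)

  feat_rows <- list()
  track_rows <- list()
  truth_feat <- list()
  truth_dis <- list()
  has_planted <- logical(n)
  true_frac <- numeric(n)

  for (i in seq_len(n)) {
    len <- lens[i]
    total_dis <- as.integer(round(frac[i] * len))
    n_blocks <- if (total_dis >= 60L && runif(1) < 0.5) 2L else 1L
    blocks <- place_idr_blocks(len, total_dis, n_blocks,
                               params$terminal_idr_bias)
    if (nrow(blocks) > 0L) {
      truth_dis[[length(truth_dis) + 1L]] <-
        cbind(accession = acc[i], blocks, stringsAsFactors = FALSE)
      true_frac[i] <- interval_total_length(blocks) / len
    }
    truth_calls <- intervals_to_calls(blocks, len)

    for (pred in PREDICTORS) {
      agree <- runif(len) < params$predictor_agreement
      calls <- ifelse(agree, truth_calls, !truth_calls)
      iv <- calls_to_intervals(calls)
      if (nrow(iv) > 0L) {
        track_rows[[length(track_rows) + 1L]] <-
          cbind(accession = acc[i], predictor_id = pred, iv,
                stringsAsFactors = FALSE)
      }
    }

    fid <- 0L
    add_feature <- function(iv, type, desc, planted) {
      fid <<- fid + 1L
      id <- sprintf("F%02d", fid)
      feat_rows[[length(feat_rows) + 1L]] <<-
        data.frame(accession = acc[i], feature_id = id,
                   feature_type = type, description = desc,
                   start = iv$start, end = iv$end, stringsAsFactors = FALSE)
      truth_feat[[length(truth_feat) + 1L]] <<-
        data.frame(accession = acc[i], feature_id = id,
                   feature_type = type, description = desc,
                   start = iv$start, end = iv$end,
                   should_be_called = planted, stringsAsFactors = FALSE)
    }

    k <- rpois(1, params$n_planted_pros)
    for (j in seq_len(k)) {
      w <- sample(5:25, 1L)
      iv <- place_inside(blocks, w)
      if (is.null(iv)) next
      f <- sample_positive_feature(sample(partner_pool, 1L))
      add_feature(iv, f$type, f$description, planted = TRUE)
      has_planted[i] <- TRUE
    }

    m <- rpois(1, params$decoy_feature_rate)
    ordered <- complement_intervals(blocks, len)
    for (j in seq_len(m)) {
      kind <- sample(c("ordered", "negated", "long", "plain"), 1L,
                     prob = c(0.4, 0.3, 0.15, 0.15))
      if (kind == "ordered") {
        w <- sample(5:25, 1L)
        iv <- place_inside(ordered, w)
        if (is.null(iv)) kind <- "negated" else {
          f <- sample_positive_feature(sample(partner_pool, 1L))
          add_feature(iv, f$type, f$description, planted = FALSE)
          next
        }
      }
      if (kind == "negated") {
        w <- sample(5:25, 1L)
        iv <- place_inside(blocks, w)
        if (is.null(iv)) iv <- place_inside(
          data.frame(start = 1L, end = len), w)
        add_feature(iv, "mutagenesis_site",
                    sprintf(sample(negated_templates, 1L),
                            sample(partner_pool, 1L)),
                    planted = FALSE)
      } else if (kind == "long") {
        w <- sample(30:45, 1L)
        iv <- place_inside(blocks, w)
        if (is.null(iv)) iv <- place_inside(
          data.frame(start = 1L, end = len), w)
        if (is.null(iv)) next
        add_feature(iv, "region_of_interest",
                    sprintf("Interaction with %s",
                            sample(partner_pool, 1L)),
                    planted = FALSE)
      } else if (kind == "plain") {
        w <- sample(5:25, 1L)
        iv <- place_inside(data.frame(start = 1L, end = len), w)
        add_feature(iv, "region_of_interest",
                    sample(plain_descriptions, 1L), planted = FALSE)
      }
    }
  }

  # diseases: power-law counts over a categorized disease pool
  pool <- data.frame(
    disease_id = sprintf("SD%05d", seq_len(params$n_disease_pool)),
    category = sample(DISEASE_CATEGORIES, params$n_disease_pool,
                      replace = TRUE,
                      prob = c(204, 335, 687, 832, 79, 213, 256, 149, 795,
                               91, 63, 55, 104, 66, 194)),
    stringsAsFactors = FALSE)
  is_disease <- runif(n) < params$p_disease
  disease_rows <- list()
  n_dis <- integer(n)
  for (i in which(is_disease)) {
    k <- min(power_law_count(1, params$disease_powerlaw_exponent,
                             params$max_disease_count),
             params$n_disease_pool)
    picked <- pool[sample.int(nrow(pool), k), ]
    n_dis[i] <- k
    disease_rows[[length(disease_rows) + 1L]] <-
      cbind(accession = acc[i], picked, stringsAsFactors = FALSE)
  }

  # localization: CN enriched in the pProS group
  bg <- params$loc_probs[LOCATION_CLASSES]
  en <- bg
  en[["CN"]] <- bg[["CN"]] * params$cn_enrichment
  rest <- setdiff(LOCATION_CLASSES, "CN")
  en[rest] <- bg[rest] * (1 - en[["CN"]]) / (1 - bg[["CN"]])
  cls <- character(n)
  loc_rows <- list()
  other_terms <- c("endoplasmic reticulum", "mitochondrion",
                   "cell junction", "golgi apparatus", "secreted",
                   "cell projection")
  extra_terms <- c("cytoskeleton", "stress granule", "p-body",
                   "nucleolus", "lipid droplet")
  for (i in seq_len(n)) {
    p <- if (has_planted[i]) en else bg
    cls[i] <- sample(LOCATION_CLASSES, 1L, prob = p)
    terms <- switch(cls[i],
                    N = "nucleus", C = "cytoplasm", M = "membrane",
                    CN = c("cytoplasm", "nucleus"),
                    other = if (runif(1) < 0.2) c("cytoplasm", "membrane")
                            else sample(other_terms, 1L))
    if (runif(1) < 0.25) terms <- c(terms, sample(extra_terms, 1L))
    loc_rows[[i]] <- data.frame(accession = acc[i], location_term = terms,
                                stringsAsFactors = FALSE)
  }

  # interactor counts linear in disease multiplicity
  noise <- if (params$ppi_noise_sd > 0) rnorm(n, 0, params$ppi_noise_sd)
           else numeric(n)
  counts <- pmax(0, round(params$ppi_intercept +
                            params$ppi_slope * n_dis + noise))
  missing <- runif(n) < params$ppi_missing_rate
  counts[missing] <- NA_integer_

  cohort <- pros_cohort(
    proteins = data.frame(accession = acc, length = lens,
                          interactor_count = as.integer(counts),
                          stringsAsFactors = FALSE),
    features = do.call(rbind, c(feat_rows, list(empty_features()))),
    tracks = do.call(rbind, c(track_rows, list(empty_tracks()))),
    diseases = do.call(rbind, c(disease_rows, list(empty_diseases()))),
    locations = do.call(rbind, c(loc_rows, list(empty_locations()))))

  truth <- list(
    features = sort_reset(do.call(rbind, c(truth_feat, list(
      data.frame(accession = character(0), feature_id = character(0),
                 feature_type = character(0), description = character(0),
                 start = integer(0), end = integer(0),
                 should_be_called = logical(0))))),
      c("accession", "feature_id")),
    disorder = sort_reset(do.call(rbind, c(truth_dis, list(
      data.frame(accession = character(0), start = integer(0),
                 end = integer(0))))), c("accession", "start")),
    proteins = data.frame(accession = acc, length = lens,
                          true_disorder_fraction = true_frac,
                          location_class = cls,
                          pros_group = has_planted,
                          n_diseases = n_dis,
                          stringsAsFactors = FALSE))

  if (!is.null(out_dir)) {
    write_cohort(cohort, out_dir)
    gt <- truth$features
    write_tsv(gt, file.path(out_dir, "ground_truth.tsv"))
  }
  list(cohort = cohort, ground_truth = truth, params = params)
}
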