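# Brute-force oracles, deliberately written over explicit residue sets
# and token lists so they share no code path with the implementation.

bf_residues <- function(df) {
  if (nrow(df) == 0L) return(integer(0))
  sort(unique(unlist(mapply(seq.int, df$start, df$end,
                            SIMPLIFY = FALSE))))
}

bf_union_count <- function(dfs) {
  if (is.data.frame(dfs)) dfs <- list(dfs)
  length(unique(unlist(lapply(dfs, bf_residues))))
}

# per-residue vote counting over logical vectors
bf_consensus_residues <- function(tracks, len, min_votes) {
  votes <- integer(len)
  for (tr in tracks) {
    v <- logical(len)
    v[bf_residues(tr)] <- TRUE
    votes <- votes + v
  }
  which(votes >= min_votes)
}

# keyword selection via lowercase word tokens (startsWith / equality),
# independent of the regex route
bf_select <- function(features, config) {
  sel <- logical(nrow(features))
  for (i in seq_len(nrow(features))) {
    type <- features$feature_type[i]
    toks <- strsplit(tolower(features$description[i]),
                     "[^a-z0-9]+")[[1]]
    toks <- toks[toks != ""]
    starts_any <- function(words) {
      any(vapply(toks, function(t) {
        any(vapply(words, function(w) startsWith(t, w), logical(1)))
      }, logical(1)))
    }
    sel[i] <- switch(type,
      short_sequence_motif = TRUE,
      region_of_interest = starts_any(config$positive_keywords_region),
      mutagenesis_site =
        starts_any(config$positive_keywords_mutagenesis) &&
        !any(toks %in% tolower(config$negation_tokens)),
      FALSE)
  }
  sel
}

# coverage of a feature by the consensus, as residue-set arithmetic
bf_coverage <- function(feature_df, consensus_df) {
  f <- bf_residues(feature_df)
  length(intersect(f, bf_residues(consensus_df))) / length(f)
}

random_intervals <- function(n, max_end = 100L) {
  s <- sample.int(max_end, n, replace = TRUE)
  w <- sample.int(12L, n, replace = TRUE) - 1L
  data.frame(start = s, end = pmin(s + w, max_end))
}

# a small random cohort exercising every table
random_cohort <- function(n_proteins = 20L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  acc <- sprintf("R%03d", seq_len(n_proteins))
  lens <- sample(80:300, n_proteins, replace = TRUE)
  feats <- do.call(rbind, lapply(seq_len(n_proteins), function(i) {
    k <- sample(0:4, 1)
    if (k == 0) return(NULL)
    s <- sample.int(lens[i] - 30L, k, replace = TRUE)
    w <- sample(3:40, k, replace = TRUE)
    data.frame(accession = acc[i], feature_id = sprintf("F%02d", seq_len(k)),
               feature_type = sample(c(SELECTABLE_FEATURE_TYPES, "variant"),
                                     k, replace = TRUE),
               description = sample(c("Interaction with X",
                                      "Loss of binding to Y",
                                      "Does not affect binding to Z",
                                      "Disordered linker",
                                      "LXXLL motif"), k, replace = TRUE),
               start = s, end = pmin(s + w, lens[i]),
               stringsAsFactors = FALSE)
  }))
  tracks <- do.call(rbind, lapply(seq_len(n_proteins), function(i) {
    do.call(rbind, lapply(PREDICTORS, function(p) {
      k <- sample(0:3, 1)
      if (k == 0) return(NULL)
      iv <- random_intervals(k, lens[i])
      data.frame(accession = acc[i], predictor_id = p, iv,
                 stringsAsFactors = FALSE)
    }))
  }))
  dis <- do.call(rbind, lapply(seq_len(n_proteins), function(i) {
    k <- sample(0:3, 1)
    if (k == 0) return(NULL)
    data.frame(accession = acc[i],
               disease_id = sprintf("SD%03d", sample.int(40L, k)),
               category = sample(DISEASE_CATEGORIES, k, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  locs <- do.call(rbind, lapply(seq_len(n_proteins), function(i) {
    data.frame(accession = acc[i],
               location_term = sample(c("nucleus", "cytoplasm",
                                        "membrane", "mitochondrion"),
                                      sample(1:2, 1)),
               stringsAsFactors = FALSE)
  }))
  locs <- unique(locs)
  pros_cohort(proteins = data.frame(accession = acc, length = lens,
                                    interactor_count = sample(0:200,
                                                              n_proteins),
                                    stringsAsFactors = FALSE),
              features = feats, tracks = tracks, diseases = dis,
              locations = locs)
}
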