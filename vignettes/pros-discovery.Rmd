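---
title: "Discovering possible protean segments in consensus IDRs"
author: "proseg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering possible protean segments in consensus IDRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proseg)
```

## The procedure and its assumptions

Intrinsically disordered regions (IDRs) host short segments that fold
upon binding a partner molecule. Experimentally validated cases —
protean segments — are rare, but curated feature annotation plus
disorder prediction lets one mine *candidates* at scale. `proseg`
implements that mining as a deterministic pipeline:

1. **Feature extraction.** Each protein carries typed, described,
   located annotations (1-based inclusive coordinates, multi-interval
   locations allowed). A feature's length is its *non-redundant* residue
   count.
2. **Length filter.** Candidates must be shorter than 30 residues,
   implemented as length ≤ `max_feature_length` (default 29). The
   rationale is that the large majority of curated protean segments are
   below 30 residues; longer regions in IDRs are reported as
   pseudo-pProSs by the generic intersection operation but never called.
3. **Keyword selection.** "Short sequence motif" features qualify
   unconditionally. "Region of interest" features qualify when the
   description contains *interact*, *bind*, or *motif*; "mutagenesis
   site" features when it contains *interact* or *bind* and no negation
   token (*no*, *not*). We match positives case-insensitively at word
   starts, because the annotations that must be kept are inflected
   ("Interaction with USP7", "Loss of interactions with MDM2");
   negations match whole words only, because otherwise *no* would fire
   inside *nuclear*. Both sets are configurable.
4. **Consensus IDRs.** A residue is consensus-disordered when at least
   `min_predictor_votes` (default 2) of the three predictor tracks call
   it disordered. Votes are absolute: a predictor that predicts no IDR
   on a protein contributes zero votes rather than abstaining — real
   track sets contain exactly such proteins, and an interval dialect
   cannot distinguish "ran and found nothing" from "absent".
5. **Calling.** A selected feature becomes a pProS when the fraction of
   its residues inside the consensus reaches `idr_coverage_threshold`.
   The default is 1 (full containment), the strictest consistent
   reading of "located in IDRs"; the threshold is exposed because the
   boundary between contained and clipped features is scientifically
   interesting (see the `smn_like` fixture).
6. **Statistics.** Overlapping annotations count separately everywhere
   (they describe different phenomena) *except* in residue accounting,
   which is always a set union: annotations at 360–365 and 360–362
   contribute six residues.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `max_feature_length` | 29 | residues | strict reading of "shorter than 30" |
| `min_predictor_votes` | 2 | predictors | two-of-three consensus |
| `idr_coverage_threshold` | 1.0 | fraction | full containment is the strictest consistent reading of "located in an IDR"; configurable and recorded in `config.json` |
| `positive_keywords_*` | interact/bind/motif | — | word-start, case-insensitive |
| `negation_tokens` | no, not | — | whole-word only |
| `enrichment_log_base` | 2 | — | the base of the localization log ratio-of-ratios is a reporting choice; 2 makes "twice the background" read as +1 |

## Disease, localization, and interaction statistics

**Category table.** A protein assigned to diseases in several categories
contributes to each of them. Within one category a protein counts once
toward protein totals and its unique pProS count once, but
`pros_counts_redundant` weights each pProS by the protein's number of
diseases *in that category*; the ratio unique/redundant
(`pros_redundancy`, ≤ 1) drops below 1 exactly when proteins carry
several diseases of the category. Printed-style percentages use half-up
rounding to one decimal (`round_half_up`), which reproduces the
printed-style reference cells asserted in the tests from their integer
inputs; base R's round-half-even does not. Categories with no pProS-containing protein
report an average of 0 with `empty_flag` set, rather than NA, so the
table stays numeric.

**IDR fractions.** Aggregate fractions are residue-weighted (total
consensus residues over total residues); because it is not obvious
whether a quoted proteome-wide "IDR ratio" is residue-weighted or a
per-protein mean, both are emitted side by side in
`idr_fractions.tsv`.

**Localization.** Classes are N (nucleus only), C (cytoplasm only), M
(membrane only), CN (both cytoplasm and nucleus — the shuttling class),
and other (including proteins with no recognized term; term matching is
case-insensitive exact after trimming). Enrichment of a group against a
background is `log2(group fraction / background fraction)` per class; a
zero fraction on either side yields a flagged row with no numeric
value. The pipeline uses all cohort proteins as the background, so the
background is a superset that includes the group itself — a
conservative choice that slightly attenuates enrichment.

**Disease–PPI relation.** Proteins are binned by distinct assigned
diseases; the headline correlation is Pearson's r between the bin value
and the per-bin mean (or median) interactor count. The raw per-protein
correlation is also emitted: binned and raw correlations answer
different questions and the binned one is the figure-level summary. The
"fewer than 10 diseases" restriction keeps bins 1–9.

## The synthetic cohort generator

`generate_cohort()` emulates all five input tables with known ground
truth. Its defaults define the study conditions used throughout the
tests:

* **Lengths** log-normal, median 400, σ = 0.6, floor 60 — a realistic
  human-proteome-like spread; the floor guarantees a sub-30-residue
  segment always fits.
* **Disorder** per-protein disordered fraction Beta-distributed with
  mean 0.30 (close to quoted proteome-wide IDR ratios near 29%) and
  concentration 20; 1–2 IDR blocks placed with probability 0.7 at a
  terminus, since well-known exemplars carry terminal IDRs.
* **Tracks** echo the true per-residue state independently with
  probability 0.95 per predictor; setting it to 1 gives faithful
  tracks.
* **Features** planted binding annotations (Poisson mean 1.2 per
  protein, 5–25 residues, fully inside true IDRs) with descriptions
  templated from realistic phrasing ("Interaction with X", "Loss of
  interaction with X", "LXXLL motif") so the keyword rules are
  exercised as written; decoys (Poisson mean 1.0) are placed outside
  IDRs, carry negations ("Does not affect binding to X"), exceed 29
  residues, or lack keywords.
* **Diseases** 16.6% of proteins are disease-related (matching quoted
  cohort proportions); counts follow a discrete power law with exponent
  2.5 over a 300-disease pool whose category frequencies mirror a
  realistic 15-category spread.
* **Localization** class probabilities (N .20, C .20, M .15, CN .20,
  other .25) with the CN probability multiplied by 1.5 in
  pProS-containing proteins (others rescaled), planting a log₂
  enrichment of 0.585.
* **Interactors** `count = max(0, round(40 + 25·n_diseases + N(0, 30)))`,
  with 5% of proteins lacking interaction data; zero noise makes the
  per-bin mean exactly linear, so the binned correlation is exactly 1.

What the generator does *not* emulate: amino-acid sequences, predictor-
specific error structure (errors are i.i.d. per residue, real predictors
err in runs), annotation-text diversity beyond the templates, and
disease co-occurrence structure. Passing tests therefore demonstrate
correctness of the pipeline's logic under known truth, not performance
on real databases.

## Numerical and degenerate-input choices

* Coordinates are validated fail-fast with accession-level messages;
  intervals must satisfy 1 ≤ start ≤ end ≤ protein length.
* Normalization merges overlapping *and adjacent* intervals and is
  idempotent and order-independent.
* Coverage comparison uses a 10⁻¹² tolerance so a feature exactly at
  the threshold is called.
* Ranking ties break lexicographically by accession; all report tables
  carry documented sort keys, so identical inputs give byte-identical
  reports (`manifest.json`, which records wall-clock timings, is the
  one exception).
* Correlation over fewer than two bins, or with zero variance, is an
  explicit error, not an NA — the pipeline wrapper catches it and
  writes a flagged row.
* Empty groups are skipped in the localization report; empty categories
  cannot occur (a category only appears when some protein carries it).

## Problem sizes used in the packaged checks

The test-suite and acceptance script run the generator at 500 proteins
(default), 1000 for the localization-enrichment recovery (binomial
sampling error on the CN class fraction shrinks enough to resolve the
planted 0.585 log-ratio within three standard errors), and smaller
cohorts (25–150) for round-trip, determinism, and oracle-equivalence
checks; brute-force oracles run on ~1000 random interval instances.

## Known limitations

* Keyword selection is lexical; it neither parses negation scope
  ("abolishes binding" is kept by design because *loss-of-binding*
  mutagenesis evidence marks a binding site) nor maps descriptions to
  ontologies.
* Only explicit integer endpoints are accepted; UniProt features with
  unknown or fuzzy endpoints must be resolved upstream.
* The localization classifier uses three plain terms; GO-based
  cellular-component resolution is out of scope.
* Disorder tracks are consumed, never computed: predictions must be
  supplied as intervals (or per-residue calls).
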