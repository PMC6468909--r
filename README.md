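# proseg

Discovery of **possible protean segments (pProSs)** — short
binding-associated feature annotations located inside consensus-predicted
intrinsically disordered regions (IDRs) — together with the
disease-category, subcellular-localization, and protein–protein
interaction statistics built on top of the calls.

## Background

Intrinsically disordered regions carry short functional segments (often
under 30 residues) that fold when they bind a partner — the coupled
folding and binding mechanism. Segments with direct experimental evidence
of this behaviour are called protean segments (ProSs), but only a few
hundred are curated. `proseg` mines *candidates* for such segments from
curated protein annotation instead: a UniProt-style feature (a typed,
described, located annotation) is called a **pProS** when

1. its non-redundant length is **shorter than 30 residues**;
2. its description is **binding-associated**: every "short sequence
   motif" qualifies; a "region of interest" needs *interact*, *bind*, or
   *motif* in its description; a "mutagenesis site" needs *interact* or
   *bind* and must not contain *no*/*not* as a whole word;
3. it lies inside a **consensus IDR** — residues called disordered by at
   least 2 of 3 predictor tracks (MobiDB-lite, DISOPRED3, DICHOT), with
   full containment required by default.

Downstream, the package computes per-disease-category statistics
(protein coverage = % of a category's proteins carrying a pProS; average
annotations = unique pProSs per pProS-containing protein; non-redundant
pProS residue accounting, so annotations at 360–365 and 360–362 count 6
residues), localization enrichment as the log₂ ratio-of-ratios of
class fractions (N/C/M/CN/other, where CN is the cytoplasm-and-nucleus
shuttling class), and the Pearson correlation between per-bin mean (or
median) interactor counts and the number of assigned diseases.

All inputs are flat TSVs (see `?read_cohort` for the dialects); a
synthetic cohort generator (`?generate_cohort`) emulates all five input
tables with known ground truth, so the full pipeline is testable without
any database download.

## Worked example

The packaged `p53_like` fixture transcribes a 393-residue transcription
factor with 11 short annotations on its terminal and linker IDRs:

```r
library(proseg)
res <- run_pipeline(make_fixture("p53_like"), quiet = TRUE)
res$pros_calls[, c("feature_id", "start", "end", "idr_coverage", "selection_reason")]
#>    feature_id start end idr_coverage    selection_reason
#> 1         F01    15  25            1         motif_class
#> 2         F02    15  25            1 keyword_mutagenesis
#> 3         F03    15  25            1 keyword_mutagenesis
#> 4         F04    48  56            1         motif_class
#> 5         F05   305 321            1         motif_class
#> 6         F06   370 372            1         motif_class
#> 7         F07   359 363            1      keyword_region
#> 8         F08   359 363            1 keyword_mutagenesis
#> 9         F09   359 363            1      keyword_region
#> 10        F10   359 363            1         motif_class
#> 11        F11   368 387            1      keyword_region
```

All 11 annotations are called: each is ≤ 29 residues, binding-associated
(note three *distinct* overlapping annotations at 15–25 — overlaps are
counted separately, they describe different phenomena), and fully inside
the 2-of-3 consensus IDRs. Residue accounting is nevertheless
non-redundant:

```r
pros_residues_per_protein(res$pros_calls)
#>   accession pros_residues
#> 1    P04637            61
```

By contrast, the `smn_like` fixture contains a 32-residue
GEMIN2-interaction region that sits entirely in an IDR but exceeds the
length limit — a *pseudo-pProS* that is never called.

A full synthetic run:

```r
g   <- generate_cohort(cohort_params(seed = 7))        # 500 proteins
res <- run_pipeline(g$cohort, out_dir = "report")      # writes 12 files
aggregate_idr_fraction(g$cohort, res$consensus)$residue_weighted
#> [1] 0.3016399   # generator target: 0.30
```

`run_pipeline()` writes `pros_calls.tsv`, `table1.tsv` (cohort
annotation statistics), `table2.tsv` (per-category statistics),
`table3.tsv` (proteins ranked by pProS residues), `idr_fractions.tsv`,
`localization_enrichment.tsv`, `ppi_correlation.tsv`, `ppi_bins.tsv`,
plus `config.json` and `manifest.json`. A thin command-line wrapper
lives at `inst/cli/proseg.R` (`run` / `generate` / `fixture` verbs).

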