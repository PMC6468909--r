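Package: proseg
Title: Possible Protean Segments in Intrinsically Disordered Regions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovers possible protean segments (pProSs): short
    binding-associated feature annotations that fall inside consensus
    predicted intrinsically disordered regions (IDRs) of human proteins.
    Combines per-predictor disorder tracks into a two-of-three consensus,
    applies length and keyword rules to UniProt-style feature annotations,
    intersects the selected features with the consensus IDRs, and computes
    downstream statistics: per-disease-category counts and coverage,
    non-redundant pProS residue accounting, subcellular-localization
    enrichment as log ratio-of-ratios, and the relation between per-protein
    disease multiplicity and protein-protein interaction degree. Includes a
    synthetic cohort generator with known ground truth so the whole
    pipeline is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    IRanges,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
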