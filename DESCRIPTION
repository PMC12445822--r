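Package: kacmeta
Title: Cross-Species Lysine Acetylome Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for meta-analysis of lysine acetylation (Kac) across
    species: proteome-normalized acetylation metrics, per-protein site-count
    distributions, protein-domain summaries, Fisher-exact GO/KEGG term
    enrichment built from 2x2 contingency tables, glycolysis/TCA enzyme
    acetylation matrices, cross-species projection of regulatory lysines
    through global sequence alignment, and structure-based measurements
    (funnel-region lysine counts, sphere-grid catalytic-cavity volumes and
    minimum residue distances on trajectory frames). Includes a synthetic-data
    generator that emulates every input format with planted ground truth so
    the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
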