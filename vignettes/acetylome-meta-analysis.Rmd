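---
title: "Methods: cross-species acetylome meta-analysis with kacmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species acetylome meta-analysis with kacmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kacmeta)
```

## The problem and the model

Lysine acetylation (Kac) is a reversible post-translational modification
found from bacteria to mammals. Comparing published acetylomes across
species is confounded by proteome size: a mammalian proteome holds an
order of magnitude more lysines than a bacterial one, so absolute site
counts say little. `kacmeta` normalizes every acetylome against its own
predicted proteome:

- `pct_kac_sites` — 100 × (distinct acetylated positions) / (total
  proteome lysines); the denominator counts `K` case-insensitively and
  never counts ambiguity codes (X/B/Z/U), so it is deterministic for a
  given FASTA release.
- `pct_kac_proteins` — 100 × (proteins with ≥ 1 site) / (proteome size).

Sites are identified by (protein, 1-based position), duplicates
collapsed, so "site count" always means *distinct positions*, never
spectral counts. Both percentages error out rather than return NaN when
a denominator is zero.

Per-protein site counts are binned into 1 / 2 / 3–5 / 6–10 / >10. The
published convention also names an overlapping "5" class; here the five
bins are kept disjoint (the ">5–10" class is {6,…,10}) and the
exactly-5 class appears only in the high-acetylation selection
(`select_high_acetyl()`: exactly_5 / 6–10 / >10), which is what the
domain summaries consume. Pooling across acetylomes is count-weighted —
percentages are recomputed from summed counts, not averaged — because
acetylomes differ in size by orders of magnitude; the unweighted mean is
attached as an attribute for comparison.

## Enrichment engine

Term enrichment follows the classical contingency construction: for a
term with K carriers in a background of N genes and a study of n genes
of which a carry the term, the 2×2 table is (a, n−a, K−a, N−n−K+a) and
the one-sided Fisher exact p-value is the hypergeometric upper tail
P(X ≥ a). The tail is summed in log space from `lchoose` terms, which
keeps the computation stable well beyond N = 10⁶; `p = 1` is returned
identically when a = 0. Fold enrichment is (a/n)/(K/N).

Choices the published pipelines leave open are explicit switches here:

- **Background**: defaults to all genes with at least one annotation
  (the least-assuming population); any explicit vector is accepted, and
  study ⊄ background is an error rather than silent clipping.
- **GO propagation**: on by default (the true-path rule: a gene
  annotated to a term is annotated to all its is_a ancestors); turning
  it off reproduces flat per-term counting. Both paths are tested.
- **Multiplicity**: default is the raw p < 0.01 cut; Benjamini–Hochberg
  is available (`correction = "BH"`) since meta-analyses routinely test
  hundreds of terms.
- **Alternative**: one-sided "greater" by default (enrichment is the
  question); a two-sided option exists for depletion designs.

The OBO parser keeps id/name/namespace/is_a/is_obsolete, rejects cycles
(Kahn peeling) and edges to undeclared terms; obsolete terms are
excluded from propagation. The KEGG BRITE parser maps D-level KO entries
to their enclosing C-level pathway, one mapping per enclosure.

## Conservation projection

Regulatory-lysine projection aligns the reference to each ortholog with
an in-package Needleman–Wunsch/Gotoh global aligner (BLOSUM62, gap open
−10, gap extend −0.5; a gap of length L costs −10 − 0.5·(L−1)).
Traceback ties resolve diagonal > up > left, so alignments are
deterministic. A pre-computed multiple alignment, when supplied, takes
precedence over pairwise alignment. The aligner lives in the package
(rather than wrapping an external tool) to keep the projection fully
reproducible offline; its scores are checked against an independent
naive dynamic program and against `Biostrings::pairwiseAlignment` in
the tests.

Percent identity counts identical columns over columns where at least
one sequence has a residue (both-gap columns, possible in MSA slices,
are excluded) — stated explicitly because "percent identity" is
otherwise ambiguous. Projected residues are classified conserved_K /
conservative_R / gap / other; the conservative class is exactly {R},
the charge-preserving substitution, and histidine deliberately falls
under "other".

## Structure measurements

Cavity volume emulates the sphere-grid approach of trajectory cavity
tools: an axis-aligned grid (default 0.5 Å) centered on the probe
center is intersected with a sphere (default 8 Å, the radius that
covers a catalytic-site cavity), and points farther than
r_atom + probe_radius from every atom count as free; volume = free
points × spacing³. Atomic radii are a fixed element table (C 1.70,
N 1.55, O 1.52, S 1.80, H 1.20 Å) and `probe_radius` defaults to 0
(free-volume counting). The empty sphere at 0.5 Å spacing lands within
0.5% of the analytic 4/3·π·8³ ≈ 2144.66 ų, and the discretization error
shrinks monotonically through 1.0/0.5/0.25 Å. Trajectory summaries
report the population SD (the parenthetical-SD reporting style), not
the sample SD. Molecular dynamics itself — force fields, thermostats,
replica protocols — is out of scope; the module measures frames
produced elsewhere or by the synthetic generator, so published MD
volume means are not reproduction targets here.

Funnel-region lysine counting (FK and its acetylated subset FKac) takes
the region as explicit residue ranges per species: the ranges are data,
not constants, because published figures do not print them.

## The synthetic generator: what it emulates, what it does not

The generator stands in for a curated compilation of published
acetylomes, which cannot be redistributed or fetched at build time. It
emulates the *analysis inputs*: proteomes with a controllable lysine
frequency (default 0.07, a typical proteome composition — a default,
not a biological claim), acetylomes with a planted site-count
distribution (default proportions 0.50/0.20/0.20/0.07/0.03 over the
five bins, chosen to echo the single-site-dominated shape real
acetylomes show), annotation sets with one term planted at a stated
odds ratio, ortholog families with planted key-residue fates, and
breathing multi-model structures. It does **not** model
mass-spectrometry artifacts (missed cleavages, FDR, spectral counts),
real domain architectures, or phylogenetic correlation between species.
Passing tests therefore demonstrate that the *machinery* is correct —
counting, normalization, exact tests, projection, volumetrics — not
that any biological conclusion transfers to real data.

Two generator details matter for testing. Deterministic-quota mode
allocates bin counts by largest-remainder rounding, so the realized
distribution matches the plant *exactly* and distribution recovery can
be asserted with `expect_identical`; multinomial mode samples bins and
is checked within binomial bounds instead. And every generator is a
pure function of (parameters, seed): identical seeds give identical
bytes, which the determinism tests assert on the emitted files.

The packaged ortholog/SODA fixtures were generated once with these
generators (seeds fixed) so that published coordinate relationships
hold: aldolase K147 maps to K185/K147/K162/K147/K157 via N-terminal
extensions, the Hsp70 panel carries the KRLIGERKFGDP motif with K77 and
four arginine-substituted orthologs, and the human SODA carries the
largest planted funnel-Kac count. Their filenames and headers mark them
as synthetic.

## Numerical and design choices

- Fisher p-values: exact tail summation, not a normal approximation;
  agreement with `stats::phyper` is ≤ 2×10⁻¹³ relative over all 635,376
  tables with N ≤ 60 (the acceptance sweep).
- The null calibration uses 500 permutation-null datasets (1000 genes,
  5 terms) and the power check 200 seeds (term 30/1000, study 100,
  odds ratio 8) — sizes at which the whole suite runs in well under a
  minute while the binomial bands are still informative. The observed
  false-positive rate sits below the nominal 0.01, as expected for a
  discrete exact test.
- Validation of site tables defaults to lenient-with-report (published
  tables were built on proteome releases one may not hold); strict mode
  is used for synthetic data, where any mismatch is a bug.
- Protein identifiers default to the first whitespace-delimited FASTA
  header token, with a regex override for UniProt-style headers.
- Ranking ties (enzyme levels) break lexicographically and are flagged
  rather than hidden.
- Degenerate inputs error loudly: empty proteomes, zero-lysine
  denominators, empty study sets, unresolvable residues, regions beyond
  the sequence.

## Known limitations

- The ingestion layer does not map accessions across databases; it
  records identifiers as given (an accession-mapping service would be a
  network dependency).
- Isoforms/paralogs of a pathway enzyme are pooled (union of sites,
  summed lysines); per-isoform reporting would need a richer catalog
  format.
- The aligner is O(n·m) in memory and intended for single proteins, not
  genome-scale alignment.
- Grid volumes depend on the radii table and spacing; absolute values
  are comparable only within a fixed configuration.
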