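---
title: "proteopick: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{proteopick: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteopick)
```

## Problem and scope

Targeted mass-spectrometry assays (PRM/MRM) and cell-type spectral-library
resources both rest on the same computational substrate: digest a reference
proteome in silico, decide which peptides are unambiguous surrogates for
their proteins, rank candidates by their chemical suitability, quantify
relative protein abundance from spectral counts, and integrate
post-translational modification (PTM) evidence under strict reliability
gates. `proteopick` implements that substrate as composable functions plus
a command-line pipeline. It consumes the *tabular* outputs of upstream
search engines (PSM/peptide tables, spectral counts, PTM observations); it
does not process raw spectra, rescore identifications, or render
interactive reports.

## Digestion model

Trypsin cleaves C-terminal of Lys and Arg. By default cleavage is
suppressed when the next residue is Pro — the "Trypsin (full)" convention
of common search software; because published search settings frequently
omit which convention was used, `digest_params(cleave_before_proline =
TRUE)` switches to the permissive rule. Defaults follow common database
search practice:

* `max_missed_cleavages = 2`,
* peptide length 6–150 residues,
* fixed carbamidomethylation of Cys (+57.02146 Da) on every peptide mass,
* variable Met oxidation (+15.99491 Da) available per peptide via
  `n_oxidation`.

Peptide coordinates are 1-based inclusive on the parent sequence, matching
how PTM sites are reported on UniProt entries. Precursor m/z uses the
proton mass 1.007276 Da; masses are carried in double precision and only
rounded (5 decimals) at the TSV boundary. Protein-level masses are
*average* masses (the convention for molecular-mass distributions);
peptide masses are monoisotopic. Sequences containing non-standard
residues (B/J/O/U/X/Z) are rejected — their masses and cleavage behaviour
are undefined — or dropped with a warning under `read_fasta(lenient =
TRUE)`.

## Uniqueness (proteotypicity)

A peptide is proteotypic when it maps to exactly one protein. Two
semantics are offered:

* **substring** (default): any protein whose sequence contains the peptide
  anywhere is a parent. This is the conservative definition — a peptide is
  only called unique if no other protein could produce it under any
  digestion irregularity.
* **digest**: parents are proteins whose in-silico digest (same
  parameters) yields the peptide, reproducing search-space semantics.

Leucine and isoleucine are isobaric and indistinguishable by most MS
workflows; `equate_li = TRUE` collapses them during matching. It defaults
to off, since reference resources typically index the literal sequences.
The index is deterministic: parent sets are stored sorted by accession,
and construction is a pure function of the proteome and parameters.

## The additive suitability score

Each candidate peptide receives the sum of ten criteria (total 0–11);
uniqueness contributes +2, everything else +1:
library presence, proteome uniqueness, length 6–25, zero missed
cleavages, no Met/Cys, N-terminal residue not Trp/Glu, and absence of
Pro-Pro, Asp-Pro, Asp-Gly, and of runs of more than three consecutive
serines. The chemistry behind the flags: Met and Cys oxidise or alkylate
variably; N-terminal Glu cyclises to pyroglutamate and N-terminal Trp
oxidises, shifting mass; Asp-Pro bonds are acid-labile; Asp-Gly
isomerises; poly-Ser stretches fragment poorly and are phosphosite-prone.

Decisions worth recording:

* "N-terminus" means the *peptide's* first residue, not the protein's —
  the degradation chemistry acts on the free peptide terminus.
* The serine rule reads "more than three consecutive": `SSS` passes,
  `SSSS` fails.
* Library presence (`c1`) and uniqueness (`c2`) are caller-supplied
  inputs, so hypothetical peptides can be ranked before being measured;
  the library assembler wires them from the evidence tables and the index.
* Ranking ties are not defined by the scheme; they are broken by shorter
  sequence first (shorter proteotypic peptides ionize and transmit more
  predictably), then lexicographically, making ranking deterministic.
* The raw additive total is reported without normalisation.

## NSAF quantification

The normalized spectral abundance factor for protein $i$ in one sample is
$\mathrm{SAF}_i = \mathrm{SpC}_i / L_i$ and $\mathrm{NSAF}_i =
\mathrm{SAF}_i / \sum_j \mathrm{SAF}_j$, computed within each cell type.
The formula is the standard spectral-counting definition; counts are
consumed as already aggregated per protein group by the upstream search,
and no razor-peptide apportionment is attempted. Zero-count proteins
(identified only in another cell type) keep NSAF 0 rather than being
dropped, so cross-cell-type matrices align. `dynamic_range()` reports
$\log_{10}(\max \mathrm{NSAF} / \min \mathrm{NSAF}_{>0})$ — the "orders of
magnitude" a proteome spans. Either PSM counts or distinct-spectrum counts
may be supplied; the arithmetic is agnostic.

## PTM integration rules

A modified-peptide observation enters a library only if

1. its peptide is proteotypic *and* its sole parent matches the claimed
   accession;
2. its identification q-value is below `q_max` (default 0.01);
3. N-glycopeptides additionally pass the glycan-level q-value (< 0.01),
   a peptide mass window of 600–4000 Da, a length window of 6–40
   residues, and at most 2 modifications per precursor.

Every rejection carries a machine-readable reason code (first failing gate
in the order above, preceded by structural validation:
`invalid_record`, `not_proteotypic`, `parent_mismatch`, `q_value`,
`glyco_q_value`, `glyco_mass`, `glyco_length`, `glyco_mod_count`). The
partition is exhaustive and disjoint, idempotent, and monotone in every
threshold — properties the test suite asserts.

The modification-count gate is interpreted per record via an optional
`n_mods` column (modifications on the precursor, default 1), matching
glyco search-engine semantics; counting distinct records per peptide would
wrongly penalise independent observations of different sites.

Residue vocabulary defaults: oxidation {M}, phosphorylation {S,T,Y},
monomethylation {K,R}, deamidation {N,Q}, acetylation {K, R,
protein-N-term}, N-glycosylation {N}. Acetylation is the union of the two
residue sets that appear in common search configurations (Lys vs Arg +
protein N-terminus); the vocabulary is configurable because conventions
differ between pipelines. Site-localization scoring is out of scope: the
record's stated site is trusted, then verified against the protein
sequence during projection. If a peptide occurs more than once in its
parent, every occurrence is annotated and flagged `ambiguous`.

## Library assembly, intersections, clustering

A protein is "present" in a cell type when at least `min_peptides`
(default 1) of its observed evidence peptides are proteotypic; raising the
threshold to 2 gives a stricter library. Per-cell-type tables carry the
accession, description, gene symbol, number of proteotypic peptides
observed, NSAF, pass-through pathway annotations, and the full scored
candidate-peptide list with m/z at charges 2–4 (the usual DDA
precursor-charge window).

Exclusive intersections are UpSet-style: for each of the $2^k - 1$
non-empty subsets of cell types, the number of proteins present in
*exactly* those types; the counts always sum to the union size, the
all-types cell is the core proteome, and singleton cells are the
cell-type-unique proteins.

Marker clustering follows the conventional recipe: protein-wise min-max
scaling, pairwise Euclidean distances, agglomerative complete linkage.
Numerical conventions chosen where the recipe is silent:

* rows with zero range scale to all-zeros, so constant proteins cluster
  together at distance 0;
* exact merge-distance ties are broken by merging the pair with the
  lexicographically smallest cluster creation order — the merge tree is
  fully deterministic;
* leaf order places the branch containing the lexicographically smallest
  label first at every node, making the displayed order invariant under
  row permutation of the input.

The agglomerator is implemented in-package (naive $O(n^3)$, adequate for
marker panels) and is cross-checked in the tests against both a
from-scratch oracle that recomputes max-linkage distances at every step
and `stats::hclust` on tie-free random matrices.

## Synthetic fixtures: what they emulate, and what a green test proves

`fixture_spec()` describes a small world: 30 proteins of 120–300 residues
(uniform residue frequencies), 3 cell types each expressing ~60% of the
proteome, 3 planted shared peptides (9-mers embedded in two hosts behind a
forced Lys, ending in Arg, so they digest out cleanly), one planted unique
9-mer, and one planted 45-mer (to exercise the glycopeptide length gate,
which random digests essentially never reach). Spectral counts are
`round(K * p_i * L_i)` with `K = 3000`, so `compute_nsaf()` must recover
the planted proportions within rounding error (±0.01); a `K` too small to
represent the smallest proportion is an error. PTM records are planted one
per outcome — kept, plus each rejection reason.

A single integer seed drives all randomness; identical seeds give
byte-identical output files. Every TSV embeds `# seed=N`; FASTA has no
comment syntax, so the proteome's provenance lives in the adjacent
`fixture.json`.

The generator emulates the *table contracts* and planted arithmetic of
real pipelines, not their physics: no spectra, retention times,
intensities, homologous sequence families, decoys, or protein-inference
ambiguity. A green end-to-end test therefore establishes that the
bookkeeping (digestion, indexing, scoring, normalisation, gating,
set arithmetic) is correct — not that the defaults are optimal for any
particular instrument or organism.

## Numerical conventions

* Residue masses: standard 20-residue monoisotopic and average tables;
  water 18.010565 / 18.01528 Da; proton 1.007276 Da.
* Mass additivity holds to 1e-6 Da; NSAF conservation to 1e-9.
* TSVs: UTF-8, tab-delimited, header row, `.` decimal separator; masses
  and m/z rounded to 5 decimals, NSAF to 6 significant digits — only at
  the file boundary.
* All orderings (digest output, parent sets, rankings, intersections,
  merge trees) are deterministic, so repeated runs are byte-identical.

## Known limitations

* Only trypsin; no semi-tryptic or non-specific digestion.
* No predicted detectability, retention time, or transition selection —
  the score is deliberately transparent and rule-based.
* Uniqueness is exact string matching (optionally L=I); no near-isobaric
  substitution search (e.g. GG vs N).
* NSAF inherits the upstream protein-group assignment; shared-peptide
  apportionment is out of scope.
* The clustering is $O(n^3)$ — fine for CD-marker panels, not for
  clustering thousands of proteins.
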