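# proteopick

Selecting the right peptides is the central design problem of targeted mass
spectrometry (PRM/MRM) and of spectral-library resources built from shotgun
(DDA) proteomics. A peptide is useful as a surrogate for its protein only if
it is *proteotypic* — mapping to exactly one protein in the reference
proteome — and chemically well-behaved during digestion, ionization and
storage. `proteopick` implements the computational core of such a resource
for immune-cell (or any) proteomes:

* **in-silico tryptic digestion** with missed cleavages, fixed/variable
  modifications, and precursor m/z;
* a **proteome-wide uniqueness index** (substring or strict-digest
  semantics, optional Leu/Ile equivalence);
* an **additive 11-point peptide suitability score**;
* **NSAF relative abundance** from spectral counts;
* **PTM integration rules** (proteotypic-only, FDR-gated, glycopeptide
  mass/length/modification-count gates) and projection of sites onto
  protein coordinates;
* **library assembly**: per-cell-type tables, UpSet-style exclusive
  intersections (core proteome, cell-type-unique markers), and
  complete-linkage clustering of min-max-scaled abundance profiles;
* a **synthetic-fixture generator** that plants ground truth (shared
  peptides, NSAF proportions, PTM filter outcomes) so the whole pipeline is
  testable offline.

## The score

For each candidate peptide the score is the sum of ten criteria; all add
+1 except proteome uniqueness, which adds +2 (maximum 11):

| criterion | points |
|---|---|
| present in the cell type's spectral library | +1 |
| proteotypic (unique in the reference proteome) | +2 |
| length 6–25 residues | +1 |
| no missed tryptic cleavages | +1 |
| contains neither Met nor Cys | +1 |
| N-terminal residue is neither Trp nor Glu | +1 |
| no Pro-Pro | +1 |
| no Asp-Pro | +1 |
| no Asp-Gly | +1 |
| no run of more than three consecutive Ser | +1 |

NSAF (normalized spectral abundance factor) for protein *i* in one sample is

```
SAF_i = SpC_i / L_i          NSAF_i = SAF_i / Σ_j SAF_j
```

with `SpC` the spectral count and `L` the protein length; NSAF sums to 1
within each cell type.

## Worked example

```r
library(proteopick)
prot <- read_fasta("proteome.fasta")   # UniProt-style headers
idx  <- build_index(prot)              # uniqueness over the whole proteome
peps <- digest(prot)                   # trypsin, <=2 missed cleavages, 6-150 aa
cls  <- classify_peptide(idx, peps$sequence)
sc   <- score_peptides(peps$sequence, peps$missed_cleavages,
                       in_library = TRUE,
                       proteotypic = cls$status == "proteotypic")
rank_peptides(sc[peps$parent_accession == "P10300"])
```

On a two-protein toy FASTA (Cd8b1 fragment + a decay-accelerating-factor
fragment sharing two tryptic peptides) this prints:

```
 rank                  sequence total     c2     c5    c10
    1                 LLLSSSAGK    11   TRUE   TRUE   TRUE
    2              AAEQHDLLYVDK    11   TRUE   TRUE   TRUE
    3              DQEFLTAAGENR    11   TRUE   TRUE   TRUE
    ...
    8           TTAWSATNLVGFCPK     8  FALSE  FALSE   TRUE
   11                 WMDPSSSSK     7   TRUE  FALSE  FALSE
```

Reading: `LLLSSSAGK` passes all ten criteria (total 11) and is the best
assay candidate; `TTAWSATNLVGFCPK` occurs in both proteins (loses the +2
uniqueness bonus, `c2 = FALSE`) and contains Cys; `WMDPSSSSK` starts with
Trp, contains Met, an Asp-Pro bond and a four-Ser run. The top candidate's
2+ precursor is at m/z 438.2635
(`peptide_mz("LLLSSSAGK", 2)`).

## Command line

```sh
Rscript inst/cli/proteopick.R simulate --out sim --seed 42
Rscript inst/cli/proteopick.R build \
    --proteome sim/proteome.fasta --counts sim/counts.tsv \
    --evidence sim/evidence.tsv --ptms sim/ptms.tsv --out out
```

Commands: `digest`, `index`, `score`, `nsaf`, `ptm-filter`, `build`,
`intersect`, `cluster`, `simulate`. Exit codes: 0 success, 1 input error,
2 internal error. A JSON config file (`--config`) can hold any flag;
precedence is flags > config > defaults.

## Documentation

The methods vignette (`vignettes/proteopick-methods.Rmd`) describes the
model, parameter defaults and units, what the synthetic fixtures do and do
not emulate, numerical conventions, and known limitations.
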