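# Synthetic proteomes and evidence tables with planted ground truth.
#
# The generator emulates the *tabular* world the toolkit consumes — a FASTA
# proteome, per-cell-type spectral counts, observed-peptide evidence and PTM
# records — with known answers planted: shared peptides embedded in several
# hosts, per-cell-type NSAF proportions, and PTM records labelled with the
# exact filter outcome they must receive. It does not simulate spectra,
# retention times or intensities.

#' Specification for a synthetic fixture
#'
#' All randomness derives from `seed`; the same spec yields byte-identical
#' outputs on re-run. Defaults describe a small but structured world: 30
#' proteins of 120-300 residues, 3 cell types each expressing ~60% of the
#' proteome, 3 planted shared peptides, spectral counts scaled by
#' `k_counts = 3000` so NSAF recovery is exact to within rounding (about
#' 0.01).
#'
#' @param seed Integer seed controlling all randomness.
#' @param n_proteins Number of proteins in the toy proteome.
#' @param length_range Protein length bounds (residues).
#' @param n_cell_types Number of cell types.
#' @param n_shared Number of planted shared peptides (each embedded in 2
#'   hosts).
#' @param shared_length Length of planted shared peptides.
#' @param expressed_fraction Fraction of proteins expressed per cell type.
#' @param k_counts Count scale: spectral counts are
#'   `round(k_counts * nsaf_i * length_i)`.
#' @param n_evidence_peptides Proteotypic peptides observed per expressed
#'   protein (up to availability).
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_proteins = 30L, length_range = c(120L, 300L),
                         n_cell_types = 3L, n_shared = 3L, shared_length = 9L,
                         expressed_fraction = 0.6, k_counts = 3000,
                         n_evidence_peptides = 3L) {
  if (n_proteins < 4L) pp_stop_input("need at least 4 proteins")
  if (n_proteins < 2L * n_shared + 2L)
    pp_stop_input("n_proteins must be at least 2 * n_shared + 2 to host the planted peptides")
  if (shared_length + 2L > length_range[1])
    pp_stop_input("planted peptide longer than the smallest host protein")
  structure(list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 n_cell_types = as.integer(n_cell_types),
                 n_shared = as.integer(n_shared),
                 shared_length = as.integer(shared_length),
                 expressed_fraction = expressed_fraction,
                 k_counts = k_counts,
                 n_evidence_peptides = as.integer(n_evidence_peptides)),
            class = "fixture_spec")
}

# Random amino-acid string; uniform residue frequencies are adequate for
# uniqueness testing.
random_aa <- function(n, alphabet = .AA_LETTERS) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# A tryptic planted peptide: no internal K/R (so it survives digestion as a
# zero-missed-cleavage peptide), ends in R, no proline anywhere.
random_tryptic_peptide <- function(len) {
  inner <- random_aa(len - 1L, setdiff(.AA_LETTERS, c("K", "R", "P")))
  paste0(inner, "R")
}

#' Generate a toy proteome with planted shared peptides
#'
#' Each planted peptide is embedded in two host proteins immediately after a
#' forced K (and never followed by P), so it appears in both digests as a
#' clean tryptic peptide. Ground truth records every planted peptide and its
#' true parent set.
#'
#' @param spec A [fixture_spec()].
#' @return A list: `proteome` (table as from [read_fasta()]), `truth`
#'   (`data.table`: `peptide`, `parents`, `kind`).
#' @export
generate_proteome <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    lens <- sample(seq(spec$length_range[1], spec$length_range[2]),
                   spec$n_proteins, replace = TRUE)
    seqs <- vapply(lens, random_aa, character(1))
    acc <- sprintf("SYN%04d", seq_len(spec$n_proteins))

    truth <- list()
    if (spec$n_shared > 0L) {
      host_pool <- sample(spec$n_proteins)
      for (s in seq_len(spec$n_shared)) {
        pep <- random_tryptic_peptide(spec$shared_length)
        hosts <- host_pool[c(2L * s - 1L, 2L * s)]
        for (h in hosts) seqs[h] <- embed_peptide(seqs[h], pep)
        truth[[length(truth) + 1L]] <- data.table::data.table(
          peptide = pep, parents = paste(sort(acc[hosts]), collapse = ";"),
          kind = "shared")
      }
      # one planted unique peptide as a positive control
      pep_u <- random_tryptic_peptide(spec$shared_length)
      h <- host_pool[2L * spec$n_shared + 1L]
      seqs[h] <- embed_peptide(seqs[h], pep_u)
      truth[[length(truth) + 1L]] <- data.table::data.table(
        peptide = pep_u, parents = acc[h], kind = "unique")
      # one planted long unique peptide (45 residues, contains N): exercises
      # the glycopeptide length gate, which random digests rarely reach
      inner <- random_aa(43L, setdiff(.AA_LETTERS, c("K", "R", "P")))
      pep_l <- paste0(substring(inner, 1L, 20L), "N", substring(inner, 21L), "R")
      h <- host_pool[2L * spec$n_shared + 2L]
      seqs[h] <- embed_peptide(seqs[h], pep_l)
      truth[[length(truth) + 1L]] <- data.table::data.table(
        peptide = pep_l, parents = acc[h], kind = "long_unique")
    }
    proteome <- data.table::data.table(
      accession = acc,
      description = sprintf("Synthetic protein %d OS=Toy GN=Syn%d", seq_len(spec$n_proteins),
                            seq_len(spec$n_proteins)),
      gene_symbol = sprintf("Syn%d", seq_len(spec$n_proteins)),
      sequence = seqs,
      length = nchar(seqs),
      mass = protein_mass(seqs, scale = "average"))
    list(proteome = proteome,
         truth = data.table::rbindlist(truth))
  })
}

# Embed a peptide in a host sequence at a random internal position,
# preceded by K and followed by a residue that is not P (the planted peptide
# itself ends in R). Host length is preserved.
embed_peptide <- function(host, pep) {
  need <- nchar(pep) + 2L # preceding K + peptide + safe following residue
  if (need > nchar(host)) pp_stop_input("planted peptide longer than host")
  at <- sample(seq_len(nchar(host) - need + 1L), 1L)
  paste0(substring(host, 1L, at - 1L), "K", pep, "A",
         substring(host, at + need, nchar(host)))
}

#' Generate evidence tables with planted ground truth
#'
#' Spectral counts are `round(k_counts * p_i * length_i)` for planted
#' per-cell-type proportions `p_i`, so [compute_nsaf()] recovers the planted
#' proportions to within rounding error. PTM records are planted with known
#' filter outcomes (ground-truth label = `"kept"` or the expected rejection
#' reason code).
#'
#' @param spec A [fixture_spec()].
#' @param prot The [generate_proteome()] result for the same spec.
#' @return A list: `counts`, `evidence`, `ptms`, `truth_nsaf` (`cell_type`,
#'   `accession`, `planted_nsaf`), `truth_ptm` (`ptm_id`, `expected`).
#' @export
generate_evidence <- function(spec, prot) {
  stopifnot(inherits(spec, "fixture_spec"))
  proteome <- prot$proteome
  idx <- build_index(proteome)
  with_seed(spec$seed + 1L, {
    cts <- sprintf("cell%d", seq_len(spec$n_cell_types))
    n_expr <- max(2L, round(spec$expressed_fraction * spec$n_proteins))

    counts <- list(); truth_nsaf <- list(); evidence <- list()
    for (ct in cts) {
      expr <- sort(sample(proteome$accession, n_expr))
      w <- stats::rexp(n_expr) # heavy-ish tail: few proteins dominate
      p <- w / sum(w)
      len <- proteome$length[match(expr, proteome$accession)]
      cnt <- round(spec$k_counts * p * len)
      if (any(cnt == 0L & p > 0))
        pp_stop_input("k_counts too small to represent the smallest planted proportion; increase k_counts")
      counts[[ct]] <- data.table::data.table(cell_type = ct, accession = expr,
                                             spectral_count = as.integer(cnt))
      truth_nsaf[[ct]] <- data.table::data.table(cell_type = ct, accession = expr,
                                                 planted_nsaf = p)
      # observed peptide evidence: proteotypic digest peptides per protein
      prot_peps <- idx$peptides[proteotypic == TRUE]
      for (a in expr) {
        mine <- prot_peps[parents == a, peptide]
        take <- utils::head(sample(mine), spec$n_evidence_peptides)
        if (length(take))
          evidence[[paste(ct, a)]] <- data.table::data.table(
            cell_type = ct, peptide = take, accession = a)
      }
    }
    counts <- data.table::rbindlist(counts)
    truth_nsaf <- data.table::rbindlist(truth_nsaf)
    evidence <- data.table::rbindlist(evidence)

    ptm <- plant_ptms(spec, proteome, idx, prot$truth, cts, evidence)
    list(counts = counts, evidence = evidence, ptms = ptm$records,
         truth_nsaf = truth_nsaf, truth_ptm = ptm$truth)
  })
}

# Plant one PTM record per interesting outcome. Callers run under with_seed.
plant_ptms <- function(spec, proteome, idx, planted, cts, evidence) {
  proteo <- idx$peptides[proteotypic == TRUE & nchar(peptide) >= 8 & nchar(peptide) <= 30]
  pick <- function(residue) {
    cand <- proteo[stringi::stri_detect_fixed(peptide, residue)]
    if (nrow(cand) == 0L) pp_stop_input(sprintf("fixture proteome lacks a proteotypic peptide with %s", residue))
    cand[sample(nrow(cand), 1L)]
  }
  rec <- function(id, peptide, accession, mod_type, residue, q, gq = NA_real_,
                  gcomp = NA_character_, pmass = NA_real_, n_mods = 1L,
                  expected = "kept") {
    pos <- stringi::stri_locate_first_fixed(peptide, residue)[1]
    data.table::data.table(
      ptm_id = id, cell_type = cts[1], peptide = peptide, accession = accession,
      mod_type = mod_type, site_residue = residue, site_position = as.integer(pos),
      q_value = q, glycan_composition = gcomp, glycan_q_value = gq,
      peptide_mass = pmass, n_mods = n_mods, expected = expected)
  }
  rows <- list()
  m <- pick("M")
  rows$keep_ox <- rec("keep_ox", m$peptide, m$parents, "oxidation", "M", 0.005)
  s <- pick("S")
  rows$keep_ph <- rec("keep_ph", s$peptide, s$parents, "phosphorylation", "S", 0.001)
  s2 <- pick("T")
  rows$fail_q <- rec("fail_q", s2$peptide, s2$parents, "phosphorylation", "T", 0.05,
                     expected = "q_value")
  # shared planted peptide -> not proteotypic; monomethylation of its
  # C-terminal R keeps the record structurally valid for any peptide
  if (nrow(planted[kind == "shared"])) {
    sh <- planted[kind == "shared"][1]
    first_parent <- strsplit(sh$parents, ";", fixed = TRUE)[[1]][1]
    rows$fail_proteo <- data.table::data.table(
      ptm_id = "fail_proteo", cell_type = cts[1], peptide = sh$peptide,
      accession = first_parent, mod_type = "monomethylation",
      site_residue = "R", site_position = nchar(sh$peptide),
      q_value = 0.001, glycan_composition = NA_character_,
      glycan_q_value = NA_real_, peptide_mass = NA_real_, n_mods = 1L,
      expected = "not_proteotypic")
  }
  # peptide claimed under the wrong accession
  other_acc <- setdiff(proteome$accession, m$parents)[1]
  rows$fail_parent <- rec("fail_parent", m$peptide, other_acc, "oxidation", "M",
                          0.001, expected = "parent_mismatch")
  # glyco records: one kept, one per failing gate; restrict the pick so the
  # peptide mass sits inside the accepted 600-4000 Da window
  gcand <- proteo[stringi::stri_detect_fixed(peptide, "N") & nchar(peptide) <= 25]
  gcand <- gcand[peptide_mass(peptide) >= 650 & peptide_mass(peptide) <= 3900]
  if (nrow(gcand) == 0L) pp_stop_input("fixture proteome lacks a glyco-eligible peptide")
  g <- gcand[sample(nrow(gcand), 1L)]
  gm <- peptide_mass(g$peptide)
  rows$keep_gly <- rec("keep_gly", g$peptide, g$parents, "n_glycosylation", "N",
                       0.002, gq = 0.003, gcomp = "HexNAc(2)Hex(5)", pmass = gm)
  rows$fail_gq <- rec("fail_gq", g$peptide, g$parents, "n_glycosylation", "N",
                      0.002, gq = 0.2, gcomp = "HexNAc(2)Hex(5)", pmass = gm,
                      expected = "glyco_q_value")
  rows$fail_gmass <- rec("fail_gmass", g$peptide, g$parents, "n_glycosylation", "N",
                         0.002, gq = 0.003, gcomp = "HexNAc(2)Hex(5)", pmass = 5500,
                         expected = "glyco_mass")
  rows$fail_gmods <- rec("fail_gmods", g$peptide, g$parents, "n_glycosylation", "N",
                         0.002, gq = 0.003, gcomp = "HexNAc(2)Hex(5)", pmass = gm,
                         n_mods = 3L, expected = "glyco_mod_count")
  # the planted 45-residue unique peptide trips the glyco length gate
  if (nrow(planted[kind == "long_unique"])) {
    gl <- planted[kind == "long_unique"][1]
    rows$fail_glen <- rec("fail_glen", gl$peptide, gl$parents, "n_glycosylation",
                          "N", 0.002, gq = 0.003, gcomp = "HexNAc(2)Hex(5)",
                          pmass = min(peptide_mass(gl$peptide), 3999),
                          expected = "glyco_length")
  }
  # structurally invalid: phospho site on a non-STY residue
  a_pep <- pick("A")
  pos_a <- stringi::stri_locate_first_fixed(a_pep$peptide, "A")[1]
  rows$fail_invalid <- data.table::data.table(
    ptm_id = "fail_invalid", cell_type = cts[1], peptide = a_pep$peptide,
    accession = a_pep$parents, mod_type = "phosphorylation",
    site_residue = "A", site_position = as.integer(pos_a), q_value = 0.001,
    glycan_composition = NA_character_, glycan_q_value = NA_real_,
    peptide_mass = NA_real_, n_mods = 1L, expected = "invalid_record")

  recs <- data.table::rbindlist(rows, use.names = TRUE)
  list(records = recs[, !"expected"],
       truth = recs[, .(ptm_id, expected)])
}

#' Write a generated fixture to disk
#'
#' Emits the exact dialects the other modules consume: `proteome.fasta`,
#' `counts.tsv`, `evidence.tsv`, `ptms.tsv`, plus ground-truth tables
#' (`truth_*.tsv`) and `fixture.json` recording the spec. TSVs carry the
#' seed in a `#` comment header; FASTA has no comment syntax, so its seed
#' provenance lives in `fixture.json`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory.
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixture <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prot <- generate_proteome(spec)
  ev <- generate_evidence(spec, prot)
  seed_c <- sprintf("seed=%d", spec$seed)
  paths <- c(
    proteome = write_fasta(prot$proteome, file.path(dir, "proteome.fasta")),
    counts = write_tsv(ev$counts, file.path(dir, "counts.tsv"), seed_c),
    evidence = write_tsv(ev$evidence, file.path(dir, "evidence.tsv"), seed_c),
    ptms = write_tsv(ev$ptms, file.path(dir, "ptms.tsv"), seed_c),
    truth_uniqueness = write_tsv(prot$truth, file.path(dir, "truth_uniqueness.tsv"), seed_c),
    truth_nsaf = write_tsv(ev$truth_nsaf, file.path(dir, "truth_nsaf.tsv"), seed_c),
    truth_ptm = write_tsv(ev$truth_ptm, file.path(dir, "truth_ptm.tsv"), seed_c))
  jsonlite::write_json(unclass(spec), file.path(dir, "fixture.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, fixture = file.path(dir, "fixture.json")))
}
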