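# A controlled proteome for PTM tests: P1 unique context, P1/P2 share
# "TESTR" (shared peptide), digest peptides of length >= 1 indexed.
ptm_world <- function() {
  prot <- data.table::data.table(
    accession = c("P1", "P2"),
    description = c("first", "second"),
    gene_symbol = c("", ""),
    sequence = c("MAAAKSSTNYMWRTESTRAAAK", "GGGKTESTRDDDK"))
  prot[, length := nchar(sequence)]
  idx <- build_index(prot, params = digest_params(2, 1, 150))
  list(prot = prot, idx = idx)
}

rec_row <- function(peptide, accession, mod_type, site_residue, site_position,
                    q_value, glycan_composition = NA_character_,
                    glycan_q_value = NA_real_, peptide_mass = NA_real_,
                    n_mods = 1L, cell_type = "ctA") {
  data.table::data.table(cell_type = cell_type, peptide = peptide,
                         accession = accession, mod_type = mod_type,
                         site_residue = site_residue,
                         site_position = site_position, q_value = q_value,
                         glycan_composition = glycan_composition,
                         glycan_q_value = glycan_q_value,
                         peptide_mass = peptide_mass, n_mods = n_mods)
}

test_that("integration gates keep and reject with the right reason codes", {
  w <- ptm_world()
  # "SSTNYMWR" is proteotypic for P1 (positions 6-13)
  recs <- rbind(
    rec_row("SSTNYMWR", "P1", "oxidation", "M", 6L, 0.005),        # kept
    rec_row("TESTR", "P1", "phosphorylation", "T", 1L, 0.001),     # shared
    rec_row("SSTNYMWR", "P2", "oxidation", "M", 6L, 0.005),        # wrong parent
    rec_row("SSTNYMWR", "P1", "phosphorylation", "S", 1L, 0.02),   # q fail
    rec_row("SSTNYMWR", "P1", "phosphorylation", "A", 1L, 0.001))  # bad residue
  fl <- filter_ptms(recs, w$idx)
  expect_equal(nrow(fl$kept), 1L)
  expect_equal(fl$kept$mod_type, "oxidation")
  expect_equal(fl$rejected$reason,
               c("not_proteotypic", "parent_mismatch", "q_value", "invalid_record"))
  # partition: kept + rejected == input, disjointly
  expect_equal(nrow(fl$kept) + nrow(fl$rejected), nrow(recs))
})

test_that("glycopeptide gates apply in order after the shared gates", {
  w <- ptm_world()
  pep <- "SSTNYMWR"
  gm <- peptide_mass(pep)
  base <- function(...) rec_row(pep, "P1", "n_glycosylation", "N", 9L, 0.001,
                                glycan_composition = "HexNAc(2)Hex(5)", ...)
  # position of N in SSTNYMWR is 4
  mk <- function(gq, pm, nm) {
    r <- base(glycan_q_value = gq, peptide_mass = pm, n_mods = nm)
    r$site_position <- 4L
    r
  }
  recs <- rbind(mk(0.003, gm, 1L),      # kept
                mk(0.5, gm, 1L),        # glyco_q_value
                mk(0.003, 5000, 1L),    # glyco_mass
                mk(0.003, gm, 3L))      # glyco_mod_count
  fl <- filter_ptms(recs, w$idx)
  expect_equal(nrow(fl$kept), 1L)
  expect_equal(fl$rejected$reason,
               c("glyco_q_value", "glyco_mass", "glyco_mod_count"))

  # length gate: a 45-mer proteotypic peptide
  long_prot <- data.table::data.table(
    accession = "PL",
    sequence = paste0(strrep("A", 20), "N", strrep("A", 23), "R"))
  idx_l <- build_index(long_prot, params = digest_params(0, 1, 150))
  r_long <- rec_row(long_prot$sequence, "PL", "n_glycosylation", "N", 21L, 0.001,
                    glycan_composition = "HexNAc(2)", glycan_q_value = 0.001,
                    peptide_mass = 3500)
  fl2 <- filter_ptms(r_long, idx_l)
  expect_equal(fl2$rejected$reason, "glyco_length")
})

test_that("filtering is idempotent and monotone in thresholds", {
  w <- ptm_world()
  set.seed(15)
  peps <- w$idx$peptides[proteotypic == TRUE & nchar(peptide) >= 4]
  recs <- data.table::rbindlist(lapply(seq_len(nrow(peps)), function(i) {
    p <- peps$peptide[i]
    pos <- regexpr("[STY]", p)
    if (pos < 1) return(NULL)
    rec_row(p, peps$parents[i], "phosphorylation",
            substring(p, pos, pos), as.integer(pos), runif(1, 0, 0.05))
  }))
  fl <- filter_ptms(recs, w$idx)
  fl2 <- filter_ptms(fl$kept, w$idx)
  expect_equal(fl2$kept, fl$kept)
  expect_equal(nrow(fl2$rejected), 0L)
  # tightening q_max can only shrink the kept set
  for (q in c(0.02, 0.01, 0.005, 0.001)) {
    kept_q <- filter_ptms(recs, w$idx, ptm_filter_params(q_max = q))$kept
    expect_true(all(kept_q$q_value < q))
    expect_true(nrow(kept_q) <= nrow(filter_ptms(
      recs, w$idx, ptm_filter_params(q_max = q * 2))$kept))
  }
})

test_that("site projection does the coordinate arithmetic and checks residues", {
  w <- ptm_world()
  p1 <- w$prot[1]
  # SSTNYMWR occupies protein residues 6-13; site at peptide position 6 -> 11
  kept <- rec_row("SSTNYMWR", "P1", "oxidation", "M", 6L, 0.005)
  sites <- project_sites(p1, kept)
  expect_equal(sites$position, 11L)
  expect_equal(sites$residue, "M")
  expect_false(sites$ambiguous)
  # site at peptide position 1 of a peptide starting at 1 -> position 1
  kept2 <- rec_row("MAAAK", "P1", "oxidation", "M", 1L, 0.005)
  expect_equal(project_sites(p1, kept2)$position, 1L)
  # round trip: the peptide window at the projected site reproduces the peptide
  st <- regexpr("SSTNYMWR", p1$sequence, fixed = TRUE)
  expect_equal(substring(p1$sequence, st, st + 7), "SSTNYMWR")
  # residue mismatch errors with the offending position
  bad <- rec_row("SSTNYMWR", "P1", "oxidation", "W", 6L, 0.005)
  expect_error(project_sites(p1, bad), "mismatch")
  # peptide not present errors
  expect_error(project_sites(p1, rec_row("QQQQQQ", "P1", "oxidation", "M", 1L, 0.005)),
               "not found", class = "proteopick_input_error")
})

test_that("repeated peptides annotate every occurrence and flag ambiguity", {
  prot <- data.table::data.table(accession = "PR",
                                 sequence = "AAMTKGGGAAMTK")
  kept <- rec_row("AAMTK", "PR", "oxidation", "M", 3L, 0.001)
  sites <- project_sites(prot, kept)
  expect_equal(sites$position, c(3L, 11L))
  expect_true(all(sites$ambiguous))
})

test_that("duplicate (position, mod_type) pairs collapse with cell types merged", {
  w <- ptm_world()
  kept <- rbind(rec_row("SSTNYMWR", "P1", "oxidation", "M", 6L, 0.005, cell_type = "ctB"),
                rec_row("SSTNYMWR", "P1", "oxidation", "M", 6L, 0.001, cell_type = "ctA"))
  sites <- project_sites(w$prot[1], kept)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$cell_types, "ctA;ctB")
})

test_that("PTM TSV dialect accepts compact site notation", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c(
    "cell_type\tpeptide\taccession\tmod_type\tsite\tq_value",
    "ctA\tSSTNYMWR\tP1\tphosphorylation\tS1\t0.004",
    "ctA\tMAAAK\tP1\tacetylation\tN-term\t0.004"), collapse = "\n"), f)
  r <- read_ptms(f)
  expect_equal(r$site_residue, c("S", "protein-N-term"))
  expect_equal(r$site_position, c(1L, 1L))
})
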