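# PTM record validation, FDR filtering and projection onto protein
# coordinates.
#
# Integration rules: a modified-peptide observation enters the library only
# if (a) its peptide is proteotypic and maps to the claimed protein,
# (b) it passes the identification q-value gate (< 0.01 by default), and
# (c) N-glycopeptides additionally pass the glycan q-value gate and the
# glyco search-space gates (peptide mass 600-4000 Da, length 6-40 residues,
# at most 2 modifications per precursor). Every rejection carries a
# machine-readable reason code (first failing gate, in the order checked):
#   invalid_record, unknown_accession, not_proteotypic, parent_mismatch,
#   q_value, glyco_q_value, glyco_mass, glyco_length, glyco_mod_count.

.PTM_TYPES <- c("oxidation", "phosphorylation", "monomethylation",
                "deamidation", "acetylation", "n_glycosylation")

#' PTM filter parameters
#'
#' @param q_max Identification q-value gate (records kept when
#'   `q_value < q_max`); default 0.01.
#' @param glyco_q_max Glycan-level q-value gate for N-glycopeptides.
#' @param glyco_mass_range Accepted glycopeptide mass window in Daltons.
#' @param glyco_length_range Accepted glycopeptide length window in residues.
#' @param glyco_max_mods Maximum modifications per glycopeptide precursor.
#' @param residue_vocab Named list mapping modification type to its allowed
#'   site residues. The default takes the union of commonly searched
#'   acetylation sites (K, R and the protein N-terminus).
#' @return A list of class `ptm_filter_params`.
#' @export
ptm_filter_params <- function(q_max = 0.01, glyco_q_max = 0.01,
                              glyco_mass_range = c(600, 4000),
                              glyco_length_range = c(6L, 40L),
                              glyco_max_mods = 2L,
                              residue_vocab = default_residue_vocab()) {
  if (q_max <= 0 || glyco_q_max <= 0)
    pp_stop_input("q-value thresholds must be positive")
  if (length(glyco_mass_range) != 2L || diff(glyco_mass_range) < 0 ||
      any(glyco_mass_range <= 0))
    pp_stop_input("glyco_mass_range must be positive and ordered")
  if (length(glyco_length_range) != 2L || diff(glyco_length_range) < 0 ||
      any(glyco_length_range < 1))
    pp_stop_input("glyco_length_range must be positive and ordered")
  structure(list(q_max = q_max, glyco_q_max = glyco_q_max,
                 glyco_mass_range = as.numeric(glyco_mass_range),
                 glyco_length_range = as.integer(glyco_length_range),
                 glyco_max_mods = as.integer(glyco_max_mods),
                 residue_vocab = residue_vocab),
            class = "ptm_filter_params")
}

#' Default modification-site vocabulary
#'
#' @return Named list: modification type -> allowed residues
#'   (`"protein-N-term"` marks a protein N-terminal site).
#' @export
default_residue_vocab <- function() {
  list(oxidation = "M",
       phosphorylation = c("S", "T", "Y"),
       monomethylation = c("K", "R"),
       deamidation = c("N", "Q"),
       acetylation = c("K", "R", "protein-N-term"),
       n_glycosylation = "N")
}

# Structural validity of one batch of records; returns a character vector of
# reason codes ("" when valid).
ptm_invalid_reason <- function(r, vocab) {
  n <- nrow(r)
  reason <- character(n)
  plen <- nchar(r$peptide)
  bad_type <- !(r$mod_type %in% names(vocab))
  is_nterm <- r$site_residue == "protein-N-term"
  bad_pos <- is.na(r$site_position) | r$site_position < 1L | r$site_position > plen
  res_at <- substring(r$peptide, r$site_position, r$site_position)
  bad_res <- !is_nterm & (res_at != r$site_residue)
  bad_vocab <- mapply(function(mt, sr) !(sr %in% vocab[[mt]]),
                      r$mod_type, r$site_residue)
  bad_vocab[bad_type] <- TRUE
  is_glyco <- r$mod_type == "n_glycosylation"
  has_glycan <- !is.na(r$glycan_composition) & nzchar(r$glycan_composition) &
    !is.na(r$glycan_q_value)
  bad_glycan_fields <- (is_glyco & !has_glycan) | (!is_glyco & has_glycan)
  bad_q <- is.na(r$q_value) | r$q_value < 0 | r$q_value > 1
  reason[bad_type | bad_pos | bad_res | bad_vocab | bad_glycan_fields | bad_q] <- "invalid_record"
  reason
}

#' Filter PTM observations against the integration rules
#'
#' Partitions the input into kept records and rejected records with a reason
#' code. The split is exhaustive and disjoint; filtering is idempotent and
#' monotone in every threshold.
#'
#' @param records PTM record table with columns `cell_type`, `peptide`,
#'   `accession`, `mod_type`, `site_residue`, `site_position`, `q_value`,
#'   and (for N-glycopeptides) `glycan_composition`, `glycan_q_value`,
#'   `peptide_mass`; an optional `n_mods` column gives the number of
#'   modifications on the precursor (default 1).
#' @param index A [build_index()] result covering the relevant proteome.
#' @param params A [ptm_filter_params()] object.
#' @return A list with elements `kept` and `rejected` (the latter with an
#'   extra `reason` column).
#' @export
filter_ptms <- function(records, index, params = ptm_filter_params()) {
  stopifnot(inherits(index, "proteotypicity_index"),
            inherits(params, "ptm_filter_params"))
  r <- data.table::as.data.table(records)
  require_columns(r, c("cell_type", "peptide", "accession", "mod_type",
                       "site_residue", "site_position", "q_value"),
                  "PTM record table")
  for (col in c("glycan_composition", "glycan_q_value", "peptide_mass"))
    if (!col %in% names(r)) r[, (col) := NA]
  if (!"n_mods" %in% names(r)) r[, n_mods := 1L]
  r[is.na(n_mods), n_mods := 1L]
  if (nrow(r) == 0L)
    return(list(kept = r, rejected = data.table::copy(r)[, reason := character(0)]))

  reason <- ptm_invalid_reason(r, params$residue_vocab)

  cls <- classify_peptide(index, r$peptide)
  open <- reason == ""
  reason[open & cls$status != "proteotypic"] <- "not_proteotypic"
  open <- reason == ""
  reason[open & cls$parents != r$accession] <- "parent_mismatch"
  open <- reason == ""
  reason[open & r$q_value >= params$q_max] <- "q_value"

  glyco <- r$mod_type == "n_glycosylation"
  open <- reason == "" & glyco
  reason[open & r$glycan_q_value >= params$glyco_q_max] <- "glyco_q_value"
  open <- reason == "" & glyco
  bad_mass <- is.na(r$peptide_mass) | r$peptide_mass < params$glyco_mass_range[1] |
    r$peptide_mass > params$glyco_mass_range[2]
  reason[open & bad_mass] <- "glyco_mass"
  open <- reason == "" & glyco
  plen <- nchar(r$peptide)
  reason[open & (plen < params$glyco_length_range[1] |
                 plen > params$glyco_length_range[2])] <- "glyco_length"
  open <- reason == "" & glyco
  reason[open & r$n_mods > params$glyco_max_mods] <- "glyco_mod_count"

  kept <- r[reason == ""]
  rejected <- r[reason != ""]
  rej_reason <- reason[reason != ""]
  rejected[, reason := rej_reason]
  list(kept = kept, rejected = rejected)
}

#' Project kept PTM records onto protein coordinates
#'
#' Protein position = peptide start (1-based) + site position in peptide - 1.
#' The residue at the projected position is verified against the record. If
#' the peptide occurs more than once in the protein every occurrence is
#' annotated and flagged ambiguous. Duplicate (position, mod_type) pairs are
#' collapsed, aggregating the cell types observing them.
#'
#' @param protein One-row proteome table (or a list with `accession` and
#'   `sequence`).
#' @param kept Kept PTM records for this protein (from [filter_ptms()]).
#' @return A `data.table`: `accession`, `position`, `residue`, `mod_type`,
#'   `cell_types` (semicolon-joined, sorted), `ambiguous`.
#' @export
project_sites <- function(protein, kept) {
  acc <- protein$accession[1]
  pseq <- protein$sequence[1]
  k <- data.table::as.data.table(kept)
  if (nrow(k) == 0L)
    return(data.table::data.table(accession = character(), position = integer(),
                                  residue = character(), mod_type = character(),
                                  cell_types = character(), ambiguous = logical()))
  rows <- vector("list", nrow(k))
  for (i in seq_len(nrow(k))) {
    occ <- stringi::stri_locate_all_fixed(pseq, k$peptide[i])[[1]]
    if (any(is.na(occ[, 1])))
      pp_stop_input(sprintf("peptide %s not found in protein %s", k$peptide[i], acc))
    ambiguous <- nrow(occ) > 1L
    nterm <- k$site_residue[i] == "protein-N-term"
    pos <- occ[, 1] + k$site_position[i] - 1L
    if (nterm) {
      if (!any(occ[, 1] == 1L))
        pp_stop_input(sprintf(
          "protein-N-term record for %s but peptide %s does not start the protein",
          acc, k$peptide[i]))
      pos <- 1L
      ambiguous <- FALSE
    }
    res <- substring(pseq, pos, pos)
    if (!nterm && any(res != k$site_residue[i]))
      pp_stop_input(sprintf(
        "residue mismatch for %s %s at protein position %s: expected %s, found %s",
        acc, k$mod_type[i], paste(pos[res != k$site_residue[i]], collapse = ","),
        k$site_residue[i], paste(unique(res[res != k$site_residue[i]]), collapse = ",")))
    rows[[i]] <- data.table::data.table(
      accession = acc, position = as.integer(pos), residue = res,
      mod_type = k$mod_type[i], cell_type = k$cell_type[i], ambiguous = ambiguous)
  }
  out <- data.table::rbindlist(rows)
  out <- out[, .(cell_types = paste(sort(unique(cell_type)), collapse = ";"),
                 ambiguous = any(ambiguous)),
             by = .(accession, position, residue, mod_type)]
  data.table::setorder(out, position, mod_type)
  out[]
}

#' Read a PTM record table from TSV
#'
#' Accepts the site either as separate `site_residue` + `site_position`
#' columns or as a compact `site` column (`"S45"` in peptide coordinates, or
#' `"N-term"` for the protein N-terminus).
#'
#' @param path TSV path.
#' @return A `data.table` of PTM records.
#' @export
read_ptms <- function(path) {
  r <- read_tsv(path)
  if ("site" %in% names(r) && !"site_residue" %in% names(r)) {
    nterm <- r$site %in% c("N-term", "protein-N-term")
    r[, site_residue := data.table::fifelse(nterm, "protein-N-term",
                                            substring(site, 1L, 1L))]
    r[, site_position := data.table::fifelse(
        nterm, 1L,
        suppressWarnings(as.integer(substring(site, 2L))))]
    r[, site := NULL]
  }
  r
}
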