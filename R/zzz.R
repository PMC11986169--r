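#' @importFrom data.table := .N .SD data.table
#' @import stats
#' @import utils
#' @keywords internal
"_PACKAGE"

.datatable.aware <- TRUE

# Column names used in data.table non-standard evaluation.
utils::globalVariables(c(
  ".", "..sequence", "accession", "ambiguous", "cell_type", "end", "exclusive_count",
  "expected", "gene_symbol", "key", "len", "length", "mod_type", "mono_mass",
  "missed_cleavages", "n_mods", "n_parents", "n_proteotypic_peptides", "n_types",
  "nsaf", "parent", "parent_accession", "parents", "peptide", "planted_nsaf",
  "position", "proteotypic", "ptm_id", "rank", "reason", "residue", "saf",
  "sequence", "site", "site_position", "site_residue", "spectral_count", "start",
  "status", "terms", "tot", "total"
))
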