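# Additive peptide suitability score for targeted-MS assay design.
#
# Ten criteria distilled from established assay-design guidance
# (PeptidePicker, Picky, Skyline recommendations). Each satisfied criterion
# adds 1 point except proteome uniqueness, which adds 2; the total ranges
# 0-11:
#
#   c1  present in the cell type's spectral library            +1
#   c2  proteotypic (unique) within the reference proteome     +2
#   c3  length 6-25 residues                                   +1
#   c4  no missed tryptic cleavages                            +1
#   c5  contains neither Met nor Cys (oxidation/alkylation)    +1
#   c6  N-terminal residue is neither Trp nor Glu (pyroGlu)    +1
#   c7  no Pro-Pro                                             +1
#   c8  no Asp-Pro (acid-labile bond)                          +1
#   c9  no Asp-Gly (isomerization-prone)                       +1
#   c10 no run of more than three consecutive Ser              +1

#' Score peptides for targeted-assay suitability
#'
#' Evaluates the ten-criterion additive score. Library presence (`c1`) and
#' proteome uniqueness (`c2`) are supplied by the caller so hypothetical,
#' not-yet-measured peptides can be ranked; the library assembly wires them
#' from the evidence tables and the [build_index()] result.
#'
#' @param sequence Character vector of peptide sequences.
#' @param missed_cleavages Integer vector of missed-cleavage counts.
#' @param in_library Logical vector: observed in the spectral library.
#' @param proteotypic Logical vector: unique in the reference proteome.
#' @return A `data.table` with the inputs, logical columns `c1`..`c10` and
#'   integer `total` (0-11).
#' @examples
#' score_peptides("LGQSTR", 0, in_library = TRUE, proteotypic = TRUE)$total # 11
#' @export
score_peptides <- function(sequence, missed_cleavages, in_library, proteotypic) {
  n <- length(sequence)
  if (n == 0L) pp_stop_input("score_peptides: no peptides")
  if (any(is.na(sequence) | !nzchar(sequence)))
    pp_stop_input("score_peptides: empty peptide sequence")
  missed_cleavages <- rep_len(as.integer(missed_cleavages), n)
  in_library <- rep_len(as.logical(in_library), n)
  proteotypic <- rep_len(as.logical(proteotypic), n)
  len <- nchar(sequence)

  dt <- data.table::data.table(
    sequence = sequence,
    length = len,
    missed_cleavages = missed_cleavages,
    c1 = in_library,
    c2 = proteotypic,
    c3 = len >= 6L & len <= 25L,
    c4 = missed_cleavages == 0L,
    c5 = !stringi::stri_detect_regex(sequence, "[MC]"),
    c6 = !substring(sequence, 1L, 1L) %in% c("W", "E"),
    c7 = !stringi::stri_detect_fixed(sequence, "PP"),
    c8 = !stringi::stri_detect_fixed(sequence, "DP"),
    c9 = !stringi::stri_detect_fixed(sequence, "DG"),
    c10 = !stringi::stri_detect_fixed(sequence, "SSSS")
  )
  dt[, total := score_total(.SD)]
  dt[]
}

# Additive total from the criterion flags: c2 is worth 2 points, the rest 1.
score_total <- function(flags) {
  as.integer(flags$c1) + 2L * as.integer(flags$c2) +
    as.integer(flags$c3) + as.integer(flags$c4) + as.integer(flags$c5) +
    as.integer(flags$c6) + as.integer(flags$c7) + as.integer(flags$c8) +
    as.integer(flags$c9) + as.integer(flags$c10)
}

#' Rank scored peptides
#'
#' Descending by total score; ties broken by shorter sequence first, then
#' lexicographically by sequence, making the order stable and deterministic.
#' Shorter-first is preferred because shorter proteotypic peptides ionize and
#' transmit more predictably.
#'
#' @param scores A table from [score_peptides()].
#' @return The table reordered, with a 1-based `rank` column prepended.
#' @export
rank_peptides <- function(scores) {
  dt <- data.table::as.data.table(scores)
  if (nrow(dt) == 0L) return(dt)
  require_columns(dt, c("sequence", "total"), "score table")
  data.table::setorderv(dt, c("total", "length", "sequence"),
                        order = c(-1L, 1L, 1L))
  dt[, rank := seq_len(.N)]
  data.table::setcolorder(dt, "rank")
  dt[]
}

#' Write a score table as TSV
#'
#' Criterion flags are emitted as 0/1 columns.
#'
#' @param scores Table from [score_peptides()] or [rank_peptides()].
#' @param path Output TSV path.
#' @param accession Optional parent accession column to prepend.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, accession = NULL) {
  out <- data.table::copy(data.table::as.data.table(scores))
  flags <- grep("^c([1-9]|10)$", names(out), value = TRUE)
  out[, (flags) := lapply(.SD, as.integer), .SDcols = flags]
  if (!is.null(accession)) out[, accession := accession]
  data.table::setcolorder(out, intersect(c("accession", "rank", "sequence"), names(out)))
  write_tsv(out, path)
}
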