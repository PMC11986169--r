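# NSAF relative abundance from spectral counts.
#
# The normalized spectral abundance factor expresses each protein's
# proportional contribution to the total proteome of one sample:
#   SAF_i  = SpC_i / L_i        (spectral count per residue)
#   NSAF_i = SAF_i / sum_j SAF_j
# computed within each cell type independently, so NSAF sums to 1 per cell
# type. Counts are consumed as already aggregated per protein group by the
# upstream search; no razor-peptide apportionment is attempted here.

#' Compute NSAF per cell type
#'
#' @param counts Spectral count table: one row per (cell_type, accession)
#'   with columns `cell_type`, `accession`, `spectral_count` (non-negative
#'   integers; zero is allowed, e.g. a protein identified only in another
#'   cell type, and yields NSAF 0).
#' @param proteome Proteome table from [read_fasta()] supplying protein
#'   lengths.
#' @return A `data.table` with columns `cell_type`, `accession`,
#'   `spectral_count`, `saf`, `nsaf`, ordered by cell type then accession.
#' @examples
#' prot <- data.table::data.table(accession = c("X", "Y"),
#'   sequence = c(strrep("A", 100), strrep("A", 200)))
#' prot$length <- nchar(prot$sequence)
#' cnt <- data.table::data.table(cell_type = "T", accession = c("X", "Y"),
#'   spectral_count = c(10L, 10L))
#' compute_nsaf(cnt, prot)$nsaf # 2/3, 1/3
#' @export
compute_nsaf <- function(counts, proteome) {
  counts <- data.table::as.data.table(counts)
  require_columns(counts, c("cell_type", "accession", "spectral_count"), "count table")
  require_columns(proteome, c("accession"), "proteome")
  if (!"length" %in% names(proteome)) {
    require_columns(proteome, "sequence", "proteome")
    proteome <- data.table::as.data.table(proteome)[, length := nchar(sequence)]
  }
  unknown <- setdiff(counts$accession, proteome$accession)
  if (length(unknown))
    pp_stop_input(sprintf("unknown accession(s) in count table: %s",
                          paste(unknown, collapse = ", ")))
  if (anyDuplicated(counts[, .(cell_type, accession)]))
    pp_stop_input("count table has duplicate (cell_type, accession) rows")
  if (any(is.na(counts$spectral_count) | counts$spectral_count < 0))
    pp_stop_input("spectral counts must be non-negative")

  dt <- merge(counts,
              data.table::as.data.table(proteome)[, .(accession, length)],
              by = "accession", sort = FALSE)
  dt[, saf := spectral_count / length]
  zero_ct <- dt[, .(tot = sum(saf)), by = cell_type][tot <= 0, cell_type]
  if (length(zero_ct))
    pp_stop_input(sprintf("cell type(s) with no positive spectral count: %s",
                          paste(zero_ct, collapse = ", ")))
  dt[, nsaf := saf / sum(saf), by = cell_type]
  data.table::setorder(dt, cell_type, accession)
  dt[, .(cell_type, accession, spectral_count, saf, nsaf)]
}

#' Dynamic range of a cell type's NSAF distribution
#'
#' log10 ratio of the largest to the smallest positive NSAF — the "orders of
#' magnitude" spanned by protein abundance.
#'
#' @param nsaf An [compute_nsaf()] table.
#' @param cell_type Which cell type to evaluate.
#' @return A single number (log10 units).
#' @export
dynamic_range <- function(nsaf, cell_type) {
  nsaf <- data.table::as.data.table(nsaf)
  require_columns(nsaf, c("cell_type", "nsaf"), "NSAF table")
  ct <- cell_type
  x <- nsaf[cell_type == ct & nsaf > 0, nsaf]
  if (length(x) < 2L)
    pp_stop_input(sprintf("need >= 2 proteins with positive NSAF in cell type '%s'", ct))
  log10(max(x) / min(x))
}

#' Write an NSAF table as TSV
#'
#' `saf` and `nsaf` are reported to 6 significant digits.
#'
#' @param nsaf Table from [compute_nsaf()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_nsaf <- function(nsaf, path) {
  out <- data.table::copy(data.table::as.data.table(nsaf))
  out[, saf := signif(saf, 6)]
  out[, nsaf := signif(nsaf, 6)]
  write_tsv(out, path)
}
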