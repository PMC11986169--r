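# FASTA proteome input/output with UniProt-style header parsing.

#' Read a protein database in FASTA format
#'
#' Accessions are parsed from UniProt-style headers (`sp|ACC|NAME` or
#' `tr|ACC|NAME`); for plain headers the first whitespace-delimited token is
#' used. The description is everything after the first token; a gene symbol
#' is extracted from a `GN=` field when present. The protein mass column is
#' the average molecular mass, the convention for protein-level reporting.
#'
#' @param path Path to a FASTA file.
#' @param lenient If `FALSE` (default) a sequence containing non-standard
#'   residues (B/J/O/U/X/Z, ...) is an error; if `TRUE` such records are
#'   dropped with a warning.
#' @return A `data.table` with columns `accession`, `description`,
#'   `gene_symbol`, `sequence`, `length`, `mass`; one row per FASTA entry,
#'   input order preserved.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|P10300|CD8B_MOUSE T-cell surface glycoprotein Cd8 b chain GN=Cd8b1",
#'              "MRPQLSLLLLW"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, lenient = FALSE) {
  if (!file.exists(path)) pp_stop_input(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) pp_stop_input(
                    sprintf("not FASTA-formatted: %s (%s)", path, conditionMessage(e))))
  if (length(set) == 0L) pp_stop_input(sprintf("empty proteome: %s", path))
  headers <- names(set)
  seqs <- toupper(as.character(set))

  acc <- stringi::stri_match_first_regex(headers, "^(?:sp|tr)\\|([^|\\s]+)\\|")[, 2]
  first_tok <- stringi::stri_extract_first_regex(headers, "^\\S+")
  acc[is.na(acc)] <- first_tok[is.na(acc)]
  desc <- stringi::stri_replace_first_regex(headers, "^\\S+\\s*", "")
  gene <- stringi::stri_match_first_regex(desc, "\\bGN=(\\S+)")[, 2]
  gene[is.na(gene)] <- ""

  bad <- stringi::stri_detect_regex(seqs, "[^GASPVTCLINDQKEMHFRYW]") | !nzchar(seqs)
  if (any(bad)) {
    if (!lenient)
      pp_stop_input(sprintf(
        "invalid sequence(s) (non-standard residues or empty) in: %s",
        paste(acc[bad], collapse = ", ")))
    warning(sprintf("skipping %d record(s) with non-standard residues: %s",
                    sum(bad), paste(acc[bad], collapse = ", ")))
    keep <- !bad
    acc <- acc[keep]; desc <- desc[keep]; gene <- gene[keep]; seqs <- seqs[keep]
  }
  if (!length(acc)) pp_stop_input(sprintf("no valid records in: %s", path))
  dup <- unique(acc[duplicated(acc)])
  if (length(dup))
    pp_stop_input(sprintf("duplicate accession(s) in proteome: %s",
                          paste(dup, collapse = ", ")))

  data.table::data.table(
    accession = acc,
    description = desc,
    gene_symbol = gene,
    sequence = seqs,
    length = nchar(seqs),
    mass = protein_mass(seqs, scale = "average")
  )
}

#' Write a proteome back to FASTA
#'
#' Headers are `>accession description`; a read -> write -> read round trip
#' preserves accession, description and sequence.
#'
#' @param proteome A proteome table as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteome, path, width = 60L) {
  require_columns(proteome, c("accession", "sequence"), "proteome")
  desc <- if ("description" %in% names(proteome)) proteome$description else ""
  hdr <- ifelse(nzchar(desc), paste(proteome$accession, desc), proteome$accession)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(proteome))) {
    writeLines(paste0(">", hdr[i]), con)
    s <- proteome$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# Look up one protein row by accession; input error when absent.
get_protein <- function(proteome, accession) {
  i <- match(accession, proteome$accession)
  if (is.na(i))
    pp_stop_input(sprintf("unknown accession: %s", accession))
  proteome[i, ]
}
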