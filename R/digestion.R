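# In-silico tryptic digestion with missed cleavages.

#' Digestion parameters
#'
#' Defaults mirror common database-search settings for trypsin: up to 2
#' missed cleavages and peptide lengths 6-150. Trypsin cleaves C-terminal of
#' K/R; by default cleavage is suppressed when the next residue is proline
#' ("Trypsin (full)" behaviour), switchable via `cleave_before_proline`.
#'
#' @param max_missed_cleavages Maximum internal K/R sites left uncut (>= 0).
#' @param min_length,max_length Peptide length bounds after digestion.
#' @param cleave_before_proline If `TRUE`, cleave after K/R even when
#'   followed by P.
#' @return A list of class `digest_params`.
#' @export
digest_params <- function(max_missed_cleavages = 2L, min_length = 6L,
                          max_length = 150L, cleave_before_proline = FALSE) {
  max_missed_cleavages <- as.integer(max_missed_cleavages)
  min_length <- as.integer(min_length)
  max_length <- as.integer(max_length)
  if (is.na(max_missed_cleavages) || max_missed_cleavages < 0L)
    pp_stop_input("max_missed_cleavages must be >= 0")
  if (is.na(min_length) || is.na(max_length) || min_length < 1L ||
      min_length > max_length)
    pp_stop_input("length bounds must satisfy 1 <= min_length <= max_length")
  structure(list(max_missed_cleavages = max_missed_cleavages,
                 min_length = min_length, max_length = max_length,
                 cleave_before_proline = isTRUE(cleave_before_proline)),
            class = "digest_params")
}

# 0-based cleavage boundaries of a sequence: positions after which the chain
# is cut, including 0 and nchar(seq).
cleavage_boundaries <- function(sequence, cleave_before_proline = FALSE) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(res)
  is_site <- res %in% c("K", "R")
  if (!cleave_before_proline && n > 1L) {
    followed_by_p <- c(res[-1L] == "P", FALSE)
    is_site <- is_site & !followed_by_p
  }
  unique(c(0L, which(is_site), n))
}

#' Digest one protein sequence with trypsin
#'
#' Returns every peptide carrying 0..`max_missed_cleavages` internal cleavage
#' sites, filtered to the configured length range, ordered by start then end
#' coordinate. Coordinates are 1-based inclusive on the parent sequence.
#' `mono_mass` is the monoisotopic peptide mass with fixed
#' carbamidomethylation of Cys applied.
#'
#' @param sequence One amino-acid sequence.
#' @param params A [digest_params()] object.
#' @param accession Parent accession recorded on each peptide row.
#' @return A `data.table` with columns `parent_accession`, `sequence`,
#'   `start`, `end`, `missed_cleavages`, `mono_mass`.
#' @examples
#' digest_protein("AKRLPK", digest_params(max_missed_cleavages = 0, min_length = 1))
#' @export
digest_protein <- function(sequence, params = digest_params(), accession = NA_character_) {
  stopifnot(inherits(params, "digest_params"))
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    pp_stop_input("digest_protein: empty sequence")
  check_sequence_alphabet(sequence)
  full_seq <- sequence
  acc <- accession
  b <- cleavage_boundaries(sequence, params$cleave_before_proline)
  m <- length(b) - 1L # number of fully cleaved fragments
  rows <- vector("list", m)
  for (i in seq_len(m)) {
    j_max <- min(i + params$max_missed_cleavages, m)
    js <- i:j_max
    start <- b[i] + 1L
    ends <- b[js + 1L]
    rows[[i]] <- data.table::data.table(
      start = start, end = ends, missed_cleavages = js - i)
  }
  dt <- data.table::rbindlist(rows)
  dt[, len := end - start + 1L]
  dt <- dt[len >= params$min_length & len <= params$max_length]
  data.table::setorder(dt, start, end)
  dt[, sequence := substring(full_seq, start, end)]
  dt[, mono_mass := peptide_mass(sequence)]
  dt[, parent_accession := acc]
  dt[, len := NULL]
  data.table::setcolorder(dt, c("parent_accession", "sequence", "start", "end",
                                "missed_cleavages", "mono_mass"))
  dt[]
}

#' Digest every protein of a proteome
#'
#' @param proteome A proteome table from [read_fasta()].
#' @param params A [digest_params()] object.
#' @return A `data.table` of peptides (see [digest_protein()]), proteins in
#'   input order.
#' @export
digest <- function(proteome, params = digest_params()) {
  require_columns(proteome, c("accession", "sequence"), "proteome")
  if (nrow(proteome) == 0L) pp_stop_input("empty proteome")
  data.table::rbindlist(lapply(seq_len(nrow(proteome)), function(i)
    digest_protein(proteome$sequence[i], params, proteome$accession[i])))
}

#' Count internal missed cleavage sites of a peptide sequence
#'
#' The tryptic context is taken from the peptide itself: internal K/R
#' positions (excluding the C-terminal residue), with the
#' proline-suppression rule applied.
#'
#' @param sequence Character vector of peptide sequences.
#' @param cleave_before_proline Same convention as [digest_params()].
#' @return Integer vector of missed-cleavage counts.
#' @export
count_missed_cleavages <- function(sequence, cleave_before_proline = FALSE) {
  vapply(sequence, function(s) {
    b <- cleavage_boundaries(s, cleave_before_proline)
    # boundaries minus the two termini = internal uncut sites
    length(setdiff(b, c(0L, nchar(s))))
  }, integer(1), USE.NAMES = FALSE)
}

#' Write a peptide table with precursor m/z columns
#'
#' @param peptides A digest table from [digest()].
#' @param path Output TSV path.
#' @param charges Charge states for which m/z columns are added (default 2:4,
#'   the usual DDA precursor-charge window).
#' @return `path`, invisibly.
#' @export
write_peptides <- function(peptides, path, charges = 2:4) {
  out <- data.table::copy(data.table::as.data.table(peptides))
  for (z in charges)
    out[, (paste0("mz_z", z)) := round((mono_mass + z * .PROTON) / z, 5)]
  out[, mono_mass := round(mono_mass, 5)]
  write_tsv(out, path)
}
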