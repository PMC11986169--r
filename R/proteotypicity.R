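# Proteome-wide peptide -> parent-protein index and proteotypicity calls.
#
# A peptide is proteotypic when it maps to exactly one protein of the
# reference proteome and can therefore stand in for that protein in a
# targeted assay. The index is built over the tryptic peptide universe of
# the proteome; parent assignment uses either plain substring containment
# (conservative default: any protein containing the peptide anywhere) or
# strict digest membership.

#' Build a peptide uniqueness index over a proteome
#'
#' @param proteome A proteome table from [read_fasta()].
#' @param mode `"substring"` (default): a protein is a parent of a peptide if
#'   its sequence contains the peptide anywhere, regardless of tryptic
#'   context. `"digest"`: parents are proteins whose in-silico digest yields
#'   the peptide.
#' @param params [digest_params()] controlling the peptide universe (and, in
#'   digest mode, parent assignment).
#' @param equate_li If `TRUE`, leucine and isoleucine (isobaric) are treated
#'   as identical during matching.
#' @return An object of class `proteotypicity_index`: list with `peptides`
#'   (a keyed `data.table`: `peptide`, `parents` semicolon-joined and sorted,
#'   `n_parents`, `proteotypic`) and `metadata`.
#' @export
build_index <- function(proteome, mode = c("substring", "digest"),
                        params = digest_params(), equate_li = FALSE) {
  mode <- match.arg(mode)
  require_columns(proteome, c("accession", "sequence"), "proteome")
  if (nrow(proteome) == 0L) pp_stop_input("empty proteome")

  peps <- digest(proteome, params)
  collapse <- function(x) if (equate_li) stringi::stri_replace_all_fixed(x, "I", "L") else x

  if (mode == "digest") {
    map <- unique(peps[, .(key = collapse(sequence), parent = parent_accession)])
  } else {
    uni <- unique(collapse(peps$sequence))
    seqs <- collapse(proteome$sequence)
    hits <- lapply(seq_along(seqs), function(i) {
      found <- stringi::stri_detect_fixed(seqs[i], uni)
      # (list construction: plain data.table(key=) would hit its key= argument)
      data.table::as.data.table(list(key = uni[found],
                                     parent = rep(proteome$accession[i], sum(found))))
    })
    map <- data.table::rbindlist(hits)
  }
  tab <- map[, .(parents = paste(sort(unique(parent)), collapse = ";"),
                 n_parents = data.table::uniqueN(parent)), by = key]
  # display sequence: first observed spelling for each collapsed key
  disp <- unique(data.table::as.data.table(list(key = collapse(peps$sequence),
                                                peptide = peps$sequence)),
                 by = "key")
  tab <- disp[tab, on = "key"]
  tab[, proteotypic := n_parents == 1L]
  data.table::setkey(tab, key)

  structure(list(
    peptides = tab,
    metadata = list(mode = mode, params = params, equate_li = equate_li,
                    n_proteins = nrow(proteome))
  ), class = "proteotypicity_index")
}

#' @export
print.proteotypicity_index <- function(x, ...) {
  cat(sprintf(
    "proteotypicity index: %d peptides over %d proteins (%d proteotypic; mode=%s%s)\n",
    nrow(x$peptides), x$metadata$n_proteins, sum(x$peptides$proteotypic),
    x$metadata$mode, if (x$metadata$equate_li) ", L=I" else ""))
  invisible(x)
}

#' Classify peptides against a uniqueness index
#'
#' @param index A [build_index()] result.
#' @param peptide Character vector of peptide sequences.
#' @return A `data.table` with columns `peptide`, `status` (one of
#'   `"proteotypic"`, `"shared"`, `"absent"`), `parents` (semicolon-joined,
#'   sorted; empty string when absent) and `n_parents`.
#' @export
classify_peptide <- function(index, peptide) {
  stopifnot(inherits(index, "proteotypicity_index"))
  qkey <- if (index$metadata$equate_li)
    stringi::stri_replace_all_fixed(peptide, "I", "L") else peptide
  # precompute the i-table: symbols inside a join expression would resolve
  # against the index's own columns first
  qdt <- data.table::as.data.table(list(key = qkey))
  hit <- index$peptides[qdt, on = "key"]
  data.table::data.table(
    peptide = peptide,
    status = data.table::fifelse(is.na(hit$n_parents), "absent",
             data.table::fifelse(hit$n_parents == 1L, "proteotypic", "shared")),
    parents = data.table::fifelse(is.na(hit$parents), "", hit$parents),
    n_parents = data.table::fifelse(is.na(hit$n_parents), 0L, hit$n_parents)
  )
}

#' Export a uniqueness index as TSV
#'
#' Columns: peptide, semicolon-joined sorted parents. Metadata is written as
#' `#` comment lines so [read_index()] can restore it.
#'
#' @param index A [build_index()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "proteotypicity_index"))
  md <- index$metadata
  write_tsv(index$peptides[order(peptide), .(peptide, parents)], path,
            comments = c(sprintf("mode=%s", md$mode),
                         sprintf("equate_li=%s", md$equate_li),
                         sprintf("n_proteins=%d", md$n_proteins)))
}

#' Import a uniqueness index written by [write_index()]
#'
#' @param path TSV path.
#' @return A `proteotypicity_index`. Digestion parameters are not round
#'   tripped; the peptide universe is taken as stored.
#' @export
read_index <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  field <- function(k, default) {
    m <- stringi::stri_match_first_regex(hdr, paste0(k, "=(\\S+)"))[, 2]
    m <- m[!is.na(m)]
    if (length(m)) m[1] else default
  }
  tab <- read_tsv(path)
  require_columns(tab, c("peptide", "parents"), "index table")
  equate_li <- identical(field("equate_li", "FALSE"), "TRUE")
  tab <- data.table::as.data.table(tab)
  tab[, key := if (equate_li) stringi::stri_replace_all_fixed(peptide, "I", "L") else peptide]
  tab[, n_parents := lengths(strsplit(parents, ";", fixed = TRUE))]
  tab[, proteotypic := n_parents == 1L]
  tab <- tab[, .(key, peptide, parents, n_parents, proteotypic)]
  data.table::setkey(tab, key)
  structure(list(
    peptides = tab,
    metadata = list(mode = field("mode", "substring"), params = NULL,
                    equate_li = equate_li,
                    n_proteins = as.integer(field("n_proteins", NA)))
  ), class = "proteotypicity_index")
}
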