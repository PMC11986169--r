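# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Enumerate tryptic fragments of `seq` by scanning residues directly:
# returns data.frame(sequence, start, end, missed_cleavages).
oracle_digest <- function(seq, max_mc = Inf, min_len = 1L, max_len = Inf,
                          cleave_before_proline = FALSE) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  cut_after <- logical(n)
  for (i in seq_len(n)) {
    if (res[i] %in% c("K", "R")) {
      if (i == n || cleave_before_proline || res[i + 1] != "P")
        cut_after[i] <- TRUE
    }
  }
  bounds <- c(0, which(cut_after), n)
  bounds <- bounds[!duplicated(bounds)]
  out <- list()
  for (i in seq_len(length(bounds) - 1)) {
    for (j in i:(length(bounds) - 1)) {
      mc <- j - i
      if (mc > max_mc) next
      start <- bounds[i] + 1
      end <- bounds[j + 1]
      len <- end - start + 1
      if (len < min_len || len > max_len) next
      out[[length(out) + 1]] <- data.frame(
        sequence = substr(seq, start, end), start = start, end = end,
        missed_cleavages = mc, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$end), , drop = FALSE]
}

# Naive substring-search parent sets: scan every protein for containment.
oracle_parents <- function(peptide, accessions, sequences) {
  hits <- vapply(sequences, function(s) grepl(peptide, s, fixed = TRUE),
                 logical(1))
  sort(accessions[hits])
}

# From-scratch complete-linkage clustering: keeps explicit member sets and
# recomputes the max pairwise distance between every cluster pair at every
# step. Returns list of merges as member-set pairs plus heights.
oracle_complete_linkage <- function(x) {
  d <- as.matrix(dist(x))
  clusters <- lapply(seq_len(nrow(x)), identity)
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL; best_d <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (b <= a) next
      dv <- max(d[clusters[[a]], clusters[[b]]])
      if (dv < best_d) { best_d <- dv; best <- c(a, b) }
    }
    merges[[length(merges) + 1]] <- list(sort(clusters[[best[1]]]),
                                         sort(clusters[[best[2]]]))
    heights <- c(heights, best_d)
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  list(heights = heights, merges = merges)
}

# Random amino-acid sequence for property tests.
rand_seq <- function(n) {
  paste(sample(strsplit("GASPVTCLINDQKEMHFRYW", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# Tiny deterministic toy proteome used across tests.
toy_proteome <- function() {
  data.table::data.table(
    accession = c("P1", "P2", "P3"),
    description = c("first toy", "second toy", "third toy GN=Tt3"),
    gene_symbol = c("", "", "Tt3"),
    sequence = c("AAAKTESTRCCCK", "GGGKTESTRDDDK", "MMMKWWWK"),
    length = nchar(c("AAAKTESTRCCCK", "GGGKTESTRDDDK", "MMMKWWWK")),
    mass = proteopick::protein_mass(c("AAAKTESTRCCCK", "GGGKTESTRDDDK", "MMMKWWWK")))
}
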