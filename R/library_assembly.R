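# Per-cell-type library assembly, exclusive set intersections and marker
# clustering.

#' Assemble per-cell-type spectral library tables
#'
#' For every cell type: a protein table (accession, description, gene
#' symbol, number of proteotypic peptides observed, NSAF, pathway
#' annotations), a candidate-peptide table (all digest peptides of the
#' present proteins, scored and ranked; library presence = observed in this
#' cell type's evidence), and projected PTM site annotations.
#'
#' A protein is "present" in a cell type when at least `min_peptides` of its
#' observed evidence peptides are proteotypic (default 1; raise to 2 for a
#' stricter library).
#'
#' @param counts Spectral count table (see [compute_nsaf()]).
#' @param evidence Observed-peptide evidence: columns `cell_type`, `peptide`,
#'   `accession`.
#' @param proteome Proteome table from [read_fasta()].
#' @param index A [build_index()] result.
#' @param ptms Kept PTM records (from [filter_ptms()]`$kept`), or `NULL`.
#' @param annotations Optional pathway annotation table: columns `accession`,
#'   `terms` (semicolon-joined identifiers). Missing accessions get an empty
#'   annotation, not an error.
#' @param params [digest_params()] for the candidate-peptide digest.
#' @param charges Charge states reported in the peptide table.
#' @param min_peptides Presence threshold (proteotypic peptides observed).
#' @return A named list of `cell_type_library` objects, one per cell type in
#'   `counts`, each a list with `cell_type`, `proteins`, `peptides`, `ptms`.
#' @export
build_library <- function(counts, evidence, proteome, index, ptms = NULL,
                          annotations = NULL, params = digest_params(),
                          charges = 2:4, min_peptides = 1L) {
  counts <- data.table::as.data.table(counts)
  evidence <- data.table::as.data.table(evidence)
  require_columns(evidence, c("cell_type", "peptide", "accession"), "evidence table")
  unknown <- setdiff(evidence$accession, proteome$accession)
  if (length(unknown))
    pp_stop_input(sprintf("evidence references unknown accession(s): %s",
                          paste(unknown, collapse = ", ")))
  nsaf <- compute_nsaf(counts, proteome)
  cls <- classify_peptide(index, evidence$peptide)
  evidence <- cbind(evidence, cls[, .(status)])

  ann <- if (is.null(annotations)) NULL else data.table::as.data.table(annotations)
  cell_types <- sort(unique(counts$cell_type))
  libs <- lapply(cell_types, function(ct) {
    ev <- evidence[cell_type == ct]
    n_prot <- ev[status == "proteotypic",
                 .(n_proteotypic_peptides = data.table::uniqueN(peptide)),
                 by = accession]
    present <- n_prot[n_proteotypic_peptides >= min_peptides, accession]
    prot <- data.table::as.data.table(proteome)[accession %in% present,
                 .(accession, description, gene_symbol)]
    prot <- merge(prot, n_prot, by = "accession", sort = FALSE)
    prot <- merge(prot, nsaf[cell_type == ct, .(accession, nsaf)],
                  by = "accession", all.x = TRUE, sort = FALSE)
    prot[is.na(nsaf), nsaf := 0]
    if (!is.null(ann)) {
      prot <- merge(prot, ann[, .(accession, terms)], by = "accession",
                    all.x = TRUE, sort = FALSE)
      prot[is.na(terms), terms := ""]
    } else prot[, terms := ""]
    data.table::setorder(prot, accession)

    pep <- digest(proteome[proteome$accession %in% present, , drop = FALSE], params)
    observed <- unique(ev$peptide)
    pcls <- classify_peptide(index, pep$sequence)
    sc <- score_peptides(pep$sequence, pep$missed_cleavages,
                         in_library = pep$sequence %in% observed,
                         proteotypic = pcls$status == "proteotypic")
    pep_tab <- cbind(pep[, .(accession = parent_accession, start, end, mono_mass)], sc)
    for (z in charges)
      pep_tab[, (paste0("mz_z", z)) := (mono_mass + z * .PROTON) / z]
    pep_tab <- pep_tab[order(accession, -total, length, sequence)]
    pep_tab[, rank := seq_len(.N), by = accession]

    ptm_tab <- if (is.null(ptms) || nrow(ptms) == 0L) {
      project_sites(list(accession = "", sequence = "A"),
                    data.table::data.table())
    } else {
      pt <- data.table::as.data.table(ptms)[cell_type == ct & accession %in% present]
      if (nrow(pt) == 0L)
        project_sites(list(accession = "", sequence = "A"), data.table::data.table())
      else data.table::rbindlist(lapply(split(pt, pt$accession), function(g)
        project_sites(get_protein(proteome, g$accession[1]), g)))
    }
    structure(list(cell_type = ct, proteins = prot, peptides = pep_tab,
                   ptms = ptm_tab), class = "cell_type_library")
  })
  names(libs) <- cell_types
  libs
}

#' @export
print.cell_type_library <- function(x, ...) {
  cat(sprintf("cell type library '%s': %d proteins, %d candidate peptides, %d PTM sites\n",
              x$cell_type, nrow(x$proteins), nrow(x$peptides), nrow(x$ptms)))
  invisible(x)
}

#' Write a cell-type library to TSV files
#'
#' @param lib A `cell_type_library`.
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_library <- function(lib, dir) {
  stopifnot(inherits(lib, "cell_type_library"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, paste0("library_", gsub("[^A-Za-z0-9_.-]", "_", lib$cell_type)))
  p1 <- write_tsv(lib$proteins, paste0(base, "_proteins.tsv"))
  pep <- data.table::copy(lib$peptides)
  numcols <- grep("^(mono_mass|mz_z)", names(pep), value = TRUE)
  pep[, (numcols) := lapply(.SD, round, 5), .SDcols = numcols]
  p2 <- write_scores(pep, paste0(base, "_peptides.tsv"))
  p3 <- write_tsv(lib$ptms, paste0(base, "_ptms.tsv"))
  invisible(c(p1, p2, p3))
}

#' Exclusive intersection counts over per-cell-type protein sets
#'
#' UpSet-style decomposition: for every non-empty subset S of cell types,
#' the number of proteins present in exactly the cell types of S. Counts sum
#' to the size of the union.
#'
#' @param sets Named list of character vectors (protein accessions per cell
#'   type).
#' @return A list of class `intersection_summary`: `counts` (a `data.table`
#'   with `subset` label, `n_types`, `exclusive_count` for all 2^k - 1
#'   subsets), `core` (all-types count), `unique` (named vector of
#'   exactly-one-type counts), `union_size`.
#' @export
intersection_counts <- function(sets) {
  if (length(sets) < 1L) pp_stop_input("need at least one set")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    pp_stop_input("sets must be named by cell type")
  types <- names(sets)
  k <- length(types)
  all_prot <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) all_prot %in% s, logical(length(all_prot)))
  member <- matrix(member, nrow = length(all_prot), ncol = k,
                   dimnames = list(NULL, types))
  sig <- apply(member, 1L, function(x) paste(types[x], collapse = "&"))
  # enumerate all non-empty subsets in size order, then lexicographic
  subsets <- unlist(lapply(seq_len(k), function(m)
    utils::combn(types, m, FUN = paste, collapse = "&", simplify = FALSE)),
    recursive = FALSE)
  lab <- vapply(subsets, identity, character(1))
  counts <- data.table::data.table(
    subset = lab,
    n_types = lengths(strsplit(lab, "&", fixed = TRUE)),
    exclusive_count = vapply(lab, function(s) sum(sig == s), integer(1),
                             USE.NAMES = FALSE))
  uniq <- counts[n_types == 1L]
  structure(list(
    counts = counts,
    core = counts[n_types == k, exclusive_count],
    unique = stats::setNames(uniq$exclusive_count, uniq$subset),
    union_size = length(all_prot)
  ), class = "intersection_summary")
}

#' @export
print.intersection_summary <- function(x, ...) {
  cat(sprintf("exclusive intersections over %d proteins; core (all types) = %d\n",
              x$union_size, x$core))
  print(x$counts[exclusive_count > 0])
  invisible(x)
}

#' Proteins unique to one cell type
#'
#' @param sets Named list of accession vectors per cell type.
#' @param target Cell type of interest.
#' @param pattern Optional regular expression applied to protein descriptions
#'   (e.g. a CD-molecule pattern) after the uniqueness filter.
#' @param proteome Proteome table supplying descriptions; required when
#'   `pattern` is given.
#' @return Sorted character vector of accessions.
#' @export
unique_markers <- function(sets, target, pattern = NULL, proteome = NULL) {
  if (!target %in% names(sets))
    pp_stop_input(sprintf("unknown cell type: %s", target))
  others <- unique(unlist(sets[setdiff(names(sets), target)], use.names = FALSE))
  out <- sort(setdiff(sets[[target]], others))
  if (!is.null(pattern)) {
    if (is.null(proteome))
      pp_stop_input("a proteome with descriptions is required to filter by pattern")
    desc <- stats::setNames(proteome$description, proteome$accession)
    out <- out[grepl(pattern, desc[out])]
  }
  out
}

#' Cluster marker abundance profiles
#'
#' Protein-wise min-max scaling (rows with zero range map to all-zeros),
#' pairwise Euclidean distances, agglomerative complete linkage. Exact ties
#' in the merge distance are broken by merging the pair with the
#' lexicographically smallest cluster labels first, so results are fully
#' deterministic.
#'
#' @param mat Numeric matrix, proteins x cell types, with row names.
#' @return A list of class `marker_clustering`: `merge` and `height` in
#'   [stats::hclust()] convention, `order` (leaf order), `labels`, `scaled`
#'   (the min-max-scaled matrix), and `hclust` (an equivalent `hclust`
#'   object for plotting).
#' @export
cluster_markers <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) pp_stop_input("need at least 2 proteins to cluster")
  if (ncol(mat) < 2L) pp_stop_input("need at least 2 cell types to cluster")
  if (is.null(rownames(mat))) rownames(mat) <- as.character(seq_len(nrow(mat)))
  scaled <- minmax_rows(mat)
  hc <- complete_linkage(scaled)
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = rownames(mat), scaled = scaled, hclust = hc),
            class = "marker_clustering")
}

# Row-wise (x - min) / (max - min); constant rows -> 0.
minmax_rows <- function(mat) {
  rng <- apply(mat, 1L, range)
  span <- rng[2, ] - rng[1, ]
  out <- (mat - rng[1, ]) / ifelse(span > 0, span, 1)
  out[span == 0, ] <- 0
  out
}

# Naive O(n^3) agglomerative complete linkage with deterministic
# tie-breaking; returns an hclust-compatible object.
complete_linkage <- function(x) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  # cluster bookkeeping: id -> member leaf indices; id -> hclust node code
  members <- as.list(seq_len(n))
  node <- -seq_len(n) # hclust: negative = singleton, positive = merge step
  active <- seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  cd <- d # complete-linkage distance between current clusters (by id)
  next_id <- n
  for (step in seq_len(n - 1L)) {
    best <- c(NA_integer_, NA_integer_); best_d <- Inf
    for (ai in seq_along(active)) for (bi in seq_along(active)) {
      if (bi <= ai) next
      a <- active[ai]; b <- active[bi]
      dv <- cd[a, b]
      # strict < keeps the first pair found on exact ties; active ids are in
      # creation order, so that is the lexicographically smallest (a, b)
      if (dv < best_d) { best_d <- dv; best <- c(a, b) }
    }
    a <- best[1]; b <- best[2]
    merge[step, ] <- sort(c(node[a], node[b]))
    height[step] <- cd[a, b]
    next_id <- next_id + 1L
    members[[next_id]] <- c(members[[a]], members[[b]])
    node[next_id] <- step
    active <- c(setdiff(active, c(a, b)), next_id)
    # extend distance matrix with the new cluster (complete linkage = max)
    newd <- vapply(seq_len(next_id - 1L), function(c2)
      max(cd[c2, a], cd[c2, b]), numeric(1))
    cd <- rbind(cbind(cd, newd), c(newd, 0))
    node <- c(node, 0L)[seq_len(next_id)]
    node[next_id] <- step
  }
  ord <- leaf_order(merge, n, rownames(x))
  structure(list(merge = merge, height = height, order = ord,
                 labels = rownames(x), method = "complete",
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

# Depth-first leaf order; at every internal node the branch holding the
# lexicographically smallest leaf label comes first, so the order is
# invariant under row permutation of the input.
leaf_order <- function(merge, n, labels = as.character(seq_len(n))) {
  expand <- function(code) {
    if (code < 0L) return(-code)
    a <- expand(merge[code, 1])
    b <- expand(merge[code, 2])
    if (min(labels[a]) <= min(labels[b])) c(a, b) else c(b, a)
  }
  expand(nrow(merge))
}

#' Write an intersection summary as TSV
#'
#' @param x An [intersection_counts()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_intersections <- function(x, path) {
  stopifnot(inherits(x, "intersection_summary"))
  write_tsv(x$counts, path,
            comments = sprintf("union_size=%d core=%d", x$union_size, x$core))
}

#' Write a clustering result as TSV
#'
#' Merge tree (hclust convention) followed by the leaf order.
#'
#' @param x A [cluster_markers()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_clustering <- function(x, path) {
  stopifnot(inherits(x, "marker_clustering"))
  dt <- data.table::data.table(
    step = seq_along(x$height),
    a = x$merge[, 1], b = x$merge[, 2],
    height = signif(x$height, 9))
  write_tsv(dt, path,
            comments = c(paste("leaf_order:", paste(x$order, collapse = ",")),
                         paste("labels:", paste(x$labels, collapse = ","))))
}
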