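test_that("exclusive intersection counts match brute-force enumeration", {
  sets <- list(A = c("a", "b", "c"), B = c("b", "c"), C = "c")
  ic <- intersection_counts(sets)
  got <- setNames(ic$counts$exclusive_count, ic$counts$subset)
  expect_equal(got[["A"]], 1L)
  expect_equal(got[["A&B"]], 1L)
  expect_equal(got[["A&B&C"]], 1L)
  expect_equal(sum(got), ic$union_size)
  expect_equal(sum(got[!names(got) %in% c("A", "A&B", "A&B&C")]), 0L)
  expect_equal(ic$core, 1L)
  expect_equal(unname(ic$unique["A"]), 1L)
})

test_that("degenerate set families behave", {
  disj <- intersection_counts(list(A = c("x", "y"), B = c("z")))
  got <- setNames(disj$counts$exclusive_count, disj$counts$subset)
  expect_equal(unname(got[c("A", "B", "A&B")]), c(2L, 1L, 0L))
  same <- intersection_counts(list(A = c("x", "y"), B = c("x", "y")))
  got2 <- setNames(same$counts$exclusive_count, same$counts$subset)
  expect_equal(unname(got2[c("A", "B", "A&B")]), c(0L, 0L, 2L))
})

test_that("intersection counts sum to the union on random families", {
  set.seed(16)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    pool <- sprintf("p%03d", 1:40)
    sets <- setNames(lapply(1:k, function(j) sample(pool, sample(5:30, 1))),
                     LETTERS[1:k])
    ic <- intersection_counts(sets)
    expect_equal(sum(ic$counts$exclusive_count),
                 length(unique(unlist(sets))))
    # brute-force: membership signature of every protein
    u <- unique(unlist(sets))
    sig <- vapply(u, function(p) paste(names(sets)[vapply(sets, function(s)
      p %in% s, logical(1))], collapse = "&"), character(1))
    for (r in seq_len(nrow(ic$counts)))
      expect_equal(ic$counts$exclusive_count[r],
                   sum(sig == ic$counts$subset[r]))
    # permuting cell-type order permutes labels, not the multiset of counts
    ic2 <- intersection_counts(rev(sets))
    expect_equal(sort(ic2$counts$exclusive_count),
                 sort(ic$counts$exclusive_count))
    expect_equal(ic2$core, ic$core)
  }
})

test_that("unique_markers returns target-exclusive accessions", {
  sets <- list(A = c("a", "b", "c"), B = c("b", "c"), C = "c")
  expect_equal(unique_markers(sets, "A"), "a")
  expect_equal(unique_markers(sets, "C"), character(0)) # subset of others
  prot <- data.table::data.table(accession = c("a", "b", "c"),
                                 description = c("Cd8 antigen", "other", "x"))
  expect_equal(unique_markers(sets, "A", pattern = "^Cd\\d", proteome = prot), "a")
  expect_equal(unique_markers(sets, "A", pattern = "ZZZ", proteome = prot),
               character(0))
  expect_error(unique_markers(sets, "D"), class = "proteopick_input_error")
})

test_that("min-max scaling maps rows to [0,1] and zero-range rows to 0", {
  m <- rbind(a = c(2, 4, 6), b = c(5, 5, 5), c = c(0, 1, 3))
  cl <- cluster_markers(m)
  expect_equal(unname(cl$scaled["a", ]), c(0, 0.5, 1))
  expect_equal(unname(cl$scaled["b", ]), c(0, 0, 0))
  expect_true(all(cl$scaled >= 0 & cl$scaled <= 1))
})

test_that("two proteins merge at their Euclidean distance", {
  m <- rbind(a = c(0, 1), b = c(1, 0))
  cl <- cluster_markers(m)
  expect_equal(length(cl$height), 1L)
  expect_equal(cl$height, sqrt(2)) # scaled rows are (0,1) and (1,0)
})

test_that("merge trees match a from-scratch complete-linkage oracle", {
  set.seed(17)
  for (i in 1:12) {
    m <- matrix(runif(10 * 5), 10, 5,
                dimnames = list(sprintf("p%02d", 1:10), NULL))
    cl <- cluster_markers(m)
    o <- oracle_complete_linkage(cl$scaled)
    expect_equal(cl$height, o$heights, tolerance = 1e-12)
    # same member sets merged at every step
    members_of <- function(code) {
      if (code < 0) return(-code)
      sort(c(members_of(cl$merge[code, 1]), members_of(cl$merge[code, 2])))
    }
    for (s in seq_along(cl$height)) {
      got <- sort(c(members_of(cl$merge[s, 1]), members_of(cl$merge[s, 2])))
      expect_equal(got, sort(unlist(o$merges[[s]])))
    }
    # heights are non-decreasing; leaf order is a permutation
    expect_true(all(diff(cl$height) >= -1e-12))
    expect_equal(sort(cl$order), 1:10)
    # agreement with stats::hclust on tie-free data
    hc <- stats::hclust(stats::dist(cl$scaled), method = "complete")
    expect_equal(cl$height, hc$height, tolerance = 1e-12)
  }
})

test_that("clustering is invariant under row permutation (up to relabeling)", {
  set.seed(18)
  m <- matrix(runif(8 * 4), 8, 4, dimnames = list(letters[1:8], NULL))
  perm <- sample(8)
  cl1 <- cluster_markers(m)
  cl2 <- cluster_markers(m[perm, ])
  expect_equal(cl1$height, cl2$height, tolerance = 1e-12)
  expect_equal(cl1$labels[cl1$order], cl2$labels[cl2$order])
  expect_error(cluster_markers(m[1, , drop = FALSE]),
               class = "proteopick_input_error")
})

test_that("build_library assembles consistent per-cell-type tables", {
  spec <- fixture_spec(seed = 3, n_proteins = 12, n_cell_types = 2,
                       length_range = c(100L, 160L), n_shared = 2)
  prot <- generate_proteome(spec)
  ev <- generate_evidence(spec, prot)
  idx <- build_index(prot$proteome)
  fl <- filter_ptms(ev$ptms, idx)
  libs <- build_library(ev$counts, ev$evidence, prot$proteome, idx,
                        ptms = fl$kept)
  expect_equal(length(libs), 2L)
  for (lib in libs) {
    # every peptide row's parent has a protein row
    expect_true(all(lib$peptides$accession %in% lib$proteins$accession))
    # n_proteotypic_peptides matches the evidence under index classification
    ev_ct <- ev$evidence[cell_type == lib$cell_type]
    cls <- classify_peptide(idx, ev_ct$peptide)
    for (r in seq_len(nrow(lib$proteins))) {
      a <- lib$proteins$accession[r]
      expect_equal(lib$proteins$n_proteotypic_peptides[r],
                   length(unique(ev_ct$peptide[ev_ct$accession == a &
                                                 cls$status == "proteotypic"])))
    }
    # candidate peptides observed in evidence carry c1
    obs <- lib$peptides$sequence %in% ev_ct$peptide
    expect_equal(lib$peptides$c1, obs)
    expect_true(all(lib$peptides$total >= 0 & lib$peptides$total <= 11))
  }
  # empty PTM input builds with empty ptm rows
  libs2 <- build_library(ev$counts, ev$evidence, prot$proteome, idx, ptms = NULL)
  expect_equal(nrow(libs2[[1]]$ptms), 0L)
  # unknown accession in evidence errors
  bad_ev <- data.table::copy(ev$evidence)[1, accession := "NOPE"]
  expect_error(build_library(ev$counts, bad_ev, prot$proteome, idx),
               "NOPE", class = "proteopick_input_error")
})
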