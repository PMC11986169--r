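test_that("shared and unique peptides are classified per the toy example", {
  prot <- data.table::data.table(
    accession = c("P1", "P2"),
    sequence = c("AAAKTESTRCCC", "GGGKTESTRDDD"))
  idx <- build_index(prot, params = digest_params(2, 1, 150))
  cls <- classify_peptide(idx, c("TESTR", "WWWWWW"))
  expect_equal(cls$status, c("shared", "absent"))
  expect_equal(cls$parents, c("P1;P2", ""))
  expect_equal(cls$n_parents, c(2L, 0L))
})

test_that("every peptide of a single-protein proteome is proteotypic", {
  prot <- data.table::data.table(accession = "P1",
                                 sequence = rand_seq(80))
  idx <- build_index(prot, params = digest_params(2, 1, 150))
  expect_true(all(idx$peptides$proteotypic))
  cls <- classify_peptide(idx, idx$peptides$peptide)
  expect_true(all(cls$status == "proteotypic"))
})

test_that("leucine/isoleucine equivalence is honoured when requested", {
  prot <- data.table::data.table(accession = "P1", sequence = "AAAKTIR")
  idx_eq <- build_index(prot, params = digest_params(0, 1, 150), equate_li = TRUE)
  idx_ne <- build_index(prot, params = digest_params(0, 1, 150), equate_li = FALSE)
  expect_equal(classify_peptide(idx_eq, "TLR")$status, "proteotypic")
  expect_equal(classify_peptide(idx_ne, "TLR")$status, "absent")
})

test_that("index agrees with a naive substring-search oracle", {
  set.seed(11)
  n_prot <- 40
  prot <- data.table::data.table(
    accession = sprintf("P%02d", 1:n_prot),
    sequence = vapply(sample(50:200, n_prot, TRUE), rand_seq, character(1)))
  idx <- build_index(prot, params = digest_params(1, 4, 60))
  # check every indexed peptide plus random foreign queries
  queries <- c(sample(idx$peptides$peptide, min(400, nrow(idx$peptides))),
               vapply(rep(8, 50), rand_seq, character(1)))
  cls <- classify_peptide(idx, queries)
  for (i in seq_along(queries)) {
    expected <- oracle_parents(queries[i], prot$accession, prot$sequence)
    got <- if (cls$parents[i] == "") character(0)
           else strsplit(cls$parents[i], ";", fixed = TRUE)[[1]]
    if (cls$status[i] == "absent") {
      # absent means: not a tryptic peptide of any protein under the digest
      # params; a random query may still occur as a substring, so only the
      # indexed peptides are compared against the oracle exhaustively
      expect_false(queries[i] %in% idx$peptides$peptide)
    } else {
      expect_identical(got, expected)
    }
  }
})

test_that("digest mode restricts parents to tryptic context", {
  # P2 contains ("LLLTESTK") only mid-sequence without a preceding cleavage
  # site, so in digest mode it is not a parent
  prot <- data.table::data.table(
    accession = c("P1", "P2"),
    sequence = c("AAAKLLLTESTK", "GGGLLLTESTKGGG"))
  idx_sub <- build_index(prot, mode = "substring", params = digest_params(0, 1, 150))
  idx_dig <- build_index(prot, mode = "digest", params = digest_params(0, 1, 150))
  expect_equal(classify_peptide(idx_sub, "LLLTESTK")$n_parents, 2L)
  expect_equal(classify_peptide(idx_dig, "LLLTESTK")$n_parents, 1L)
})

test_that("adding a protein never shrinks a parent set", {
  set.seed(12)
  base <- data.table::data.table(
    accession = sprintf("P%02d", 1:10),
    sequence = vapply(sample(60:150, 10, TRUE), rand_seq, character(1)))
  extra <- data.table::data.table(accession = "PX", sequence = rand_seq(150))
  idx1 <- build_index(base, params = digest_params(1, 5, 60))
  idx2 <- build_index(rbind(base, extra), params = digest_params(1, 5, 60))
  cls1 <- classify_peptide(idx1, idx1$peptides$peptide)
  cls2 <- classify_peptide(idx2, idx1$peptides$peptide)
  expect_true(all(cls2$n_parents >= cls1$n_parents))
  # a proteotypic peptide can only stay proteotypic or become shared
  expect_true(all(cls2$status[cls1$status == "proteotypic"] %in%
                    c("proteotypic", "shared")))
})

test_that("index TSV export/import round trips classifications", {
  prot <- toy_proteome()
  idx <- build_index(prot, params = digest_params(2, 1, 150))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_index(idx, f)
  idx2 <- read_index(f)
  q <- idx$peptides$peptide
  expect_equal(classify_peptide(idx2, q), classify_peptide(idx, q))
  expect_error(build_index(prot[0, ]), "empty", class = "proteopick_input_error")
})
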