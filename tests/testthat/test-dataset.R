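test_that("a 2x2 toy dataset round-trips through TSV files unchanged", {
  ds <- toy_dataset()
  paths <- write_fixture_files(ds)
  back <- read_dti_dataset(paths$Y, paths$Sd, paths$Sp)
  expect_identical(back$drug_ids, ds$drug_ids)
  expect_identical(back$protein_ids, ds$protein_ids)
  expect_equal(back$Y, ds$Y)
  expect_equal(back$S_d, ds$S_d)
  expect_equal(back$S_p, ds$S_p)
})

test_that("a simulated dataset round-trips numerically exactly", {
  ds <- simulate_dti_dataset(n_d = 12, n_p = 9, seed = 3)
  paths <- write_fixture_files(ds)
  back <- read_dti_dataset(paths$Y, paths$Sd, paths$Sp)
  expect_identical(back$Y, ds$Y)
  expect_identical(back$S_d, ds$S_d)
  expect_identical(back$S_p, ds$S_p)
})

test_that("similarity matrices in files are re-aligned to the interaction matrix order", {
  ds <- simulate_dti_dataset(n_d = 8, n_p = 6, seed = 4)
  paths <- write_fixture_files(ds)
  # scramble S_d's row/column order on disk
  perm <- c(3, 1, 8, 5, 2, 7, 4, 6)
  shuffled <- ds$S_d[perm, perm]
  df <- data.frame(id = rownames(shuffled), shuffled, check.names = FALSE)
  names(df)[1] <- ""
  utils::write.table(df, paths$Sd, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_dti_dataset(paths$Y, paths$Sd, paths$Sp)
  expect_equal(back$S_d, ds$S_d, tolerance = 1e-12)
})

test_that("validation rejects malformed inputs with the offending matrix named", {
  Y <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_error(dti_dataset(matrix(c(1, 0.5, 0, 1), 2, 2), diag(2), diag(2)),
               "Y.*0\\.5", class = "dti_validation_error")
  S_bad <- matrix(c(1, 0.9, 0.2, 1), 2, 2)  # asymmetry 0.7 > 1e-6
  expect_error(dti_dataset(Y, S_bad, diag(2)),
               "S_d.*asymmetric", class = "dti_validation_error")
  S_diag <- matrix(c(0.5, 0.2, 0.2, 1), 2, 2)
  expect_error(dti_dataset(Y, S_diag, diag(2)),
               "S_d diagonal", class = "dti_validation_error")
  S_range <- matrix(c(1, 1.4, 1.4, 1), 2, 2)
  expect_error(dti_dataset(Y, S_range, diag(2)),
               "S_d entries", class = "dti_validation_error")
  expect_error(dti_dataset(Y, diag(2), diag(3)),
               "S_p", class = "dti_validation_error")
  expect_error(dti_dataset(Y, diag(2), diag(2), drug_ids = c("d1", "d1")),
               "duplicate", class = "dti_validation_error")
})

test_that("tiny asymmetry from file rounding is repaired by symmetrization", {
  S <- matrix(c(1, 0.4 + 5e-7, 0.4, 1), 2, 2)
  ds <- dti_dataset(matrix(c(1, 0, 0, 1), 2, 2), S, diag(2))
  expect_equal(ds$S_d[1, 2], ds$S_d[2, 1])
  expect_equal(ds$S_d[1, 2], 0.4 + 2.5e-7)
})

test_that("reading a non-binary interaction file names the file", {
  ds <- toy_dataset()
  paths <- write_fixture_files(ds)
  bad <- ds$Y
  storage.mode(bad) <- "double"
  bad[1, 2] <- 0.5
  df <- data.frame(id = rownames(bad), bad, check.names = FALSE)
  names(df)[1] <- ""
  utils::write.table(df, paths$Y, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_dti_dataset(paths$Y, paths$Sd, paths$Sp),
               "Y", class = "dti_validation_error")
})

test_that("rank_edges ranks by score with deterministic tie-breaking", {
  ds <- toy_dataset()
  # top novel pair only: Y is diagonal so (d1,p2) and (d2,p1) are novel
  scores <- matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2)
  top <- rank_edges(scores, ds, top_k = 1)
  expect_equal(nrow(top), 1)
  expect_equal(top$drug_id, "d2")
  expect_equal(top$protein_id, "p1")
  expect_false(top$known)

  # no top_k: all pairs, sorted by score descending
  all_edges <- rank_edges(scores, ds)
  expect_equal(nrow(all_edges), 4)
  expect_equal(all_edges$score, sort(as.vector(scores), decreasing = TRUE))

  # ties broken by (drug index, protein index) ascending, matching a
  # stable sort on (-score, drug, protein)
  set.seed(11)
  n_d <- 5; n_p <- 4
  tied <- matrix(sample(c(0.1, 0.5, 0.9), n_d * n_p, replace = TRUE), n_d, n_p)
  ds2 <- dti_dataset(matrix(0:1, n_d, n_p), random_similarity(n_d),
                     random_similarity(n_p))
  got <- rank_edges(tied, ds2)
  ref <- expand.grid(d = seq_len(n_d), p = seq_len(n_p))
  ref$score <- tied[cbind(ref$d, ref$p)]
  ref <- ref[order(-ref$score, ref$d, ref$p), ]
  expect_equal(got$drug_id, ds2$drug_ids[ref$d])
  expect_equal(got$protein_id, ds2$protein_ids[ref$p])
})

test_that("rank_edges with top_k emits exactly min(k, number of novel pairs) rows", {
  set.seed(12)
  ds <- random_dataset(6, 5, density = 0.4)
  scores <- matrix(stats::runif(30), 6, 5)
  n_novel <- sum(ds$Y == 0)
  for (k in c(1, 3, n_novel)) {
    expect_equal(nrow(rank_edges(scores, ds, top_k = k)), min(k, n_novel))
  }
  expect_false(any(rank_edges(scores, ds, top_k = n_novel)$known))
  expect_error(rank_edges(scores, ds, top_k = 31), class = "dti_validation_error")
})

test_that("write_edges writes a readable TSV edge list", {
  ds <- toy_dataset()
  path <- withr::local_tempfile(fileext = ".tsv")
  scores <- matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2)
  write_edges(scores, ds, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(names(back), c("drug_id", "protein_id", "score", "known"))
  expect_equal(nrow(back), 4)
  expect_equal(back$score[1], 0.9)
})
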