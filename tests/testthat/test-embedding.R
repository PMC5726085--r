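test_that("row normalisation produces unit-norm square-root shares", {
  X <- two_share_matrix()
  nm <- row_normalize(X)
  expect_equal(as.numeric(nm$R["d1", ]), c(sqrt(0.75), sqrt(0.25)),
               tolerance = 1e-12)
  expect_equal(Matrix::rowSums(nm$R^2), c(d1 = 1, d2 = 1), tolerance = 1e-10)
  expect_false(any(nm$degenerate))

  # all-zero row is flagged degenerate and left as a zero vector
  X0 <- Matrix::Matrix(rbind(c(2, 1), c(0, 0)), sparse = TRUE)
  nm0 <- row_normalize(X0)
  expect_identical(unname(nm0$degenerate), c(FALSE, TRUE))
  expect_equal(sum(abs(nm0$R[2, ])), 0)

  # plain L1 dialect keeps rows summing to one instead
  l1 <- row_normalize(X, sqrt_shares = FALSE)
  expect_equal(as.numeric(l1$R["d1", ]), c(0.75, 0.25))
})

test_that("pairwise similarity is the Bhattacharyya coefficient", {
  nm <- row_normalize(two_share_matrix())
  expect_equal(pairwise_similarity(nm, 1, 1), 1, tolerance = 1e-12)
  expect_equal(pairwise_similarity(nm, "d1", "d2"),
               sqrt(0.75 * 0.25) + sqrt(0.25 * 0.75), tolerance = 1e-12)
  disj <- row_normalize(Matrix::Matrix(rbind(c(1, 0), c(0, 1)),
                                       sparse = TRUE))
  expect_equal(pairwise_similarity(disj, 1, 2), 0)

  X0 <- Matrix::Matrix(rbind(c(2, 1), c(0, 0)), sparse = TRUE)
  expect_error(pairwise_similarity(row_normalize(X0), 1, 2), "degenerate")
})

test_that("degree vector equals row sums of the similarity matrix", {
  nm <- row_normalize(two_share_matrix())
  expect_equal(degree_vector(nm), rep(1 + 0.8660254, 2), tolerance = 1e-7)
  # mutually orthogonal rows: degrees all 1
  I3 <- row_normalize(Matrix::Matrix(diag(3), sparse = TRUE))
  expect_equal(degree_vector(I3), rep(1, 3))
  one <- row_normalize(Matrix::Matrix(matrix(c(2, 3), 1), sparse = TRUE))
  expect_equal(degree_vector(one), 1)
})

test_that("two-document embedding has the closed-form 2x2 spectrum", {
  nm <- row_normalize(two_share_matrix())
  emb <- spectral_embed(nm, p = 2)
  c12 <- pairwise_similarity(nm, 1, 2)
  expect_equal(emb$values, c(1, (1 - c12) / (1 + c12)), tolerance = 1e-8)
  # full-rank reconstruction: Z Z^T recovers the normalised operator
  Ct <- brute_operator(nm)
  expect_lt(max(abs(emb$Z %*% t(emb$Z) - Ct)), 1e-8)
})

test_that("orthogonal documents give the identity operator", {
  nm <- row_normalize(Matrix::Matrix(diag(4), sparse = TRUE))
  emb <- spectral_embed(nm, p = 4)
  expect_equal(emb$values, rep(1, 4), tolerance = 1e-10)
  expect_equal(crossprod(emb$Z), diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("implicit-operator eigensolver matches a dense oracle", {
  co <- small_synth(n = 150, seed = 11)
  vocab <- build_vocabulary(co)
  nm <- row_normalize(tfidf_matrix(co, vocab))
  # independent dense route: explicit operator + base eigen
  Ct <- brute_operator(nm)
  dense <- eigen(Ct, symmetric = TRUE)
  p <- 20
  arp <- spectral_embed(nm, p = p, dense_threshold = 0, seed = 5)
  expect_equal(arp$values, dense$values[seq_len(p)], tolerance = 1e-6)
  # eigenvectors agree up to sign
  for (j in seq_len(5)) {
    zj <- arp$Z[, j] / sqrt(arp$values[j])
    expect_equal(abs(sum(zj * dense$vectors[, j])), 1, tolerance = 1e-6)
  }
})

test_that("full-dimension embedding preserves pairwise similarities", {
  co <- small_synth(n = 80, seed = 3)
  nm <- row_normalize(tfidf_matrix(co))
  emb <- spectral_embed(nm, p = nrow(co))
  Ct <- brute_operator(nm)
  expect_lt(max(abs(emb$Z %*% t(emb$Z) - Ct)), 1e-6)
  # <z_d, z_d'> = C~[d, d'] entrywise is the same statement
  expect_equal(sum(emb$Z[1, ] * emb$Z[2, ]), Ct[1, 2], tolerance = 1e-6)
})

test_that("spectrum invariants hold across generated corpora", {
  for (seed in c(2, 7)) {
    co <- small_synth(n = 120, seed = seed, scatter = 0.2)
    emb <- embed_corpus(co, p = 30)
    expect_true(all(diff(emb$values_raw) <= 1e-10))
    expect_true(all(emb$values_raw >= -1e-8 & emb$values_raw <= 1 + 1e-8))
    expect_equal(emb$values_raw[1], 1, tolerance = 1e-8)
  }
})

test_that("leading eigenvector is the degree fixed point", {
  co <- small_synth(n = 100, seed = 9)
  nm <- row_normalize(tfidf_matrix(co))
  v <- sqrt(degree_vector(nm))
  v <- v / sqrt(sum(v^2))
  Ct <- brute_operator(nm)
  expect_lt(max(abs(Ct %*% v - v)), 1e-8)
})

test_that("degenerate rows, p bounds and rank deficits are handled", {
  co <- citation_corpus(c("d1", "d2", "d3"),
                        c("shared rare1", "shared rare2", "shared"),
                        c("", "", ""), c(1L, 0L, 0L))
  # d3 contains only the ubiquitous token -> zero tf-idf row
  nm <- row_normalize(tfidf_matrix(co))
  expect_identical(unname(nm$degenerate), c(FALSE, FALSE, TRUE))
  expect_warning(emb <- spectral_embed(nm, p = 3), "nonzero")
  expect_equal(emb$Z[3, ], c(z1 = 0, z2 = 0, z3 = 0))
  expect_error(spectral_embed(nm, p = 4), "exceeds")
})

test_that("embedding export writes coordinates and eigenvalues", {
  co <- small_synth(n = 40, seed = 1)
  emb <- embed_corpus(co, p = 5)
  prefix <- file.path(withr::local_tempdir(), "emb")
  write_embedding(emb, prefix)
  tab <- read.delim(paste0(prefix, ".tsv"))
  expect_identical(dim(tab), c(40L, 6L))
  expect_identical(tab$id, co$id)
  ev <- read.delim(paste0(prefix, ".eigenvalues.tsv"))
  expect_equal(ev$eigenvalue, emb$values, tolerance = 1e-12)
  Zmm <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  expect_equal(Zmm, unname(emb$Z), tolerance = 1e-12)
})
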