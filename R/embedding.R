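#' Row-normalised term matrix
#'
#' Converts the TF-IDF matrix into per-citation term-share vectors. With the
#' default square-root form, row `d` becomes
#' `r_dw = sqrt(X_dw / sum_w' X_dw')`, so each non-degenerate row has unit
#' Euclidean norm and the inner product of two rows equals the Bhattacharyya
#' coefficient between the citations' term-share distributions (with
#' `diag(C) = 1` exactly). The plain L1-share form (`r_dw = X_dw / sum X_dw`)
#' is available for comparison via `sqrt_shares = FALSE`.
#'
#' Rows whose TF-IDF entries are all zero (every token occurs in every
#' citation, or no tokens at all) cannot be normalised; they are kept as zero
#' vectors and flagged degenerate. Degenerate citations are excluded as
#' sources and targets of label propagation and get zero embedding
#' coordinates.
#'
#' @param X a non-negative sparse term matrix, typically from
#'   [tfidf_matrix()].
#' @param sqrt_shares logical; use the square-root dialect (default `TRUE`).
#' @return An object of class `normalised_matrix`: list with `R` (sparse
#'   n x m matrix), `degenerate` (logical vector) and `sqrt_shares`.
#' @export
row_normalize <- function(X, sqrt_shares = TRUE) {
  X <- methods::as(X, "CsparseMatrix")
  if (any(X@x < 0)) stop("term matrix must be non-negative")
  rs <- Matrix::rowSums(X)
  degenerate <- rs <= 0
  scale <- ifelse(degenerate, 0, 1 / rs)
  R <- Matrix::Diagonal(nrow(X), scale) %*% X
  if (sqrt_shares) R <- sqrt(R)
  R <- methods::as(R, "CsparseMatrix")
  dimnames(R) <- dimnames(X)
  structure(list(R = R, degenerate = degenerate, sqrt_shares = sqrt_shares),
            class = "normalised_matrix")
}

#' @export
print.normalised_matrix <- function(x, ...) {
  cat("<normalised_matrix> ", nrow(x$R), " x ", ncol(x$R),
      if (x$sqrt_shares) " (sqrt shares)" else " (L1 shares)",
      "; ", sum(x$degenerate), " degenerate row(s)\n", sep = "")
  invisible(x)
}

#' Bhattacharyya similarity of two citations
#'
#' Inner product of the two normalised rows; under the square-root dialect
#' this is the Bhattacharyya coefficient `sum_w sqrt(p_w q_w)` of the two
#' term-share distributions, lying in `[0, 1]` with 1 for identical shares
#' and 0 for disjoint vocabularies.
#'
#' @param nm a `normalised_matrix`.
#' @param d,d2 row indices (or citation ids).
#' @return Similarity in `[0, 1]`.
#' @export
pairwise_similarity <- function(nm, d, d2) {
  stopifnot(inherits(nm, "normalised_matrix"))
  if (is.character(d)) d <- match(d, rownames(nm$R))
  if (is.character(d2)) d2 <- match(d2, rownames(nm$R))
  if (nm$degenerate[d] || nm$degenerate[d2]) {
    stop("similarity undefined for degenerate (all-zero) citation rows")
  }
  as.numeric(nm$R[d, , drop = FALSE] %*% Matrix::t(nm$R[d2, , drop = FALSE]))
}

#' Degree vector of the similarity graph
#'
#' Row sums of the (never materialised) similarity matrix
#' `C = R R^T`, computed as `R (R^T 1)`. Every non-degenerate row has degree
#' >= 1 because its self-similarity is 1.
#'
#' @param nm a `normalised_matrix`.
#' @return Numeric vector of degrees (0 for degenerate rows).
#' @export
degree_vector <- function(nm) {
  stopifnot(inherits(nm, "normalised_matrix"))
  as.numeric(nm$R %*% Matrix::colSums(nm$R))
}

#' Spectral embedding of a citation corpus
#'
#' Computes the top-`p` eigenpairs of the symmetrically normalised
#' similarity operator `C~ = D^{-1/2} C D^{-1/2}` with `C = R R^T` and
#' `D = diag(C 1)`, and returns the embedding whose `j`-th column is
#' `u_j * sqrt(lambda_j)`. Rows of the result are citation coordinates;
#' inner products between rows approximate `C~` and converge to it as `p`
#' approaches the rank of `C~`.
#'
#' `C~` is dense in general, so it is never formed for large corpora:
#' matrix-vector products are evaluated as
#' `C~ x = D^{-1/2} (R (R^T (D^{-1/2} x)))`, a chain of sparse products, and
#' fed to an implicitly restarted Lanczos eigensolver (ARPACK). For corpora
#' with at most `dense_threshold` citations a dense eigendecomposition of
#' the explicit `C~` is used instead; the two routes agree to solver
#' tolerance and the dense one doubles as an internal oracle.
#'
#' All eigenvalues of `C~` lie in `[0, 1]` and the top one is exactly 1,
#' with eigenvector proportional to `D^{1/2} 1` (restricted to
#' non-degenerate rows). Eigenvector signs are arbitrary; only distances
#' between embedding rows are used downstream. If `p` exceeds the number of
#' numerically nonzero eigenvalues the trailing columns are zero and a
#' warning is raised.
#'
#' @param nm a `normalised_matrix` from [row_normalize()].
#' @param p embedding dimension (default 50); must not exceed the number of
#'   citations.
#' @param tol eigensolver tolerance (default 1e-10).
#' @param maxiter maximum ARPACK iterations (default 5000).
#' @param seed integer seed for the solver's start vector, making the
#'   iterative route reproducible.
#' @param dense_threshold corpora up to this size use the dense
#'   eigendecomposition (default 500).
#' @return Object of class `spectral_embedding`: list with `Z` (dense n x p
#'   matrix, citation ids as row names), `values` (eigenvalues, non
#'   increasing, clipped to `[0, 1]`), `values_raw` (unclipped solver
#'   output), `p`, and `degenerate`.
#' @export
spectral_embed <- function(nm, p = 50L, tol = 1e-10, maxiter = 5000L,
                           seed = 1L, dense_threshold = 500L) {
  stopifnot(inherits(nm, "normalised_matrix"))
  n <- nrow(nm$R)
  p <- as.integer(p)
  if (p < 1L) stop("p must be >= 1")
  if (p > n) stop("embedding dimension p = ", p,
                  " exceeds corpus size n = ", n)
  if (all(nm$degenerate)) stop("all rows are degenerate; nothing to embed")
  deg <- degree_vector(nm)
  dinv <- ifelse(nm$degenerate, 0, 1 / sqrt(deg))
  R <- nm$R

  # ARPACK needs nev < ncv <= n; full-spectrum requests go the dense route
  if (n <= dense_threshold || p >= n - 1L) {
    Ct <- dense_operator(nm, deg = deg)
    es <- eigen(Ct, symmetric = TRUE)
    values <- es$values[seq_len(p)]
    vectors <- es$vectors[, seq_len(p), drop = FALSE]
  } else {
    mult <- function(x, extra) {
      y <- dinv * x
      y <- as.numeric(R %*% as.numeric(Matrix::crossprod(R, y)))
      dinv * y
    }
    ncv <- min(n, max(2L * p + 1L, p + 20L))
    set.seed(seed)
    res <- tryCatch(
      igraph::arpack(mult, sym = TRUE,
                     options = list(n = n, nev = p, ncv = ncv, which = "LA",
                                    maxiter = maxiter, tol = tol)),
      error = function(e) {
        stop("eigensolver failed to converge (maxiter = ", maxiter,
             ", tol = ", tol, "): ", conditionMessage(e))
      })
    ord <- order(res$values, decreasing = TRUE)
    values <- res$values[ord]
    vectors <- res$vectors[, ord, drop = FALSE]
  }

  # spectrum of C~ is contained in [0, 1]; clip solver round-off but keep
  # the raw values for diagnostics
  values_raw <- values
  values <- pmin(pmax(values, 0), 1)
  nz <- values > 1e-12
  if (!all(nz)) {
    warning("only ", sum(nz), " numerically nonzero eigenvalue(s); ",
            "trailing embedding columns are zero")
  }
  Z <- vectors %*% diag(sqrt(values), nrow = p)
  Z[nm$degenerate, ] <- 0
  rownames(Z) <- rownames(R)
  colnames(Z) <- paste0("z", seq_len(p))
  structure(list(Z = Z, values = values, values_raw = values_raw, p = p,
                 degenerate = nm$degenerate),
            class = "spectral_embedding")
}

# explicit dense C~ (small corpora / oracle use only)
dense_operator <- function(nm, deg = degree_vector(nm)) {
  dinv <- ifelse(nm$degenerate, 0, 1 / sqrt(deg))
  C <- as.matrix(Matrix::tcrossprod(nm$R))
  dinv * sweep(C, 2, dinv, "*")
}

#' @export
print.spectral_embedding <- function(x, ...) {
  cat("<spectral_embedding> ", nrow(x$Z), " citations in ", x$p,
      " dimensions; lambda_1 = ", format(x$values[1], digits = 6), "\n",
      sep = "")
  invisible(x)
}

#' End-to-end embedding of a corpus
#'
#' Convenience pipeline: tokenise, build the vocabulary, form the TF-IDF
#' matrix, row-normalise and spectrally embed.
#'
#' @inheritParams build_vocabulary
#' @inheritParams spectral_embed
#' @param sqrt_shares passed to [row_normalize()].
#' @return A `spectral_embedding`.
#' @export
embed_corpus <- function(corpus, p = 50L, stopwords = character(),
                         sqrt_shares = TRUE, tol = 1e-10, maxiter = 5000L,
                         seed = 1L, dense_threshold = 500L) {
  vocab <- build_vocabulary(corpus, stopwords = stopwords)
  X <- tfidf_matrix(corpus, vocab)
  nm <- row_normalize(X, sqrt_shares = sqrt_shares)
  spectral_embed(nm, p = p, tol = tol, maxiter = maxiter,
                 seed = seed, dense_threshold = dense_threshold)
}

#' Export an embedding
#'
#' Writes `<prefix>.tsv` (id plus the `p` coordinates), `<prefix>.mtx`
#' (the coordinate matrix in Matrix Market form) and
#' `<prefix>.eigenvalues.tsv` (one eigenvalue per line).
#'
#' @param embedding a `spectral_embedding`.
#' @param prefix output path prefix.
#' @return The three paths written, invisibly.
#' @export
write_embedding <- function(embedding, prefix) {
  stopifnot(inherits(embedding, "spectral_embedding"))
  etsv <- paste0(prefix, ".tsv")
  emtx <- paste0(prefix, ".mtx")
  ltsv <- paste0(prefix, ".eigenvalues.tsv")
  out <- data.frame(id = rownames(embedding$Z), embedding$Z,
                    check.names = FALSE)
  utils::write.table(out, etsv, sep = "\t", row.names = FALSE, quote = FALSE)
  Matrix::writeMM(methods::as(Matrix::Matrix(embedding$Z, sparse = TRUE),
                              "CsparseMatrix"), emtx)
  utils::write.table(data.frame(eigenvalue = embedding$values), ltsv,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(etsv, emtx, ltsv))
}
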