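# Small fixture builders and independent brute-force oracles used across
# the suite. Oracles deliberately use only base R arithmetic, never the
# package code paths they check.

tiny_corpus <- function() {
  citation_corpus(
    id = c("c1", "c2", "c3"),
    title = c("Alpha beta", "Alpha gamma", "Delta"),
    abstract = c("alpha alpha", "", "delta delta"),
    label = c(1L, 0L, NA))
}

# corpus whose two documents have term shares (0.75, 0.25) and (0.25, 0.75)
# after square-root normalisation of the raw count matrix rbind(c(3,1), c(1,3))
two_share_matrix <- function() {
  X <- Matrix::Matrix(rbind(c(3, 1), c(1, 3)), sparse = TRUE)
  rownames(X) <- c("d1", "d2")
  X
}

# brute-force k-NN label propagation: score every (source, target) pair with
# scalar cosine distances and resolve conflicts by explicit sorting
brute_propagate <- function(labels, vectors, k) {
  ids <- rownames(vectors)
  norms <- apply(vectors, 1, function(v) sqrt(sum(v^2)))
  claims <- list()
  for (sid in names(labels)) {
    s <- match(sid, ids)
    if (norms[s] == 0) next
    d <- rep(NA_real_, nrow(vectors))
    for (j in seq_len(nrow(vectors))) {
      if (j == s || norms[j] == 0) next
      d[j] <- 1 - sum(vectors[s, ] * vectors[j, ]) / (norms[s] * norms[j])
      if (d[j] < 0) d[j] <- 0
    }
    cand <- which(!is.na(d))
    nb <- cand[order(d[cand], cand)]
    nb <- head(nb, k)
    for (j in nb) {
      if (ids[j] %in% names(labels)) next
      claims[[length(claims) + 1L]] <- data.frame(
        id = ids[j], label = unname(labels[sid]), source_id = sid,
        source_idx = s, distance = d[j], stringsAsFactors = FALSE)
    }
  }
  if (length(claims) == 0L) {
    return(data.frame(id = character(), label = integer(),
                      source_id = character(), distance = numeric(),
                      stringsAsFactors = FALSE))
  }
  all <- do.call(rbind, claims)
  out <- lapply(split(all, all$id), function(g) {
    g <- g[order(g$distance, g$source_idx), ]
    g[1L, c("id", "label", "source_id", "distance")]
  })
  out <- do.call(rbind, out)
  out <- out[order(match(out$id, ids)), ]
  rownames(out) <- NULL
  out
}

# independent dense construction of the symmetrically normalised similarity
# operator from a normalised matrix, using base linear algebra only
brute_operator <- function(nm) {
  M <- as.matrix(nm$R)
  C <- M %*% t(M)
  D <- rowSums(C)
  dinv <- ifelse(D > 0, 1 / sqrt(D), 0)
  diag(dinv) %*% C %*% diag(dinv)
}

small_synth <- function(n = 150, seed = 11, scatter = 0, ratio = 0.1) {
  generate_corpus(generator_params(n = n, m = 300, ratio = ratio,
                                   n_topics = 6, doc_length = 40,
                                   scatter_frac = scatter, rng_seed = seed))
}
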