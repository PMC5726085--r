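#' Cosine distance between two vectors
#'
#' `1 - <v, u> / (||v|| ||u||)`, in `[0, 2]`. The normalisation makes the
#' comparison fair between documents of different length, which matters for
#' bag-of-words vectors whose magnitude grows with the word count.
#'
#' @param v,u numeric vectors of equal length and positive norm.
#' @return The cosine distance.
#' @examples
#' cosine_distance(c(1, 1), c(1, 0))  # 1 - 1/sqrt(2)
#' @export
cosine_distance <- function(v, u) {
  stopifnot(length(v) == length(u))
  nv <- sqrt(sum(v^2))
  nu <- sqrt(sum(u^2))
  if (nv == 0 || nu == 0) {
    stop("cosine distance undefined for zero-norm vectors")
  }
  1 - sum(v * u) / (nv * nu)
}

# cross cosine-distance matrix: rows of A (queries) vs rows of B.
# Zero-norm rows give NA entries; callers treat those as unusable.
cosine_distance_matrix <- function(A, B) {
  na <- sqrt(Matrix::rowSums(A^2))
  nb <- sqrt(Matrix::rowSums(B^2))
  G <- as.matrix(Matrix::tcrossprod(A, B))
  D <- 1 - G / outer(na, nb)
  D[!is.finite(D)] <- NA_real_
  # clip round-off outside [0, 2]
  D[D < 0 & !is.na(D)] <- 0
  D
}

#' k nearest neighbours of a citation
#'
#' Returns the `k` citations (excluding the query itself) with the smallest
#' cosine distance to the query in the given feature space, ascending by
#' distance with ties broken by ascending corpus index. Degenerate
#' (zero-norm) candidates are excluded. If fewer than `k` candidates exist,
#' all available are returned.
#'
#' @param d a citation id (row name of `vectors`) or row index.
#' @param vectors numeric matrix of feature vectors, one row per citation in
#'   corpus order (row names are citation ids). Either the TF-IDF matrix or
#'   the rows of a spectral embedding.
#' @param k neighbourhood size.
#' @return Character vector of neighbour ids, nearest first, with the
#'   distances as the `"distances"` attribute.
#' @export
nearest_neighbours <- function(d, vectors, k = 3L) {
  if (is.character(d)) d <- match(d, rownames(vectors))
  stopifnot(!is.na(d), d >= 1, d <= nrow(vectors), k >= 0)
  if (k == 0L) return(character())
  dv <- cosine_distance_matrix(vectors[d, , drop = FALSE], vectors)[1L, ]
  if (is.na(dv[d]) && all(is.na(dv))) {
    stop("query citation has a zero-norm vector; distance undefined")
  }
  dv[d] <- NA_real_
  cand <- which(!is.na(dv))
  ord <- cand[order(dv[cand], cand)]
  take <- utils::head(ord, k)
  out <- rownames(vectors)[take]
  attr(out, "distances") <- unname(dv[take])
  out
}

#' Propagate labels to nearest unlabelled neighbours
#'
#' For every manually labelled citation, its `k` nearest neighbours among
#' all citations are located (cosine distance in the chosen feature space);
#' those neighbours that are unlabelled receive the source's label as a
#' pseudo-label. An unlabelled citation claimed by several sources takes the
#' label of the nearest one (distance ties broken by the source of lower
#' corpus index, for determinism). Manually labelled citations are never
#' relabelled — labelled neighbours are simply skipped — and degenerate
#' zero-norm citations take no part, as sources or targets.
#'
#' Pseudo-labels are intended to be recomputed from scratch from the current
#' manual set at each active-learning iteration; nothing is cached here.
#'
#' @param labels named integer vector of manual labels (names are citation
#'   ids, values 0 or 1). Must be non-empty.
#' @param vectors feature matrix as in [nearest_neighbours()], covering all
#'   citations in corpus order.
#' @param k neighbours per labelled citation (default 3). `k = 0` is a
#'   no-op returning zero pseudo-labels.
#' @return A data frame with one row per pseudo-labelled citation: `id`,
#'   `label`, `source_id`, `distance`, ordered by corpus index.
#' @export
propagate_labels <- function(labels, vectors, k = 3L) {
  if (length(labels) == 0L) stop("label propagation needs >= 1 manual label")
  stopifnot(!is.null(names(labels)), all(labels %in% c(0L, 1L)))
  ids <- rownames(vectors)
  src_idx <- match(names(labels), ids)
  if (anyNA(src_idx)) {
    stop("labelled id(s) missing from feature matrix: ",
         paste(names(labels)[is.na(src_idx)], collapse = ", "))
  }
  empty <- data.frame(id = character(), label = integer(),
                      source_id = character(), distance = numeric(),
                      stringsAsFactors = FALSE)
  if (k == 0L) return(empty)

  norms <- sqrt(Matrix::rowSums(vectors^2))
  degenerate <- norms == 0
  usable_src <- src_idx[!degenerate[src_idx]]
  if (length(usable_src) == 0L) return(empty)

  D <- cosine_distance_matrix(vectors[usable_src, , drop = FALSE], vectors)
  D[, degenerate] <- NA_real_
  D[cbind(seq_along(usable_src), usable_src)] <- NA_real_  # self

  # per source: its k nearest neighbours over ALL citations
  lab_of_src <- labels[match(ids[usable_src], names(labels))]
  manual_set <- ids[src_idx]
  claims_id <- character(); claims_lab <- integer()
  claims_src <- integer(); claims_d <- numeric()
  for (s in seq_along(usable_src)) {
    dv <- D[s, ]
    cand <- which(!is.na(dv))
    nb <- cand[order(dv[cand], cand)]
    nb <- utils::head(nb, k)
    nb <- nb[!(ids[nb] %in% manual_set)]  # labelled neighbours are skipped
    if (length(nb) == 0L) next
    claims_id <- c(claims_id, ids[nb])
    claims_lab <- c(claims_lab, rep.int(lab_of_src[s], length(nb)))
    claims_src <- c(claims_src, rep.int(usable_src[s], length(nb)))
    claims_d <- c(claims_d, dv[nb])
  }
  if (length(claims_id) == 0L) return(empty)

  # conflict resolution: nearest source wins; tie -> lower source index
  ord <- order(match(claims_id, ids), claims_d, claims_src)
  keep <- ord[!duplicated(claims_id[ord])]
  keep <- keep[order(match(claims_id[keep], ids))]
  data.frame(id = claims_id[keep], label = claims_lab[keep],
             source_id = ids[claims_src[keep]], distance = claims_d[keep],
             stringsAsFactors = FALSE)
}
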