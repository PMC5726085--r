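#' Parameters for the synthetic corpus generator
#'
#' The generator emulates the statistical structure of real screening
#' datasets: severe class imbalance (eligible fractions of roughly
#' 0.02-0.14), eligible citations concentrated in a small number of topical
#' clusters, and a minority of eligible "singletons" scattered across
#' otherwise ineligible topics — the hard cases typical of multidisciplinary
#' public-health reviews.
#'
#' Documents follow a mixture-of-topics multinomial model: each topic draws
#' a word distribution once from a symmetric Dirichlet
#' (`topic_concentration`; smaller = sharper, more separated topics), each
#' citation picks one topic, a Poisson token count, and multinomial token
#' draws. `ceiling(n_topics / 5)` topics are reserved for the eligible
#' class; a fraction `scatter_frac` of eligible citations is instead drawn
#' from a random ineligible topic.
#'
#' @param n corpus size.
#' @param m vocabulary size.
#' @param ratio eligible fraction (default 0.05); each citation is eligible
#'   independently with this probability.
#' @param n_topics number of topics (>= 2).
#' @param doc_length mean tokens per citation (Poisson; minimum 1 enforced).
#' @param topic_concentration symmetric Dirichlet concentration of the
#'   per-topic word distributions (default 0.05).
#' @param scatter_frac fraction of eligible citations drawn from off-cluster
#'   topics (default 0.1).
#' @param rng_seed integer seed; the generator is fully deterministic given
#'   it (Mersenne-Twister).
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(n = 2000L, m = 1200L, ratio = 0.05,
                             n_topics = 10L, doc_length = 60,
                             topic_concentration = 0.05,
                             scatter_frac = 0.1, rng_seed = 1L) {
  stopifnot(n >= 2, m >= 2, ratio > 0, ratio < 1, n_topics >= 2,
            doc_length >= 1, topic_concentration > 0,
            scatter_frac >= 0, scatter_frac <= 1)
  if (n_topics > m) stop("n_topics must not exceed the vocabulary size m")
  structure(list(n = as.integer(n), m = as.integer(m), ratio = ratio,
                 n_topics = as.integer(n_topics), doc_length = doc_length,
                 topic_concentration = topic_concentration,
                 scatter_frac = scatter_frac,
                 rng_seed = as.integer(rng_seed)),
            class = "generator_params")
}

rdirichlet1 <- function(m, alpha) {
  g <- stats::rgamma(m, shape = alpha)
  if (sum(g) == 0) g[sample.int(m, 1L)] <- 1  # degenerate draw guard
  g / sum(g)
}

#' Generate a synthetic citation corpus
#'
#' Draws a fully gold-labelled corpus under the topic-mixture model of
#' [generator_params()]. Tokens are synthetic words `w0001 ... w<m>`; the
#' first few tokens of each citation form its title and the rest its
#' abstract (the split is cosmetic — all downstream processing pools the two
#' fields). Generation metadata (parameters, per-citation topic, scatter
#' flag, RNG kind) is attached as the `"meta"` attribute.
#'
#' @param params a [generator_params()].
#' @return A `citation_corpus` (also of class `synthetic_corpus`) with gold
#'   labels and a `"meta"` attribute.
#' @export
generate_corpus <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(params$rng_seed, kind = "Mersenne-Twister")
  n <- params$n; m <- params$m
  words <- sprintf("w%04d", seq_len(m))
  n_elig_topics <- ceiling(params$n_topics / 5)
  elig_topics <- seq_len(n_elig_topics)
  inelig_topics <- setdiff(seq_len(params$n_topics), elig_topics)

  topic_words <- t(vapply(seq_len(params$n_topics), function(t) {
    rdirichlet1(m, params$topic_concentration)
  }, numeric(m)))

  label <- stats::rbinom(n, 1L, params$ratio)
  # guard: screening metrics need at least one of each class
  if (sum(label) == 0L) label[sample.int(n, 1L)] <- 1L
  if (sum(label) == n) label[sample.int(n, 1L)] <- 0L

  scatter <- label == 1L & stats::runif(n) < params$scatter_frac
  topic <- integer(n)
  for (d in seq_len(n)) {
    topic[d] <- if (label[d] == 1L && !scatter[d]) {
      elig_topics[sample.int(length(elig_topics), 1L)]
    } else if (label[d] == 1L) {
      inelig_topics[sample.int(length(inelig_topics), 1L)]
    } else {
      inelig_topics[sample.int(length(inelig_topics), 1L)]
    }
  }

  len <- pmax(1L, stats::rpois(n, params$doc_length))
  title <- character(n); abstract <- character(n)
  for (d in seq_len(n)) {
    cnt <- stats::rmultinom(1L, len[d], topic_words[topic[d], ])[, 1L]
    toks <- sample(rep.int(words, cnt))
    n_title <- min(length(toks), 6L)
    title[d] <- paste(toks[seq_len(n_title)], collapse = " ")
    abstract[d] <- paste(toks[-seq_len(n_title)], collapse = " ")
  }

  corpus <- citation_corpus(sprintf("syn%05d", seq_len(n)), title, abstract,
                            label)
  class(corpus) <- c("synthetic_corpus", class(corpus))
  attr(corpus, "meta") <- list(params = unclass(params), topic = topic,
                               scatter = scatter,
                               eligible_topics = elig_topics,
                               rng_kind = "Mersenne-Twister")
  corpus
}

#' Pairwise-distance structure of an embedded corpus
#'
#' Summarises cosine distances between embedded citations by pair type:
#' eligible-eligible, ineligible-ineligible and mixed. In clustered corpora
#' the eligible-eligible mean falls below the mixed mean — the geometric
#' fact that licenses propagating labels between neighbours. Pairs are
#' subsampled for large corpora.
#'
#' @param corpus a gold-labelled [citation_corpus].
#' @param embedding its `spectral_embedding` (or any feature matrix rows
#'   via a `spectral_embedding`-shaped list).
#' @param n_pairs pairs sampled per type (default 20000).
#' @param sample_seed seed for the pair subsample.
#' @return Data frame with rows `eligible-eligible`,
#'   `ineligible-ineligible`, `mixed`: columns `pair_type`, `n_pairs`,
#'   `mean_distance`, `sd_distance`.
#' @export
structure_report <- function(corpus, embedding, n_pairs = 20000L,
                             sample_seed = 1L) {
  validate_corpus(corpus)
  stopifnot(inherits(embedding, "spectral_embedding"))
  if (anyNA(corpus$label)) stop("structure report needs full gold labels")
  Z <- embedding$Z
  stopifnot(nrow(Z) == nrow(corpus))
  ok <- !embedding$degenerate & sqrt(rowSums(Z^2)) > 0
  pos <- which(corpus$label == 1L & ok)
  neg <- which(corpus$label == 0L & ok)
  set.seed(sample_seed)
  sample_pairs <- function(a, b, same) {
    if (same && length(a) < 2L) return(numeric())
    if (!same && (length(a) < 1L || length(b) < 1L)) return(numeric())
    i <- sample(a, n_pairs, replace = TRUE)
    j <- sample(b, n_pairs, replace = TRUE)
    keep <- i != j
    i <- i[keep]; j <- j[keep]
    zi <- Z[i, , drop = FALSE]; zj <- Z[j, , drop = FALSE]
    1 - rowSums(zi * zj) /
      (sqrt(rowSums(zi^2)) * sqrt(rowSums(zj^2)))
  }
  groups <- list(
    `eligible-eligible` = sample_pairs(pos, pos, TRUE),
    `ineligible-ineligible` = sample_pairs(neg, neg, TRUE),
    mixed = sample_pairs(pos, neg, FALSE))
  do.call(rbind, lapply(names(groups), function(g) {
    d <- groups[[g]]
    data.frame(pair_type = g, n_pairs = length(d),
               mean_distance = if (length(d)) mean(d) else NA_real_,
               sd_distance = if (length(d) > 1L) stats::sd(d) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
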