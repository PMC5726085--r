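#' Confusion counts for a screening round
#'
#' Splits the corpus into the human-screened part (whose labels are taken as
#' correct, so it contributes only true positives `tp_h` and true negatives
#' `tn_h`) and the unscreened remainder, on which the classifier's hard
#' predictions are compared with the gold labels (`tp_a`, `fp_a`, `fn_a`,
#' `tn_a`).
#'
#' @param tp_h,tn_h human-screened eligible / ineligible counts.
#' @param tp_a,fp_a,fn_a,tn_a confusion counts of the automatic predictions
#'   over the unscreened remainder.
#' @return A list of class `confusion_counts` with the six counts plus
#'   `n_h`, `n_a` and `n`.
#' @export
confusion_counts <- function(tp_h, tn_h, tp_a, fp_a, fn_a, tn_a) {
  cnt <- c(tp_h = tp_h, tn_h = tn_h, tp_a = tp_a, fp_a = fp_a,
           fn_a = fn_a, tn_a = tn_a)
  if (any(cnt < 0)) stop("confusion counts must be non-negative")
  out <- as.list(cnt)
  out$n_h <- tp_h + tn_h
  out$n_a <- tp_a + fp_a + fn_a + tn_a
  out$n <- out$n_h + out$n_a
  structure(out, class = "confusion_counts")
}

#' Yield of a screening round
#'
#' Fraction of all eligible citations identified, counting both the
#' human-screened eligibles and those the classifier correctly predicts
#' eligible in the remainder: `(tp_h + tp_a) / (tp_h + tp_a + fn_a)`.
#' At full manual screening the remainder is empty and yield is 1.
#'
#' @param cc a [confusion_counts()].
#' @return Yield in `[0, 1]`.
#' @export
screening_yield <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  den <- cc$tp_h + cc$tp_a + cc$fn_a
  if (den == 0) {
    stop("yield undefined: corpus contains no eligible citations")
  }
  (cc$tp_h + cc$tp_a) / den
}

#' Burden of a screening round
#'
#' Fraction of the corpus a human must read: the citations already screened
#' plus everything the classifier flags eligible (which the reviewer would
#' then screen manually): `(n_h + tp_a + fp_a) / n`.
#'
#' @param cc a [confusion_counts()].
#' @return Burden in `[0, 1]`.
#' @export
screening_burden <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  if (cc$n == 0) stop("burden undefined for an empty corpus")
  (cc$n_h + cc$tp_a + cc$fp_a) / cc$n
}

#' Utility of a screening round
#'
#' Weighted combination `(beta * yield + (1 - burden)) / (beta + 1)`.
#' The default `beta = 19` encodes the expert judgement that finding every
#' eligible citation is 19 times as important as saving reviewer effort;
#' a fully manual screen therefore scores `19/20 = 0.95`.
#'
#' @param yield,burden values in `[0, 1]`.
#' @param beta positive weighting factor (default 19).
#' @return Utility in `[0, 1]`.
#' @export
screening_utility <- function(yield, burden, beta = 19) {
  stopifnot(beta > 0, all(yield >= 0 & yield <= 1),
            all(burden >= 0 & burden <= 1))
  (beta * yield + (1 - burden)) / (beta + 1)
}

#' Average utility over the first R iterations
#'
#' Mean of the per-iteration utilities up to iteration `R`; a smoother
#' summary of early-screening performance than the point utility, since it
#' rewards methods that perform well throughout the run-up.
#'
#' @param utilities numeric vector of per-iteration utilities.
#' @param R number of leading iterations to average (`1 <= R <=
#'   length(utilities)`).
#' @return The average utility at `R`.
#' @export
average_utility <- function(utilities, R) {
  R <- as.integer(R)
  if (R < 1L || R > length(utilities)) {
    stop("R must lie in [1, ", length(utilities), "]")
  }
  mean(utilities[seq_len(R)])
}

#' Manual screening baseline
#'
#' Simulates conventional screening: citations are read one at a time in a
#' seeded random order, with no classifier assistance. At every step the
#' remainder is implicitly predicted ineligible (`tp_a = fp_a = 0`,
#' `fn_a` = unscreened eligibles), so utility grows approximately linearly
#' with the number of citations screened.
#'
#' @param corpus a fully gold-labelled [citation_corpus].
#' @param order_seed integer seed for the screening order.
#' @param beta utility weighting factor.
#' @return A `screening_trajectory` data frame with one row per screened
#'   citation.
#' @export
manual_baseline <- function(corpus, order_seed = 1L, beta = 19) {
  validate_corpus(corpus)
  if (anyNA(corpus$label)) stop("manual baseline needs full gold labels")
  n <- nrow(corpus)
  pos_total <- sum(corpus$label == 1L)
  if (pos_total == 0L) {
    stop("yield undefined: corpus contains no eligible citations")
  }
  set.seed(order_seed)
  ord <- sample.int(n)
  y <- corpus$label[ord]
  tp_h <- cumsum(y == 1L)
  n_h <- seq_len(n)
  yield <- tp_h / pos_total
  burden <- n_h / n
  traj <- data.frame(iteration = n_h, n_manual = n_h, n_pseudo = 0L,
                     yield = yield, burden = burden,
                     utility = screening_utility(yield, burden, beta))
  class(traj) <- c("screening_trajectory", "data.frame")
  attr(traj, "screened_ids") <- corpus$id[ord]
  attr(traj, "n") <- n
  traj
}

#' One-tailed sign test
#'
#' Exact binomial tail probability of observing at least `wins` successes in
#' `n` paired comparisons under the null of equal chance:
#' `P(X >= wins | n, 1/2)`. Six wins out of six give `1/64 = 0.015625`.
#'
#' @param wins number of datasets where the candidate beats the baseline.
#' @param n number of paired comparisons (ties dropped beforehand).
#' @return The one-tailed p-value.
#' @export
sign_test_pvalue <- function(wins, n) {
  stopifnot(wins >= 0, n >= wins, n >= 0)
  if (n == 0L) return(1)
  if (wins == 0) return(1)
  # exact binomial-coefficient sum; half-powers are exact in doubles here
  if (n <= 1000) {
    sum(choose(n, seq.int(wins, n))) / 2^n
  } else {
    stats::pbinom(wins - 1, size = n, prob = 0.5, lower.tail = FALSE)
  }
}

#' Workload of fully manual screening
#'
#' Hours required to hand-screen a corpus at a constant per-abstract
#' decision time (30 seconds per abstract for an experienced reviewer).
#'
#' @param n_citations corpus size.
#' @param seconds_per_abstract mean decision time (default 30).
#' @return Hours of reviewer work.
#' @examples
#' manual_workload_hours(15544)  # about 130 h, over 3 weeks full time
#' @export
manual_workload_hours <- function(n_citations, seconds_per_abstract = 30) {
  n_citations * seconds_per_abstract / 3600
}

checkpoint_iteration <- function(traj, fraction) {
  n <- attr(traj, "n")
  hit <- which(traj$n_manual / n >= fraction)
  if (length(hit) == 0L) {
    stop("no iteration reaches a manual fraction of ", fraction)
  }
  hit[1L]
}

#' Aggregate repeated screening runs at reporting checkpoints
#'
#' For each checkpoint fraction, finds in every trajectory the first
#' iteration whose manually screened fraction reaches it (iterations are
#' batch-quantised) and summarises, across runs, both the average utility
#' up to that iteration and the point utility at it. Mean and sample
#' standard deviation (`ddof = 1`) are reported.
#'
#' @param trajectories list of `screening_trajectory` objects from repeated
#'   seeded runs of one method on one corpus.
#' @param checkpoints fractions in `(0, 1]` (default 5%, 10%, 25%, 100%).
#' @return Data frame with one row per checkpoint: `checkpoint`, `n_runs`,
#'   `mean_avg_utility`, `sd_avg_utility`, `mean_utility`, `sd_utility`.
#' @export
aggregate_trajectories <- function(trajectories,
                                   checkpoints = c(0.05, 0.1, 0.25, 1)) {
  stopifnot(length(trajectories) >= 1L,
            all(vapply(trajectories, inherits, TRUE,
                       "screening_trajectory")))
  stopifnot(all(checkpoints > 0 & checkpoints <= 1))
  ns <- vapply(trajectories, attr, 0, "n")
  if (length(unique(ns)) != 1L) {
    stop("trajectories come from corpora of different sizes")
  }
  out <- lapply(checkpoints, function(cp) {
    avg_u <- vapply(trajectories, function(tr) {
      average_utility(tr$utility, checkpoint_iteration(tr, cp))
    }, 0)
    pt_u <- vapply(trajectories, function(tr) {
      tr$utility[checkpoint_iteration(tr, cp)]
    }, 0)
    data.frame(checkpoint = cp, n_runs = length(trajectories),
               mean_avg_utility = mean(avg_u),
               sd_avg_utility = stats::sd(avg_u),
               mean_utility = mean(pt_u),
               sd_utility = stats::sd(pt_u))
  })
  do.call(rbind, out)
}

#' Simulate the method grid on one corpus
#'
#' Runs every requested `mode x semi` variant `repeats` times with seeds
#' `rng_seeds`, plus (optionally) the manual baseline, and aggregates each
#' variant at the checkpoints. Seeds are matched across variants, so runs
#' are paired for sign-test comparisons.
#'
#' @param corpus fully labelled [citation_corpus].
#' @param modes,semis character vectors of variants to cross.
#' @param repeats number of seeded repeats (default 10).
#' @param rng_seeds seeds to use; default `seq_len(repeats)`.
#' @param checkpoints reporting fractions.
#' @param p spectral embedding dimension.
#' @param max_fraction passed to [al_config()]; lets large studies stop
#'   after the last checkpoint of interest.
#' @param ... further arguments to [al_config()] (e.g. `k`, `cost`).
#' @return A list with `summary` (one aggregated data frame row-bound over
#'   variants, with `mode` and `semi` columns) and `trajectories` (nested
#'   list by variant then seed).
#' @export
simulate_screening <- function(corpus,
                               modes = c("certainty", "uncertainty"),
                               semis = c("none", "bow", "spectral"),
                               repeats = 10L, rng_seeds = seq_len(repeats),
                               checkpoints = c(0.05, 0.1, 0.25, 1),
                               p = 50L, max_fraction = 1, ...) {
  validate_corpus(corpus)
  if (anyNA(corpus$label)) {
    stop("simulation needs gold labels for every citation; missing: ",
         paste(utils::head(corpus$id[is.na(corpus$label)], 5L),
               collapse = ", "))
  }
  bow <- tfidf_matrix(corpus)
  embedding <- NULL
  if ("spectral" %in% semis) {
    embedding <- embed_corpus(corpus, p = min(p, nrow(corpus)))
  }
  grid <- expand.grid(mode = modes, semi = semis, stringsAsFactors = FALSE)
  trajectories <- list()
  summaries <- list()
  for (g in seq_len(nrow(grid))) {
    key <- paste(grid$mode[g], grid$semi[g], sep = "_")
    runs <- lapply(rng_seeds, function(s) {
      cfg <- al_config(mode = grid$mode[g], semi = grid$semi[g],
                       rng_seed = s, max_fraction = max_fraction, ...)
      run_active_learning(corpus, cfg, bow = bow, embedding = embedding)
    })
    trajectories[[key]] <- runs
    agg <- aggregate_trajectories(runs,
                                  checkpoints = checkpoints[checkpoints <=
                                                              max_fraction])
    agg$mode <- grid$mode[g]
    agg$semi <- grid$semi[g]
    summaries[[key]] <- agg
  }
  list(summary = do.call(rbind, c(summaries, list(make.row.names = FALSE))),
       trajectories = trajectories)
}
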