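test_that("yield, burden and utility match hand-evaluated examples", {
  cc <- confusion_counts(tp_h = 5, tn_h = 15, tp_a = 8, fp_a = 12,
                         fn_a = 2, tn_a = 58)
  expect_equal(screening_yield(cc), 13 / 15, tolerance = 1e-12)
  expect_equal(screening_burden(cc), 0.40, tolerance = 1e-12)
  expect_equal(screening_utility(13 / 15, 0.40),
               (19 * 13 / 15 + 0.6) / 20, tolerance = 1e-12)

  # full manual screening: everything found, everything read
  full <- confusion_counts(tp_h = 7, tn_h = 93, tp_a = 0, fp_a = 0,
                           fn_a = 0, tn_a = 0)
  expect_equal(screening_yield(full), 1)
  expect_equal(screening_burden(full), 1)
  expect_equal(screening_utility(1, 1), 0.95)
  expect_equal(screening_utility(1, 0), 1)

  none <- confusion_counts(tp_h = 0, tn_h = 0, tp_a = 0, fp_a = 0,
                           fn_a = 3, tn_a = 40)
  expect_equal(screening_yield(none), 0)
  expect_equal(screening_burden(none), 0)
  expect_error(screening_yield(confusion_counts(0, 5, 0, 0, 0, 5)),
               "no eligible")
})

test_that("utility rises with yield and falls with burden on a grid", {
  g <- expand.grid(y = seq(0, 1, 0.25), b = seq(0, 1, 0.25))
  u <- screening_utility(g$y, g$b)
  expect_true(all(u >= 0 & u <= 1))
  for (b in unique(g$b)) {
    expect_true(all(diff(u[g$b == b][order(g$y[g$b == b])]) > 0))
  }
  for (y in unique(g$y)) {
    expect_true(all(diff(u[g$y == y][order(g$b[g$y == y])]) < 0))
  }
})

test_that("average utility is a truncated running mean", {
  expect_equal(average_utility(c(0.5, 0.7), 2), 0.6)
  expect_equal(average_utility(c(0.4, 0.9, 0.1), 1), 0.4)
  expect_equal(average_utility(rep(0.3, 6), 4), 0.3)
  # invariant to anything after iteration R
  u <- c(0.2, 0.4, 0.6, 0.99)
  expect_equal(average_utility(u, 2), average_utility(c(u[1:2], 0, 0), 2))
  expect_error(average_utility(c(0.1), 2), "R must lie")
})

test_that("sign test gives the exact binomial tail", {
  expect_equal(sign_test_pvalue(6, 6), 1 / 64)
  expect_equal(round(sign_test_pvalue(6, 6), 4), 0.0156)
  expect_equal(sign_test_pvalue(5, 6), 7 / 64)
  expect_equal(sign_test_pvalue(0, 9), 1)
  for (n in c(3, 6, 10)) expect_equal(sign_test_pvalue(n, n), 2^(-n))
})

test_that("screening a large review by hand costs weeks of work", {
  expect_equal(manual_workload_hours(15544), 15544 * 30 / 3600)
  expect_equal(round(manual_workload_hours(15544)), 130)
  expect_equal(manual_workload_hours(120, 60), 2)
})

test_that("manual baseline grows linearly and ends at utility 0.95", {
  co <- small_synth(n = 400, seed = 13, ratio = 0.1)
  tr <- manual_baseline(co, order_seed = 3)
  expect_identical(nrow(tr), 400L)
  last <- tr[nrow(tr), ]
  expect_equal(c(last$yield, last$burden, last$utility), c(1, 1, 0.95))
  # expected yield at half screening is about one half over random orders
  mid <- vapply(1:20, function(s) {
    trs <- manual_baseline(co, order_seed = s)
    trs$yield[200]
  }, 0)
  expect_lt(abs(mean(mid) - 0.5), 0.05)
  empty <- citation_corpus(c("a", "b"), c("t", "t"), c("x", "y"), c(0L, 0L))
  expect_error(manual_baseline(empty), "no eligible")
})

test_that("aggregation summarises runs at checkpoint iterations", {
  mk <- function(us, n_manual, n = 100) {
    tr <- data.frame(iteration = seq_along(us), n_manual = n_manual,
                     n_pseudo = 0L, yield = us, burden = us, utility = us)
    class(tr) <- c("screening_trajectory", "data.frame")
    attr(tr, "n") <- n
    tr
  }
  t1 <- mk(c(0.2, 0.4, 0.6), c(10L, 50L, 100L))
  t2 <- mk(c(0.4, 0.6, 0.8), c(10L, 50L, 100L))
  agg <- aggregate_trajectories(list(t1, t2), checkpoints = c(0.5, 1))
  # checkpoint 0.5 maps to iteration 2: avg utilities 0.3 and 0.5
  expect_equal(agg$mean_avg_utility[1], 0.4)
  expect_equal(agg$sd_avg_utility[1], sd(c(0.3, 0.5)))
  expect_equal(agg$sd_avg_utility[1], 0.1414214, tolerance = 1e-6)
  # point utility at the checkpoint is also reported
  expect_equal(agg$mean_utility[1], 0.5)
  # checkpoint 1 uses the final iteration
  expect_equal(agg$mean_utility[2], 0.7)
  # identical runs have zero spread
  same <- aggregate_trajectories(list(t1, t1), checkpoints = 1)
  expect_equal(same$sd_avg_utility, 0)
  expect_error(aggregate_trajectories(list(t1, mk(0.5, 10L, n = 50))),
               "different sizes")
})

test_that("the simulation harness crosses variants with matched seeds", {
  co <- small_synth(n = 70, seed = 21, ratio = 0.15)
  sim <- simulate_screening(co, modes = "certainty",
                            semis = c("none", "bow"), repeats = 2,
                            checkpoints = c(0.25, 1), p = 20,
                            seed_size = 10, batch_size = 10)
  expect_identical(length(sim$trajectories), 2L)
  expect_identical(names(sim$trajectories),
                   c("certainty_none", "certainty_bow"))
  expect_identical(nrow(sim$summary), 4L)
  expect_true(all(c("mode", "semi", "mean_avg_utility") %in%
                    names(sim$summary)))
  # matched seeds: rerunning gives the identical summary
  sim2 <- simulate_screening(co, modes = "certainty",
                             semis = c("none", "bow"), repeats = 2,
                             checkpoints = c(0.25, 1), p = 20,
                             seed_size = 10, batch_size = 10)
  expect_identical(sim$summary, sim2$summary)
})
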