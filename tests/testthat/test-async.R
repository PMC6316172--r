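test_that("a synchronous fixed point is absorbing under any update order", {
  m <- concrete_model(toy_pair(), logical(), c(A = 8L, B = 8L))
  for (seed in 1:5) {
    states <- async_trajectory(m, c(A = TRUE, B = TRUE), max_steps = 30,
                               seed = seed)
    expect_true(all(states))
  }
})

test_that("asynchronous runs replay identically under a fixed seed", {
  net <- toy_chain()
  m <- concrete_model(net, c(TRUE, TRUE), c(A = 8L, B = 8L, C = 8L))
  sched <- schedule(c(S = TRUE))
  s1 <- async_trajectory(m, c(), sched, max_steps = 40, seed = 9)
  s2 <- async_trajectory(m, c(), sched, max_steps = 40, seed = 9)
  expect_identical(s1, s2)
})

test_that("empirical reachability matches the exact Markov chain", {
  # 3-gene chain driven by a signal: reachability of C within k updates is
  # computable exactly from the uniform-update transition matrix
  net <- toy_chain()
  m <- concrete_model(net, c(TRUE, TRUE), c(A = 8L, B = 8L, C = 8L))
  sched <- schedule(c(S = TRUE))
  k <- 8
  p_exact <- async_reach_prob_exact(m, c(), sched, c(C = TRUE), k)
  n_runs <- 3000
  hits <- vapply(seq_len(n_runs), function(r) {
    states <- async_trajectory(m, c(), sched, max_steps = k, seed = r)
    any(states[, "C"])
  }, NA)
  expect_lt(abs(mean(hits) - p_exact), 0.03)
})

test_that("empirical reachability tightens as the run count grows", {
  net <- toy_chain()
  m <- concrete_model(net, c(TRUE, TRUE), c(A = 8L, B = 8L, C = 8L))
  sched <- schedule(c(S = TRUE))
  p_exact <- async_reach_prob_exact(m, c(), sched, c(C = TRUE), 6)
  est <- function(n, off) {
    mean(vapply(seq_len(n), function(r) {
      any(async_trajectory(m, c(), sched, max_steps = 6,
                           seed = off + r)[, "C"])
    }, NA))
  }
  # averaged absolute error over a few repetitions shrinks with n
  err_small <- mean(abs(vapply(0:4, function(b) est(40, 1000 * b), 0) -
                          p_exact))
  err_large <- mean(abs(vapply(0:4, function(b) est(640, 1000 * b + 500),
                               0) - p_exact))
  expect_lt(err_large, err_small + 0.02)
})

test_that("the async battery summarises reachability and ordering queries", {
  net <- toy_chain()
  m <- concrete_model(net, c(TRUE, TRUE), c(A = 8L, B = 8L, C = 8L))
  battery <- list(
    list(name = "reach_C", type = "reachability",
         sched = schedule(c(S = TRUE)), initial = c(),
         target = c(C = TRUE)),
    list(name = "reach_C_no_signal", type = "reachability",
         sched = schedule(c(S = FALSE)), initial = c(),
         target = c(C = TRUE)),
    list(name = "A_before_C", type = "ordering",
         sched = schedule(c(S = TRUE)), initial = c(),
         geneX = "A", geneY = "C"))
  res <- async_battery(m, battery, n_runs = 200, max_steps = 25, seed = 4)
  s <- res$summary
  expect_identical(s$outcome[s$query == "reach_C"], "positive")
  expect_identical(s$outcome[s$query == "reach_C_no_signal"], "negative")
  expect_identical(s$outcome[s$query == "A_before_C"], "always_before")
  expect_true(all(s$fraction >= 0 & s$fraction <= 1))
})
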