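# Toy cABN used across prediction tests: S drives A (definite); A drives B
# through an optional edge whose presence the constraints leave open, so
# queries about B genuinely split the model set.
toy_cabn <- function() {
  net <- abn(data.frame(name = c("S", "A", "B"),
                        role = c("signal", "gene", "gene")),
             data.frame(source = c("S", "A"), target = c("A", "B"),
                        sign = "positive", definite = c(TRUE, FALSE)),
             allowed_conditions = list(A = 8L, B = 8L))
  con <- experiment("warmup", schedule(c(S = TRUE)), c(),
                    expectation("reached", c(A = TRUE)), bound = 6)
  cabn(net, list(con))
}

test_that("prediction outcomes follow the hypothesis/null trichotomy", {
  cb <- toy_cabn()
  sched <- schedule(c(S = TRUE))
  # A activates in every model (definite signal axis); the full state only
  # settles at step 2 in models that instantiate the A -> B edge
  st_a <- steps_to_target(cb, sched, c(), c(A = TRUE), bound = 6)
  expect_identical(st_a$some_range[1], 1L)
  expect_identical(st_a$all_step, 2L)
  # B depends on the optional edge: some models reach, some never
  st_b <- steps_to_target(cb, sched, c(), c(B = TRUE), bound = 6)
  expect_true(is.na(st_b$all_step))
  expect_identical(st_b$some_range[1], 2L)
  # with S off neither A nor B can ever activate: explicit never
  st_off <- steps_to_target(cb, schedule(c(S = FALSE)), c(),
                            c(A = TRUE), bound = 6)
  expect_identical(st_off$outcome, "never")
})

test_that("steps_to_target matches exhaustive enumeration on toys", {
  for (seed in 501:512) {
    inst <- random_instance(seed, max_constraints = 1)
    syn <- synthesize(inst$net, inst$cons)
    if (syn$status != "satisfiable") next
    bf <- bf_synthesize(inst$net, inst$cons)
    genes <- network_genes(inst$net)
    target <- stats::setNames(TRUE, genes[1])
    sched <- schedule(stats::setNames(
      rep(TRUE, length(network_signals(inst$net))),
      network_signals(inst$net)))
    bound <- 6
    cb <- cabn(inst$net, inst$cons)
    st <- steps_to_target(cb, sched, c(), target, bound = bound)
    # oracle: simulate every consistent model
    idx <- which(bf$consistent)
    stable_at <- sapply(idx, function(i) {
      m <- concrete_model(inst$net, bf$space$E[i, ], bf$space$S[i, ])
      traj <- sync_trajectory(m, c(), sched, bound)
      ok <- vapply(0:bound, function(s) {
        nxt <- if (s == bound) traj$next_state else traj$states[s + 2L, ]
        abnsynth:::state_matches(traj$states[s + 1L, ], target) &&
          all(traj$states[s + 1L, ] == nxt)
      }, NA)
      if (any(ok)) min(which(ok)) - 1L else NA_integer_
    })
    if (all(is.na(stable_at))) {
      expect_identical(st$outcome, "never", info = paste("seed", seed))
    } else {
      expect_identical(st$some_range[1], as.integer(min(stable_at,
                                                        na.rm = TRUE)),
                       info = paste("seed", seed))
      exp_all <- if (any(is.na(stable_at))) NA_integer_
                 else as.integer(max(stable_at))
      expect_identical(st$all_step, exp_all, info = paste("seed", seed))
    }
  }
})

test_that("permanent activation steps respect some <= all ordering", {
  cb <- toy_cabn()
  sched <- schedule(c(S = TRUE))
  act <- activation_step(cb, "A", sched, c(), bound = 6)
  expect_identical(act$first_step_some, 1L)
  expect_identical(act$first_step_all, 1L)
  act_b <- activation_step(cb, "B", sched, c(), bound = 6)
  expect_identical(act_b$first_step_some, 2L)
  expect_true(is.na(act_b$first_step_all))
  expect_error(
    activation_step(cb, "A", schedule(c(S = TRUE), clamp("A", FALSE)),
                    c()), "clamped Low")
})

test_that("comparing a schedule against itself is reflexively never-slower", {
  cb <- toy_cabn()
  sched <- schedule(c(S = TRUE))
  res <- compare_schedules(cb, sched, sched, c(A = TRUE), initial = c(),
                           bound = 6)
  expect_true(res$A_never_slower)
  expect_true(res$B_never_slower)
  expect_identical(res$outcome, "equivalent")
})

test_that("a head start is detected by paired-schedule comparison", {
  cb <- toy_cabn()
  fast <- schedule(c(S = TRUE), clamp("A", TRUE))   # A High from step 0
  slow <- schedule(c(S = TRUE))                     # A High from step 1
  res <- compare_schedules(cb, fast, slow, c(A = TRUE), initial = c(),
                           bound = 6)
  expect_true(res$A_never_slower)
  expect_false(res$B_never_slower)
  expect_identical(res$outcome, "A_never_slower")
})

test_that("a forced gene always precedes a gene that starts Low", {
  cb <- toy_cabn()
  sched <- schedule(c(S = TRUE), clamp("A", TRUE))
  expect_identical(precedes(cb, "A", "B", sched, c(), bound = 6),
                   "always_before")
  # B can never be active before A in any model (B needs A)
  expect_identical(precedes(cb, "A", "B", schedule(c(S = TRUE)), c(),
                            bound = 6), "always_before")
})

test_that("essentiality separates required from dispensable components", {
  cb <- toy_cabn()
  sched <- schedule(c(S = TRUE))
  # without A, B can never turn on: A is required for target B
  expect_identical(essentiality(cb, "A", sched, c(), c(B = TRUE),
                                bound = 6), "required")
  # B has no outgoing edges and is Low in target {A High}: dispensable
  expect_identical(essentiality(cb, "B", sched, c(), c(A = TRUE),
                                bound = 6), "dispensable")
  expect_error(essentiality(cb, "S", sched, c(), c(A = TRUE)), "signal")
})

test_that("cocktail queries clamp the cocktail and warn on unknown factors", {
  cb <- toy_cabn()
  expect_warning(
    out <- cocktail_outcome(cb, c("A", "cMyc"), c(S = FALSE),
                            c(A = TRUE), bound = 6),
    "cMyc")
  expect_identical(out, "reprograms")
  # empty cocktail with no inputs cannot activate anything
  expect_identical(
    cocktail_outcome(cb, character(), c(S = FALSE), c(A = TRUE),
                     bound = 6), "fails")
})

test_that("prediction scoring computes plain and conservative accuracy", {
  preds <- c(q1 = "positive", q2 = "negative", q3 = "no_prediction",
             q4 = "positive")
  outcomes <- data.frame(query = c("q1", "q2", "q3", "q4", "q5"),
                         result = c("supports-positive",
                                    "supports-positive",
                                    "supports-negative",
                                    "supports-positive",
                                    "supports-negative"))
  sc <- score_predictions(preds, outcomes)
  expect_identical(sc$n_correct, 2L)       # q1, q4
  expect_identical(sc$n_incorrect, 1L)     # q2
  expect_identical(sc$n_no_prediction, 1L)
  expect_equal(sc$accuracy, 2 / 3)
  expect_equal(sc$conservative_accuracy, 2 / 4)
  expect_identical(sc$unmapped, "q5")
  all_right <- score_predictions(c(q1 = "positive"),
                                 data.frame(query = "q1",
                                            result = "supports-positive"))
  expect_equal(all_right$accuracy, 1)
})

test_that("definitive predictions never contradict a generating ground truth", {
  for (seed in c(3, 9)) {
    gt <- sample_ground_truth(seed = seed)
    obs <- generate_observations(gt, seed = seed)
    cb <- cabn(gt$network, obs$constraints)
    preds <- run_query_battery(cb, obs$queries)
    sc <- score_predictions(preds, obs$outcomes)
    expect_identical(sc$n_incorrect, 0L, info = paste("seed", seed))
  }
})
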