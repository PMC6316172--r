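test_that("a single optional edge is instantiated when a constraint needs it", {
  net <- abn(c("A", "B"),
             data.frame(source = "A", target = "B", sign = "positive",
                        definite = FALSE))
  con <- experiment("ab", schedule(), c(A = TRUE),
                    expectation("reached", c(B = TRUE), 1, 1), bound = 3)
  syn <- synthesize(net, list(con))
  expect_identical(syn$status, "satisfiable")
  expect_true(syn$witness$chosen_optional)
  expect_identical(classify_interactions(net, list(con))[["A->B"]],
                   "required")
})

test_that("contradictory expectations are unsatisfiable", {
  net <- abn(c("A", "B"),
             data.frame(source = "A", target = "B", sign = "positive",
                        definite = FALSE))
  con <- experiment("bad", schedule(), c(A = TRUE),
                    list(expectation("never", c(B = TRUE), 0, 3),
                         expectation("reached", c(B = TRUE), 1, 1)),
                    bound = 3)
  expect_identical(synthesize(net, list(con))$status, "unsatisfiable")
  expect_identical(count_models(net, list(con), cap = 100)$count, 0L)
  expect_error(classify_interactions(net, list(con)), "unsatisfiable")
})

test_that("an unconstrained space counts 2^n topologies times conditions", {
  net <- abn(c("A", "B"),
             data.frame(source = c("A", "A"), target = c("B", "B"),
                        sign = c("positive", "negative"),
                        definite = FALSE),
             allowed_conditions = list(A = 0L, B = 0L))
  cm <- count_models(net, list(), cap = 100)
  expect_identical(cm$count, 4L)   # 2 optional edges, single conditions
  expect_false(cm$capped)
  cl <- classify_interactions(net, list())
  expect_true(all(cl == "possible"))
})

test_that("engine agrees with brute force on random instances", {
  for (seed in 101:140) {
    inst <- random_instance(seed)
    bf <- bf_synthesize(inst$net, inst$cons)
    syn <- synthesize(inst$net, inst$cons)
    expect_identical(syn$status, bf$status, info = paste("seed", seed))
    cm <- count_models(inst$net, inst$cons, cap = 1e6)
    expect_identical(cm$count, bf$count, info = paste("seed", seed))
    if (bf$status == "satisfiable") {
      if (length(optional_interactions(inst$net))) {
        cl <- classify_interactions(inst$net, inst$cons)
        expect_identical(unname(cl), unname(bf$classification),
                         info = paste("seed", seed))
      }
      cu <- classify_conditions(inst$net, inst$cons)
      for (g in names(cu)) {
        expect_identical(unname(cu[[g]]),
                         unname(bf$condition_usage[[g]]),
                         info = paste("seed", seed, "gene", g))
      }
    }
  }
})

test_that("minimal model matches the brute-force minimum", {
  for (seed in 201:215) {
    inst <- random_instance(seed)
    bf <- bf_synthesize(inst$net, inst$cons)
    if (bf$status != "satisfiable") next
    mm <- minimal_model(inst$net, inst$cons)
    bf_min <- min(rowSums(cbind(
      bf$space$E[bf$consistent, , drop = FALSE]))) +
      sum(inst$net$interactions$definite)
    expect_identical(mm$n_interactions, as.integer(bf_min),
                     info = paste("seed", seed))
    expect_true(all(vapply(inst$cons, check_constraint,
                           model = mm$model, FUN.VALUE = NA)))
  }
})

test_that("an all-definite network is its own minimal model", {
  net <- toy_pair()
  mm <- minimal_model(net, list())
  expect_identical(mm$n_interactions, 2L)
})

test_that("component deletion reports per-component satisfiability", {
  net <- toy_chain()
  con <- experiment("chain", schedule(c(S = TRUE)), c(),
                    expectation("reached", c(C = TRUE)), bound = 5)
  scan <- component_deletion_scan(net, list(con))
  # B is the only route from A to C, so deleting it breaks the constraint
  expect_identical(unname(scan["B"]), "unsatisfiable")
  expect_identical(unname(scan["A"]), "unsatisfiable")
  # C removal strips the only expectation, leaving nothing to violate
  expect_identical(unname(scan["C"]), "satisfiable")
  expect_error(component_deletion_scan(net, list(con), components = "S"),
               "signal")
})

test_that("adding a constraint never shrinks required or relaxes disallowed", {
  for (seed in 301:315) {
    inst <- random_instance(seed, max_constraints = 2)
    if (length(inst$cons) < 2 ||
        !length(optional_interactions(inst$net))) next
    s1 <- synthesize(inst$net, inst$cons[1])
    s2 <- synthesize(inst$net, inst$cons)
    if (s1$status != "satisfiable" || s2$status != "satisfiable") next
    c1 <- classify_interactions(inst$net, inst$cons[1])
    c2 <- classify_interactions(inst$net, inst$cons)
    expect_true(all(which(c1 == "required") %in% which(c2 == "required")))
    expect_true(all(which(c1 == "disallowed") %in%
                      which(c2 == "disallowed")))
  }
})

test_that("random ABN controls are reproducible and preserve shape", {
  net <- toy_chain()
  con <- experiment("chain", schedule(c(S = TRUE)), c(),
                    expectation("reached", c(C = TRUE)), bound = 5)
  r1 <- random_abn_control(net, list(con), n_models = 12, seed = 5)
  r2 <- random_abn_control(net, list(con), n_models = 12, seed = 5)
  expect_identical(r1$n_satisfiable, r2$n_satisfiable)
  expect_lte(r1$n_satisfiable, 12L)
})

test_that("solver witnesses re-simulate correctly on every query", {
  for (seed in 401:420) {
    inst <- random_instance(seed)
    syn <- synthesize(inst$net, inst$cons)
    if (syn$status != "satisfiable") next
    expect_true(all(vapply(inst$cons, check_constraint,
                           model = syn$witness, FUN.VALUE = NA)))
  }
})
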