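test_that("bulk discretization uses the inclusive half-reference rule", {
  ref <- c(Oct4 = 10, Sox2 = 8, Nanog = 4)
  expect_true(all(discretize_bulk(ref, ref)))
  exact_half <- ref * 0.5
  expect_true(all(discretize_bulk(exact_half, ref)))   # inclusive boundary
  expect_false(any(discretize_bulk(ref * 0.49, ref)))
  expect_error(discretize_bulk(ref, c(Oct4 = 0, Sox2 = 8, Nanog = 4)),
               "positive")
})

test_that("the GOF18 EpiSC state falls out of the discretization rule", {
  lib <- discrete_state_library()
  tfs <- names(lib$naive_ESC)
  ref <- stats::setNames(rep(100, length(tfs)), tfs)
  expr <- stats::setNames(rep(1, length(tfs)), tfs)
  expr[c("Oct4", "Sox2", "Sall4")] <- 100
  got <- discretize_bulk(expr, ref)
  expect_identical(got, lib$GOF18_EpiSC[tfs])
})

test_that("single-cell 2-means separates well-separated log-normal modes", {
  set.seed(1)
  n <- 100
  mode <- stats::runif(n) < 0.5
  x <- stats::rnorm(n, ifelse(mode, 4, 1), 0.3)
  res <- discretize_single_cell(cbind(g1 = x))
  expect_gt(res$threshold[["g1"]], 2)
  expect_lt(res$threshold[["g1"]], 3)
  expect_gte(mean(res$binary[, "g1"] == mode), 0.99)
  expect_false(res$degenerate[["g1"]])
})

test_that("single-cell 2-means recovers an unbalanced minority mode", {
  set.seed(2)
  n <- 200
  mode <- stats::runif(n) < 0.1
  x <- stats::rnorm(n, ifelse(mode, 4, 1), 0.3)
  res <- discretize_single_cell(cbind(g = x))
  expect_gte(mean(res$binary[, "g"] == mode), 0.95)
})

test_that("constant single-cell expression is flagged degenerate", {
  res <- discretize_single_cell(cbind(g = rep(2, 10)))
  expect_true(res$degenerate[["g"]])
  expect_false(any(res$binary[, "g"]))
  expect_true(is.na(res$threshold[["g"]]))
})

test_that("the six resetting constraints have the documented structure", {
  rc <- builtin_resetting_constraints()
  expect_length(rc$experiments, 6L)
  expect_length(rc$comparatives, 1L)
  expect_true(all(vapply(rc$experiments, function(e) e$bound, 0L) == 20L))
  lib <- discrete_state_library()
  # control starts from the all-off state
  expect_identical(rc$experiments[[1]]$initial, lib$all_off)
  # constraints 2 and 3 differ only in the LIF input
  e2 <- rc$experiments[[2]]
  e3 <- rc$experiments[[3]]
  expect_identical(e2$initial, e3$initial)
  expect_identical(e2$sched$inputs[c("CH", "PD")],
                   e3$sched$inputs[c("CH", "PD")])
  expect_true(e2$sched$inputs[["LIF"]])
  expect_false(e3$sched$inputs[["LIF"]])
  # constraint 4 pins its target at two sequential steps
  ex4 <- rc$experiments[[4]]$expectations[[1]]
  expect_identical(ex4$modality, "held")
  rg <- abnsynth:::resolve_range(ex4, 20)
  expect_identical(unname(rg["to"] - rg["from"]), 1L)
  # knockouts are Low clamps over the whole trajectory
  expect_false(rc$experiments[[5]]$sched$clamps$value)
  expect_identical(rc$experiments[[5]]$sched$clamps$component, "Nanog")
})

test_that("the comparative constraint is vacuous when the reference never hits", {
  # model where the target is unreachable: single gene, no activator route
  net <- abn(c("A", "B"),
             data.frame(source = "A", target = "B", sign = "positive",
                        definite = TRUE))
  m <- concrete_model(net, logical(), c(A = 0L, B = 0L))
  ref <- experiment("ref", schedule(), c(), list(), bound = 5)
  treated <- experiment("tr", schedule(clamps = clamp("B", TRUE)), c(),
                        list(), bound = 5)
  cmp <- comparative("cmp", treated, ref, c(B = TRUE))
  # reference never reaches B High (no activator on), treated instantly does
  expect_true(check_constraint(m, cmp))
})

test_that("first-hit comparison is enforced when the reference reaches", {
  net <- abn(c("A", "B"),
             data.frame(source = "A", target = "B", sign = "positive",
                        definite = TRUE))
  m <- concrete_model(net, logical(), c(A = 8L, B = 8L))
  slow <- experiment("slow", schedule(clamps = clamp("A", TRUE)), c(),
                     list(), bound = 5)   # B High from step 1
  fast <- experiment("fast", schedule(clamps = clamp("B", TRUE)), c(),
                     list(), bound = 5)   # B High from step 0
  expect_true(check_constraint(
    m, comparative("ok", slow, fast, c(B = TRUE))))
  expect_false(check_constraint(
    m, comparative("bad", fast, slow, c(B = TRUE))))
})

test_that("expectation ranges are validated against the bound", {
  expect_error(
    experiment("x", schedule(), c(),
               expectation("reached", c(A = TRUE), 0, 30), bound = 20),
    "outside trajectory bound")
  expect_error(expectation("sometime", c(A = TRUE)), "modality")
})
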