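test_that("a network with no interactions is frozen Low", {
  net <- abn(c("A", "B"))
  m <- concrete_model(net, logical(), c(A = 0L, B = 0L))
  traj <- sync_trajectory(m, c(A = FALSE, B = FALSE), bound = 3)
  expect_false(any(traj$states))
  expect_true(traj$fixed_point)
})

test_that("a clamped activator switches its target on after one step", {
  net <- abn(c("A", "B"),
             data.frame(source = "A", target = "B", sign = "positive",
                        definite = TRUE))
  for (k in 0:8) {
    m <- concrete_model(net, logical(), c(A = 0L, B = k))
    sched <- schedule(clamps = clamp("A", TRUE))
    nxt <- sync_step(m, c(A = TRUE, B = FALSE), sched)
    expect_true(nxt[["B"]], info = paste("condition", k))
  }
})

test_that("condition 0 vetoes expression when a repressor is active", {
  net <- abn(c("A", "B", "C"),
             data.frame(source = c("A", "C"), target = c("B", "B"),
                        sign = c("positive", "negative"), definite = TRUE))
  m <- concrete_model(net, logical(), c(A = 0L, B = 0L, C = 0L))
  sched <- schedule(clamps = rbind(clamp("A", TRUE), clamp("C", TRUE)))
  nxt <- sync_step(m, c(A = TRUE, B = FALSE, C = TRUE), sched)
  expect_false(nxt[["B"]])  # (all activators, all repressors) is FALSE
})

test_that("mutual activation holds an all-High state forever", {
  m <- concrete_model(toy_pair(), logical(), c(A = 8L, B = 8L))
  traj <- sync_trajectory(m, c(A = TRUE, B = TRUE), bound = 5)
  expect_true(all(traj$states))
  expect_true(traj$fixed_point)
})

test_that("sync_step is a pure function and replay is deterministic", {
  inst <- random_instance(42)
  space <- enumerate_model_space(inst$net)
  m <- concrete_model(inst$net, space$E[nrow(space$E) %/% 2, ],
                      space$S[nrow(space$S) %/% 2, ])
  init <- stats::setNames(rep(TRUE, 0), character())
  t1 <- sync_trajectory(m, init, schedule(), 6)
  t2 <- sync_trajectory(m, init, schedule(), 6)
  expect_identical(t1$states, t2$states)
})

test_that("synchronous trajectories enter a cycle within 2^m steps", {
  for (seed in 1:10) {
    inst <- random_instance(seed, max_comp = 4)
    space <- enumerate_model_space(inst$net)
    m <- concrete_model(inst$net, space$E[1, ], space$S[1, ])
    ncomp <- length(inst$net$components)
    traj <- sync_trajectory(m, stats::setNames(logical(), character()),
                            schedule(), 2^ncomp + 1)
    keys <- apply(traj$states, 1, paste, collapse = "")
    expect_true(anyDuplicated(keys) > 0)
  }
})

test_that("an uninstantiated optional interaction never changes dynamics", {
  base <- abn(c("A", "B"),
              data.frame(source = "A", target = "B", sign = "positive",
                         definite = TRUE))
  extra <- abn(c("A", "B", "C"),
               data.frame(source = c("A", "C"), target = c("B", "B"),
                          sign = c("positive", "negative"),
                          definite = c(TRUE, FALSE)))
  mb <- concrete_model(base, logical(), c(A = 4L, B = 4L))
  me <- concrete_model(extra, FALSE, c(A = 4L, B = 4L, C = 4L))
  sched <- schedule(clamps = clamp("A", TRUE))
  tb <- sync_trajectory(mb, c(B = FALSE), sched, 5)
  te <- sync_trajectory(me, c(B = FALSE, C = TRUE), sched, 5)
  expect_identical(tb$states[, c("A", "B")], te$states[, c("A", "B")])
})

test_that("states referencing unknown components are rejected", {
  m <- concrete_model(toy_pair(), logical(), c(A = 0L, B = 0L))
  expect_error(sync_step(m, c(A = TRUE, B = TRUE, Z = TRUE)), "components")
  expect_error(sync_trajectory(m, c(Z = TRUE)), "unknown component")
})
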