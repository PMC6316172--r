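test_that("ground-truth sampling is reproducible and validated", {
  gt1 <- sample_ground_truth(seed = 7)
  gt2 <- sample_ground_truth(seed = 7)
  expect_identical(gt1$network$interactions, gt2$network$interactions)
  expect_identical(gt1$model$conditions, gt2$model$conditions)
  expect_error(sample_ground_truth(n_genes = 12, n_interactions = 10),
               "n_interactions")
  # every gene has at least one activator
  ia <- gt1$network$interactions
  for (g in network_genes(gt1$network)) {
    expect_true(any(ia$target == g & ia$sign == "positive"))
  }
})

test_that("a sampled model settles into an attractor from all-High", {
  gt <- sample_ground_truth(seed = 7)
  genes <- network_genes(gt$network)
  init <- stats::setNames(rep(TRUE, length(genes)), genes)
  sigs <- network_signals(gt$network)
  traj <- sync_trajectory(gt$model, init,
                          schedule(stats::setNames(rep(TRUE, length(sigs)),
                                                   sigs)),
                          bound = 40)
  keys <- apply(traj$states, 1, paste, collapse = "")
  expect_true(anyDuplicated(keys) > 0)  # cycle (possibly a fixed point)
})

test_that("a noiseless single-activator pair correlates exactly", {
  # at equilibrium a single-activator target copies its regulator, so with
  # zero emission noise and no perturbation clamps the Pearson coefficient
  # is exactly 1 in every panel where the pair varies
  gt <- sample_ground_truth(n_genes = 4, n_signals = 2,
                            n_interactions = 4, seed = 2)
  ia <- gt$network$interactions
  genes <- network_genes(gt$network)
  gg <- ia[ia$source %in% genes, , drop = FALSE]
  expect_gt(nrow(gg), 0L)
  ds <- simulate_expression(gt, n_datasets = 3, samples_per_dataset = 40,
                            seed = 5, noise_sd = 0, clamp_prob = 0)
  prof <- compute_correlation_profiles(ds)
  for (i in seq_len(nrow(gg))) {
    r <- prof$cors[gg$source[i], gg$target[i], ]
    r <- r[!is.na(r)]
    expect_gt(length(r), 0L)
    expect_true(all(abs(abs(r) - 1) < 1e-12))
  }
})

test_that("edge recovery at the planted threshold matches recorded values", {
  # fixed-seed regression values for the default generator settings
  gt <- sample_ground_truth(seed = 3)
  ds <- simulate_expression(gt, seed = 3)
  rec <- interaction_recovery(
    call_possible_interactions(compute_correlation_profiles(ds),
                               gt$planted_threshold), gt)
  expect_equal(rec$recall, 0.8333, tolerance = 1e-3)
  gt7 <- sample_ground_truth(seed = 7)
  ds7 <- simulate_expression(gt7, seed = 3)
  rec7 <- interaction_recovery(
    call_possible_interactions(compute_correlation_profiles(ds7),
                               gt7$planted_threshold), gt7)
  expect_equal(rec7$recall, 0.7143, tolerance = 1e-3)
})

test_that("recall does not improve as emission noise grows", {
  gt <- sample_ground_truth(seed = 7)
  recall_at <- function(sd) {
    ds <- simulate_expression(gt, seed = 3, noise_sd = sd)
    interaction_recovery(
      call_possible_interactions(compute_correlation_profiles(ds),
                                 gt$planted_threshold), gt)$recall
  }
  r_low <- recall_at(0.05)
  r_mid <- recall_at(0.5)
  r_high <- recall_at(1.5)
  expect_gte(r_low, r_mid)
  expect_gte(r_mid, r_high)
})

test_that("generated constraints are satisfied by their own ground truth", {
  for (seed in c(1, 5)) {
    gt <- sample_ground_truth(seed = seed)
    obs <- generate_observations(gt, seed = seed)
    expect_true(all(vapply(obs$constraints, check_constraint,
                           model = gt$model, FUN.VALUE = NA)),
                info = paste("seed", seed))
    expect_true(all(obs$outcomes$result %in%
                      c("supports-positive", "supports-negative")))
    expect_identical(nrow(obs$outcomes), length(obs$queries))
  }
})

test_that("the ground truth is a member of its own cABN", {
  gt <- sample_ground_truth(seed = 5)
  obs <- generate_observations(gt, seed = 5)
  cb <- cabn(gt$network, obs$constraints)
  # membership: the gt instantiates a subset of the ABN's interactions and
  # satisfies every constraint by simulation
  expect_true(all(vapply(cb$constraints, check_constraint,
                         model = gt$model, FUN.VALUE = NA)))
})
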