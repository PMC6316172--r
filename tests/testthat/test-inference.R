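mk_ds <- function(mat, label = "d") {
  expression_dataset(mat, label)
}

test_that("proportional and anti-proportional pairs give r of 1 and -1", {
  set.seed(1)
  a <- stats::runif(10, 1, 5)
  datasets <- lapply(1:3, function(i) {
    a <- stats::runif(10, 1, 5)
    mk_ds(rbind(A = a, B = 2 * a, C = max(a) + 1 - a), paste0("d", i))
  })
  prof <- compute_correlation_profiles(datasets)
  expect_equal(unname(prof$cors["A", "B", ]), rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(prof$cors["A", "C", ]), rep(-1, 3), tolerance = 1e-12)
})

test_that("a planted noisy linear pair matches the analytic correlation", {
  # y = x + e with x ~ U(0, 1), e ~ N(0, 0.1): rho = sd_x/sqrt(sd_x^2+0.01)
  rho <- sqrt(1 / 12) / sqrt(1 / 12 + 0.01)
  set.seed(42)
  rs <- replicate(200, {
    x <- stats::runif(20)
    y <- x + stats::rnorm(20, 0, 0.1)
    stats::cor(x, y)
  })
  expect_lt(abs(mean(rs) - rho), 0.05)
})

test_that("constant genes yield undefined coefficients, excluded from calls", {
  d1 <- mk_ds(rbind(A = c(1, 2, 3), B = c(2, 4, 6), C = c(5, 5, 5)))
  prof <- compute_correlation_profiles(list(d1))
  expect_true(is.na(prof$cors["A", "C", 1]))
  called <- call_possible_interactions(prof, 0.8)
  expect_false(any(called$source == "C" | called$target == "C"))
})

test_that("the positive-call rule follows the trigger-plus-majority logic", {
  co <- function(...) c(...)
  # one high coefficient, remaining majority positive: positive call
  expect_identical(abnsynth:::call_pair(
    co(0.9, 0.2, 0.3, 0.1, 0.4, 0.2, 0.5), 0.832), "positive")
  # trigger present but remaining majority negative: no call either way
  expect_identical(abnsynth:::call_pair(
    co(0.9, -0.2, -0.3, -0.4, -0.1, -0.2, -0.5), 0.832), NA_character_)
  # all-zero profile: no call
  expect_identical(abnsynth:::call_pair(rep(0, 7), 0.832), NA_character_)
  # both signs trigger: majority over all defined coefficients decides
  expect_identical(abnsynth:::call_pair(
    co(0.9, -0.9, 0.5, 0.4, -0.1), 0.832), "positive")
  expect_identical(abnsynth:::call_pair(
    co(0.9, -0.9, 0.5, -0.4), 0.832), NA_character_)  # tie: conservative
  # mirrored negative rule
  expect_identical(abnsynth:::call_pair(
    co(-0.9, -0.2, -0.3, 0.1, -0.4), 0.832), "negative")
})

test_that("calls are bidirectional and symmetric in gene order", {
  set.seed(3)
  a <- stats::runif(12)
  ds <- list(mk_ds(rbind(X = a, Y = a + stats::rnorm(12, 0, 0.01))))
  called <- call_possible_interactions(compute_correlation_profiles(ds),
                                       0.9)
  expect_identical(nrow(called), 2L)
  expect_setequal(paste(called$source, called$target),
                  c("X Y", "Y X"))
  expect_true(all(called$sign == "positive"))
  expect_false(any(called$definite))
})

test_that("lowering the threshold never removes a call", {
  set.seed(4)
  for (rep in 1:10) {
    mats <- lapply(1:4, function(i) {
      matrix(stats::runif(40), 4, 10,
             dimnames = list(paste0("g", 1:4), NULL))
    })
    prof <- compute_correlation_profiles(lapply(mats, mk_ds))
    hi <- call_possible_interactions(prof, 0.7)
    lo <- call_possible_interactions(prof, 0.3)
    expect_true(all(paste(hi$source, hi$target, hi$sign) %in%
                      paste(lo$source, lo$target, lo$sign)))
  }
})

test_that("mismatched gene sets are rejected", {
  d1 <- mk_ds(rbind(A = 1:3, B = 3:1))
  d2 <- mk_ds(rbind(A = 1:3, C = 3:1))
  expect_error(compute_correlation_profiles(list(d1, d2)), "mismatched")
})

test_that("threshold search returns the grid maximum for empty constraints", {
  gt <- sample_ground_truth(seed = 11, n_genes = 6, n_interactions = 10)
  ds <- simulate_expression(gt, samples_per_dataset = 30, seed = 2)
  defi <- gt$network$interactions[gt$network$interactions$definite, ]
  grid <- c(0.4, 0.6, 0.8)
  res <- find_max_threshold(ds, defi, list(), candidate_grid = grid)
  expect_identical(res$threshold, 0.8)
})

test_that("threshold search finds the largest satisfiable threshold", {
  gt <- sample_ground_truth(seed = 7)
  ds <- simulate_expression(gt, seed = 3)
  obs <- generate_observations(gt, seed = 7)
  defi <- gt$network$interactions[gt$network$interactions$definite, ]
  grid <- seq(0.3, 0.9, by = 0.1)
  res <- find_max_threshold(ds, defi, obs$constraints,
                            candidate_grid = grid)
  expect_true(res$threshold %in% grid)
  expect_identical(synthesize(res$network, obs$constraints)$status,
                   "satisfiable")
  # one grid step higher (when it exists) must be unsatisfiable
  above <- grid[grid > res$threshold]
  if (length(above)) {
    prof <- compute_correlation_profiles(ds)
    called <- call_possible_interactions(prof, above[1])
    key <- paste(called$source, called$target, called$sign)
    dkey <- paste(defi$source, defi$target, defi$sign)
    called <- called[!key %in% dkey, , drop = FALSE]
    genes <- prof$genes
    extra <- setdiff(unique(c(defi$source, defi$target)), genes)
    net_above <- abn(data.frame(name = c(genes, extra),
                                role = c(rep("gene", length(genes)),
                                         rep("signal", length(extra)))),
                     rbind(defi, called))
    expect_identical(synthesize(net_above, obs$constraints)$status,
                     "unsatisfiable")
  }
})
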