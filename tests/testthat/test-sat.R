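# The CDCL solver is the decision engine behind every synthesis query, so
# its verdicts are checked against exhaustive truth-table evaluation on
# random small formulas.

brute_sat <- function(nvars, clauses) {
  for (bits in 0:(2^nvars - 1)) {
    model <- as.logical(bitwAnd(bitwShiftR(bits, 0:(nvars - 1L)), 1L))
    ok <- all(vapply(clauses, function(cl) {
      any((cl > 0) == model[abs(cl)])
    }, NA))
    if (ok) return(TRUE)
  }
  FALSE
}

test_that("solver verdicts match truth-table enumeration on random 3-SAT", {
  for (seed in 1:60) {
    set.seed(seed)
    nv <- sample(3:10, 1)
    nc <- sample(2:(4 * nv), 1)
    clauses <- lapply(seq_len(nc), function(i) {
      k <- sample(1:3, 1)
      v <- sample(nv, k)
      v * sample(c(-1L, 1L), k, replace = TRUE)
    })
    cnf <- abnsynth:::cnf_new()
    vars <- abnsynth:::cnf_var(cnf, nv)
    for (cl in clauses) {
      abnsynth:::cnf_clause(cnf, sign(cl) * vars[abs(cl)])
    }
    res <- abnsynth:::cnf_solve(cnf)
    expect_identical(res$status == "sat", brute_sat(nv, clauses),
                     info = paste("seed", seed))
    if (res$status == "sat") {
      model <- res$model[vars]
      ok <- all(vapply(clauses, function(cl) {
        any((cl > 0) == model[abs(cl)])
      }, NA))
      expect_true(ok, info = paste("model check seed", seed))
    }
  }
})

test_that("empty and contradictory clause sets are handled", {
  cnf <- abnsynth:::cnf_new()
  v <- abnsynth:::cnf_var(cnf, 2)
  abnsynth:::cnf_clause(cnf, v[1])
  abnsynth:::cnf_clause(cnf, -v[1])
  expect_identical(abnsynth:::cnf_solve(cnf)$status, "unsat")
})

test_that("snapshot/rollback isolates query clauses", {
  cnf <- abnsynth:::cnf_new()
  v <- abnsynth:::cnf_var(cnf, 3)
  abnsynth:::cnf_clause(cnf, c(v[1], v[2]))
  mark <- abnsynth:::cnf_mark(cnf)
  abnsynth:::cnf_clause(cnf, -v[1])
  abnsynth:::cnf_clause(cnf, -v[2])
  expect_identical(abnsynth:::cnf_solve(cnf)$status, "unsat")
  abnsynth:::cnf_reset(cnf, mark)
  expect_identical(abnsynth:::cnf_solve(cnf)$status, "sat")
  # extra units at solve time do not persist either
  expect_identical(abnsynth:::cnf_solve(cnf,
                                        extra_units = c(-v[1], -v[2]))$status,
                   "unsat")
  expect_identical(abnsynth:::cnf_solve(cnf)$status, "sat")
})

test_that("cardinality constraints bound the number of true literals", {
  for (k in 0:4) {
    cnf <- abnsynth:::cnf_new()
    v <- abnsynth:::cnf_var(cnf, 5)
    abnsynth:::cnf_at_most_k(cnf, v, k)
    # force k+1 variables true -> unsat; k true -> sat
    res_over <- abnsynth:::cnf_solve(cnf, extra_units = v[seq_len(k + 1)])
    expect_identical(res_over$status, "unsat", info = paste("k =", k))
    if (k > 0) {
      res_ok <- abnsynth:::cnf_solve(cnf, extra_units = v[seq_len(k)])
      expect_identical(res_ok$status, "sat")
    }
  }
})
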