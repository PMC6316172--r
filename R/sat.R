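# CNF construction and the interface to the CDCL solver. Literals use the
# DIMACS convention: +v / -v for variable v >= 1. A distinguished variable
# asserted TRUE stands in for Boolean constants so that Tseitin helpers never
# need special-casing.

# Clauses are kept in a cons list (newest first): appending is O(1) without
# copying, and snapshot/rollback for per-query scratch clauses is a pointer
# save/restore. Flattening for the solver is cached incrementally.
cnf_new <- function() {
  e <- new.env(parent = emptyenv())
  e$nvars <- 0L
  e$clauses <- NULL
  e$n_clauses <- 0L
  e$gen <- 0L
  e$cache <- NULL
  e$vtrue <- cnf_var(e)
  cnf_clause(e, e$vtrue)
  e
}

cnf_var <- function(cnf, n = 1L) {
  v <- cnf$nvars + seq_len(n)
  cnf$nvars <- cnf$nvars + as.integer(n)
  v
}

cnf_clause <- function(cnf, ...) {
  cnf$clauses <- list(as.integer(c(...)), cnf$clauses)
  cnf$n_clauses <- cnf$n_clauses + 1L
  invisible(NULL)
}

lit_true <- function(cnf) cnf$vtrue
lit_false <- function(cnf) -cnf$vtrue

# Snapshot / rollback, so per-query definitional clauses and variables do not
# accumulate in a shared base encoding.
cnf_mark <- function(cnf) {
  list(nvars = cnf$nvars, n_clauses = cnf$n_clauses, ptr = cnf$clauses)
}
cnf_reset <- function(cnf, mark) {
  cnf$nvars <- mark$nvars
  cnf$n_clauses <- mark$n_clauses
  cnf$clauses <- mark$ptr
  cnf$gen <- cnf$gen + 1L
  if (!is.null(cnf$cache) && cnf$cache$n > mark$n_clauses) cnf$cache <- NULL
  invisible(NULL)
}

# Flatten the cons list to (lits, lengths), reusing any cached prefix.
cnf_flatten <- function(cnf) {
  cache <- cnf$cache
  n <- cnf$n_clauses
  base_n <- if (!is.null(cache)) cache$n else 0L
  if (!is.null(cache) && base_n == n) return(cache)
  delta <- vector("list", n - base_n)
  p <- cnf$clauses
  for (i in (n - base_n):1L) {
    delta[[i]] <- p[[1L]]
    p <- p[[2L]]
  }
  new_lits <- unlist(delta, use.names = FALSE)
  out <- list(n = n,
              lits = c(if (!is.null(cache)) cache$lits, new_lits),
              lens = c(if (!is.null(cache)) cache$lens,
                       lengths(delta)))
  cnf$cache <- out
  out
}

# v <-> AND(lits); returns the literal for v (folds empty/singleton cases)
t_and <- function(cnf, lits) {
  lits <- as.integer(lits)
  if (length(lits) == 0L) return(lit_true(cnf))
  if (length(lits) == 1L) return(lits)
  v <- cnf_var(cnf)
  for (l in lits) cnf_clause(cnf, -v, l)
  cnf_clause(cnf, v, -lits)
  v
}

# v <-> OR(lits)
t_or <- function(cnf, lits) {
  lits <- as.integer(lits)
  if (length(lits) == 0L) return(lit_false(cnf))
  if (length(lits) == 1L) return(lits)
  v <- cnf_var(cnf)
  for (l in lits) cnf_clause(cnf, v, -l)
  cnf_clause(cnf, -v, lits)
  v
}

# v <-> (a <-> b)
t_eq <- function(cnf, a, b) {
  v <- cnf_var(cnf)
  cnf_clause(cnf, -v, -a, b)
  cnf_clause(cnf, -v, a, -b)
  cnf_clause(cnf, v, a, b)
  cnf_clause(cnf, v, -a, -b)
  v
}

# exactly-one over lits (pairwise at-most-one; sets are small)
cnf_exactly_one <- function(cnf, lits) {
  cnf_clause(cnf, lits)
  if (length(lits) > 1L) {
    for (i in seq_len(length(lits) - 1L)) {
      for (j in seq(i + 1L, length(lits))) {
        cnf_clause(cnf, -lits[i], -lits[j])
      }
    }
  }
  invisible(NULL)
}

# Sequential-counter at-most-k over lits; appends clauses only.
cnf_at_most_k <- function(cnf, lits, k) {
  n <- length(lits)
  if (k >= n) return(invisible(NULL))
  if (k == 0L) {
    for (l in lits) cnf_clause(cnf, -l)
    return(invisible(NULL))
  }
  # r[i, j]: among lits[1..i] at least j are true
  r <- matrix(0L, n, k)
  for (i in seq_len(n)) r[i, ] <- cnf_var(cnf, k)
  for (i in seq_len(n)) {
    cnf_clause(cnf, -lits[i], r[i, 1L])
    if (i > 1L) {
      for (j in seq_len(k)) {
        cnf_clause(cnf, -r[i - 1L, j], r[i, j])
        if (j > 1L) {
          cnf_clause(cnf, -lits[i], -r[i - 1L, j - 1L], r[i, j])
        }
      }
      cnf_clause(cnf, -lits[i], -r[i - 1L, k])
    }
  }
  invisible(NULL)
}

# Solve the accumulated clauses plus any extra unit literals / clauses.
# Returns list(status = "sat"/"unsat"/"unknown", model = logical vector).
cnf_solve <- function(cnf, extra_units = integer(), extra_clauses = list(),
                      max_conflicts = getOption("abnsynth.max_conflicts",
                                                2e6)) {
  # Force the extras before flattening: building them may append their
  # defining (Tseitin) clauses to `cnf`.
  force(extra_units)
  force(extra_clauses)
  flat <- cnf_flatten(cnf)
  lits <- flat$lits
  lens <- flat$lens
  if (length(extra_units)) {
    lits <- c(lits, as.integer(extra_units))
    lens <- c(lens, rep(1L, length(extra_units)))
  }
  if (length(extra_clauses)) {
    lits <- c(lits, as.integer(unlist(extra_clauses, use.names = FALSE)))
    lens <- c(lens, lengths(extra_clauses))
  }
  res <- cdcl_solve_cpp(cnf$nvars, lits, lens, max_conflicts)
  status <- switch(as.character(res$status),
                   "1" = "sat", "0" = "unsat", "-1" = "unknown")
  model <- res$model
  if (identical(status, "sat") &&
      isTRUE(getOption("abnsynth.check_cnf", TRUE))) {
    vals <- (lits > 0L) == model[abs(lits)]
    grp <- rep.int(seq_along(lens), lens)
    sat_per <- rowsum(as.integer(vals), grp, reorder = FALSE) > 0L
    if (!all(sat_per)) stop("internal: solver model violates a clause")
  }
  list(status = status, model = model, conflicts = res$conflicts)
}
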