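#' All-models predictions from a constrained ABN
#'
#' A prediction is formulated only when every concrete model in the cABN
#' agrees. Each query encodes a hypothesis about trajectory behaviour as an
#' additional constraint and tests, against the full constraint set, both the
#' hypothesis and its null (that the behaviour cannot be obtained):
#' \itemize{
#'   \item hypothesis satisfiable, null unsatisfiable: \emph{positive} — all
#'     models show the behaviour;
#'   \item hypothesis unsatisfiable, null satisfiable: \emph{negative} — no
#'     model shows it;
#'   \item both satisfiable: \emph{no_prediction} — the models disagree.
#' }
#'
#' @name predictions
NULL

cabn_encoding <- function(cb) {
  if (is.null(cb$env$enc)) {
    cb$env$enc <- build_encoding(cb$network, cb$constraints)
  }
  cb$env$enc
}

# Test a hypothesis literal and its negation against the base encoding.
hypothesis_test <- function(enc, lit, max_conflicts = 2e6) {
  h <- cnf_solve(enc$cnf, extra_units = lit, max_conflicts = max_conflicts)
  n <- cnf_solve(enc$cnf, extra_units = -lit, max_conflicts = max_conflicts)
  if (h$status == "unknown" || n$status == "unknown") {
    return("indeterminate")
  }
  if (h$status == "sat" && n$status == "unsat") return("positive")
  if (h$status == "unsat" && n$status == "sat") return("negative")
  "no_prediction"
}

# Literal: trajectory x has stabilised in `target` at step s (the partial
# state holds and the full state is a synchronous fixed point).
stable_at_lit <- function(enc, x, target, s) {
  eqs <- vapply(seq_len(ncol(x)),
                function(i) t_eq(enc$cnf, x[s + 1L, i], x[s + 2L, i]), 0L)
  t_and(enc$cnf, c(hold_lit(enc, x, target, s), eqs))
}

#' Steps for the model set to stabilise in a target state
#'
#' For each step s up to the bound, tests the hypothesis "the trajectory has
#' stabilised in the target at step s" and its null. The interval where the
#' hypothesis is satisfiable is where *some* models have stabilised; the
#' least step where the null is unsatisfiable is where *all* models have.
#'
#' @param cb a [cabn()]
#' @param sched [schedule()] for the queried condition
#' @param initial partial initial state
#' @param target named logical partial target state
#' @param bound trajectory bound (default 20)
#' @param max_conflicts solver conflict budget per query
#' @return list with \code{some_range} (c(min, max) steps at which some
#'   model is stabilised, NA if none), \code{all_step} (least step at which
#'   every model is stabilised, NA if never) and \code{outcome}
#'   (\code{"reached"} or \code{"never"})
#' @export
steps_to_target <- function(cb, sched, initial, target, bound = 20,
                            max_conflicts =
                              getOption("abnsynth.max_conflicts", 2e6)) {
  bound <- as.integer(bound)
  enc <- cabn_encoding(cb)
  mark <- cnf_mark(enc$cnf)
  on.exit(cnf_reset(enc$cnf, mark))
  x <- encode_experiment_trajectory(enc, sched, initial, bound)
  lits <- new.env(parent = emptyenv())
  lit_at <- function(s) {
    k <- as.character(s)
    if (is.null(lits[[k]])) lits[[k]] <- stable_at_lit(enc, x, target, s)
    lits[[k]]
  }
  ask <- function(unit) {
    res <- cnf_solve(enc$cnf, extra_units = unit,
                     max_conflicts = max_conflicts)
    if (res$status == "unknown") stop("solver budget exhausted")
    res$status == "sat"
  }
  # When every clamp is constant (to = Inf) stability is monotone in s for
  # each model, so the boundaries can be found by binary search; transient
  # clamp windows fall back to a per-step scan.
  cl <- sched$clamps
  monotone <- !nrow(cl) || all(!is.finite(cl$to))
  if (monotone) {
    if (!ask(lit_at(bound))) {
      return(list(some_range = c(NA, NA), all_step = NA_integer_,
                  outcome = "never"))
    }
    bsearch <- function(pred) {  # least s in 0..bound with pred(s) TRUE
      lo <- 0L; hi <- bound
      while (lo < hi) {
        mid <- (lo + hi) %/% 2L
        if (pred(mid)) hi <- mid else lo <- mid + 1L
      }
      lo
    }
    some_min <- bsearch(function(s) ask(lit_at(s)))
    all_any <- !ask(-lit_at(bound))
    all_step <- if (all_any) bsearch(function(s) !ask(-lit_at(s)))
                else NA_integer_
    return(list(some_range = c(some_min, bound), all_step = all_step,
                outcome = "reached"))
  }
  some <- logical(bound + 1L)
  all_ <- logical(bound + 1L)
  for (s in 0:bound) {
    some[s + 1L] <- ask(lit_at(s))
    if (some[s + 1L]) all_[s + 1L] <- !ask(-lit_at(s))
  }
  list(some_range = if (any(some)) range(which(some) - 1L) else c(NA, NA),
       all_step = if (any(all_)) min(which(all_) - 1L) else NA_integer_,
       outcome = if (any(some)) "reached" else "never")
}

#' First step of permanent gene activation across the model set
#'
#' Permanent activation at step s means the gene is High from s through the
#' bound and one step beyond (so transient pulses do not count). Reports the
#' earliest step at which some model has permanently activated the gene and
#' the earliest at which all models have.
#'
#' @inheritParams steps_to_target
#' @param gene gene name
#' @return list with \code{first_step_some}, \code{first_step_all} (NA when
#'   never) and \code{outcome}
#' @export
activation_step <- function(cb, gene, sched, initial, bound = 20,
                            max_conflicts =
                              getOption("abnsynth.max_conflicts", 2e6)) {
  cl <- sched$clamps
  if (nrow(cl) && any(cl$component == gene & !cl$value)) {
    stop("gene ", gene, " is clamped Low by the schedule")
  }
  enc <- cabn_encoding(cb)
  mark <- cnf_mark(enc$cnf)
  on.exit(cnf_reset(enc$cnf, mark))
  x <- encode_experiment_trajectory(enc, sched, initial, bound)
  perm_lit <- function(s) t_and(enc$cnf, x[(s + 1L):(bound + 2L), gene])
  some <- rep(NA, bound + 1L)
  all_ <- rep(NA, bound + 1L)
  for (s in 0:bound) {
    lit <- perm_lit(s)
    h <- cnf_solve(enc$cnf, extra_units = lit, max_conflicts = max_conflicts)
    if (h$status == "unknown") stop("solver budget exhausted")
    some[s + 1L] <- h$status == "sat"
    n <- cnf_solve(enc$cnf, extra_units = -lit, max_conflicts = max_conflicts)
    if (n$status == "unknown") stop("solver budget exhausted")
    all_[s + 1L] <- n$status == "unsat"
    if (all_[s + 1L]) break  # monotone: permanently active from s onwards
  }
  list(first_step_some = if (any(some, na.rm = TRUE))
         min(which(some)) - 1L else NA_integer_,
       first_step_all = if (any(all_, na.rm = TRUE))
         min(which(all_)) - 1L else NA_integer_,
       outcome = if (any(some, na.rm = TRUE)) "activates" else "never")
}

# Prefix-reach literal vectors under first-hit or first-stable semantics.
reach_lits <- function(enc, x, target, bound, mode = c("hit", "stable")) {
  mode <- match.arg(mode)
  if (mode == "hit") {
    return(prefix_reach_lits(enc, x, target, bound))
  }
  r <- integer(bound + 1L)
  r[1L] <- stable_at_lit(enc, x, target, 0L)
  for (t in seq_len(bound)) {
    r[t + 1L] <- t_or(enc$cnf, c(r[t], stable_at_lit(enc, x, target, t)))
  }
  r
}

#' Compare resetting efficiency of two schedules across all models
#'
#' Tests, in a paired query sharing the model-choice variables, whether any
#' concrete model lets schedule A reach the target strictly later than
#' schedule B (and vice versa). \code{A_never_slower} is TRUE when no such
#' model exists.
#'
#' @inheritParams steps_to_target
#' @param schedA,schedB the two [schedule()]s
#' @param initialA,initialB initial states (default: shared \code{initial})
#' @param initial shared default initial state
#' @param mode \code{"hit"} compares first steps at which the target holds;
#'   \code{"stable"} first steps at which it holds stably
#' @return list with logical \code{A_never_slower}, \code{B_never_slower}
#'   and a combined \code{outcome}
#' @export
compare_schedules <- function(cb, schedA, schedB, target, initial = NULL,
                              initialA = initial, initialB = initial,
                              bound = 20, mode = c("hit", "stable"),
                              max_conflicts =
                                getOption("abnsynth.max_conflicts", 2e6)) {
  mode <- match.arg(mode)
  enc <- cabn_encoding(cb)
  mark <- cnf_mark(enc$cnf)
  on.exit(cnf_reset(enc$cnf, mark))
  xa <- encode_experiment_trajectory(enc, schedA, initialA, bound)
  xb <- encode_experiment_trajectory(enc, schedB, initialB, bound)
  ra <- reach_lits(enc, xa, target, bound, mode)
  rb <- reach_lits(enc, xb, target, bound, mode)
  slower_than <- function(r_self, r_other) {
    # some step where the other has reached but self has not
    t_or(enc$cnf, vapply(seq_len(bound + 1L), function(t) {
      t_and(enc$cnf, c(r_other[t], -r_self[t]))
    }, 0L))
  }
  solve_lit <- function(lit) {
    res <- cnf_solve(enc$cnf, extra_units = lit,
                     max_conflicts = max_conflicts)
    if (res$status == "unknown") stop("solver budget exhausted")
    res$status
  }
  a_slower_sat <- solve_lit(slower_than(ra, rb))
  b_slower_sat <- solve_lit(slower_than(rb, ra))
  a_never <- a_slower_sat == "unsat"
  b_never <- b_slower_sat == "unsat"
  outcome <- if (a_never && b_never) "equivalent"
             else if (a_never) "A_never_slower"
             else if (b_never) "B_never_slower"
             else "no_prediction"
  list(A_never_slower = a_never, B_never_slower = b_never, outcome = outcome)
}

#' Does activation of one gene always precede another?
#'
#' \code{always_before}: in no consistent model is \code{geneY} High at a
#' step by which \code{geneX} has not yet been High. \code{never_before}:
#' every model violates that order. Otherwise no prediction.
#'
#' @inheritParams steps_to_target
#' @param geneX,geneY gene names (X the putative earlier gene)
#' @return one of \code{"always_before"}, \code{"never_before"},
#'   \code{"no_prediction"}
#' @export
precedes <- function(cb, geneX, geneY, sched, initial, bound = 20,
                     max_conflicts =
                       getOption("abnsynth.max_conflicts", 2e6)) {
  enc <- cabn_encoding(cb)
  mark <- cnf_mark(enc$cnf)
  on.exit(cnf_reset(enc$cnf, mark))
  x <- encode_experiment_trajectory(enc, sched, initial, bound)
  rx <- prefix_reach_lits(enc, x, stats::setNames(TRUE, geneX), bound)
  viol <- t_or(enc$cnf, vapply(0:bound, function(t) {
    t_and(enc$cnf, c(x[t + 1L, geneY], -rx[t + 1L]))
  }, 0L))
  out <- hypothesis_test(enc, -viol, max_conflicts)
  switch(out,
         positive = "always_before",
         negative = "never_before",
         indeterminate = "indeterminate",
         "no_prediction")
}

#' Is a component required to reach and hold a target state?
#'
#' Clamps the component Low for the whole trajectory and asks whether the
#' model set can still permanently stabilise in the target. \code{required}:
#' no model can; \code{dispensable}: all models can; otherwise no
#' prediction.
#'
#' @inheritParams steps_to_target
#' @param component gene to deplete (signals are rejected)
#' @return one of \code{"required"}, \code{"dispensable"},
#'   \code{"no_prediction"}
#' @export
essentiality <- function(cb, component, sched, initial, target, bound = 20,
                         max_conflicts =
                           getOption("abnsynth.max_conflicts", 2e6)) {
  if (cb$network$roles[[component]] == "signal") {
    stop("cannot deplete a signal; change the schedule inputs instead")
  }
  sched <- with_clamps(sched, clamp(component, FALSE))
  target <- target[setdiff(names(target), component)]
  enc <- cabn_encoding(cb)
  mark <- cnf_mark(enc$cnf)
  on.exit(cnf_reset(enc$cnf, mark))
  x <- encode_experiment_trajectory(enc, sched, initial, bound)
  reach_hold <- t_or(enc$cnf, vapply(0:bound, function(s) {
    stable_at_lit(enc, x, target, s)
  }, 0L))
  out <- hypothesis_test(enc, reach_hold, max_conflicts)
  switch(out,
         positive = "dispensable",
         negative = "required",
         indeterminate = "indeterminate",
         "no_prediction")
}

#' Outcome of a reprogramming cocktail
#'
#' Starts from a state in which all components are inactive except the
#' cocktail factors, clamps the cocktail High under the given culture
#' inputs, and asks whether the model set reaches and holds the target
#' (naive) state. Factors outside the network roster (e.g. cMyc in OSKM)
#' are dropped with a warning.
#'
#' @inheritParams steps_to_target
#' @param cocktail character vector of factor names
#' @param inputs named logical over the network signals
#' @return one of \code{"reprograms"}, \code{"fails"},
#'   \code{"no_prediction"}
#' @export
cocktail_outcome <- function(cb, cocktail, inputs, target, bound = 20,
                             max_conflicts =
                               getOption("abnsynth.max_conflicts", 2e6)) {
  genes <- network_genes(cb$network)
  unknown <- setdiff(cocktail, genes)
  if (length(unknown)) {
    warning("cocktail factor(s) outside the network roster ignored: ",
            paste(unknown, collapse = ", "))
    cocktail <- intersect(cocktail, genes)
  }
  sched <- schedule(inputs,
                    if (length(cocktail))
                      do.call(rbind, lapply(cocktail, clamp, value = TRUE)))
  initial <- stats::setNames(genes %in% cocktail, genes)
  enc <- cabn_encoding(cb)
  mark <- cnf_mark(enc$cnf)
  on.exit(cnf_reset(enc$cnf, mark))
  x <- encode_experiment_trajectory(enc, sched, initial, bound)
  reach_hold <- t_or(enc$cnf, vapply(0:bound, function(s) {
    stable_at_lit(enc, x, target, s)
  }, 0L))
  out <- hypothesis_test(enc, reach_hold, max_conflicts)
  switch(out,
         positive = "reprograms",
         negative = "fails",
         indeterminate = "indeterminate",
         "no_prediction")
}

#' Score definitive predictions against experimental outcomes
#'
#' @param predictions named character vector (or data.frame with columns
#'   \code{query}, \code{outcome}) of prediction outcomes
#'   (\code{positive}/\code{negative}/\code{no_prediction}, or
#'   domain-specific labels mapped via \code{positive_labels}/
#'   \code{negative_labels})
#' @param outcomes data.frame with columns \code{query} and \code{result}
#'   (\code{supports-positive}/\code{supports-negative})
#' @param positive_labels,negative_labels prediction labels counted as
#'   positive / negative calls
#' @return list with counts, \code{accuracy} = correct / (correct +
#'   incorrect) over definitive predictions, \code{conservative_accuracy}
#'   counting no-prediction cases as incorrect (with its denominator), and
#'   any \code{unmapped} outcome rows
#' @export
score_predictions <- function(predictions, outcomes,
                              positive_labels = c("positive", "reprograms",
                                                  "dispensable",
                                                  "always_before"),
                              negative_labels = c("negative", "fails",
                                                  "required",
                                                  "never_before")) {
  if (is.data.frame(predictions)) {
    predictions <- stats::setNames(predictions$outcome, predictions$query)
  }
  stopifnot(all(c("query", "result") %in% names(outcomes)))
  unmapped <- setdiff(outcomes$query, names(predictions))
  mapped <- outcomes[outcomes$query %in% names(predictions), , drop = FALSE]
  pred <- predictions[mapped$query]
  call <- ifelse(pred %in% positive_labels, "positive",
                 ifelse(pred %in% negative_labels, "negative",
                        "no_prediction"))
  supports <- ifelse(mapped$result == "supports-positive",
                     "positive", "negative")
  n_correct <- sum(call != "no_prediction" & call == supports)
  n_incorrect <- sum(call != "no_prediction" & call != supports)
  n_nopred <- sum(call == "no_prediction")
  denom <- n_correct + n_incorrect
  denom_cons <- denom + n_nopred
  list(n_correct = n_correct, n_incorrect = n_incorrect,
       n_no_prediction = n_nopred,
       accuracy = if (denom) n_correct / denom else NA_real_,
       conservative_accuracy = if (denom_cons) n_correct / denom_cons
                               else NA_real_,
       conservative_denominator = denom_cons,
       unmapped = unmapped)
}
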