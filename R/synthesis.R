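#' Synthesise concrete models consistent with experimental constraints
#'
#' Decides whether any concrete model of the ABN (an optional-interaction
#' subset plus a regulation-condition assignment) generates trajectories
#' satisfying every constraint. The decision is made by a CDCL SAT solver on
#' a bounded-model-checking encoding in which all experiments share the
#' model-choice variables. Returned witnesses are always re-simulated with
#' the reference dynamics ([check_constraint()]) independently of the
#' solver.
#'
#' @param network an [abn()]
#' @param constraints list of [experiment()] / [comparative()] objects, or
#'   the list returned by [builtin_resetting_constraints()]
#' @param max_conflicts solver conflict budget per query; exceeding it gives
#'   status \code{"indeterminate"}, never \code{"unsatisfiable"}
#' @return list of class \code{"synthesis_result"}: \code{status}
#'   (\code{satisfiable}/\code{unsatisfiable}/\code{indeterminate}),
#'   \code{witness} (a [concrete_model()] when satisfiable) and
#'   \code{witness_trajectories} (per-constraint simulated trajectories of
#'   the witness).
#' @export
synthesize <- function(network, constraints,
                       max_conflicts = getOption("abnsynth.max_conflicts",
                                                 2e6)) {
  constraints <- flatten_constraints(constraints)
  enc <- build_encoding(network, constraints)
  res <- cnf_solve(enc$cnf, max_conflicts = max_conflicts)
  out <- list(status = switch(res$status, sat = "satisfiable",
                              unsat = "unsatisfiable", "indeterminate"),
              witness = NULL, witness_trajectories = NULL)
  if (res$status == "sat") {
    w <- decode_witness(enc, res$model)
    verify_witness(w, constraints)
    out$witness <- w
    out$witness_trajectories <- lapply(constraints, function(con) {
      if (inherits(con, "comparative")) {
        list(treated = sync_trajectory(w, con$treated$initial,
                                       con$treated$sched, con$bound),
             reference = sync_trajectory(w, con$reference$initial,
                                         con$reference$sched, con$bound))
      } else {
        sync_trajectory(w, con$initial, con$sched, con$bound)
      }
    })
    names(out$witness_trajectories) <-
      vapply(constraints, function(con) con$name, "")
  }
  class(out) <- "synthesis_result"
  out
}

#' @export
print.synthesis_result <- function(x, ...) {
  cat("Synthesis:", x$status, "\n")
  if (!is.null(x$witness)) print(x$witness)
  invisible(x)
}

verify_witness <- function(witness, constraints) {
  for (con in constraints) {
    if (!check_constraint(witness, con)) {
      stop("internal error: solver witness fails constraint '",
           con$name, "' under re-simulation")
    }
  }
  invisible(TRUE)
}

solve_status <- function(enc, extra_units = integer(),
                         extra_clauses = list(), max_conflicts = 2e6) {
  cnf_solve(enc$cnf, extra_units = extra_units,
            extra_clauses = extra_clauses, max_conflicts = max_conflicts)
}

#' Classify optional interactions as required, disallowed or possible
#'
#' Finds one consistent concrete model, then tests each optional interaction
#' individually: an interaction instantiated in the seed witness whose
#' removal makes the constraints unsatisfiable is *required* (present in
#' every consistent model); one absent from the witness whose imposition
#' makes them unsatisfiable is *disallowed* (present in none); all others
#' remain *possible*.
#'
#' @inheritParams synthesize
#' @return character vector over the optional interactions of
#'   \code{network}, values in \code{required}, \code{disallowed},
#'   \code{possible} (or \code{indeterminate} on solver budget exhaustion),
#'   named \code{"source->target"} / \code{"source-|target"}.
#' @export
classify_interactions <- function(network, constraints,
                                  max_conflicts =
                                    getOption("abnsynth.max_conflicts", 2e6)) {
  constraints <- flatten_constraints(constraints)
  enc <- build_encoding(network, constraints)
  base <- solve_status(enc, max_conflicts = max_conflicts)
  if (base$status == "unsat") {
    stop("constraints are unsatisfiable; nothing to classify")
  }
  if (base$status == "unknown") stop("solver budget exhausted on base query")
  witness <- decode_witness(enc, base$model)
  verify_witness(witness, constraints)
  opt <- enc$opt
  out <- character(length(opt))
  for (i in seq_along(opt)) {
    ev <- enc$elit[opt[i]]
    unit <- if (witness$chosen_optional[i]) -ev else ev
    res <- solve_status(enc, extra_units = unit,
                        max_conflicts = max_conflicts)
    out[i] <- switch(res$status,
                     unsat = if (witness$chosen_optional[i]) "required"
                             else "disallowed",
                     sat = "possible",
                     "indeterminate")
  }
  names(out) <- interaction_labels(network)[opt]
  out
}

interaction_labels <- function(network) {
  ia <- network$interactions
  paste0(ia$source, ifelse(ia$sign == "positive", "->", "-|"), ia$target)
}

#' Classify regulation-condition usage per component
#'
#' A condition is *used* by a component iff some consistent model assigns
#' it, *unused* iff fixing it makes the constraints unsatisfiable.
#'
#' @inheritParams synthesize
#' @return named list (per gene) of character vectors over the gene's
#'   allowed condition indices, values \code{used}/\code{unused}/
#'   \code{indeterminate}.
#' @export
classify_conditions <- function(network, constraints,
                                max_conflicts =
                                  getOption("abnsynth.max_conflicts", 2e6)) {
  constraints <- flatten_constraints(constraints)
  enc <- build_encoding(network, constraints)
  base <- solve_status(enc, max_conflicts = max_conflicts)
  if (base$status == "unsat") {
    stop("constraints are unsatisfiable; nothing to classify")
  }
  if (base$status == "unknown") stop("solver budget exhausted on base query")
  genes <- network_genes(network)
  out <- lapply(genes, function(g) {
    sv <- enc$svar[[g]]
    vapply(seq_along(sv), function(k) {
      res <- solve_status(enc, extra_units = sv[k],
                          max_conflicts = max_conflicts)
      switch(res$status, sat = "used", unsat = "unused", "indeterminate")
    }, "")
  })
  names(out) <- genes
  for (g in genes) names(out[[g]]) <- names(enc$svar[[g]])
  out
}

#' Count consistent concrete models by enumeration with blocking clauses
#'
#' Each satisfying assignment's full (topology, condition-assignment) vector
#' is blocked and the solver re-run, so the count is of concrete models.
#'
#' @inheritParams synthesize
#' @param cap stop counting at this many models
#' @return list with \code{count} and \code{capped} (TRUE when enumeration
#'   stopped at \code{cap})
#' @export
count_models <- function(network, constraints, cap = 10000,
                         max_conflicts =
                           getOption("abnsynth.max_conflicts", 2e6)) {
  constraints <- flatten_constraints(constraints)
  enc <- build_encoding(network, constraints)
  genes <- network_genes(network)
  blocking <- list()
  count <- 0L
  repeat {
    res <- solve_status(enc, extra_clauses = blocking,
                        max_conflicts = max_conflicts)
    if (res$status == "unknown") {
      return(list(count = count, capped = TRUE, indeterminate = TRUE))
    }
    if (res$status == "unsat") break
    count <- count + 1L
    if (count >= cap) return(list(count = count, capped = TRUE))
    block <- integer()
    if (length(enc$opt)) {
      ev <- enc$elit[enc$opt]
      block <- ifelse(res$model[ev], -ev, ev)
    }
    for (g in genes) {
      sv <- enc$svar[[g]]
      block <- c(block, -sv[which(res$model[sv])[1L]])
    }
    blocking[[length(blocking) + 1L]] <- block
  }
  list(count = count, capped = FALSE)
}

#' Find a consistent model with the fewest instantiated interactions
#'
#' Minimises the number of instantiated interactions (definite plus chosen
#' optional) by binary search over a cardinality bound; minimality is
#' certified by unsatisfiability at one fewer interaction.
#'
#' @inheritParams synthesize
#' @return list with \code{model} (the minimal [concrete_model()]) and
#'   \code{n_interactions} (definite + chosen optional count)
#' @export
minimal_model <- function(network, constraints,
                          max_conflicts =
                            getOption("abnsynth.max_conflicts", 2e6)) {
  constraints <- flatten_constraints(constraints)
  enc <- build_encoding(network, constraints)
  base <- solve_status(enc, max_conflicts = max_conflicts)
  if (base$status == "unsat") stop("constraints are unsatisfiable")
  if (base$status == "unknown") stop("solver budget exhausted on base query")
  best <- decode_witness(enc, base$model)
  if (!length(enc$opt)) {
    verify_witness(best, constraints)
    return(list(model = best, n_interactions = n_instantiated(best)))
  }
  evars <- enc$elit[enc$opt]
  sat_at <- function(k) {
    mark <- cnf_mark(enc$cnf)
    cnf_at_most_k(enc$cnf, evars, k)
    res <- solve_status(enc, max_conflicts = max_conflicts)
    cnf_reset(enc$cnf, mark)
    res
  }
  lo <- 0L
  hi <- sum(best$chosen_optional)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    res <- sat_at(mid)
    if (res$status == "unknown") stop("solver budget exhausted")
    if (res$status == "sat") {
      hi <- mid
      best <- decode_witness(enc, res$model)
    } else {
      lo <- mid + 1L
    }
  }
  verify_witness(best, constraints)
  list(model = best, n_interactions = n_instantiated(best))
}

strip_component_state <- function(state, comp) {
  state[setdiff(names(state), comp)]
}

strip_component_experiment <- function(exp, comp) {
  cl <- exp$sched$clamps
  cl <- cl[cl$component != comp, , drop = FALSE]
  sched <- schedule(exp$sched$inputs, cl)
  keeps <- list()
  for (ex in exp$expectations) {
    st <- strip_component_state(ex$state, comp)
    if (length(ex$state) && !length(st)) next  # mentioned only this component
    keeps[[length(keeps) + 1L]] <- expectation(ex$modality, st, ex$from, ex$to)
  }
  if (length(exp$expectations) && !length(keeps)) return(NULL)
  experiment(exp$name, sched, strip_component_state(exp$initial, comp),
             keeps, exp$bound)
}

strip_component_constraint <- function(con, comp) {
  if (inherits(con, "comparative")) {
    target <- strip_component_state(con$target, comp)
    if (!length(target)) return(NULL)
    tr <- strip_component_experiment(
      experiment(con$treated$name, con$treated$sched, con$treated$initial,
                 list(), con$bound), comp)
    rf <- strip_component_experiment(
      experiment(con$reference$name, con$reference$sched,
                 con$reference$initial, list(), con$bound), comp)
    comparative(con$name, tr, rf, target)
  } else {
    strip_component_experiment(con, comp)
  }
}

remove_component <- function(network, comp) {
  keep <- setdiff(network$components, comp)
  ia <- network$interactions
  ia <- ia[ia$source != comp & ia$target != comp, , drop = FALSE]
  abn(data.frame(name = keep, role = unname(network$roles[keep])), ia,
      network$allowed_conditions[intersect(names(network$allowed_conditions),
                                           keep)])
}

#' Test constraint satisfiability after deleting each component
#'
#' Removes one gene at a time — together with its interactions and any
#' constraint expectations that concern only it — and reports whether the
#' remaining constraints stay satisfiable. Signals cannot be deleted.
#'
#' @inheritParams synthesize
#' @param components genes to scan (default: all genes)
#' @return named character vector of statuses per deleted component
#' @export
component_deletion_scan <- function(network, constraints,
                                    components = network_genes(network),
                                    max_conflicts =
                                      getOption("abnsynth.max_conflicts",
                                                2e6)) {
  constraints <- flatten_constraints(constraints)
  if (any(network$roles[components] == "signal")) {
    stop("signals cannot be deleted")
  }
  out <- vapply(components, function(comp) {
    reduced_net <- remove_component(network, comp)
    reduced_cons <- Filter(Negate(is.null),
                           lapply(constraints, strip_component_constraint,
                                  comp = comp))
    synthesize(reduced_net, reduced_cons, max_conflicts)$status
  }, "")
  names(out) <- components
  out
}

#' Randomised-network control for constraint specificity
#'
#' Generates random ABNs with the same component roster and the same counts
#' of definite/optional and positive/negative interactions as the template
#' (targets drawn among genes, sources among all components, no duplicate
#' signed edges, self-loops excluded unless the template contains one) and
#' reports how many satisfy the constraints.
#'
#' @param template the data-derived [abn()] whose shape is preserved
#' @inheritParams synthesize
#' @param n_models number of random networks to draw
#' @param seed RNG seed (recorded in the output)
#' @return list with \code{n_satisfiable}, \code{n_indeterminate},
#'   \code{n_models}, \code{seed}
#' @export
random_abn_control <- function(template, constraints, n_models, seed,
                               max_conflicts =
                                 getOption("abnsynth.max_conflicts", 2e6)) {
  stopifnot(n_models >= 1)
  constraints <- flatten_constraints(constraints)
  set.seed(seed)
  ia <- template$interactions
  cats <- table(definite = ia$definite, sign = ia$sign)
  allow_self <- any(ia$source == ia$target)
  genes <- network_genes(template)
  comps <- template$components
  pairs <- expand.grid(source = comps, target = genes,
                       stringsAsFactors = FALSE)
  if (!allow_self) pairs <- pairs[pairs$source != pairs$target, ]
  n_sat <- 0L
  n_ind <- 0L
  for (m in seq_len(n_models)) {
    rows <- list()
    taken <- character()
    for (def in c(TRUE, FALSE)) {
      for (sg in c("positive", "negative")) {
        k <- sum(ia$definite == def & ia$sign == sg)
        if (!k) next
        avail <- which(!paste(pairs$source, pairs$target, sg) %in% taken)
        pick <- sample(avail, k)
        taken <- c(taken, paste(pairs$source[pick], pairs$target[pick], sg))
        rows[[length(rows) + 1L]] <-
          data.frame(source = pairs$source[pick],
                     target = pairs$target[pick],
                     sign = sg, definite = def)
      }
    }
    net <- abn(data.frame(name = comps, role = unname(template$roles[comps])),
               do.call(rbind, rows), template$allowed_conditions)
    st <- synthesize(net, constraints, max_conflicts)$status
    if (st == "satisfiable") n_sat <- n_sat + 1L
    if (st == "indeterminate") n_ind <- n_ind + 1L
  }
  list(n_satisfiable = n_sat, n_indeterminate = n_ind,
       n_models = n_models, seed = seed)
}

#' Constrained Abstract Boolean Network
#'
#' Bundles a network with a satisfiable constraint set; the object is what
#' the prediction engine interrogates ("all consistent models ...").
#'
#' @inheritParams synthesize
#' @return list of class \code{"cabn"} with the network, flattened
#'   constraints, and a seed witness
#' @export
cabn <- function(network, constraints,
                 max_conflicts = getOption("abnsynth.max_conflicts", 2e6)) {
  constraints <- flatten_constraints(constraints)
  syn <- synthesize(network, constraints, max_conflicts)
  if (syn$status != "satisfiable") {
    stop("constraints are ", syn$status, "; no cABN exists")
  }
  structure(list(network = network, constraints = constraints,
                 witness = syn$witness,
                 env = new.env(parent = emptyenv())),
            class = "cabn")
}

#' @export
print.cabn <- function(x, ...) {
  cat(sprintf("Constrained ABN: %d constraints over ", length(x$constraints)))
  print(x$network)
  invisible(x)
}
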