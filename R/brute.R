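#' Exhaustive enumeration of an ABN's concrete-model space
#'
#' Enumerates every concrete model (optional-interaction subset x regulation
#' condition assignment) of a small ABN and checks constraints by direct
#' simulation, all models in parallel via matrix operations. This is the
#' reference semantics against which the SAT-based synthesis engine is
#' validated; it is only feasible for small candidate spaces.
#'
#' @param network an [abn()]
#' @param cap refuse to enumerate spaces larger than this many models
#' @return list with \code{E} (models x optional-interaction logical matrix),
#'   \code{S} (models x gene integer matrix of condition indices 0..8)
#' @export
enumerate_model_space <- function(network, cap = 2^20) {
  opt <- optional_interactions(network)
  genes <- network_genes(network)
  sizes <- c(rep(2, length(opt)),
             lengths(network$allowed_conditions[genes]))
  if (prod(sizes) > cap) {
    stop("model space has ", prod(sizes), " models, above cap ", cap)
  }
  choices <- c(rep(list(c(FALSE, TRUE)), length(opt)),
               network$allowed_conditions[genes])
  grid <- expand.grid(choices, KEEP.OUT.ATTRS = FALSE)
  ne <- length(opt)
  E <- as.matrix(grid[, seq_len(ne), drop = FALSE])
  S <- as.matrix(grid[, ne + seq_along(genes), drop = FALSE])
  colnames(E) <- if (ne) paste0("opt", seq_len(ne)) else character()
  colnames(S) <- genes
  storage.mode(E) <- "logical"
  storage.mode(S) <- "integer"
  list(E = E, S = S)
}

# Simulate all models in `space` under one experiment schedule; returns a
# (models x steps) logical matrix of whether `partial` holds at each step
# 0..bound, plus the full state array needed for stability checks.
bf_run <- function(network, space, initial, sched, bound) {
  comps <- network$components
  idx <- stats::setNames(seq_along(comps), comps)
  genes <- network_genes(network)
  ia <- network$interactions
  opt <- optional_interactions(network)
  M <- nrow(space$E)
  arr <- regulation_condition_array()

  present <- matrix(TRUE, M, nrow(ia))
  if (length(opt)) present[, opt] <- space$E

  per_gene <- lapply(genes, function(g) {
    rows_a <- which(ia$target == g & ia$sign == "positive")
    rows_r <- which(ia$target == g & ia$sign == "negative")
    list(a = rows_a, asrc = idx[ia$source[rows_a]],
         r = rows_r, rsrc = idx[ia$source[rows_r]])
  })
  names(per_gene) <- genes

  init <- stats::setNames(rep(FALSE, length(comps)), comps)
  if (length(initial)) init[names(initial)] <- initial
  for (comp in comps) {
    sv <- scheduled_value(sched, comp, 0, network$roles)
    if (!is.na(sv)) init[comp] <- sv
  }
  state <- matrix(rep(init, each = M), nrow = M,
                  dimnames = list(NULL, comps))

  states <- vector("list", bound + 2L)  # steps 0..bound+1
  states[[1L]] <- state
  level_of <- function(nact, ntot) {
    ifelse(ntot == 0L | nact == 0L, 1L, ifelse(nact == ntot, 3L, 2L))
  }
  for (t in seq_len(bound + 1L)) {
    nxt <- state
    for (comp in comps) {
      sv <- scheduled_value(sched, comp, t, network$roles)
      if (!is.na(sv)) {
        nxt[, comp] <- sv
      } else if (network$roles[[comp]] == "gene") {
        pg <- per_gene[[comp]]
        if (length(pg$a) == 0L) {
          nxt[, comp] <- FALSE
        } else {
          pa <- present[, pg$a, drop = FALSE]
          na_tot <- rowSums(pa)
          na_act <- rowSums(pa & state[, pg$asrc, drop = FALSE])
          la <- level_of(na_act, na_tot)
          if (length(pg$r)) {
            pr <- present[, pg$r, drop = FALSE]
            lr <- level_of(rowSums(pr & state[, pg$rsrc, drop = FALSE]),
                           rowSums(pr))
          } else {
            lr <- rep(1L, M)
          }
          nxt[, comp] <- arr[cbind(space$S[, comp] + 1L, la, lr)]
        }
      } else {
        nxt[, comp] <- FALSE
      }
    }
    state <- nxt
    states[[t + 1L]] <- state
  }
  states
}

bf_holds <- function(states, partial, M) {
  if (!length(partial)) {
    return(matrix(TRUE, M, length(states)))
  }
  res <- vapply(states, function(st) {
    sub <- st[, names(partial), drop = FALSE]
    rowSums(sub == rep(partial, each = M)) == length(partial)
  }, logical(M))
  if (!is.matrix(res)) res <- matrix(res, nrow = M)
  res
}

bf_check_experiment <- function(network, space, exp) {
  M <- nrow(space$E)
  states <- bf_run(network, space, exp$initial, exp$sched, exp$bound)
  ok <- rep(TRUE, M)
  for (ex in exp$expectations) {
    rg <- resolve_range(ex, exp$bound)
    holds <- bf_holds(states, ex$state, M)  # cols = steps 0..bound+1
    cols <- (rg["from"]:rg["to"]) + 1L
    sub <- holds[, cols, drop = FALSE]
    this <- switch(ex$modality,
      reached = rowSums(sub) > 0L,
      never = rowSums(sub) == 0L,
      held = rowSums(sub) == length(cols),
      stable = {
        s <- rg["to"]
        eq <- rowSums(states[[s + 1L]] == states[[s + 2L]]) ==
          ncol(states[[s + 1L]])
        holds[, s + 1L] & eq
      })
    ok <- ok & this
  }
  ok
}

bf_check_comparative <- function(network, space, comp) {
  M <- nrow(space$E)
  first_hit <- function(exp) {
    states <- bf_run(network, space, exp$initial, exp$sched, comp$bound)
    holds <- bf_holds(states, comp$target, M)[, seq_len(comp$bound + 1L),
                                              drop = FALSE]
    hit <- rep(Inf, M)
    for (t in rev(seq_len(ncol(holds)))) {
      hit[holds[, t]] <- t - 1L
    }
    hit
  }
  ref <- first_hit(comp$reference)
  treated <- first_hit(comp$treated)
  !is.finite(ref) | treated >= ref
}

flatten_constraints <- function(constraints) {
  if (is.list(constraints) &&
      !is.null(names(constraints)) &&
      all(names(constraints) %in% c("experiments", "comparatives"))) {
    constraints <- c(constraints$experiments, constraints$comparatives)
  }
  if (inherits(constraints, "experiment") ||
      inherits(constraints, "comparative")) {
    constraints <- list(constraints)
  }
  constraints
}

#' Brute-force synthesis by exhaustive enumeration
#'
#' @param network an [abn()]
#' @param constraints list of [experiment()]/[comparative()] constraints
#'   (or the list returned by [builtin_resetting_constraints()])
#' @param cap model-space cap passed to [enumerate_model_space()]
#' @return list with \code{status} (\code{"satisfiable"}/
#'   \code{"unsatisfiable"}), \code{count} of consistent models,
#'   \code{consistent} logical vector over the enumerated space, the space
#'   itself, and per-optional-interaction \code{classification}
#'   (\code{required}/\code{disallowed}/\code{possible}) plus per-gene
#'   \code{condition_usage}.
#' @export
bf_synthesize <- function(network, constraints, cap = 2^20) {
  constraints <- flatten_constraints(constraints)
  space <- enumerate_model_space(network, cap)
  ok <- rep(TRUE, nrow(space$E))
  for (con in constraints) {
    ok <- ok & if (inherits(con, "comparative")) {
      bf_check_comparative(network, space, con)
    } else {
      bf_check_experiment(network, space, con)
    }
  }
  n_ok <- sum(ok)
  classification <- character(ncol(space$E))
  if (n_ok > 0L && ncol(space$E)) {
    Eok <- space$E[ok, , drop = FALSE]
    classification <- ifelse(colSums(Eok) == n_ok, "required",
                             ifelse(colSums(Eok) == 0L, "disallowed",
                                    "possible"))
  }
  names(classification) <- colnames(space$E)
  genes <- network_genes(network)
  usage <- lapply(genes, function(g) {
    allowed <- network$allowed_conditions[[g]]
    used <- vapply(allowed, function(cc) any(space$S[ok, g] == cc), NA)
    stats::setNames(ifelse(used, "used", "unused"), allowed)
  })
  names(usage) <- genes
  list(status = if (n_ok) "satisfiable" else "unsatisfiable",
       count = n_ok, consistent = ok, space = space,
       classification = classification, condition_usage = usage)
}
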