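#' Asynchronous stochastic simulation of a concrete model
#'
#' Under the asynchronous scheme a single unclamped gene updates at each
#' step, the updating gene chosen at random. This relaxes the synchronous
#' assumption used for synthesis and is used to cross-validate predictions
#' on a single model (typically the minimal model). Two update policies are
#' available: \code{"uniform"} draws the updating gene independently each
#' step; \code{"rounds"} updates genes in random-permutation rounds, which
#' enforces a weak fairness (every gene updates once per round).
#'
#' @param model a [concrete_model()]
#' @param initial partial initial state (unspecified genes Low)
#' @param sched a [schedule()]; clamped components and signals hold their
#'   scheduled value throughout
#' @param max_steps number of single-gene updates
#' @param seed RNG seed
#' @param policy update-order policy, \code{"uniform"} or \code{"rounds"}
#' @return a \code{(max_steps+1) x n_components} logical state matrix
#' @export
async_trajectory <- function(model, initial, sched = schedule(),
                             max_steps = 100, seed = 1,
                             policy = c("uniform", "rounds")) {
  stopifnot(max_steps >= 1)
  policy <- match.arg(policy)
  set.seed(seed)
  cm <- compile_model(model)
  state <- complete_initial_state(model, initial, sched)
  clamped_at <- function(comp, t) {
    !is.na(scheduled_value(sched, comp, t, cm$roles))
  }
  states <- matrix(FALSE, max_steps + 1L, length(cm$comps),
                   dimnames = list(0:max_steps, cm$comps))
  states[1L, ] <- state
  order_queue <- character()
  for (t in seq_len(max_steps)) {
    # refresh scheduled values (clamp windows may open/close)
    for (comp in cm$comps) {
      sv <- scheduled_value(sched, comp, t, cm$roles)
      if (!is.na(sv)) state[cm$idx[[comp]]] <- sv
    }
    free <- cm$genes[!vapply(cm$genes, clamped_at, NA, t = t)]
    if (length(free)) {
      if (policy == "uniform") {
        g <- free[sample.int(length(free), 1L)]
      } else {
        if (!length(order_queue)) {
          order_queue <- free[sample.int(length(free))]
        }
        g <- order_queue[1L]
        order_queue <- order_queue[-1L]
        if (!g %in% free) g <- free[sample.int(length(free), 1L)]
      }
      rule <- cm$rules[[g]]
      na <- length(rule$act)
      val <- FALSE
      if (na > 0L) {
        la <- level_index(sum(state[rule$act]), na)
        if (la > 1L) {
          lr <- level_index(sum(state[rule$rep]), length(rule$rep))
          val <- rule$table[la, lr]
        }
      }
      state[cm$idx[[g]]] <- val
    }
    states[t + 1L, ] <- state
  }
  states
}

async_first_activation <- function(states, genes) {
  vapply(genes, function(g) {
    w <- which(states[, g])
    if (length(w)) w[1L] - 1L else NA_integer_
  }, 0L)
}

#' Evaluate a query battery on one model under asynchronous updates
#'
#' Each query is evaluated empirically over \code{n_runs} simulations.
#' Reachability queries count positive when the target is reached in more
#' than \code{reach_threshold} of runs (default: any run, the permissive
#' convention for non-deterministic reachability); ordering queries by the
#' majority of runs respecting the order.
#'
#' @inheritParams async_trajectory
#' @param battery list of queries; each a list with \code{name},
#'   \code{type} (\code{"reachability"} or \code{"ordering"}),
#'   \code{sched}, \code{initial}, and either \code{target} (partial state)
#'   or \code{geneX}/\code{geneY}
#' @param n_runs simulations per query
#' @param reach_threshold fraction of runs above which a reachability query
#'   counts positive (default 0: reached in any run)
#' @return list with \code{summary} (per-query data.frame of fractions and
#'   outcomes) and \code{first_activation} (per-query list of per-gene
#'   first-activation step matrices)
#' @export
async_battery <- function(model, battery, n_runs = 1000, max_steps = 100,
                          seed = 1, policy = c("uniform", "rounds"),
                          reach_threshold = 0) {
  policy <- match.arg(policy)
  genes <- network_genes(model$network)
  rows <- list()
  firsts <- list()
  for (qi in seq_along(battery)) {
    q <- battery[[qi]]
    hit <- logical(n_runs)
    fa <- matrix(NA_integer_, n_runs, length(genes),
                 dimnames = list(NULL, genes))
    for (r in seq_len(n_runs)) {
      states <- async_trajectory(model, q$initial, q$sched, max_steps,
                                 seed = seed + (qi - 1L) * n_runs + r,
                                 policy = policy)
      fa[r, ] <- async_first_activation(states, genes)
      if (q$type == "reachability") {
        sub <- states[, names(q$target), drop = FALSE]
        hit[r] <- any(colSums(t(sub) == q$target) == length(q$target))
      } else {
        fx <- async_first_activation(states, q$geneX)
        fy <- async_first_activation(states, q$geneY)
        # order respected when Y never activates before X has
        hit[r] <- is.na(fy) || (!is.na(fx) && fx <= fy)
      }
    }
    frac <- mean(hit)
    outcome <- if (q$type == "reachability") {
      if (frac > reach_threshold) "positive" else "negative"
    } else {
      if (frac > 0.5) "always_before" else "no_order"
    }
    rows[[qi]] <- data.frame(query = q$name, type = q$type,
                             fraction = frac, outcome = outcome)
    firsts[[q$name]] <- fa
  }
  list(summary = do.call(rbind, rows),
       first_activation = firsts,
       n_runs = n_runs, max_steps = max_steps, seed = seed, policy = policy)
}
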