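#' Deterministic synchronous dynamics of a concrete model
#'
#' Under the synchronous update scheme every gene updates simultaneously at
#' each step: its next value is its regulation condition evaluated on the
#' current values of its instantiated activators and repressors. Signals and
#' clamped components take their scheduled value instead.
#'
#' @name sync-dynamics
NULL

# Precompute per-gene regulator index lists and condition tables so that
# stepping is a tight loop. States are logical vectors ordered like
# model$network$components.
compile_model <- function(model) {
  net <- model$network
  comps <- net$components
  idx <- stats::setNames(seq_along(comps), comps)
  ia <- net$interactions[model$present, , drop = FALSE]
  genes <- network_genes(net)
  arr <- regulation_condition_array()
  rules <- lapply(genes, function(g) {
    mine <- ia[ia$target == g, , drop = FALSE]
    list(act = idx[mine$source[mine$sign == "positive"]],
         rep = idx[mine$source[mine$sign == "negative"]],
         table = arr[model$conditions[[g]] + 1L, , ])
  })
  names(rules) <- genes
  list(comps = comps, idx = idx, genes = genes, roles = net$roles,
       gene_idx = idx[genes], rules = rules)
}

level_index <- function(n_active, n_total) {
  # 1 = none, 2 = some, 3 = all
  if (n_total == 0L || n_active == 0L) return(1L)
  if (n_active == n_total) return(3L)
  2L
}

step_compiled <- function(cm, state, sched, t) {
  nxt <- state
  for (i in seq_along(cm$comps)) {
    comp <- cm$comps[i]
    sv <- scheduled_value(sched, comp, t, cm$roles)
    if (!is.na(sv)) {
      nxt[i] <- sv
    } else if (cm$roles[[comp]] == "gene") {
      rule <- cm$rules[[comp]]
      na <- length(rule$act)
      if (na == 0L) {
        nxt[i] <- FALSE
      } else {
        acta <- sum(state[rule$act])
        la <- level_index(acta, na)
        if (la == 1L) {
          nxt[i] <- FALSE
        } else {
          lr <- level_index(sum(state[rule$rep]), length(rule$rep))
          nxt[i] <- rule$table[la, lr]
        }
      }
    } else {
      nxt[i] <- FALSE  # signal with no scheduled value defaults off
    }
  }
  nxt
}

# Complete a partial initial state: named logical over all components, with
# unspecified genes Low and signals/clamped components taking scheduled
# values at step 0.
complete_initial_state <- function(model, initial, sched) {
  cm_net <- model$network
  state <- stats::setNames(rep(FALSE, length(cm_net$components)),
                           cm_net$components)
  if (length(initial)) {
    unknown <- setdiff(names(initial), cm_net$components)
    if (length(unknown)) {
      stop("initial state references unknown component(s): ",
           paste(unknown, collapse = ", "))
    }
    state[names(initial)] <- initial
  }
  for (comp in cm_net$components) {
    sv <- scheduled_value(sched, comp, 0, cm_net$roles)
    if (!is.na(sv)) state[comp] <- sv
  }
  state
}

#' Advance a concrete model by one synchronous step
#'
#' @param model a [concrete_model()]
#' @param state named logical vector over all components (TRUE = High)
#' @param sched a [schedule()]
#' @param t the step index of the state being produced (used to decide which
#'   clamps apply); defaults to 1.
#' @return the next state, a named logical vector
#' @export
sync_step <- function(model, state, sched = schedule(), t = 1) {
  cm <- compile_model(model)
  if (!setequal(names(state), cm$comps)) {
    stop("state must cover exactly the network components")
  }
  step_compiled(cm, state[cm$comps], sched, t)
}

#' Simulate a bounded synchronous trajectory
#'
#' Runs \code{bound} synchronous updates from a (possibly partial) initial
#' state. Unspecified genes start Low; signals and clamped components follow
#' the schedule throughout.
#'
#' @inheritParams sync_step
#' @param initial named logical vector, possibly partial
#' @param bound number of update steps (the trajectory has
#'   \code{bound + 1} states, at steps \code{0..bound})
#' @return a list of class \code{"trajectory"} with elements \code{states}
#'   (a \code{(bound+1) x n_components} logical matrix, rows named by step),
#'   \code{fixed_point} (TRUE iff one further update leaves the final state
#'   unchanged and no finite clamp is still pending), \code{bound} and
#'   \code{next_state} (the state one step past the bound, used for
#'   stability checks).
#' @export
sync_trajectory <- function(model, initial, sched = schedule(), bound = 20) {
  stopifnot(bound >= 1)
  cm <- compile_model(model)
  state <- complete_initial_state(model, initial, sched)
  states <- matrix(FALSE, nrow = bound + 1L, ncol = length(cm$comps),
                   dimnames = list(0:bound, cm$comps))
  states[1L, ] <- state
  for (t in seq_len(bound)) {
    state <- step_compiled(cm, state, sched, t)
    states[t + 1L, ] <- state
  }
  nxt <- step_compiled(cm, state, sched, bound + 1L)
  cl <- sched$clamps
  pending <- nrow(cl) > 0L && any(is.finite(cl$to) & cl$to > bound)
  structure(list(states = states,
                 fixed_point = all(nxt == state) && !pending,
                 next_state = nxt,
                 bound = bound),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Synchronous trajectory: %d steps, fixed point: %s\n",
              x$bound, x$fixed_point))
  invisible(x)
}

# Does a full state satisfy a partial state?
state_matches <- function(state, partial) {
  if (!length(partial)) return(TRUE)
  all(state[names(partial)] == partial)
}

# Steps (0-based) of a trajectory at which a partial state holds.
matching_steps <- function(traj, partial) {
  if (!length(partial)) return(0:traj$bound)
  sub <- traj$states[, names(partial), drop = FALSE]
  ok <- colSums(t(sub) == partial) == length(partial)
  which(ok) - 1L
}
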