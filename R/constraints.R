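#' Encode an experimental observation as a trajectory constraint
#'
#' An experiment constraint states that, under given culture inputs and
#' perturbations, every consistent concrete model's synchronous trajectory
#' from the given initial state must show (or never show) certain partial
#' states. Modalities:
#' \describe{
#'   \item{\code{reached}}{the partial state holds at some step in
#'     \code{[from, to]}}
#'   \item{\code{never}}{the partial state holds at no step in
#'     \code{[from, to]} (alias \code{never-reached})}
#'   \item{\code{held}}{the partial state holds at every step in
#'     \code{[from, to]}; with the default range \code{[bound-1, bound]}
#'     this is the "final state at two sequential steps" encoding used when
#'     a full stable state cannot be defined}
#'   \item{\code{stable}}{the partial state holds at step \code{to}
#'     (default: the bound) and that state is a synchronous fixed point
#'     (alias \code{reached-and-stable})}
#' }
#'
#' @param modality one of \code{"reached"}, \code{"never"}, \code{"held"},
#'   \code{"stable"}
#' @param state named logical partial state (TRUE = High)
#' @param from,to step range (0-based, inclusive); defaults depend on the
#'   modality as described above and are resolved against the experiment
#'   bound when the experiment is built.
#' @return a list of class \code{"expectation"}
#' @export
expectation <- function(modality, state, from = NULL, to = NULL) {
  modality <- switch(modality,
                     "reached-and-stable" = "stable",
                     "never-reached" = "never",
                     modality)
  if (!modality %in% c("reached", "never", "held", "stable")) {
    stop("unknown expectation modality: ", modality)
  }
  stopifnot(is.logical(state), length(names(state)) == length(state))
  structure(list(modality = modality, state = state, from = from, to = to),
            class = "expectation")
}

resolve_range <- function(ex, bound) {
  from <- ex$from
  to <- ex$to
  if (ex$modality == "stable") {
    if (is.null(to)) to <- bound
    from <- to
  } else if (ex$modality == "held") {
    if (is.null(to)) to <- bound
    if (is.null(from)) from <- max(0L, to - 1L)
  } else {
    if (is.null(from)) from <- 0L
    if (is.null(to)) to <- bound
  }
  if (from < 0L || to > bound || from > to) {
    stop("expectation step range [", from, ", ", to,
         "] outside trajectory bound ", bound)
  }
  c(from = as.integer(from), to = as.integer(to))
}

#' @rdname expectation
#' @param name experiment name
#' @param sched a [schedule()] of inputs and clamps
#' @param initial named logical partial initial state; unspecified genes
#'   start Low
#' @param expectations list of [expectation()] objects
#' @param bound trajectory bound in steps (default 20)
#' @return for \code{experiment}, a list of class \code{"experiment"}
#' @export
experiment <- function(name, sched, initial, expectations, bound = 20) {
  stopifnot(inherits(sched, "schedule"), bound >= 1)
  if (inherits(expectations, "expectation")) {
    expectations <- list(expectations)
  }
  for (ex in expectations) {
    stopifnot(inherits(ex, "expectation"))
    resolve_range(ex, bound)
  }
  structure(list(name = name, sched = sched, initial = initial,
                 expectations = expectations, bound = as.integer(bound)),
            class = "experiment")
}

#' Paired-trajectory comparative constraint
#'
#' Requires, of every concrete model, that the treated trajectory does not
#' reach the target partial state at an earlier step than the reference
#' trajectory. The constraint is vacuously satisfied by models whose
#' reference trajectory never reaches the target within the bound.
#' First-hitting steps are the smallest step at which the target partial
#' state holds, not necessarily stably.
#'
#' @param name constraint name
#' @param treated,reference [experiment()] objects describing the two
#'   schedules/initial states (their own expectations are ignored here; the
#'   relation is on first-hitting steps of \code{target})
#' @param target named logical partial state
#' @return a list of class \code{"comparative"}
#' @export
comparative <- function(name, treated, reference, target) {
  stopifnot(inherits(treated, "experiment"), inherits(reference, "experiment"))
  if (treated$bound != reference$bound) {
    stop("treated and reference must share a bound")
  }
  structure(list(name = name, treated = treated, reference = reference,
                 target = target, bound = treated$bound),
            class = "comparative")
}

#' Check constraints against a single concrete model by simulation
#'
#' These are the solver-independent reference semantics: every witness
#' returned by the synthesis engine is re-checked with them.
#'
#' @param model a [concrete_model()]
#' @param constraint an [experiment()] or [comparative()] object
#' @return logical
#' @export
check_constraint <- function(model, constraint) {
  if (inherits(constraint, "comparative")) {
    check_comparative_model(model, constraint)
  } else {
    check_experiment_model(model, constraint)
  }
}

check_experiment_model <- function(model, exp) {
  traj <- sync_trajectory(model, exp$initial, exp$sched, exp$bound)
  for (ex in exp$expectations) {
    rg <- resolve_range(ex, exp$bound)
    hits <- matching_steps(traj, ex$state)
    inrange <- hits[hits >= rg["from"] & hits <= rg["to"]]
    ok <- switch(ex$modality,
      reached = length(inrange) > 0L,
      never = length(inrange) == 0L,
      held = length(inrange) == rg["to"] - rg["from"] + 1L,
      stable = {
        s <- rg["to"]
        at_s <- state_matches(traj$states[s + 1L, ], ex$state)
        nxt <- if (s == exp$bound) traj$next_state else traj$states[s + 2L, ]
        at_s && all(traj$states[s + 1L, ] == nxt)
      })
    if (!ok) return(FALSE)
  }
  TRUE
}

first_hit_step <- function(model, exp, target) {
  traj <- sync_trajectory(model, exp$initial, exp$sched, exp$bound)
  hits <- matching_steps(traj, target)
  if (length(hits)) hits[1L] else Inf
}

check_comparative_model <- function(model, comp) {
  ref <- first_hit_step(model, comp$reference, comp$target)
  if (!is.finite(ref)) return(TRUE)
  first_hit_step(model, comp$treated, comp$target) >= ref
}

#' Discretize a bulk expression profile against an ESC reference
#'
#' A gene is High iff its expression is at least half (inclusive) of its
#' level in the reference condition (mouse ESCs in 2i+LIF).
#'
#' @param expr named numeric expression vector
#' @param esc_reference named numeric reference vector (strictly positive)
#' @return named logical partial state
#' @export
discretize_bulk <- function(expr, esc_reference) {
  stopifnot(length(names(expr)) == length(expr))
  esc_reference <- esc_reference[names(expr)]
  if (any(is.na(esc_reference)) || any(esc_reference <= 0)) {
    stop("reference expression must be strictly positive for every gene")
  }
  stats::setNames(expr >= 0.5 * esc_reference, names(expr))
}

#' Discretize single-cell expression by per-gene 2-means clustering
#'
#' For each gene, k-means with k = 2 is run on the log10-transformed
#' expression values across cells; cells in the higher-centroid cluster are
#' High. The reported threshold is the midpoint between the two centroids.
#' Genes with fewer than two distinct values are flagged degenerate and all
#' cells set Low.
#'
#' @param log_expr cells x genes numeric matrix of log10 expression
#' @return list with \code{binary} (cells x genes logical), \code{threshold}
#'   (per gene; NA when degenerate) and \code{degenerate} (per-gene logical)
#' @export
discretize_single_cell <- function(log_expr) {
  log_expr <- as.matrix(log_expr)
  if (nrow(log_expr) < 2L) stop("need at least 2 cells")
  ngene <- ncol(log_expr)
  gene_names <- colnames(log_expr)
  binary <- matrix(FALSE, nrow(log_expr), ngene,
                   dimnames = dimnames(log_expr))
  thr <- stats::setNames(rep(NA_real_, ngene), gene_names)
  degen <- stats::setNames(rep(FALSE, ngene), gene_names)
  for (j in seq_len(ngene)) {
    x <- log_expr[, j]
    if (length(unique(x)) < 2L) {
      degen[j] <- TRUE
      next
    }
    km <- stats::kmeans(x, centers = 2, nstart = 10)
    hi <- which.max(km$centers)
    binary[, j] <- km$cluster == hi
    thr[j] <- mean(km$centers)
  }
  list(binary = binary, threshold = thr, degenerate = degen)
}

# ---- pluripotency roster and canonical discrete states -----------------

pluripotency_tfs <- function() {
  c("Oct4", "Sox2", "Sall4", "Nanog", "Esrrb", "Klf2", "Klf4",
    "Tfcp2l1", "Gbx2", "Tbx3", "Stat3")
}

#' Canonical discrete states of the pluripotency circuit
#'
#' Named partial states used by the resetting constraints: the naive-ESC
#' state (all network TFs High, as in 2i+LIF culture), the discretized
#' GOF18 EpiSC state (only Oct4, Sox2 and Sall4 High among the TFs, with
#' MEK/ERK and Tcf3 active as in FGF2/Activin culture), and the all-off
#' state. The naive target is a partial state over the TFs only;
#' signal-proximal components (MEK/ERK, Tcf3) follow the culture inputs.
#'
#' @return named list of named logical partial states
#' @export
discrete_state_library <- function() {
  tfs <- pluripotency_tfs()
  naive <- stats::setNames(rep(TRUE, length(tfs)), tfs)
  episc <- stats::setNames(rep(FALSE, length(tfs)), tfs)
  episc[c("Oct4", "Sox2", "Sall4")] <- TRUE
  episc <- c(episc, MEKERK = TRUE, Tcf3 = TRUE)
  all_off <- stats::setNames(rep(FALSE, length(tfs) + 2L),
                             c(tfs, "MEKERK", "Tcf3"))
  list(naive_ESC = naive, GOF18_EpiSC = episc, all_off = all_off)
}

inputs_2iL <- function() c(LIF = TRUE, CH = TRUE, PD = TRUE)
inputs_2i <- function() c(LIF = FALSE, CH = TRUE, PD = TRUE)
inputs_LIF_CH <- function() c(LIF = TRUE, CH = TRUE, PD = FALSE)

#' Signal inputs for the standard culture conditions
#'
#' 2i is the dual inhibition of MEK (PD) and GSK3 (CH); LIF is the
#' cytokine input. Each condition maps to on/off values for the three
#' signal components.
#'
#' @param condition culture condition name
#' @return named logical vector over \code{LIF}, \code{CH}, \code{PD}
#' @export
culture_inputs <- function(condition = c("2i+LIF", "2i", "LIF+CH", "LIF",
                                         "none")) {
  condition <- match.arg(condition)
  switch(condition,
         "2i+LIF" = inputs_2iL(),
         "2i" = inputs_2i(),
         "LIF+CH" = inputs_LIF_CH(),
         "LIF" = c(LIF = TRUE, CH = FALSE, PD = FALSE),
         "none" = c(LIF = FALSE, CH = FALSE, PD = FALSE))
}

#' The six EpiSC-resetting constraints and the Sall4 comparative constraint
#'
#' Encodes the published observations on when EpiSC resetting to the naive
#' state can or cannot be achieved, each as a 20-step bounded-trajectory
#' constraint:
#' \enumerate{
#'   \item \strong{Control} — from the all-off state, 2i+LIF alone never
#'     reaches the naive state.
#'   \item \strong{EpiSC in 2i+LIF} — from the GOF18 EpiSC state, 2i+LIF
#'     reaches the naive state and stabilises there.
#'   \item \strong{EpiSC in 2i only} — 2i alone never reaches it.
#'   \item \strong{EpiSC in 2i with Tfcp2l1 expression} — with Tfcp2l1
#'     clamped High, 2i suffices; since Stat3 cannot be active without LIF,
#'     the target is the naive state minus Stat3, held at two sequential
#'     steps.
#'   \item \strong{Nanog-knockout EpiSC in 2i+LIF} — with Nanog clamped
#'     Low, the rest of the naive network is never activated.
#'   \item \strong{Nanog-knockout EpiSC in LIF+CH} — with Nanog clamped
#'     Low, LIF+CH activates Oct4, Esrrb, Klf2, Tfcp2l1, Klf4 and Stat3.
#' }
#' plus the comparative constraint that forced Sall4 expression never makes
#' an EpiSC reach the naive state at an earlier step than control.
#'
#' @param bound trajectory bound (default 20 steps)
#' @return list with elements \code{experiments} (list of six
#'   [experiment()]s) and \code{comparatives} (list with the Sall4
#'   [comparative()])
#' @export
builtin_resetting_constraints <- function(bound = 20) {
  lib <- discrete_state_library()
  naive <- lib$naive_ESC
  episc <- lib$GOF18_EpiSC
  naive_no_stat3 <- naive[setdiff(names(naive), "Stat3")]
  naive_no_nanog <- naive[setdiff(names(naive), "Nanog")]
  stat3_targets <- stats::setNames(
    rep(TRUE, 6L), c("Oct4", "Esrrb", "Klf2", "Tfcp2l1", "Klf4", "Stat3"))

  e1 <- experiment("control_no_factors_2iL",
                   schedule(inputs_2iL()), lib$all_off,
                   expectation("never", naive), bound)
  e2 <- experiment("episc_2iL",
                   schedule(inputs_2iL()), episc,
                   expectation("stable", naive), bound)
  e3 <- experiment("episc_2i_only",
                   schedule(inputs_2i()), episc,
                   expectation("never", naive), bound)
  e4 <- experiment("episc_2i_tfcp2l1_forced",
                   schedule(inputs_2i(), clamp("Tfcp2l1", TRUE)), episc,
                   expectation("held", naive_no_stat3), bound)
  e5 <- experiment("nanog_ko_episc_2iL",
                   schedule(inputs_2iL(), clamp("Nanog", FALSE)), episc,
                   expectation("never", naive_no_nanog), bound)
  e6 <- experiment("nanog_ko_episc_LIF_CH",
                   schedule(inputs_LIF_CH(), clamp("Nanog", FALSE)), episc,
                   expectation("reached", stat3_targets), bound)

  sall4_forced <- experiment("episc_2iL_sall4_forced",
                             schedule(inputs_2iL(), clamp("Sall4", TRUE)),
                             episc, list(), bound)
  ref <- experiment("episc_2iL_ref", schedule(inputs_2iL()), episc,
                    list(), bound)
  cmp <- comparative("sall4_not_faster_than_control",
                     sall4_forced, ref, naive)

  list(experiments = list(e1, e2, e3, e4, e5, e6),
       comparatives = list(cmp))
}
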