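#' Construct an Abstract Boolean Network (ABN)
#'
#' An ABN lists the components of a regulatory circuit together with signed
#' interactions that are either *definite* (present in every concrete model)
#' or *optional* (present in some). With \eqn{n} optional interactions the
#' ABN implicitly defines \eqn{2^n} candidate topologies; a concrete model
#' additionally assigns one regulation condition to every gene
#' (see [regulation_conditions()]).
#'
#' Components are either genes, updated by their regulators, or signals
#' (culture inputs such as LIF, CH, PD) that have no regulators and are
#' clamped by the experimental condition.
#'
#' @param components character vector of component names, or a data.frame
#'   with columns \code{name} and \code{role} (\code{"gene"}/\code{"signal"}).
#'   A plain character vector declares all components as genes.
#' @param interactions data.frame with columns \code{source}, \code{target},
#'   \code{sign} (\code{"positive"}/\code{"negative"}) and \code{definite}
#'   (logical).
#' @param allowed_conditions named list mapping gene names to integer vectors
#'   of allowed regulation-condition indices (0..8). Genes not listed are
#'   allowed all nine.
#' @return an object of class \code{"abn"}.
#' @export
abn <- function(components, interactions = NULL, allowed_conditions = list()) {
  if (is.character(components)) {
    components <- data.frame(name = components, role = "gene")
  }
  stopifnot(is.data.frame(components),
            all(c("name", "role") %in% names(components)))
  if (anyDuplicated(components$name)) {
    stop("component names must be unique")
  }
  if (!all(components$role %in% c("gene", "signal"))) {
    stop("component role must be 'gene' or 'signal'")
  }
  if (is.null(interactions)) {
    interactions <- data.frame(source = character(), target = character(),
                               sign = character(), definite = logical())
  }
  stopifnot(all(c("source", "target", "sign", "definite") %in%
                  names(interactions)))
  interactions <- as.data.frame(interactions)
  rownames(interactions) <- NULL
  if (!all(interactions$sign %in% c("positive", "negative"))) {
    stop("interaction sign must be 'positive' or 'negative'")
  }
  known <- components$name
  bad <- setdiff(unique(c(interactions$source, interactions$target)), known)
  if (length(bad)) {
    stop("interaction references unknown component(s): ",
         paste(bad, collapse = ", "))
  }
  roles <- stats::setNames(components$role, components$name)
  if (any(roles[interactions$target] == "signal")) {
    stop("signals cannot be interaction targets")
  }
  key <- with(interactions, paste(source, target, sign))
  if (anyDuplicated(key)) stop("duplicate (source, target, sign) interaction")
  genes <- components$name[components$role == "gene"]
  allowed <- stats::setNames(rep(list(0:8), length(genes)), genes)
  for (g in names(allowed_conditions)) {
    if (!g %in% genes) stop("allowed_conditions for unknown gene: ", g)
    ac <- sort(unique(as.integer(allowed_conditions[[g]])))
    if (length(ac) == 0L || any(ac < 0L | ac > 8L)) {
      stop("every gene needs >=1 allowed condition in 0..8 (gene ", g, ")")
    }
    allowed[[g]] <- ac
  }
  structure(list(components = components$name,
                 roles = roles,
                 allowed_conditions = allowed,
                 interactions = interactions),
            class = "abn")
}

#' @export
print.abn <- function(x, ...) {
  n_opt <- sum(!x$interactions$definite)
  cat(sprintf(
    "Abstract Boolean Network: %d components (%d genes, %d signals)\n",
    length(x$components), sum(x$roles == "gene"), sum(x$roles == "signal")))
  cat(sprintf("  %d interactions (%d definite, %d optional; 2^%d topologies)\n",
              nrow(x$interactions), sum(x$interactions$definite), n_opt,
              n_opt))
  invisible(x)
}

#' @rdname abn
#' @param network an \code{"abn"} object
#' @export
network_genes <- function(network) {
  network$components[network$roles[network$components] == "gene"]
}

#' @rdname abn
#' @export
network_signals <- function(network) {
  network$components[network$roles[network$components] == "signal"]
}

#' @rdname abn
#' @export
optional_interactions <- function(network) {
  which(!network$interactions$definite)
}

#' Instantiate a concrete Boolean model from an ABN
#'
#' A concrete model fixes one topology (a subset of the optional
#' interactions, plus all definite ones) and assigns one regulation condition
#' to each gene.
#'
#' @param network an [abn()] object
#' @param chosen_optional logical vector over the optional interactions of
#'   \code{network} (in the order given by [optional_interactions()]), or an
#'   integer vector of optional-interaction row indices to instantiate.
#' @param conditions named integer vector (0..8) assigning a regulation
#'   condition to each gene; each must be among the gene's allowed conditions.
#' @return object of class \code{"concrete_model"}.
#' @export
concrete_model <- function(network, chosen_optional, conditions) {
  stopifnot(inherits(network, "abn"))
  opt <- optional_interactions(network)
  if (is.logical(chosen_optional)) {
    stopifnot(length(chosen_optional) == length(opt))
    chosen <- chosen_optional
  } else {
    stopifnot(all(chosen_optional %in% opt))
    chosen <- opt %in% chosen_optional
  }
  genes <- network_genes(network)
  if (!all(genes %in% names(conditions))) {
    stop("conditions must cover every gene")
  }
  conditions <- conditions[genes]
  for (g in genes) {
    if (!conditions[[g]] %in% network$allowed_conditions[[g]]) {
      stop("condition ", conditions[[g]], " not allowed for gene ", g)
    }
  }
  present <- network$interactions$definite
  present[opt] <- chosen
  structure(list(network = network,
                 chosen_optional = chosen,
                 present = present,
                 conditions = stats::setNames(as.integer(conditions), genes)),
            class = "concrete_model")
}

#' @export
print.concrete_model <- function(x, ...) {
  cat(sprintf("Concrete Boolean model: %d/%d optional interactions present\n",
              sum(x$chosen_optional), length(x$chosen_optional)))
  invisible(x)
}

#' Number of instantiated interactions of a concrete model
#' @param model a [concrete_model()]
#' @return integer count of definite plus chosen optional interactions
#' @export
n_instantiated <- function(model) {
  sum(model$present)
}

#' Perturbation schedule: culture inputs and clamps
#'
#' A schedule fixes the signal inputs for an experiment (e.g. 2i+LIF means
#' LIF, CH and PD all on) and optionally clamps components to a value over a
#' step interval. Forced expression is a clamp High over the whole
#' trajectory; knockdown/knockout a clamp Low; finite windows model
#' DOX-style transient induction.
#'
#' @param inputs named logical vector over the network's signals
#' @param clamps data.frame with columns \code{component}, \code{value}
#'   (logical), \code{from}, \code{to} (steps, \code{Inf} allowed), e.g. built
#'   with [clamp()]. May be \code{NULL}.
#' @return object of class \code{"schedule"}
#' @export
schedule <- function(inputs = NULL, clamps = NULL) {
  if (is.null(inputs)) inputs <- stats::setNames(logical(), character())
  stopifnot(is.logical(inputs))
  if (is.null(clamps)) {
    clamps <- data.frame(component = character(), value = logical(),
                         from = numeric(), to = numeric())
  }
  stopifnot(all(c("component", "value", "from", "to") %in% names(clamps)))
  if (nrow(clamps)) {
    for (comp in unique(clamps$component)) {
      iv <- clamps[clamps$component == comp, , drop = FALSE]
      if (nrow(iv) > 1L) {
        iv <- iv[order(iv$from), ]
        if (any(iv$to[-nrow(iv)] >= iv$from[-1])) {
          stop("component ", comp, " has overlapping clamps")
        }
      }
    }
  }
  structure(list(inputs = inputs, clamps = clamps), class = "schedule")
}

#' @rdname schedule
#' @param component component name
#' @param value logical clamp value (TRUE = High)
#' @param from,to first and last step (inclusive) at which the clamp holds
#' @export
clamp <- function(component, value, from = 0, to = Inf) {
  data.frame(component = component, value = value, from = from, to = to)
}

#' @rdname schedule
#' @param sched a schedule
#' @param ... clamp rows (from [clamp()]) to append
#' @export
with_clamps <- function(sched, ...) {
  schedule(sched$inputs, rbind(sched$clamps, ...))
}

# Value imposed on `component` at step `t` by the schedule, or NA if free.
# Signals take the input value whenever not explicitly clamped.
scheduled_value <- function(sched, component, t, roles) {
  cl <- sched$clamps
  if (nrow(cl)) {
    hit <- cl$component == component & cl$from <= t & cl$to >= t
    if (any(hit)) return(cl$value[which(hit)[1L]])
  }
  if (!is.na(roles[component]) && roles[component] == "signal") {
    if (component %in% names(sched$inputs)) {
      return(sched$inputs[[component]])
    }
    return(FALSE)  # unlisted signals default off
  }
  NA
}
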