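#' Expression dataset for correlation-based interaction inference
#'
#' One genes x samples expression matrix measured under a single culture
#' condition. Several such datasets (different input combinations) are
#' combined into per-pair correlation profiles.
#'
#' @param mat genes x samples numeric matrix with rownames (non-negative
#'   expression values, arbitrary units)
#' @param condition_label text label for the culture condition
#' @param source_label provenance label (platform/study)
#' @return object of class \code{"expression_dataset"}
#' @export
expression_dataset <- function(mat, condition_label, source_label = "") {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) stop("expression matrix needs gene rownames")
  if (ncol(mat) < 2L) stop("need at least 2 samples")
  if (any(mat < 0)) stop("expression values must be non-negative")
  structure(list(mat = mat, condition_label = condition_label,
                 source_label = source_label),
            class = "expression_dataset")
}

#' Per-pair Pearson correlation profiles across datasets
#'
#' Computes, for every unordered gene pair, one Pearson coefficient per
#' dataset. Pairs involving a gene that is constant within a dataset get an
#' undefined (NA) entry for that dataset; undefined entries are excluded
#' from majority counts when interactions are called.
#'
#' @param datasets list of [expression_dataset()]s sharing a gene set
#' @return object of class \code{"correlation_profiles"}: a genes x genes x
#'   datasets array of coefficients plus the gene roster
#' @export
compute_correlation_profiles <- function(datasets) {
  stopifnot(length(datasets) >= 1L)
  genes <- rownames(datasets[[1L]]$mat)
  for (d in datasets) {
    if (!setequal(rownames(d$mat), genes)) {
      stop("datasets have mismatched gene sets")
    }
  }
  cors <- array(NA_real_, dim = c(length(genes), length(genes),
                                  length(datasets)),
                dimnames = list(genes, genes,
                                vapply(datasets,
                                       function(d) d$condition_label, "")))
  for (k in seq_along(datasets)) {
    m <- datasets[[k]]$mat[genes, , drop = FALSE]
    cors[, , k] <- suppressWarnings(stats::cor(t(m)))
  }
  structure(list(genes = genes, cors = cors), class = "correlation_profiles")
}

# Decide the sign call for one pair's coefficient vector, or NA for no call.
call_pair <- function(coefs, threshold) {
  coefs <- coefs[!is.na(coefs)]
  if (!length(coefs)) return(NA_character_)
  pos_trig <- any(coefs >= threshold)
  neg_trig <- any(coefs <= -threshold)
  if (pos_trig && neg_trig) {
    # conflicting triggers: the majority sign over all defined coefficients
    npos <- sum(coefs > 0)
    nneg <- sum(coefs < 0)
    if (npos > nneg) return("positive")
    if (nneg > npos) return("negative")
    return(NA_character_)
  }
  if (pos_trig) {
    # "remaining" excludes the (single) triggering coefficient, so the
    # majority check does not depend on the threshold and calls are
    # monotone: lowering the threshold never removes one
    rem <- coefs[-which.max(coefs)]
    if (!length(rem) || sum(rem > 0) > length(rem) / 2) return("positive")
    return(NA_character_)
  }
  if (neg_trig) {
    rem <- coefs[-which.min(coefs)]
    if (!length(rem) || sum(rem < 0) > length(rem) / 2) return("negative")
  }
  NA_character_
}

#' Call possible interactions from correlation profiles
#'
#' A pair is called possible-and-positive when at least one of its
#' coefficients is \code{>= threshold} and a strict majority of the
#' remaining defined coefficients are positive; possible-and-negative
#' mirrors this at \code{<= -threshold}. When both signs trigger, the
#' majority sign over all defined coefficients decides (ties: no call).
#' Correlations do not orient the interaction, so each call yields two
#' directed optional interactions (A to B and B to A). Self-interactions
#' are never called.
#'
#' @param profiles a [compute_correlation_profiles()] result
#' @param threshold Pearson threshold in (0, 1)
#' @return data.frame of optional interactions (columns \code{source},
#'   \code{target}, \code{sign}, \code{definite} = FALSE)
#' @export
call_possible_interactions <- function(profiles, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  genes <- profiles$genes
  rows <- list()
  for (i in seq_len(length(genes) - 1L)) {
    for (j in seq(i + 1L, length(genes))) {
      sign <- call_pair(profiles$cors[i, j, ], threshold)
      if (!is.na(sign)) {
        rows[[length(rows) + 1L]] <-
          data.frame(source = genes[c(i, j)], target = genes[c(j, i)],
                     sign = sign, definite = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(source = character(), target = character(),
                      sign = character(), definite = logical()))
  }
  do.call(rbind, rows)
}

#' Find the maximal satisfiable Pearson threshold
#'
#' Searches for the largest threshold whose induced ABN (the definite
#' interactions plus the called optional ones) still satisfies the
#' experimental constraints. Lowering the threshold only adds optional
#' interactions, and un-instantiated optional interactions never change
#' dynamics, so satisfiability is monotone in the threshold and the search
#' is a binary search over the candidate grid.
#'
#' @param datasets list of [expression_dataset()]s
#' @param definite_interactions data.frame of definite interactions
#'   (signal axes etc.)
#' @param constraints constraint list as for [synthesize()]
#' @param components optional component data.frame (\code{name},
#'   \code{role}); by default dataset genes are genes and any other
#'   component mentioned by the definite interactions is a signal
#' @param candidate_grid candidate thresholds; default: the sorted distinct
#'   absolute values of the defined coefficients (open interval (0,1))
#' @param allowed_conditions passed to [abn()]
#' @param max_conflicts solver conflict budget per satisfiability test
#' @return list with \code{threshold}, \code{network} (the induced ABN),
#'   \code{called} (the optional interactions at that threshold) and
#'   \code{grid}
#' @export
find_max_threshold <- function(datasets, definite_interactions, constraints,
                               components = NULL, candidate_grid = NULL,
                               allowed_conditions = list(),
                               max_conflicts =
                                 getOption("abnsynth.max_conflicts", 2e6)) {
  constraints <- flatten_constraints(constraints)
  profiles <- compute_correlation_profiles(datasets)
  genes <- profiles$genes
  if (is.null(components)) {
    extra <- setdiff(unique(c(definite_interactions$source,
                              definite_interactions$target)), genes)
    components <- data.frame(name = c(genes, extra),
                             role = c(rep("gene", length(genes)),
                                      rep("signal", length(extra))))
  }
  if (is.null(candidate_grid)) {
    vals <- abs(as.vector(profiles$cors))
    vals <- vals[!is.na(vals) & vals > 0 & vals < 1]
    candidate_grid <- sort(unique(vals))
  }
  if (!length(candidate_grid)) stop("empty candidate threshold grid")
  candidate_grid <- sort(candidate_grid)
  build_net <- function(thr) {
    called <- call_possible_interactions(profiles, thr)
    # drop calls duplicating a definite interaction
    if (nrow(called) && nrow(definite_interactions)) {
      key <- paste(called$source, called$target, called$sign)
      dkey <- paste(definite_interactions$source,
                    definite_interactions$target,
                    definite_interactions$sign)
      called <- called[!key %in% dkey, , drop = FALSE]
    }
    abn(components, rbind(definite_interactions, called),
        allowed_conditions)
  }
  sat_at <- function(thr) {
    st <- synthesize(build_net(thr), constraints, max_conflicts)$status
    if (st == "indeterminate") stop("solver budget exhausted at threshold ",
                                    thr)
    st == "satisfiable"
  }
  lo <- 1L
  hi <- length(candidate_grid)
  if (!sat_at(candidate_grid[lo])) {
    # name the first violated constraint at the most permissive ABN
    net <- build_net(candidate_grid[lo])
    for (k in seq_along(constraints)) {
      if (synthesize(net, constraints[seq_len(k)],
                     max_conflicts)$status != "satisfiable") {
        stop("constraints unsatisfiable at minimum threshold ",
             candidate_grid[lo], "; first violated constraint: '",
             constraints[[k]]$name, "'")
      }
    }
    stop("constraints unsatisfiable at minimum threshold")
  }
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (sat_at(candidate_grid[mid])) lo <- mid else hi <- mid - 1L
  }
  thr <- candidate_grid[lo]
  list(threshold = thr, network = build_net(thr),
       called = call_possible_interactions(profiles, thr),
       grid = candidate_grid)
}
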