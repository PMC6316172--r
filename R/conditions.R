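#' Regulation conditions: monotone Boolean update rules
#'
#' A regulation condition is an update rule that decides whether a target gene
#' is expressed at the next step from the *availability level* of its
#' activators and repressors at the current step. Levels are \code{"none"}
#' (no instantiated regulator of that class is active), \code{"some"}
#' (strictly between) and \code{"all"} (every instantiated regulator active,
#' and at least one exists). A valid condition must
#' \itemize{
#'   \item be \code{FALSE} whenever the activator level is \code{"none"}
#'     (a gene requires at least one active activator to be expressed),
#'   \item be monotone non-decreasing in the activator level and
#'     non-increasing in the repressor level,
#'   \item be \code{TRUE} at (\code{"all"} activators, \code{"none"}
#'     repressors).
#' }
#' Exactly nine such rules exist. They are indexed 0..8 from least permissive
#' (condition 0 is \code{TRUE} only at (all, none)) to most permissive
#' (condition 8 is \code{TRUE} whenever any activator is active), ties broken
#' by lexicographic order of the table read activator-level major.
#'
#' @return A list of nine 3x3 logical matrices. Rows are activator levels
#'   (\code{none}, \code{some}, \code{all}), columns repressor levels.
#' @examples
#' conds <- regulation_conditions()
#' conds[[1]]["all", "none"]   # TRUE for every condition
#' @export
regulation_conditions <- function() {
  if (is.null(.cond_cache$list)) init_condition_cache()
  .cond_cache$list
}

#' @rdname regulation_conditions
#' @return For \code{regulation_condition_array}, a 9 x 3 x 3 logical array
#'   indexed by (condition index + 1, activator level, repressor level).
#' @export
regulation_condition_array <- function() {
  if (is.null(.cond_cache$array)) init_condition_cache()
  .cond_cache$array
}

levels3 <- c("none", "some", "all")

# Enumerate all 2^9 tables and filter by the defining invariants; done once at
# load time, so the published index order is a pure function of the rules.
build_regulation_conditions <- function() {
  keep <- list()
  for (bits in 0:511) {
    tab <- matrix(as.logical(bitwAnd(bitwShiftR(bits, 0:8), 1L)),
                  nrow = 3, byrow = TRUE,
                  dimnames = list(activator = levels3, repressor = levels3))
    if (any(tab["none", ])) next
    if (!tab["all", "none"]) next
    # monotone up rows (activator), down columns (repressor)
    if (any(tab["some", ] & !tab["all", ])) next
    mono_rep <- function(r) !any(!r[1] & r[2]) && !any(!r[2] & r[3])
    if (!mono_rep(tab["some", ]) || !mono_rep(tab["all", ])) next
    keep[[length(keep) + 1L]] <- tab
  }
  ntrue <- vapply(keep, sum, 0L)
  lexkey <- vapply(keep, function(tab) {
    paste(as.integer(t(tab)), collapse = "")   # activator-level major
  }, "")
  keep <- keep[order(ntrue, lexkey)]
  names(keep) <- paste0("condition_", seq_along(keep) - 1L)
  keep
}

.cond_cache <- new.env(parent = emptyenv())

init_condition_cache <- function() {
  lst <- build_regulation_conditions()
  arr <- array(FALSE, dim = c(length(lst), 3, 3),
               dimnames = list(NULL, levels3, levels3))
  for (i in seq_along(lst)) arr[i, , ] <- lst[[i]]
  .cond_cache$list <- lst
  .cond_cache$array <- arr
}

#' Map active/total regulator counts to an availability level
#'
#' @param n_active number of active instantiated regulators
#' @param n_total number of instantiated regulators
#' @return one of \code{"none"}, \code{"some"}, \code{"all"}. A class with no
#'   instantiated regulators has level \code{"none"}.
#' @keywords internal
regulator_level <- function(n_active, n_total) {
  if (n_total == 0L || n_active == 0L) return("none")
  if (n_active == n_total) return("all")
  "some"
}

#' Evaluate a regulation condition on regulator counts
#'
#' Applies a regulation-condition table to the counts of active and
#' instantiated activators and repressors of a target. A target with no
#' instantiated activators is never expressed.
#'
#' @param condition a 3x3 logical matrix from [regulation_conditions()], or a
#'   condition index 0..8.
#' @param n_active_activators,n_activators active / total activator counts
#' @param n_active_repressors,n_repressors active / total repressor counts
#' @return logical: is the target expressed at the next step?
#' @export
evaluate_condition <- function(condition,
                               n_active_activators, n_activators,
                               n_active_repressors, n_repressors) {
  counts <- c(n_active_activators, n_activators,
              n_active_repressors, n_repressors)
  if (any(counts < 0L)) stop("regulator counts must be non-negative")
  if (n_active_activators > n_activators ||
      n_active_repressors > n_repressors) {
    stop("active regulator counts cannot exceed totals")
  }
  if (is.numeric(condition) && length(condition) == 1L) {
    condition <- regulation_conditions()[[as.integer(condition) + 1L]]
  }
  if (n_activators == 0L) return(FALSE)
  a <- regulator_level(n_active_activators, n_activators)
  r <- regulator_level(n_active_repressors, n_repressors)
  condition[a, r]
}
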