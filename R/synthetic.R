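#' Sample a ground-truth regulatory network and concrete model
#'
#' Draws a random signed interaction network over \code{n_genes} genes and
#' \code{n_signals} clamp-only signals and assigns each gene a regulation
#' condition. The topology is layered: genes get a depth, every gene's
#' guaranteed activator comes from a shallower layer (signals at the root),
#' extra interactions are mostly feed-forward with a fraction of positive
#' feedback edges, so signal variation propagates through the whole
#' network — the property correlation-based inference relies on. Regulation
#' conditions for repressor-bearing genes are drawn only from those under
#' which the repressor is functional (conditions 0, 1, 2, 4, 6), so every
#' planted interaction influences the dynamics.
#'
#' Signal-outgoing interactions are definite (mirroring known signalling
#' axes); gene-gene interactions are optional, so the ground-truth network
#' doubles as an ABN whose candidate space contains the ground-truth model
#' (the one instantiating every optional interaction). The defaults
#' (12 genes, 3 signals, 25 interactions) mirror the scale of the
#' pluripotency circuit the pipeline was built for.
#'
#' @param n_genes,n_signals,n_interactions network size;
#'   \code{n_interactions} is a target bounded above by
#'   \code{n_genes * max_in_degree} (24 at the defaults)
#' @param seed RNG seed
#' @param planted_threshold Pearson threshold the expression generator is
#'   designed to support for direct interactions; the default 0.5 sits
#'   below the ~0.58 pairwise-correlation ceiling of dual-regulator
#'   Boolean targets
#' @param noise_sd log-scale noise of the expression generator
#' @param max_in_degree cap on regulators per gene (keeps pairwise
#'   correlations of direct interactions informative)
#' @param p_feedback fraction of extra edges drawn as positive feedback
#' @param p_negative fraction of feed-forward extra edges that repress
#' @return list of class \code{"ground_truth"}: \code{network} (an [abn()]),
#'   \code{model} (the generating [concrete_model()]), \code{conditions}
#'   (list of signal input combinations for expression datasets),
#'   \code{planted_threshold}, \code{noise_sd}, \code{seed}
#' @export
sample_ground_truth <- function(n_genes = 12, n_signals = 3,
                                n_interactions = 25, seed = 1,
                                planted_threshold = 0.5, noise_sd = 0.2,
                                max_in_degree = 2, p_feedback = 0.15,
                                p_negative = 0.25) {
  if (n_interactions < n_genes) {
    stop("need n_interactions >= n_genes so every gene can have an activator")
  }
  set.seed(seed)
  genes <- sprintf("G%02d", seq_len(n_genes))
  sigs <- if (n_signals) sprintf("S%d", seq_len(n_signals)) else character()
  comps <- data.frame(name = c(genes, sigs),
                      role = c(rep("gene", n_genes),
                               rep("signal", n_signals)))
  depth <- stats::setNames(sample(rep(1:3, length.out = n_genes)), genes)
  rows <- list()
  key <- character()
  in_deg <- stats::setNames(integer(n_genes), genes)
  add_edge <- function(src, tgt, sign) {
    k <- paste(src, tgt, sign)
    if (k %in% key || src == tgt) return(FALSE)
    rows[[length(rows) + 1L]] <<- data.frame(source = src, target = tgt,
                                             sign = sign,
                                             definite = src %in% sigs)
    key <<- c(key, k)
    in_deg[tgt] <<- in_deg[tgt] + 1L
    TRUE
  }
  for (g in genes) {  # one guaranteed activator each, from shallower layers
    repeat {
      pool <- c(if (depth[g] == 1L || !length(sigs)) sigs,
                genes[depth < depth[g]])
      if (!length(pool)) pool <- if (length(sigs)) sigs else genes
      if (add_edge(pool[sample.int(length(pool), 1L)], g, "positive")) break
    }
  }
  tries <- 0L
  while (length(rows) < n_interactions && tries < 50L * n_interactions) {
    tries <- tries + 1L
    tgt <- genes[sample.int(n_genes, 1L)]
    if (in_deg[tgt] >= max_in_degree) next
    feedback <- stats::runif(1) < p_feedback
    pool <- if (feedback) genes[depth >= depth[tgt]]
            else c(sigs, genes[depth < depth[tgt]])
    pool <- setdiff(pool, tgt)
    if (!length(pool)) next
    sign <- if (!feedback && stats::runif(1) < p_negative) "negative"
            else "positive"
    add_edge(pool[sample.int(length(pool), 1L)], tgt, sign)
  }
  network <- abn(comps, do.call(rbind, rows))
  ia <- do.call(rbind, rows)
  has_rep <- vapply(genes, function(g) {
    any(ia$target == g & ia$sign == "negative")
  }, NA)
  rep_functional <- c(0L, 1L, 2L, 4L, 6L)  # conditions where repression acts
  conds <- stats::setNames(integer(n_genes), genes)
  for (g in genes) {
    pool <- if (has_rep[[g]]) rep_functional else 0:8
    conds[g] <- pool[sample.int(length(pool), 1L)]
  }
  model <- concrete_model(network,
                          rep(TRUE, length(optional_interactions(network))),
                          conds)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), n_signals))
  if (n_signals) {
    combos <- combos[rowSums(combos) > 0, , drop = FALSE]  # drop all-off
    conditions <- lapply(seq_len(nrow(combos)), function(i) {
      stats::setNames(as.logical(combos[i, ]), sigs)
    })
  } else {
    conditions <- list(stats::setNames(logical(), character()))
  }
  structure(list(network = network, model = model, conditions = conditions,
                 planted_threshold = planted_threshold,
                 noise_sd = noise_sd, seed = seed),
            class = "ground_truth")
}

#' Simulate condition-panel expression datasets from a ground truth
#'
#' Emulates a panel of expression datasets of the kind used for
#' correlation-based interaction calling: within each dataset, every sample
#' is a near-steady Boolean state of the ground-truth model under a random
#' combination of signal inputs (occasionally with one gene clamped as a
#' perturbation), mapped to continuous expression by log-normal emission
#' around \eqn{\mu_{High}} or \eqn{\mu_{Low}}. Input variation across the
#' samples propagates through the layered network, so directly interacting
#' pairs co-vary: exactly (|r| = 1 at zero noise) for single-regulator
#' targets, and around 0.58 for balanced dual-regulator targets — which is
#' why the default planted threshold is 0.5. Datasets differ in their
#' random input panels and noise realisations, mimicking independent
#' expression studies.
#'
#' @param gt a [sample_ground_truth()] object
#' @param n_datasets number of datasets (default 7, one per non-trivial
#'   input combination of three signals)
#' @param samples_per_dataset samples per dataset
#' @param seed RNG seed
#' @param mu_high,mu_low emission means (ratio 10 by default)
#' @param noise_sd log-scale emission sd (default: the ground truth's)
#' @param clamp_prob probability that a sample carries a single-gene
#'   perturbation
#' @param settle_steps synchronous steps before the state is read out
#' @return list of [expression_dataset()]s
#' @export
simulate_expression <- function(gt, n_datasets = length(gt$conditions),
                                samples_per_dataset = 80, seed = 1,
                                mu_high = 10, mu_low = 1,
                                noise_sd = gt$noise_sd,
                                clamp_prob = 0.3, settle_steps = 10) {
  stopifnot(n_datasets >= 1)
  set.seed(seed)
  net <- gt$network
  genes <- network_genes(net)
  sigs <- network_signals(net)
  lapply(seq_len(n_datasets), function(d) {
    mat <- matrix(0, length(genes), samples_per_dataset,
                  dimnames = list(genes, NULL))
    for (k in seq_len(samples_per_dataset)) {
      inputs <- stats::setNames(stats::runif(length(sigs)) < 0.5, sigs)
      clamps <- NULL
      if (stats::runif(1) < clamp_prob) {
        g <- genes[sample.int(length(genes), 1L)]
        clamps <- clamp(g, stats::runif(1) < 0.5)
      }
      sched <- schedule(inputs, clamps)
      init <- stats::setNames(stats::runif(length(genes)) < 0.5, genes)
      traj <- sync_trajectory(gt$model, init, sched, settle_steps)
      state <- traj$states[settle_steps + 1L, genes]
      mu <- ifelse(state, mu_high, mu_low)
      mat[, k] <- if (noise_sd > 0) {
        stats::rlnorm(length(genes), meanlog = log(mu), sdlog = noise_sd)
      } else {
        mu
      }
    }
    expression_dataset(mat, condition_label = sprintf("panel_%02d", d),
                       source_label = "synthetic")
  })
}

#' Recall/precision of called interactions against planted edges
#'
#' An undirected signed pair call counts as recovering a planted
#' interaction when the planted network contains an interaction between the
#' two genes with the called sign (direction ignored, as calls are
#' bidirectional).
#'
#' @param called data.frame of called interactions
#' @param gt a [sample_ground_truth()]
#' @return list with \code{recall}, \code{precision}, counts
#' @export
interaction_recovery <- function(called, gt) {
  ia <- gt$network$interactions
  genes <- network_genes(gt$network)
  ia <- ia[ia$source %in% genes & ia$target %in% genes, , drop = FALSE]
  pkey <- unique(with(ia, paste(pmin(source, target),
                                pmax(source, target), sign)))
  ckey <- unique(with(called, paste(pmin(source, target),
                                    pmax(source, target), sign)))
  tp <- sum(pkey %in% ckey)
  list(recall = if (length(pkey)) tp / length(pkey) else NA_real_,
       precision = if (length(ckey)) sum(ckey %in% pkey) / length(ckey)
                   else NA_real_,
       n_planted = length(pkey), n_called = length(ckey), n_recovered = tp)
}

#' Generate observation constraints and held-out outcomes from a ground
#' truth
#'
#' Simulates the ground-truth model under a panel of experiment designs
#' (unperturbed resetting from partially-active states, knockdowns, forced
#' expression) and encodes the observed reach/stability behaviour as
#' constraints. A second, held-out panel of gene-depletion behaviours is
#' emitted as an outcome table together with the matching prediction
#' queries, for accuracy-recovery tests: by construction the ground-truth
#' model satisfies every emitted constraint.
#'
#' @param gt a [sample_ground_truth()]
#' @param n_constraint_designs designs encoded as constraints
#' @param n_holdout held-out gene-depletion outcomes
#' @param bound trajectory bound
#' @param seed RNG seed
#' @return list with \code{constraints}, \code{outcomes} (data.frame
#'   \code{query}, \code{result}), and \code{queries} (prediction-query
#'   specifications resolvable by the prediction engine)
#' @export
generate_observations <- function(gt, n_constraint_designs = 4,
                                  n_holdout = 6, bound = 20, seed = 1) {
  set.seed(seed)
  net <- gt$network
  genes <- network_genes(net)
  sigs <- network_signals(net)
  all_on <- stats::setNames(rep(TRUE, length(sigs)), sigs)
  base_initial <- stats::setNames(stats::runif(length(genes)) < 0.4, genes)

  observed_constraint <- function(name, sched, initial) {
    traj <- sync_trajectory(gt$model, initial, sched, bound)
    final <- traj$states[bound + 1L, genes]
    if (traj$fixed_point) {
      experiment(name, sched, initial,
                 expectation("stable", final), bound)
    } else {
      experiment(name, sched, initial,
                 expectation("held", traj$states[bound, genes],
                             from = bound - 1L, to = bound - 1L), bound)
    }
  }

  cons <- list(observed_constraint("base_resetting", schedule(all_on),
                                   base_initial))
  extra <- n_constraint_designs - 1L
  perturb_genes <- sample(genes, min(extra, length(genes)))
  for (i in seq_along(perturb_genes)) {
    g <- perturb_genes[i]
    forced <- i %% 2L == 0L
    sched <- schedule(all_on, clamp(g, forced))
    cons[[length(cons) + 1L]] <-
      observed_constraint(paste0(if (forced) "forced_" else "knockdown_", g),
                          sched, base_initial)
  }

  # held-out gene-depletion behaviours, scored against the ground truth
  base_traj <- sync_trajectory(gt$model, base_initial, schedule(all_on),
                               bound)
  target <- base_traj$states[bound + 1L, genes]
  target <- target[target]  # the genes High at the unperturbed endpoint
  hold_genes <- sample(genes, min(n_holdout, length(genes)))
  rows <- list()
  queries <- list()
  for (g in hold_genes) {
    sched <- schedule(all_on, clamp(g, FALSE))
    tgt <- target[setdiff(names(target), g)]
    traj <- sync_trajectory(gt$model, base_initial, sched, bound)
    reaches <- state_matches(traj$states[bound + 1L, ], tgt) &&
      all(traj$states[bound + 1L, ] == traj$next_state)
    qname <- paste0("deplete_", g)
    rows[[length(rows) + 1L]] <-
      data.frame(query = qname,
                 result = if (reaches) "supports-positive"
                          else "supports-negative")
    queries[[length(queries) + 1L]] <-
      list(name = qname, type = "essentiality", component = g,
           sched = schedule(all_on), initial = base_initial,
           target = target, bound = bound)
  }
  list(constraints = cons, outcomes = do.call(rbind, rows),
       queries = queries, base_initial = base_initial, target = target)
}

#' Run a prediction-query battery against a cABN
#'
#' Resolves the query specifications produced by
#' [generate_observations()] (or hand-written ones of the same shape)
#' through the prediction engine.
#'
#' @param cb a [cabn()]
#' @param queries list of query specifications
#' @param max_conflicts solver conflict budget per query
#' @return data.frame with columns \code{query} and \code{outcome}
#' @export
run_query_battery <- function(cb, queries,
                              max_conflicts =
                                getOption("abnsynth.max_conflicts", 2e6)) {
  rows <- lapply(queries, function(q) {
    outcome <- switch(q$type,
      essentiality = essentiality(cb, q$component, q$sched, q$initial,
                                  q$target, q$bound,
                                  max_conflicts = max_conflicts),
      reachability = {
        st <- steps_to_target(cb, q$sched, q$initial, q$target, q$bound,
                              max_conflicts = max_conflicts)
        if (!is.na(st$all_step)) "positive"
        else if (st$outcome == "never") "negative"
        else "no_prediction"
      },
      precedes = precedes(cb, q$geneX, q$geneY, q$sched, q$initial,
                          q$bound, max_conflicts = max_conflicts),
      cocktail = cocktail_outcome(cb, q$cocktail, q$inputs, q$target,
                                  q$bound, max_conflicts = max_conflicts),
      stop("unknown query type: ", q$type))
    data.frame(query = q$name, outcome = outcome)
  })
  do.call(rbind, rows)
}
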