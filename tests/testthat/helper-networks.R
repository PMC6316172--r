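# Shared builders for toy networks and random synthesis instances.

toy_chain <- function() {
  # A -> B -> C, all optional, one signal driving A
  abn(data.frame(name = c("S", "A", "B", "C"),
                 role = c("signal", "gene", "gene", "gene")),
      data.frame(source = c("S", "A", "B"),
                 target = c("A", "B", "C"),
                 sign = "positive",
                 definite = c(TRUE, FALSE, FALSE)))
}

toy_pair <- function() {
  # mutual activation A <-> B (definite)
  abn(c("A", "B"),
      data.frame(source = c("A", "B"), target = c("B", "A"),
                 sign = "positive", definite = TRUE))
}

# Random small synthesis instance (network + constraints), deterministic in
# `seed`; used for oracle-equivalence checks against brute force.
random_instance <- function(seed, max_comp = 4, max_opt = 6,
                            max_constraints = 2) {
  set.seed(seed)
  rs <- function(x) x[sample.int(length(x), 1L)]
  n_comp <- rs(2:max_comp)
  n_sig <- rs(0:1)
  genes <- paste0("G", seq_len(n_comp - n_sig))
  sigs <- if (n_sig) "S1" else character()
  comps <- c(genes, sigs)
  pairs <- expand.grid(source = comps, target = genes,
                       stringsAsFactors = FALSE)
  pick <- sample(nrow(pairs), min(rs(1:max_opt), nrow(pairs)))
  ia <- data.frame(source = pairs$source[pick], target = pairs$target[pick],
                   sign = sample(c("positive", "negative"), length(pick),
                                 TRUE),
                   definite = stats::runif(length(pick)) < 0.3)
  allowed <- lapply(genes, function(g) sort(sample(0:8, rs(1:3))))
  names(allowed) <- genes
  net <- abn(data.frame(name = comps,
                        role = c(rep("gene", length(genes)),
                                 rep("signal", length(sigs)))),
             ia, allowed)
  bound <- rs(4:6)
  rand_exp <- function(name) {
    inputs <- stats::setNames(stats::runif(length(sigs)) < 0.5, sigs)
    clamps <- NULL
    if (stats::runif(1) < 0.3) {
      cc <- rs(genes)
      to <- rs(c(Inf, rs(0:bound)))
      from <- rs(0:2)
      if (from > to) from <- 0
      clamps <- clamp(cc, stats::runif(1) < 0.5, from = from, to = to)
    }
    init_genes <- genes[sample.int(length(genes), rs(0:length(genes)))]
    initial <- stats::setNames(stats::runif(length(init_genes)) < 0.5,
                               init_genes)
    exps <- lapply(seq_len(rs(1:2)), function(i) {
      tgt <- comps[sample.int(length(comps), rs(seq_along(comps)))]
      st <- stats::setNames(stats::runif(length(tgt)) < 0.5, tgt)
      mod <- rs(c("reached", "never", "held", "stable"))
      a <- rs(0:bound)
      b <- rs(a:bound)
      if (mod == "held") a <- max(0, b - rs(0:2))
      expectation(mod, st, if (mod == "stable") NULL else a,
                  if (stats::runif(1) < 0.8) b else NULL)
    })
    experiment(name, schedule(inputs, clamps), initial, exps, bound)
  }
  cons <- lapply(seq_len(rs(seq_len(max_constraints))),
                 function(i) rand_exp(paste0("e", i)))
  if (stats::runif(1) < 0.25) {
    tgt <- comps[sample.int(length(comps), rs(1:2))]
    st <- stats::setNames(stats::runif(length(tgt)) < 0.5, tgt)
    cons <- c(cons, list(comparative("cmp", rand_exp("t"), rand_exp("r"),
                                     st)))
  }
  list(net = net, cons = cons)
}

# Exact reachability probability for the uniform asynchronous scheme on a
# tiny model: builds the 2^m-state Markov chain (target states absorbing)
# and iterates the distribution.
async_reach_prob_exact <- function(model, initial, sched, target,
                                   n_steps) {
  cm <- abnsynth:::compile_model(model)
  genes <- cm$genes
  comps <- cm$comps
  m <- length(comps)
  n_states <- 2^m
  state_of <- function(id) {
    stats::setNames(as.logical(bitwAnd(bitwShiftR(id - 1L, 0:(m - 1L)),
                                       1L)), comps)
  }
  id_of <- function(st) 1L + sum(2^(which(st) - 1L))
  # apply schedule values (constant clamps/signals assumed)
  norm <- function(st) {
    for (comp in comps) {
      sv <- abnsynth:::scheduled_value(sched, comp, 1, cm$roles)
      if (!is.na(sv)) st[comp] <- sv
    }
    st
  }
  is_target <- function(st) all(st[names(target)] == target)
  free <- genes[vapply(genes, function(g) {
    is.na(abnsynth:::scheduled_value(sched, g, 1, cm$roles))
  }, NA)]
  P <- matrix(0, n_states, n_states)
  for (id in seq_len(n_states)) {
    st <- norm(state_of(id))
    if (is_target(st)) {
      P[id, id_of(st)] <- 1  # absorbing
      next
    }
    for (g in free) {
      nst <- st
      rule <- cm$rules[[g]]
      val <- FALSE
      if (length(rule$act)) {
        la <- abnsynth:::level_index(sum(st[rule$act]), length(rule$act))
        if (la > 1L) {
          lr <- abnsynth:::level_index(sum(st[rule$rep]),
                                       length(rule$rep))
          val <- rule$table[la, lr]
        }
      }
      nst[cm$idx[[g]]] <- val
      P[id, id_of(nst)] <- P[id, id_of(nst)] + 1 / length(free)
    }
  }
  st0 <- norm(abnsynth:::complete_initial_state(model, initial, sched))
  v <- numeric(n_states)
  v[id_of(st0)] <- 1
  for (i in seq_len(n_steps)) v <- v %*% P
  target_ids <- which(vapply(seq_len(n_states), function(id) {
    is_target(norm(state_of(id)))
  }, NA))
  sum(v[target_ids])
}
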