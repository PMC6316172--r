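# Propositional encoding of ABN synthesis as bounded model checking.
#
# Choice variables: one presence variable per optional interaction and a
# one-hot regulation-condition selector per gene; these are shared across all
# experiments, so one satisfying assignment is one concrete model that
# explains every encoded observation. Each experiment contributes an
# unrolled synchronous trajectory (steps 0..bound+1; the extra step serves
# fixed-point checks). With the initial state fully determined (unspecified
# genes default Low) the trajectory variables are functionally determined by
# the choice variables, so the search space seen by the solver is the space
# of concrete models.

cell_index <- function(a, r) (a - 2L) * 3L + r  # a in 2:3, r in 1:3

build_encoding <- function(network, constraints = list()) {
  constraints <- flatten_constraints(constraints)
  cnf <- cnf_new()
  ia <- network$interactions
  opt <- optional_interactions(network)
  elit <- rep(lit_true(cnf), nrow(ia))
  if (length(opt)) elit[opt] <- cnf_var(cnf, length(opt))

  genes <- network_genes(network)
  arr <- regulation_condition_array()
  svar <- list()
  anyS <- list()
  for (g in genes) {
    allowed <- network$allowed_conditions[[g]]
    sv <- cnf_var(cnf, length(allowed))
    names(sv) <- allowed
    cnf_exactly_one(cnf, sv)
    svar[[g]] <- sv
    cells <- integer(6L)
    for (a in 2:3) {
      for (r in 1:3) {
        hit <- sv[arr[allowed + 1L, a, r]]
        cells[cell_index(a, r)] <- t_or(cnf, hit)
      }
    }
    anyS[[g]] <- cells
  }

  per_gene <- lapply(genes, function(g) {
    list(act = which(ia$target == g & ia$sign == "positive"),
         rep = which(ia$target == g & ia$sign == "negative"))
  })
  names(per_gene) <- genes

  enc <- new.env(parent = emptyenv())
  enc$cnf <- cnf
  enc$network <- network
  enc$elit <- elit
  enc$opt <- opt
  enc$svar <- svar
  enc$anyS <- anyS
  enc$per_gene <- per_gene
  enc$experiments <- list()
  for (con in constraints) encode_constraint(enc, con)
  enc
}

encode_gene_step <- function(enc, g, xprev, y) {
  cnf <- enc$cnf
  ia <- enc$network$interactions
  pg <- enc$per_gene[[g]]
  if (length(pg$act) == 0L) {
    cnf_clause(cnf, -y)
    return(invisible(NULL))
  }
  vt <- lit_true(cnf)
  act_src <- ia$source[pg$act]
  pa <- enc$elit[pg$act]
  aa <- xprev[act_src]
  m <- integer(length(pa))
  d <- integer(length(pa))
  for (j in seq_along(pa)) {
    if (pa[j] == vt) {
      m[j] <- aa[j]
      d[j] <- aa[j]
    } else {
      m[j] <- t_and(cnf, c(pa[j], aa[j]))
      d[j] <- t_or(cnf, c(-pa[j], aa[j]))
    }
  }
  someA <- t_or(cnf, m)
  allA <- t_and(cnf, d)
  LA <- c(NA_integer_,
          t_and(cnf, c(someA, -allA)),
          t_and(cnf, c(someA, allA)))
  if (length(pg$rep) == 0L) {
    LR <- c(vt, -vt, -vt)
  } else {
    rep_src <- ia$source[pg$rep]
    pr <- enc$elit[pg$rep]
    ar <- xprev[rep_src]
    mr <- integer(length(pr))
    dr <- integer(length(pr))
    for (j in seq_along(pr)) {
      if (pr[j] == vt) {
        mr[j] <- ar[j]
        dr[j] <- ar[j]
      } else {
        mr[j] <- t_and(cnf, c(pr[j], ar[j]))
        dr[j] <- t_or(cnf, c(-pr[j], ar[j]))
      }
    }
    someR <- t_or(cnf, mr)
    allR <- t_and(cnf, dr)
    LR <- c(-someR,
            t_and(cnf, c(someR, -allR)),
            t_and(cnf, c(someR, allR)))
  }
  terms <- integer()
  for (a in 2:3) {
    for (r in 1:3) {
      slit <- enc$anyS[[g]][cell_index(a, r)]
      if (slit == -vt) next
      p <- t_and(cnf, c(LA[a], LR[r]))
      terms <- c(terms, if (slit == vt) p else t_and(cnf, c(p, slit)))
    }
  }
  o <- t_or(cnf, terms)
  cnf_clause(cnf, -y, o)
  cnf_clause(cnf, y, -o)
  invisible(NULL)
}

# Unroll one experiment's trajectory; returns the (bound+2) x n_components
# matrix of state variables (rows = steps 0..bound+1).
encode_experiment_trajectory <- function(enc, sched, initial, bound) {
  cnf <- enc$cnf
  net <- enc$network
  comps <- net$components
  x <- matrix(0L, nrow = bound + 2L, ncol = length(comps),
              dimnames = list(0:(bound + 1L), comps))
  for (t in 0:(bound + 1L)) x[t + 1L, ] <- cnf_var(cnf, length(comps))
  init <- stats::setNames(rep(FALSE, length(comps)), comps)
  if (length(initial)) {
    unknown <- setdiff(names(initial), comps)
    if (length(unknown)) {
      stop("constraint references unknown component(s): ",
           paste(unknown, collapse = ", "))
    }
    init[names(initial)] <- initial
  }
  for (comp in comps) {
    sv <- scheduled_value(sched, comp, 0, net$roles)
    if (!is.na(sv)) init[comp] <- sv
    cnf_clause(cnf, if (init[comp]) x[1L, comp] else -x[1L, comp])
  }
  for (t in seq_len(bound + 1L)) {
    for (comp in comps) {
      y <- x[t + 1L, comp]
      sv <- scheduled_value(sched, comp, t, net$roles)
      if (!is.na(sv)) {
        cnf_clause(cnf, if (sv) y else -y)
      } else if (net$roles[[comp]] == "gene") {
        encode_gene_step(enc, comp, x[t, ], y)
      } else {
        cnf_clause(cnf, -y)
      }
    }
  }
  x
}

hold_lit <- function(enc, x, partial, s) {
  if (!length(partial)) return(lit_true(enc$cnf))
  lits <- x[s + 1L, names(partial)]
  t_and(enc$cnf, ifelse(partial, lits, -lits))
}

expectation_lit <- function(enc, x, ex, bound) {
  cnf <- enc$cnf
  rg <- resolve_range(ex, bound)
  steps <- rg["from"]:rg["to"]
  holds <- vapply(steps, function(s) hold_lit(enc, x, ex$state, s), 0L)
  switch(ex$modality,
    reached = t_or(cnf, holds),
    never = -t_or(cnf, holds),
    held = t_and(cnf, holds),
    stable = {
      s <- rg["to"]
      eqs <- vapply(seq_len(ncol(x)),
                    function(i) t_eq(cnf, x[s + 1L, i], x[s + 2L, i]), 0L)
      t_and(cnf, c(holds[length(holds)], eqs))
    })
}

# Literal per step t (0..bound): target partial state has held at some step
# <= t of trajectory x.
prefix_reach_lits <- function(enc, x, target, bound) {
  r <- integer(bound + 1L)
  r[1L] <- hold_lit(enc, x, target, 0L)
  for (t in seq_len(bound)) {
    r[t + 1L] <- t_or(enc$cnf, c(r[t], hold_lit(enc, x, target, t)))
  }
  r
}

# Literal: treated trajectory does not reach `target` strictly earlier than
# reference; vacuously true when reference never reaches it within bound.
comparative_lit <- function(enc, x_treated, x_ref, target, bound) {
  cnf <- enc$cnf
  rt <- prefix_reach_lits(enc, x_treated, target, bound)
  rr <- prefix_reach_lits(enc, x_ref, target, bound)
  inner <- t_and(cnf, vapply(seq_len(bound + 1L),
                             function(t) t_or(cnf, c(-rt[t], rr[t])), 0L))
  t_or(cnf, c(-rr[bound + 1L], inner))
}

encode_constraint <- function(enc, con) {
  cnf <- enc$cnf
  if (inherits(con, "comparative")) {
    xt <- encode_experiment_trajectory(enc, con$treated$sched,
                                       con$treated$initial, con$bound)
    xr <- encode_experiment_trajectory(enc, con$reference$sched,
                                       con$reference$initial, con$bound)
    cnf_clause(cnf, comparative_lit(enc, xt, xr, con$target, con$bound))
    enc$experiments[[con$name]] <- list(treated = xt, reference = xr)
  } else {
    x <- encode_experiment_trajectory(enc, con$sched, con$initial, con$bound)
    for (ex in con$expectations) {
      cnf_clause(cnf, expectation_lit(enc, x, ex, con$bound))
    }
    enc$experiments[[con$name]] <- list(x = x)
  }
  invisible(NULL)
}

# Recover the concrete model selected by a satisfying assignment.
decode_witness <- function(enc, model) {
  chosen <- if (length(enc$opt)) model[enc$elit[enc$opt]] else logical()
  genes <- network_genes(enc$network)
  conditions <- vapply(genes, function(g) {
    sv <- enc$svar[[g]]
    as.integer(names(sv))[which(model[sv])[1L]]
  }, 0L)
  concrete_model(enc$network, chosen, conditions)
}
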