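#!/usr/bin/env Rscript
# The update-rule family: enumerate the nine monotone regulation conditions
# and tabulate their permissiveness. These rules are the only update
# semantics used anywhere downstream.

library(abnsynth)
dir.create("results", showWarnings = FALSE)

conds <- regulation_conditions()
cat("Number of regulation conditions:", length(conds), "\n\n")
for (k in seq_along(conds)) {
  cat("condition", k - 1L, "-", sum(conds[[k]]), "active cells\n")
  print(conds[[k]])
  cat("\n")
}

tab <- data.frame(condition = seq_along(conds) - 1L,
                  n_true_cells = vapply(conds, sum, 0L),
                  needs_all_activators = vapply(conds, function(x) {
                    !any(x["some", ])
                  }, NA),
                  ignores_repressors = vapply(conds, function(x) {
                    all(x["all", ]) && (all(x["some", ]) || !any(x["some", ]))
                  }, NA))
write.csv(tab, "results/regulation_conditions.csv", row.names = FALSE)
cat("Wrote results/regulation_conditions.csv\n")
cat("Condition 0 fires only with every activator and no repressor;",
    "condition 8 fires whenever any activator is present.\n")
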