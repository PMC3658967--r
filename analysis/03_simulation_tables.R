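#!/usr/bin/env Rscript
# Stage 3: the full simulation study. Runs the scenario grid (ICC 5/15/30%
# with and without predictor-cluster correlation; 5-center/100-patient and
# 50-center/1000-patient designs; the 3%-incidence low-event setting) and
# writes one performance table per scenario under results/.
#
#   Rscript analysis/03_simulation_tables.R [reps] [table ids ...]
#
# Defaults to 100 replications of every scenario (several hours on one CPU);
# pass a smaller replication count or a subset of ids for a quicker pass,
# e.g. `Rscript analysis/03_simulation_tables.R 50 table3 table4`.

suppressPackageStartupMessages(library(clustpred))

args <- commandArgs(trailingOnly = TRUE)
reps <- if (length(args) >= 1) as.integer(args[1]) else 100L
ids <- if (length(args) >= 2) args[-1] else names(clustpred:::TABLE_SCENARIOS)

res <- reproduce_tables(ids, reps = reps, base_seed = 1, dir = "results",
                        verbose = TRUE)
for (id in names(res)) {
  cat("\n==", id, sprintf("(%d replications, %d non-converged)\n",
                          res[[id]]$n_reps, res[[id]]$n_nonconverged))
  print(format_scenario_table(res[[id]]), row.names = FALSE)
}
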