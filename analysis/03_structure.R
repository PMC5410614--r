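#!/usr/bin/env Rscript
# Stage 3: population structure.
#
# Multi-start EM admixture fits for K = 1..6 (5 runs each), Evanno delta-K
# model selection, subpopulation assignment at Q >= 0.6 (admixture
# otherwise), neighbor-joining tree on Nei distance, PCoA, allele-sharing
# kinship, and AMOVA over the assigned groups (admixture kept as a group).
#
# Reads:  results/panel.tsv
# Writes: results/evanno_delta_k.tsv, results/q_matrix.csv,
#         results/subpopulations.tsv, results/nj_tree.nwk,
#         results/pcoa.csv, results/kinship.csv, results/amova.tsv

suppressPackageStartupMessages(library(ssrmta))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
panel <- read_genotypes("results/panel.tsv")

runs_by_K <- lapply(1:6, function(K)
  fit_admixture(panel, K, restarts = 5, max_iter = 400, tol = 1e-4,
                seed = seed * 100 + K))
ev <- evanno_delta_k(runs_by_K)
write_report(ev, "results/evanno_delta_k.tsv")
best_K <- attr(ev, "best_K")
cat(sprintf("delta K peaks at K = %d\n", best_K))

Q <- runs_by_K[[best_K]][[1]]$Q
write_q_matrix(Q, "results/q_matrix.csv")
asg <- assign_subpopulations(Q, threshold = 0.6)
write_report(asg, "results/subpopulations.tsv")
print(table(asg$subpop))

D <- nei_distance(panel)
ape::write.tree(nj_tree(D), "results/nj_tree.nwk")
pc <- pcoa(D, n_axes = 3)
write_report(data.frame(line = rownames(pc$coords), pc$coords),
             "results/pcoa.csv")
cat(sprintf("PCoA axes 1-2 explain %.1f%% + %.1f%%\n",
            100 * pc$explained[1], 100 * pc$explained[2]))

km <- kinship(panel)
write_kinship(km$k, "results/kinship.csv")

am <- amova(panel, asg, n_perm = 999, seed = seed)
write_report(am$components, "results/amova.tsv")
cat(sprintf("AMOVA: %.1f%% among subpopulations, F_ST = %.3f (p = %.3g)\n",
            am$components$percent[1], am$F_ST, am$p_value))
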