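#!/usr/bin/env Rscript
# Stage 1: generate the working panel.
#
# The study panel's genotypes and phenotypes are not public, so the analysis
# runs on a synthetic stand-in with the same statistical anatomy: 130
# near-inbred lines, 267 polymorphic SSR loci (2-5 alleles), three latent
# subpopulations plus admixture, and Fe/Zn grain content phenotyped at three
# locations x two years x three replicates with H^2 around 0.8 and four
# planted marker-trait associations (R^2 ~ 0.10-0.18).
#
# Writes: results/panel.tsv, results/markers.csv, results/phenotypes.csv,
#         results/truth_qtls.tsv

suppressPackageStartupMessages(library(ssrmta))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = seed)
sim <- simulate_panel(cfg)

write_genotypes(sim$panel, "results/panel.tsv")
write_marker_map(sim$panel$markers, "results/markers.csv")
write_phenotypes(sim$pheno, "results/phenotypes.csv")
write_q_matrix(sim$truth$q, "results/truth_q.csv")
write_report(sim$truth$planted_qtls, "results/truth_qtls.tsv")

cat(sprintf("panel: %d lines x %d markers (seed %d)\n",
            length(sim$panel$line_ids), nrow(sim$panel$markers), seed))
cat(sprintf("planted QTLs: %s\n",
            paste(sprintf("%s(%s,+%.1f ppm)", sim$truth$planted_qtls$marker_id,
                          sim$truth$planted_qtls$trait,
                          sim$truth$planted_qtls$effect), collapse = ", ")))
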