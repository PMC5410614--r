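#!/usr/bin/env Rscript
# Stage 2: per-locus molecular diversity.
#
# Reports observed and effective allele numbers, major allele frequency,
# Nei gene diversity and PIC per SSR locus, plus panel means. Moderate
# diversity (mean H around 0.35, n_a around 2.7) is the regime expected of
# an agarose-resolved SSR panel of breeding lines.
#
# Reads:  results/panel.tsv, results/markers.csv
# Writes: results/diversity.tsv

suppressPackageStartupMessages(library(ssrmta))
panel <- read_genotypes("results/panel.tsv",
                        markers = read_marker_map("results/markers.csv"))
div <- allele_summary(panel)
write_report(div, "results/diversity.tsv")

m <- attr(div, "panel_means")
cat(sprintf("loci: %d; total alleles: %d\n", nrow(div), sum(div$n_a)))
cat(sprintf("mean n_a = %.2f, mean n_e = %.2f, mean H = %.3f, mean PIC = %.3f\n",
            m[["n_a"]], m[["n_e"]], m[["gene_diversity_H"]], m[["PIC"]]))
cat(sprintf("mean major-allele frequency = %.2f; loci with PIC > 0.5: %d\n",
            m[["major_allele_freq"]], sum(div$PIC > 0.5)))
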