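#!/usr/bin/env Rscript
# Stage 6: favorable-allele mining and cross proposals.
#
# For each marker significant in the MLM scans, computes per-allele
# phenotypic effects a_i (carrier mean minus population mean) on the
# datasets where the marker was significant, flags favorable (a_i > 0)
# alleles, inventories them per line, and proposes the crosses whose
# parents jointly pyramid the most favorable alleles (effect >= 4 ppm for
# cross planning). Sub-population-level one-way allele ANOVAs for the
# significant markers complete the picture.
#
# Reads:  results/panel.tsv, results/phenotypes.csv,
#         results/mta_significant.tsv, results/subpopulations.tsv
# Writes: results/allele_effects.tsv, results/favorable_alleles.tsv,
#         results/line_inventory.tsv, results/crosses.tsv,
#         results/subpop_anova.tsv

suppressPackageStartupMessages(library(ssrmta))
panel <- read_genotypes("results/panel.tsv")
pheno <- read_phenotypes("results/phenotypes.csv")
sig <- read_report("results/mta_significant.tsv")
asg <- read_report("results/subpopulations.tsv")
asg$subpop <- factor(asg$subpop)

if (!nrow(sig)) {
  cat("no significant MTAs; nothing to mine\n")
  quit(save = "no", status = 0)
}

effs <- list(); anovas <- list()
for (trait in unique(sig$trait)) {
  ds <- build_datasets(pheno, trait)
  sub <- sig[sig$trait == trait, ]
  for (nm in unique(sub$dataset)) {
    mk <- unique(sub$marker_id[sub$dataset == nm])
    effs[[paste(trait, nm)]] <-
      allele_effects(panel, ds[[nm]], mk, trait = trait, dataset_name = nm)
    for (m in mk) {
      an <- subpop_allele_anova(panel, ds[[nm]], asg, m)
      an$marker_id <- m; an$trait <- trait; an$dataset <- nm
      anovas[[paste(trait, nm, m)]] <- an
    }
  }
}
eff <- do.call(rbind, effs)
write_report(eff, "results/allele_effects.tsv")
write_report(do.call(rbind, anovas), "results/subpop_anova.tsv")

fav <- favorable_alleles(eff, min_effect = 0)
write_report(fav, "results/favorable_alleles.tsv")
cat(sprintf("favorable alleles: %d (of %d scored); strongest %s-%d (%+.1f ppm %s)\n",
            nrow(fav), nrow(eff), fav$marker_id[1], fav$allele[1],
            fav$a_i[1], fav$trait[1]))

strong <- favorable_alleles(eff, min_effect = 4)
inv <- genotype_allele_inventory(panel, strong)
write_report(inv$counts, "results/line_inventory.tsv")
best_line <- inv$counts[order(-inv$counts$n_total), ][1, ]
cat(sprintf("line with most favorable alleles (>= 4 ppm): %s (%d)\n",
            best_line$line, best_line$n_total))

crosses <- propose_crosses(inv, top_n = 9)
write_report(crosses, "results/crosses.tsv")
cat("top crosses (predicted pyramided favorable alleles):\n")
print(crosses, row.names = FALSE)
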