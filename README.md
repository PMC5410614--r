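# ssrmta

Association mapping of grain iron and zinc content in a crop diversity
panel genotyped with multiallelic SSR (microsatellite) markers — the
complete desk-side analysis, as a tested R package plus a numbered analysis
workflow.

Biofortification studies phenotype a panel of breeding lines for grain
mineral concentration (ppm) across multi-environment trials and genotype it
with SSRs scored as amplicon sizes. The questions the pipeline answers, in
order:

1. **How diverse is the panel?** Per-locus allele counts, effective allele
   number `n_e = 1/Σp_i²`, Nei gene diversity `H = 1 − Σp_i²`, and
   `PIC = 1 − Σp_i² − Σ_{i<j} 2p_i²p_j²`.
2. **Is it structured?** Maximum-likelihood admixture inference (multi-start
   EM on the mixture likelihood `Σ_k q_ik p_kla` per allele copy), Evanno
   ΔK model selection, assignment at `Q ≥ 0.6`, neighbor-joining on Nei
   distance, PCoA, allele-sharing kinship, and AMOVA over allele copies
   with permutation tests.
3. **Which markers track the traits?** Multiallelic LD
   (`r² = Σ_ab p_a q_b D_ab² / (p_a(1−p_a) q_b(1−q_b))`), then per-marker
   scans of all twelve datasets per trait (six location-years and six
   pooled means) with the GLM `y = Xa + Qb + e` and the Q+K mixed model
   `y = Xa + Qb + Zu + e`, `u ~ N(0, σu²K)` (EMMA-style REML + P3D),
   at the `1/n` threshold (`1/267 = 3.75e-3`, `−log10 = 2.43`).
4. **Which alleles are favorable, and what should we cross?** Allele effects
   `a_i = Σx_ij/n_i − ΣN_k/n_k` (carrier mean minus population mean),
   per-line favorable-allele inventories, and cross proposals ranked by the
   union of the parents' favorable-allele sets.

The original study's genotypes are not public, so a synthetic-panel
generator (`sim_config()` / `simulate_panel()`) reproduces the panel's
statistical anatomy — 130 near-inbred lines, 267 SSRs with 2–5 alleles,
three admixed subpopulations, H² ≈ 0.8 phenotypes with planted marker–trait
associations — and every stage is validated against that known truth.

## Worked example

The analysis workflow is a sequence of thin drivers over the package:

```sh
Rscript analysis/01_simulate.R 1      # panel + phenotypes + truth
Rscript analysis/02_diversity.R       # per-locus diversity
Rscript analysis/03_structure.R 1     # admixture, delta-K, tree, PCoA, AMOVA
Rscript analysis/04_phenotypes.R      # 12 datasets, H2, structure correlation
Rscript analysis/05_association.R 1   # LD + GLM/MLM scans
Rscript analysis/06_allele_mining.R   # favorable alleles + crosses
```

With seed 1 the run prints (abridged):

```
panel: 130 lines x 267 markers (seed 1)
planted QTLs: M010(Fe,+10.0 ppm), M025(Fe,+9.0 ppm), M010(Zn,+6.5 ppm), M040(Zn,+6.0 ppm)
loci: 267; total alleles: 677
mean n_a = 2.54, mean n_e = 1.70, mean H = 0.342, mean PIC = 0.292
mean major-allele frequency = 0.74; loci with PIC > 0.5: 38
delta K peaks at K = 3
        A         B         C admixture
       43        35        30        22
AMOVA: 7.1% among subpopulations, F_ST = 0.071 (p = 0.001)
Fe: grand-mean range 35.5-92.5 ppm, GM H2 = 0.93
  variance components: sigma_G2 = 134.3, sigma_GE2 = 39.4, sigma_e2 = 60.4
Zn: grand-mean range 27.4-62.0 ppm, GM H2 = 0.93
LD: 35511 pairs, mean r2 = 0.006, 7.0% with p < 0.05
significance threshold: p < 0.00375 (-log10 = 2.43)
MLM MTAs at threshold: 39 records over 8 markers (R2 0.07-0.12)
most frequent MTA: M025 (Fe) significant in 11 of 12 datasets
favorable alleles: 40 (of 94 scored); strongest M016-200 (+10.3 ppm Fe)
top crosses (predicted pyramided favorable alleles):
 parent1 parent2 n_Fe n_Zn n_total
    L005    L028    3    1       4
    L005    L034    3    1       4
    ...
```

Reading the numbers: mean gene diversity ≈ 0.35 with ≈ 2.7 alleles per
locus is the moderate-diversity regime of an agarose-resolved SSR panel;
ΔK peaking at K = 3 recovers the three simulated subpopulations, and the
single-digit AMOVA among-subpopulation percentage (F_ST ≈ 0.07) reflects
moderate differentiation — most molecular variance sits among individuals
within groups, as expected for multiallelic SSRs under drift F = 0.15. The mixed-model scan
recovers the planted QTLs — M025 is significant for Fe in 11 of the 12
datasets — at whitened-scale marker R² of 0.07–0.12, and the cross
proposal pairs lines whose favorable-allele sets complement each other.
All tables land under `results/`.

Equivalent programmatic entry point: `run_pipeline(panel, pheno, out_dir)`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the installed package end to end on the default synthetic panel —
simulation, diversity, admixture across K = 1..6 with ΔK, assignment,
tree/PCoA/kinship, AMOVA, phenotype statistics, MLM scans over all twelve
datasets per trait, allele mining and cross proposal — writing stage tables
next to the JSON report.

## Layout

```
R/                  package code (one file per analysis stage)
src/                Rcpp kernels: admixture EM, multiallelic LD
analysis/           numbered workflow drivers (the study, start to finish)
scripts/acceptance.R
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette: models, assumptions, calibration
```
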