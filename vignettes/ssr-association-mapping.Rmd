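---
title: "Association mapping of grain mineral traits with multiallelic SSR markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Association mapping of grain mineral traits with multiallelic SSR markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Biofortification programs screen diversity panels of crop lines for grain
micronutrient concentration (here iron and zinc, in ppm) and look for
molecular markers whose alleles track the trait, so that favorable alleles
can be selected and pyramided by crossing. `ssrmta` implements the complete
desk side of such a study for multiallelic SSR (microsatellite) panels:
diversity description, population-structure inference, linkage
disequilibrium, structured association scans, favorable-allele mining, and
cross proposal — plus a synthetic-panel generator so every stage can be
validated against known truth.

This vignette records the models, the tunable parameters with their
defaults, the numerical choices, and what the synthetic world does and does
not establish.

## Data model

A `genotype_panel` stores, per line and SSR locus, an unordered pair of
allele sizes (amplicon lengths in bp); a single size means a homozygote.
Diploid storage matters because two of the downstream statistics — the
"within individuals" level of AMOVA and copy-based allele frequencies —
need heterozygote calls, even in panels that are predominantly inbred.
Allele identity is the exact integer size; no binning is applied (gel
resolution is a property of the wet lab, not a computational rule).
Phenotypes are long records of (line, location, year, replicate, trait,
value) over three locations (Delhi, Jodhpur, Dharwad) and two years.

## Diversity statistics

Per locus, with copy-counted allele frequencies $p_i$:

* gene diversity (expected heterozygosity) $H = 1 - \sum_i p_i^2$,
* effective allele number $n_e = 1 / \sum_i p_i^2$,
* $\mathrm{PIC} = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$.

Alleles below 5% frequency are flagged rare but never filtered. These are
closed forms; the tests check them against an independent enumeration of
allele copies to $10^{-12}$.

## Population structure

### Admixture model and its fitting

Each allele copy of line $i$ at locus $l$ is modeled as drawn from
$\sum_k q_{ik}\, p_{kla}$, with ancestry proportions $q_i$ on the simplex —
the same admixture likelihood that Bayesian structure software samples by
MCMC. We maximize it directly with EM (a deliberate substitution: a desk-
scale, deterministic, restartable optimizer whose maximized log-likelihood
serves as the per-run model score). Defaults: 5 restarts, `tol = 1e-6` on
the absolute log-likelihood change, `max_iter = 2000`; restarts initialize
ancestry rows from a near-uniform Dirichlet and frequencies from pooled
frequencies perturbed by log-normal noise. EM ascent is monotone, which the
tests assert per iteration. Model selection uses the Evanno statistic
$\Delta K = |\bar L(K{+}1) - 2\bar L(K) + \bar L(K{-}1)| / \mathrm{sd}(L(K))$
over the restart replicates; endpoints carry no value, and a zero sd yields
$+\infty$ with a warning. Lines are assigned to the subpopulation of their
maximal $q$ when it reaches 0.6 (boundary inclusive), otherwise labeled
admixture; groups are renamed A, B, C… by decreasing size, and ties in a
row's maximum break toward the lowest component index so assignment is
deterministic.

In practice (and in the acceptance tests) `max_iter = 400, tol = 1e-4`
suffices for stable log-likelihood ordering across K; the looser setting is
a runtime choice, not a different model.

### Distances, trees, ordination, kinship

* Nei (1972) standard distance between lines treats each line as a 2-copy
  frequency profile; $-\ln 0$ (no shared alleles anywhere) is capped at a
  configurable 10.
* Neighbor-joining uses the standard Saitou–Nei agglomeration (via
  \pkg{ape}); a negative branch is clamped to zero with the deficit moved
  to its sister edge so path lengths through the parent are preserved.
* PCoA is classical Gower double-centering + eigendecomposition; negative
  eigenvalues are dropped with a warning and explained proportions are
  computed over the positive spectrum.
* Kinship is allele-sharing: per locus, the multiset intersection of the
  two diploid calls divided by 2, averaged over loci; entries lie in
  $[0, 1]$, and the matrix is shifted by $10^{-6} I$ only if its smallest
  eigenvalue is negative.

### AMOVA

Three levels over allele copies — among subpopulations, among individuals
within subpopulations, within individuals — with the inter-copy distance
being the per-locus allele mismatch indicator summed over loci. Degrees of
freedom are $(g-1,\; n-g,\; n)$; variance components come from the moment
equations, negative components are clamped to zero with a warning, and
$F_{ST} = V_a / (V_a + V_b + V_c)$. The admixture group participates as a
group of its own (the four-group layout). Significance is by permuting
individual labels; the permutation statistic is the *unclamped* among-group
component — clamping first would pile null permutations into ties at zero
and distort the p-value distribution (this surfaced in the uniformity
property test and is a deliberate numerical choice).

## Phenotype statistics

The twelve analysis datasets per trait are the six location-year replicate
means (Del-14 … DW-15) and six unweighted pooled means: per location over
years (Del-M, Jod-M, DW-M), per year over locations (Y14-M, Y15-M), and the
grand mean GM. Pooling is unweighted and idempotent; lines missing an
entire environment are excluded from pooled datasets involving it, with a
warning, rather than imputed. The incomplete-block (alpha-lattice) field
design is deliberately simplified to replicate means — spatial recovery is
out of scope, and the generator does not simulate block effects.

Variance components come from two-way genotype × environment ANOVA with
method-of-moments extraction: $\sigma_e^2 = MS_e$,
$\sigma_{GE}^2 = (MS_{GE} - MS_e)/r$,
$\sigma_G^2 = (MS_G - MS_{GE})/(nr)$, negatives clamped at zero. (Treating
the genotype factor as fixed in the trial ANOVA while still reporting
$\sigma_G^2$-based heritability mirrors common practice in these studies;
method-of-moments is the transparent reading of that convention. REML lives
only inside the mixed-model scan.) Broad-sense heritability:

$$H^2 = \frac{\sigma_G^2}{\sigma_G^2 + \sigma_e^2/r} \quad\text{(single environment)},
\qquad
H^2 = \frac{\sigma_G^2}{\sigma_G^2 + \sigma_{GE}^2/n + \sigma_e^2/nr} \quad\text{(multi-environment)}.$$

## Linkage disequilibrium and association

### Multiallelic LD

For loci with allele frequencies $p_a$, $q_b$ and composite joint
frequencies $P_{ab}$ (allele copies paired within individuals, weight 1/2
over the four combinations — exact haplotype counts for homozygotes,
phase-free otherwise), $D_{ab} = P_{ab} - p_a q_b$ and

$$r^2 = \sum_a \sum_b p_a q_b \frac{D_{ab}^2}{p_a(1-p_a)\,q_b(1-q_b)},$$

a frequency-weighted mean of squared per-allele-pair correlations, clamped
to $[0,1]$. The p-value permutes one locus's genotypes across lines.
Monomorphic pairs return $r^2 = 0$ with a flag.

### Marker scans

GLM: $y = Xa + Qb + e$ — per marker OLS of the trait on allele-dosage
columns (0/1/2 per allele, rare classes with fewer than `min_class_size =
3` carriers merged into "other", the most frequent class dropped as
reference) plus the first $K-1$ ancestry columns. Marker p is the partial
F-test of the allele columns; marker $R^2 = SS_\text{marker}/SS_\text{total}$.
Missing calls are mean-imputed in the dosage columns so the row set is
constant across markers.

MLM (Q+K): $y = Xa + Qb + Zu + e$ with $u \sim N(0, \sigma_u^2 K)$.
Variance components are estimated once per dataset by REML on the
marker-free model, profiling the ratio $\lambda = \sigma_u^2/\sigma_e^2$
over $\log_{10}\lambda \in [-6, 6]$ on the eigenbasis of $K$; each marker
is then tested on the whitened data (P3D: components are not re-estimated
per marker — the desk-scale speed/accuracy trade common in GWAS tools).
With $\sigma_u^2 = 0$ the scan reduces *exactly* to the GLM, which the
tests assert to $10^{-8}$. If REML fails the scan falls back to GLM with a
prominent warning.

The significance threshold follows the 1/n convention as printed in this
literature: $p < 1/267 = 3.75\times10^{-3}$, $-\log_{10} = 2.43$. That is
*not* the conventional Bonferroni $\alpha/n$; both are available
(`bonferroni_threshold(n, alpha =)`), the 1/n form is the default for
fidelity. Applied strictly (`p < threshold`).

Supporting diagnostics: QQ data against uniform quantiles $(i-0.5)/m$,
per-marker significance frequency across the twelve datasets, and within-
subpopulation one-way allele ANOVAs (lines grouped by diploid genotype;
groups lacking two classes of two lines are skipped with a note).

## Favorable alleles and crosses

The phenotypic effect of allele $i$ is
$a_i = \frac{\sum_j x_{ij}}{n_i} - \frac{\sum_k N_k}{n_k}$ — the carrier
mean minus the population mean over lines with a non-missing call at the
marker (the population-mean baseline in place of null alleles; it keeps the
zero-sum identity $\sum_i n_i a_i = 0$ exact under missingness).
Heterozygotes contribute their full phenotype to each carried class (a
documented choice; the literature is silent and panels are near-inbred).
$a_i > 0$ is favorable; cross planning uses the stronger $a_i \ge 4$ ppm
cut. Crosses are scored by the union of the parents' favorable
(marker, allele) sets — distinct pairs, so two different favorable alleles
at one marker both count; per-trait counts are reported alongside the
combined total, and ties break lexicographically by parent ids. (In the
published tables of such studies the total column is not the Fe + Zn sum
and the counting rule is not recoverable; the union-of-distinct-pairs rule
is asserted here as the package's own convention.)

## The synthetic world

Since no real genotypes are released with studies of this kind, the
generator is a first-class module. Its defaults are the stated world:

| Parameter | Default | Why |
|---|---|---|
| lines / loci | 130 / 267 | panel and marker counts of the emulated design |
| alleles per locus | 2–5 | agarose-resolved SSR regime |
| ancestral frequencies | Dirichlet(0.3) | calibrates pooled Nei H to ≈ 0.35 (moderate diversity), n_a ≈ 2.7, major-allele frequency ≈ 0.73 |
| subpopulations | 3, Balding–Nichols drift F = 0.15 | the correlated-frequency model the admixture likelihood assumes, so simulation and inference are coherent |
| admixture | Dirichlet(0.2) ancestry | ≈ 20–25% of lines below the 0.6 assignment threshold |
| selfing rate | 0.9 | near-inbred breeding lines with residual heterozygosity |
| trait means | Fe 59, Zn 43 ppm | grain-content scale of the emulated tables |
| σG², σGE², σe² | Fe: 100/40/60; Zn: 40/15/25 | single-environment H² ≈ 0.83 at r = 3 (the > 0.8 regime) |
| environment shifts | N(0, 9) per location-year | environment means a few ppm apart |
| planted QTLs | 2/trait, effects 10/9 (Fe), 6.5/6 (Zn) ppm, favorable frequency 0.3–0.5 | marker R² ≈ 0.10–0.18 |

Phenotype construction: base mean + (favorable-copy count / 2) × effect
(a homozygote carrier shows the full effect — near-inbred panels) +
polygenic value + environment shift + G×E deviate + replicate residual.
The polygenic kernel is the panel's allele-sharing kinship double-centered
and rescaled to unit mean diagonal, so that `sigma_G2` *is* the realized
between-line genetic variance; raw allele-sharing kinship carries a large
baseline of chance sharing that would otherwise shrink the effective
variance to roughly a third of the nominal parameter (this mattered for
variance-component recovery and is a parameter-faithfulness fix, not a
tuning knob).

For pyramiding-recovery experiments the generator can force two
"complementary parents": homozygous-favorable at the Fe-planted and
Zn-planted QTL sets respectively. That scenario uses rare favorable
alleles (ancestral frequency ≈ 0.1): with the default common favorable
alleles, most random pairs of 130 lines cover every favorable allele and
"the complementary pair ranks first" is not a well-posed prediction for
any method; rarity mirrors the situation where a top line carries several
favorable alleles while most lines carry few.

What the generator does **not** emulate: linkage — markers are simulated
independently, so LD arises from structure only and LD-decay-along-the-map
questions are out of reach; incomplete-block field effects; assay error
structure (contamination screening etc.); and any reproduction of the real
study's numbers, which would require the unreleased data. A green test
establishes internal correctness and statistical calibration of the
methods, not agreement with the original field experiment.

## Numerical and degenerate-input choices

* EM frequencies are floored at $10^{-12}$ and renormalized per locus block;
  final log-likelihood is recomputed at the returned parameters.
* `q_matrix` tolerates row sums within $10^{-6}$ and renormalizes exactly.
* Nei distance cap 10; kinship PSD shift $10^{-6}$; REML profile bounds
  $\log_{10}\lambda \in [-6, 6]$ (a boundary fit means a pure-kinship or
  pure-residual covariance — both remain valid whitening transforms).
* AMOVA negative components clamp to zero with recomputed percentages;
  permutation p uses the unclamped statistic (see above).
* Monomorphic loci: diversity returns $H = \mathrm{PIC} = 0$, $n_e = 1$;
  scans skip the marker; allele effects return a single $a_i = 0$.
* p-values are floored at `.Machine$double.xmin` so reports never carry 0.

## Known limitations

* P3D variance components are shared across markers of a dataset; exact
  per-marker REML is not implemented (the flag exists at the API level via
  `force_lambda` only for the zero case).
* The EM replaces posterior inference: no credible intervals on Q, and
  multimodality is handled only by restarts.
* Marker R² from partial sums of squares is *not* monotone under adding
  structure covariates (suppression can raise it); the tests therefore
  check the confounded direction, where deflation is guaranteed.
* `align_q_labels` enumerates permutations and is limited to K ≤ 8.
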