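#' Analysis of molecular variance over allele copies
#'
#' Three-level hierarchical AMOVA (among groups, among individuals within
#' groups, within individuals) with the inter-copy distance at each locus
#' being the allele mismatch indicator, summed over loci. Sums of squares
#' use the standard identity `SS = sum over loci (m^2 - sum_a c_a^2)/(2m)`
#' for a set of m copies with per-allele counts `c_a`; the partition
#' `SS_total = SS_among + SS_indiv_within + SS_within_indiv` is exact by
#' construction. Variance components come from the moment equations
#' `E[MS_WI] = Vc`, `E[MS_AI] = Vc + 2 Vb`, `E[MS_AG] = Vc + 2 Vb + S_c Va`
#' with `S_c = (M - sum m_g^2 / M) / (g - 1)` over copy counts, and
#' `F_ST = Va / (Va + Vb + Vc)`. Significance is by permutation of
#' individual group labels.
#'
#' @param panel a [genotype_panel()].
#' @param assignment data frame from [assign_subpopulations()] (the
#'   admixture group participates as a group of its own) or any
#'   `(line, subpop)` data frame.
#' @param n_perm number of label permutations for the p-value (0 to skip).
#' @param seed RNG seed for permutations.
#' @return list with `components` (data frame: source, df, SS, variance,
#'   percent), `F_ST`, `p_value`, `n_perm`. The permutation test compares the
#'   unclamped among-group component so ties from zero-clamping do not
#'   distort the null distribution.
#' @export
amova <- function(panel, assignment, n_perm = 999, seed = 1L) {
  grp <- assignment$subpop[match(panel$line_ids, assignment$line)]
  if (anyNA(grp)) stop("assignment missing for some panel lines")
  grp <- droplevels(factor(grp))
  sizes <- table(grp)
  if (sum(sizes >= 2) < 2)
    stop("need >= 2 groups with >= 2 lines each")
  idx <- panel_allele_index(panel)
  res <- amova_components(idx, as.integer(grp))
  obs <- res
  p_value <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    n <- length(panel$line_ids)
    ge <- 0L
    for (s in seq_len(n_perm)) {
      perm <- suppressWarnings(
        amova_components(idx, as.integer(grp)[sample.int(n)]))
      if (perm$raw_Va >= obs$raw_Va - 1e-12) ge <- ge + 1L
    }
    p_value <- (1 + ge) / (1 + n_perm)
  }
  comp <- obs$components
  list(components = comp, F_ST = obs$F_ST, p_value = p_value, n_perm = n_perm)
}

# core SS/variance computation given per-locus allele indices and group codes
amova_components <- function(idx, grp) {
  n <- nrow(idx$i1); L <- ncol(idx$i1)
  g <- max(grp)
  ss_set <- function(rows) {
    # SS over the allele copies of `rows` (both copies per non-missing call)
    total <- 0
    for (j in seq_len(L)) {
      v <- c(idx$i1[rows, j], idx$i2[rows, j])
      v <- v[!is.na(v)]
      m <- length(v)
      if (m < 2) next
      cnt <- tabulate(v, nbins = idx$n_alleles[j])
      total <- total + (m^2 - sum(cnt^2)) / (2 * m)
    }
    total
  }
  # within individuals: half a mismatch per heterozygous call
  het <- !is.na(idx$i1) & idx$i1 != idx$i2
  ss_wi <- sum(het) / 2
  ss_tot <- ss_set(seq_len(n))
  ss_wg <- sum(vapply(seq_len(g), function(k) ss_set(which(grp == k)),
                      numeric(1)))
  ss_ag <- ss_tot - ss_wg
  ss_ai <- ss_wg - ss_wi
  df_ag <- g - 1; df_ai <- n - g; df_wi <- n
  ms_wi <- ss_wi / df_wi
  ms_ai <- ss_ai / df_ai
  ms_ag <- ss_ag / df_ag
  m_g <- 2 * tabulate(grp, nbins = g)    # copies per group
  M <- sum(m_g)
  S_c <- (M - sum(m_g^2) / M) / df_ag
  Vc <- ms_wi
  Vb <- (ms_ai - ms_wi) / 2
  Va <- (ms_ag - ms_ai) / S_c
  raw_Va <- Va                     # permutation statistic, unclamped
  clamped <- c(Va, Vb, Vc) < 0
  if (any(clamped)) {
    warning("negative AMOVA variance component clamped to zero")
    Va <- max(Va, 0); Vb <- max(Vb, 0); Vc <- max(Vc, 0)
  }
  Vt <- Va + Vb + Vc
  pct <- if (Vt > 0) 100 * c(Va, Vb, Vc) / Vt else c(0, 0, 0)
  comp <- data.frame(
    source = c("Among sub-populations",
               "Among individuals within sub-populations",
               "Within individuals", "Total"),
    df = c(df_ag, df_ai, df_wi, df_ag + df_ai + df_wi),
    SS = c(ss_ag, ss_ai, ss_wi, ss_tot),
    variance = c(Va, Vb, Vc, Vt),
    percent = c(pct, 100),
    stringsAsFactors = FALSE)
  list(components = comp, F_ST = if (Vt > 0) Va / Vt else 0,
       raw_Va = raw_Va)
}
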