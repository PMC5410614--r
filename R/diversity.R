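#' Per-locus molecular diversity summary
#'
#' For each locus, reports the observed allele number `n_a`, major allele
#' frequency, effective allele number `n_e = 1 / sum(p_i^2)`, Nei gene
#' diversity `H = 1 - sum(p_i^2)`, and polymorphism information content
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`. Frequencies are counted
#' over allele copies (two per non-missing call). Alleles with frequency
#' below `rare_freq` are flagged (`n_rare`), not filtered.
#'
#' @param panel a [genotype_panel()].
#' @param rare_freq rare-allele flag threshold (default 0.05).
#' @return data frame with one row per locus and attribute `panel_means`
#'   (means of `n_a`, `n_e`, `gene_diversity_H`, `PIC`, `major_allele_freq`).
#' @export
allele_summary <- function(panel, rare_freq = 0.05) {
  freqs <- allele_frequencies(panel)
  rows <- lapply(seq_along(freqs), function(j) {
    p <- freqs[[j]]
    st <- diversity_stats(p)
    data.frame(marker_id = panel$markers$marker_id[j],
               n_a = length(p),
               major_allele_freq = max(p),
               n_e = st$n_e,
               gene_diversity_H = st$H,
               PIC = st$PIC,
               n_rare = sum(p < rare_freq),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "panel_means") <- c(
    n_a = mean(out$n_a), n_e = mean(out$n_e),
    gene_diversity_H = mean(out$gene_diversity_H), PIC = mean(out$PIC),
    major_allele_freq = mean(out$major_allele_freq))
  out
}

#' Closed-form diversity statistics from an allele-frequency vector
#'
#' @param p numeric vector of allele frequencies (must sum to 1).
#' @return list with `n_e`, `H` (Nei gene diversity) and `PIC`.
#' @export
diversity_stats <- function(p) {
  if (abs(sum(p) - 1) > 1e-8) stop("frequencies must sum to 1")
  s2 <- sum(p^2)
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
  pic <- 1 - s2 - (s2^2 - sum(p^4))
  list(n_e = 1 / s2, H = 1 - s2, PIC = pic)
}
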