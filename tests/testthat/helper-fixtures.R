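# Small deterministic fixtures built in code.

# Build a genotype_panel from a character matrix of calls ("a/b", "a", NA).
panel_from_calls <- function(calls, line_ids = NULL, marker_ids = NULL, ...) {
  calls <- as.matrix(calls)
  if (is.null(line_ids)) line_ids <- sprintf("L%02d", seq_len(nrow(calls)))
  if (is.null(marker_ids)) marker_ids <- sprintf("M%02d", seq_len(ncol(calls)))
  a1 <- matrix(NA_integer_, nrow(calls), ncol(calls))
  a2 <- a1
  for (j in seq_len(ncol(calls))) for (i in seq_len(nrow(calls))) {
    cell <- calls[i, j]
    if (is.na(cell)) next
    parts <- as.integer(strsplit(cell, "/", fixed = TRUE)[[1]])
    a1[i, j] <- parts[1]
    a2[i, j] <- parts[length(parts)]
  }
  colnames(a1) <- colnames(a2) <- marker_ids
  genotype_panel(line_ids, a1, a2, ...)
}

# Random homozygous panel with given per-locus allele pools (for oracles).
random_panel <- function(n, L, n_alleles = 3, seed = 1) {
  set.seed(seed)
  a1 <- matrix(0L, n, L)
  for (j in seq_len(L)) {
    pool <- sort(sample(seq(100L, 300L, 2L), n_alleles))
    a1[, j] <- sample(pool, n, replace = TRUE)
    # guarantee polymorphism
    if (length(unique(a1[, j])) == 1) a1[1, j] <- setdiff(pool, a1[1, j])[1]
  }
  genotype_panel(sprintf("L%03d", seq_len(n)), a1, a1, missing_cap = 1)
}

# Balanced phenotype data frame for given line-level values, replicated with
# optional per-record additions.
balanced_pheno <- function(line_values, trait = "Fe", locations = "Delhi",
                           years = 2014, reps = 3, add = 0) {
  grid <- expand.grid(line = names(line_values), location = locations,
                      year = years, replicate = seq_len(reps),
                      trait = trait, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$value <- line_values[grid$line] + add
  phenotype_table(grid)
}
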