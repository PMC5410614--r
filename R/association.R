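#' Pairwise multiallelic linkage disequilibrium
#'
#' For every pair of loci, computes the composite multiallelic r-squared:
#' the frequency-weighted mean over allele pairs of
#' `D_ab^2 / (p_a (1 - p_a) q_b (1 - q_b))`, with joint counts taken by
#' pairing allele copies within individuals (no phase required). A
#' permutation p-value shuffles one locus's genotypes across lines.
#'
#' @param panel a [genotype_panel()].
#' @param n_perm permutations per pair (0 disables p-values).
#' @param seed RNG seed for the permutations.
#' @return data frame with `marker1`, `marker2`, `r2`, `p`, `monomorphic`
#'   (`r2 = 0` with flag when a locus is effectively monomorphic); exactly
#'   `choose(L, 2)` rows.
#' @export
ld_matrix <- function(panel, n_perm = 0, seed = 1L) {
  idx <- panel_allele_index(panel)
  L <- ncol(idx$i1)
  if (L < 2) stop("need >= 2 loci")
  n <- nrow(idx$i1)
  set.seed(seed)
  perms <- if (n_perm > 0)
    t(vapply(seq_len(n_perm), function(s) sample.int(n), integer(n)))
  else matrix(0L, 0, n)
  res <- ld_matrix_cpp(idx$i1, idx$i2, idx$n_alleles, perms)
  data.frame(marker1 = panel$markers$marker_id[res$locus1],
             marker2 = panel$markers$marker_id[res$locus2],
             r2 = res$r2, p = res$p, monomorphic = res$monomorphic,
             stringsAsFactors = FALSE)
}

#' Significance threshold in the 1/n convention
#'
#' The threshold is `1/n_markers` exactly (with 267 markers, 3.75e-3,
#' -log10 = 2.43); pass `alpha` for the conventional Bonferroni `alpha/n`.
#'
#' @param n_markers number of markers tested.
#' @param alpha if non-`NULL`, use `alpha / n_markers` instead of `1 / n`.
#' @return list `(p_threshold, neg_log10)`; `neg_log10` rounded to 2
#'   decimals.
#' @export
bonferroni_threshold <- function(n_markers, alpha = NULL) {
  if (n_markers < 1) stop("n_markers must be >= 1")
  thr <- if (is.null(alpha)) 1 / n_markers else alpha / n_markers
  list(p_threshold = thr, neg_log10 = round(-log10(thr), 2))
}

# Allele-dosage design for one marker: one 0/1/2 column per allele, alleles
# with fewer than min_class_size carrier lines merged into "other", the most
# frequent remaining class dropped as reference. Missing calls are imputed
# at the column means so the row set stays fixed across markers.
marker_design <- function(panel, j, min_class_size = 3) {
  a1 <- panel$a1[, j]; a2 <- panel$a2[, j]
  sizes <- sort(unique(c(a1, a2)))
  sizes <- sizes[!is.na(sizes)]
  dos <- vapply(sizes, function(s) (a1 == s) + (a2 == s),
                numeric(length(a1)))
  colnames(dos) <- as.character(sizes)
  carriers <- colSums(dos > 0, na.rm = TRUE)
  rare <- carriers < min_class_size
  if (any(rare) && sum(rare) < length(sizes)) {
    merged <- rowSums(dos[, rare, drop = FALSE])
    dos <- cbind(dos[, !rare, drop = FALSE], other = merged)
    carriers <- colSums(dos > 0, na.rm = TRUE)
  }
  eligible <- carriers >= min_class_size
  if (sum(eligible) < 2) return(NULL)     # monomorphic at usable resolution
  copies <- colSums(dos, na.rm = TRUE)
  ref <- which.max(copies)
  X <- dos[, -ref, drop = FALSE]
  for (k in seq_len(ncol(X))) {
    m <- is.na(X[, k])
    if (any(m)) X[m, k] <- mean(X[!m, k])
  }
  X
}

# Align a named dataset vector with panel lines and Q columns.
scan_frame <- function(dataset, panel, Q) {
  lines <- panel$line_ids[panel$line_ids %in% names(dataset)]
  if (!is.null(Q)) lines <- lines[lines %in% Q$line_ids]
  if (length(lines) < 5) stop("too few lines shared across inputs")
  y <- unname(dataset[lines])
  X0 <- matrix(1, length(lines), 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(Q) && Q$K > 1)
    X0 <- cbind(X0, Q$q[match(lines, Q$line_ids), -Q$K, drop = FALSE])
  list(lines = lines, y = y, X0 = X0,
       row_of = match(lines, panel$line_ids))
}

# Partial F-test of marker columns added to a base design (possibly on
# whitened data); returns p, marker R2 (= SS_marker / SS_total about the
# base intercept fit) and allele effect estimates.
partial_f <- function(y, X0, Xm, ss_total) {
  n <- length(y)
  q0 <- qr(X0)
  X1 <- cbind(X0, Xm)
  q1 <- qr(X1)
  df_m <- q1$rank - q0$rank
  if (df_m < 1) return(NULL)              # marker collinear with base
  rss0 <- sum(qr.resid(q0, y)^2)
  rss1 <- sum(qr.resid(q1, y)^2)
  df2 <- n - q1$rank
  if (df2 < 1) return(NULL)
  Fst <- ((rss0 - rss1) / df_m) / (rss1 / df2)
  p <- stats::pf(Fst, df_m, df2, lower.tail = FALSE)
  beta <- qr.coef(q1, y)[-seq_len(ncol(X0))]
  list(p = max(p, .Machine$double.xmin), F = Fst, df1 = df_m, df2 = df2,
       R2 = (rss0 - rss1) / ss_total, beta = beta)
}

#' General linear model marker scan (Q model)
#'
#' Per marker, ordinary least squares of the trait on allele dosage columns
#' plus K-1 ancestry covariates; the marker p-value is the partial F-test of
#' the allele columns and the marker R-squared is `SS_marker / SS_total`.
#'
#' @param dataset named numeric vector of line-level trait values.
#' @param panel a [genotype_panel()].
#' @param Q a [q_matrix()] or `NULL` for no structure correction.
#' @param trait,dataset_name labels copied into the records.
#' @param min_class_size minimum carrier count per allele class (smaller
#'   classes are merged into `"other"`).
#' @return data frame of marker-trait association records: `marker_id`,
#'   `trait`, `dataset`, `model`, `p`, `marker_R2`, `allele_effects`
#'   (list column of named effect estimates vs the reference class).
#' @export
glm_scan <- function(dataset, panel, Q = NULL, trait = NA_character_,
                     dataset_name = NA_character_, min_class_size = 3) {
  sf <- scan_frame(dataset, panel, Q)
  ss_total <- sum((sf$y - mean(sf$y))^2)
  scan_core(sf, panel, ss_total, model = "GLM", trait, dataset_name,
            min_class_size)
}

scan_core <- function(sf, panel, ss_total, model, trait, dataset_name,
                      min_class_size, transform = NULL) {
  L <- nrow(panel$markers)
  recs <- vector("list", L)
  for (j in seq_len(L)) {
    Xm <- marker_design(panel, j, min_class_size)
    if (is.null(Xm)) next
    Xm <- Xm[sf$row_of, , drop = FALSE]
    if (!is.null(transform)) Xm <- transform %*% Xm
    ft <- partial_f(sf$y, sf$X0, Xm, ss_total)
    if (is.null(ft)) {
      warning("marker ", panel$markers$marker_id[j],
              " skipped (rank-deficient design)")
      next
    }
    recs[[j]] <- data.frame(marker_id = panel$markers$marker_id[j],
                            trait = trait, dataset = dataset_name,
                            model = model, p = ft$p,
                            marker_R2 = min(max(ft$R2, 0), 1),
                            F = ft$F, df1 = ft$df1, df2 = ft$df2,
                            stringsAsFactors = FALSE)
    recs[[j]]$allele_effects <- list(ft$beta)
  }
  out <- do.call(rbind, recs)
  if (is.null(out))
    out <- data.frame(marker_id = character(), trait = character(),
                      dataset = character(), model = character(),
                      p = numeric(), marker_R2 = numeric(), F = numeric(),
                      df1 = integer(), df2 = integer(),
                      stringsAsFactors = FALSE)
  out
}

# REML profile over the variance ratio lambda = sigma_u^2 / sigma_e^2 on the
# eigenbasis of the kinship matrix (one-dimensional optimization).
reml_lambda <- function(y, X0, Kmat) {
  n <- length(y)
  ek <- eigen(Kmat, symmetric = TRUE)
  U <- ek$vectors; s <- pmax(ek$values, 0)
  ys <- drop(crossprod(U, y))
  X0s <- crossprod(U, X0)
  p <- qr(X0s)$rank
  neg_reml <- function(log_lambda) {
    lam <- 10^log_lambda
    d <- lam * s + 1
    w <- 1 / sqrt(d)
    fit <- stats::lm.fit(X0s * w, ys * w)
    rss <- sum(fit$residuals^2)
    xtx <- crossprod(X0s * w)
    ld_x <- determinant(xtx, logarithm = TRUE)$modulus
    0.5 * ((n - p) * log(rss / (n - p)) + sum(log(d)) + ld_x)
  }
  opt <- stats::optimize(neg_reml, c(-6, 6), tol = 1e-6)
  lam <- 10^opt$minimum
  d <- lam * s + 1
  w <- 1 / sqrt(d)
  rss <- sum(stats::lm.fit(X0s * w, ys * w)$residuals^2)
  sigma_e2 <- rss / (n - p)
  list(lambda = lam, sigma_u2 = lam * sigma_e2, sigma_e2 = sigma_e2,
       U = U, s = s)
}

#' Mixed linear model (Q + K) marker scan
#'
#' The model `y = X a + Q b + Z u + e` with `u ~ N(0, sigma_u^2 K)` and
#' `e ~ N(0, sigma_e^2 I)`. Variance components are estimated once per
#' dataset by REML on the marker-free model via eigendecomposition of the
#' kinship matrix (P3D); each marker is then tested by a partial F-test on
#' the whitened data, with `marker_R2 = SS_marker / SS_total` on the
#' whitened scale. With `sigma_u^2 = 0` the scan reduces exactly to
#' [glm_scan()].
#'
#' @inheritParams glm_scan
#' @param K a `kinship_matrix` from [kinship()] or a labeled PSD matrix.
#' @param force_lambda optionally fix the variance ratio
#'   `sigma_u^2 / sigma_e^2` (0 gives the GLM limit); `NULL` estimates it.
#' @return records as in [glm_scan()] with `model = "MLM"`; attributes
#'   `sigma_u2`, `sigma_e2`, `lambda` carry the variance components.
#' @export
mlm_scan <- function(dataset, panel, Q, K, trait = NA_character_,
                     dataset_name = NA_character_, min_class_size = 3,
                     force_lambda = NULL) {
  Kmat <- if (inherits(K, "kinship_matrix")) K$k else as.matrix(K)
  sf <- scan_frame(dataset, panel, Q)
  Kmat <- Kmat[sf$lines, sf$lines]
  vc <- tryCatch({
    if (!is.null(force_lambda)) {
      ek <- eigen(Kmat, symmetric = TRUE)
      n <- length(sf$y); p <- qr(sf$X0)$rank
      U <- ek$vectors; s <- pmax(ek$values, 0)
      d <- force_lambda * s + 1
      ys <- drop(crossprod(U, sf$y)) / sqrt(d)
      rss <- sum(stats::lm.fit(crossprod(U, sf$X0) / sqrt(d), ys)$residuals^2)
      se2 <- rss / (n - p)
      list(lambda = force_lambda, sigma_u2 = force_lambda * se2,
           sigma_e2 = se2, U = U, s = s)
    } else reml_lambda(sf$y, sf$X0, Kmat)
  }, error = function(e) NULL)
  if (is.null(vc) || !is.finite(vc$lambda)) {
    warning("REML variance estimation failed; falling back to GLM for this ",
            "dataset")
    return(glm_scan(dataset, panel, Q, trait, dataset_name, min_class_size))
  }
  # whitening transform W = D^{-1/2} U'
  W <- (1 / sqrt(vc$lambda * vc$s + 1)) * t(vc$U)
  yw <- drop(W %*% sf$y)
  X0w <- W %*% sf$X0
  # total SS about the whitened-intercept fit
  icol <- W %*% rep(1, length(sf$y))
  ss_total <- sum(qr.resid(qr(icol), yw)^2)
  sfw <- list(y = yw, X0 = X0w, row_of = sf$row_of)
  out <- scan_core(sfw, panel, ss_total, model = "MLM", trait, dataset_name,
                   min_class_size, transform = W)
  attr(out, "sigma_u2") <- vc$sigma_u2
  attr(out, "sigma_e2") <- vc$sigma_e2
  attr(out, "lambda") <- vc$lambda
  out
}

#' Quantile-quantile data for a set of p-values
#'
#' @param pvalues numeric vector in (0, 1].
#' @return data frame with sorted `expected` (uniform quantiles
#'   `(i - 0.5) / m`), `observed`, and their `-log10` transforms.
#' @export
qq_data <- function(pvalues) {
  p <- sort(pvalues)
  m <- length(p)
  if (!m) stop("empty p-value vector")
  exp_q <- (seq_len(m) - 0.5) / m
  data.frame(expected = exp_q, observed = p,
             neg_log10_expected = -log10(exp_q),
             neg_log10_observed = -log10(p))
}

#' Tally how often each marker is significant across datasets
#'
#' @param records marker-trait association records (from [glm_scan()] /
#'   [mlm_scan()] over several datasets).
#' @param threshold significance threshold on p (strict `<`).
#' @return data frame `(marker_id, trait, n_significant, datasets)` sorted
#'   by decreasing count; `datasets` is a comma-separated name list.
#' @export
mta_frequency <- function(records, threshold) {
  sig <- records[records$p < threshold, , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(marker_id = character(), trait = character(),
                      n_significant = integer(), datasets = character(),
                      stringsAsFactors = FALSE))
  key <- paste(sig$marker_id, sig$trait, sep = "\r")
  spl <- split(sig, key)
  out <- do.call(rbind, lapply(spl, function(d) data.frame(
    marker_id = d$marker_id[1], trait = d$trait[1],
    n_significant = length(unique(d$dataset)),
    datasets = paste(sort(unique(d$dataset)), collapse = ", "),
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(-out$n_significant, out$marker_id), ]
}

#' One-way allele ANOVA within each subpopulation
#'
#' For a significant marker, tests within each subpopulation whether trait
#' means differ between allele classes (lines grouped by their diploid
#' genotype at the marker). Subpopulations lacking two classes with two
#' lines each are skipped with a note.
#'
#' @param panel a [genotype_panel()].
#' @param dataset named numeric vector of line-level trait values.
#' @param assignment data frame from [assign_subpopulations()].
#' @param marker marker id.
#' @param include_admixture whether to test the admixture group too.
#' @return data frame `(subpop, n_lines, n_classes, F, p, note)`.
#' @export
subpop_allele_anova <- function(panel, dataset, assignment, marker,
                                include_admixture = FALSE) {
  j <- match(marker, panel$markers$marker_id)
  if (is.na(j)) stop("unknown marker: ", marker)
  geno <- ifelse(is.na(panel$a1[, j]), NA_character_,
                 paste0(panel$a1[, j], "/", panel$a2[, j]))
  names(geno) <- panel$line_ids
  groups <- levels(assignment$subpop)
  if (!include_admixture) groups <- setdiff(groups, "admixture")
  rows <- lapply(groups, function(g) {
    lines <- assignment$line[assignment$subpop == g]
    lines <- lines[lines %in% names(dataset) & !is.na(geno[lines])]
    cls <- factor(geno[lines])
    keep <- names(table(cls))[table(cls) >= 2]
    lines <- lines[cls %in% keep]
    cls <- droplevels(factor(geno[lines]))
    if (nlevels(cls) < 2)
      return(data.frame(subpop = g, n_lines = length(lines),
                        n_classes = nlevels(cls), F = NA_real_, p = NA_real_,
                        note = "skipped: < 2 allele classes with >= 2 lines",
                        stringsAsFactors = FALSE))
    an <- stats::anova(stats::lm(dataset[lines] ~ cls))
    data.frame(subpop = g, n_lines = length(lines), n_classes = nlevels(cls),
               F = an$`F value`[1], p = an$`Pr(>F)`[1], note = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
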