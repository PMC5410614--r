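#' Nei (1972) standard genetic distance between lines
#'
#' Each line is treated as a two-copy allele-frequency profile per locus
#' (0, 1/2, 1). With `Jxy = sum_l sum_a x_a y_a`, `Jx`, `Jy` the analogous
#' self-products accumulated over the loci where both lines have calls,
#' `D = -ln( Jxy / sqrt(Jx Jy) )`. Lines sharing no alleles anywhere have
#' infinite distance, capped at `cap`.
#'
#' @param panel a [genotype_panel()].
#' @param cap finite stand-in for `-ln 0` (default 10).
#' @return symmetric distance matrix with zero diagonal.
#' @export
nei_distance <- function(panel, cap = 10) {
  idx <- panel_allele_index(panel)
  n <- length(panel$line_ids); L <- ncol(panel$a1)
  # per-line frequency rows over global allele levels (sparse by construction)
  lev1 <- sweep(idx$i1, 2, idx$offset, `+`)
  lev2 <- sweep(idx$i2, 2, idx$offset, `+`)
  n_levels <- sum(idx$n_alleles)
  X <- matrix(0, n, n_levels)
  for (i in seq_len(n)) {
    ok <- !is.na(lev1[i, ])
    X[i, ] <- tabulate(c(lev1[i, ok], lev2[i, ok]), nbins = n_levels) / 2
  }
  nonmiss <- !is.na(idx$i1)
  locus_of <- rep(seq_len(L), idx$n_alleles)
  D <- matrix(0, n, n, dimnames = list(panel$line_ids, panel$line_ids))
  all_zero <- TRUE
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- nonmiss[i, ] & nonmiss[j, ]
    if (!any(shared)) { D[i, j] <- D[j, i] <- cap; next }
    cols <- locus_of %in% which(shared)
    xi <- X[i, cols]; xj <- X[j, cols]
    jxy <- sum(xi * xj); jx <- sum(xi^2); jy <- sum(xj^2)
    d <- if (jxy <= 0) cap else min(-log(jxy / sqrt(jx * jy)), cap)
    D[i, j] <- D[j, i] <- max(d, 0)
    if (D[i, j] > 0) all_zero <- FALSE
  }
  if (all_zero) warning("all pairwise Nei distances are zero")
  D
}

#' Neighbor-joining tree with non-negative branch lengths
#'
#' Saitou-Nei agglomeration (via \pkg{ape}); any negative branch length is
#' clamped to zero and its magnitude moved to the adjacent sister edge so
#' path lengths through the pair are preserved.
#'
#' @param dist symmetric distance matrix (>= 3 taxa) or `dist` object.
#' @return an `ape::phylo` tree (unrooted, binary).
#' @export
nj_tree <- function(dist) {
  d <- as.matrix(dist)
  if (nrow(d) < 3) stop("neighbor-joining needs >= 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]          # negative
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1]
    sisters <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sisters)) {
      s <- sisters[1]
      # paths through the parent keep their length
      tr$edge.length[s] <- tr$edge.length[s] + deficit
    }
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Principal coordinate analysis (classical metric MDS)
#'
#' Gower double-centering of squared distances followed by
#' eigendecomposition. Axes are ordered by eigenvalue; negative eigenvalues
#' are dropped with a warning and explained proportions are computed over
#' the positive spectrum.
#'
#' @param dist symmetric distance matrix or `dist` object.
#' @param n_axes number of coordinate axes to return.
#' @return list with `coords` (taxa x axes), `eigenvalues` (positive ones),
#'   `explained` (proportions over positive eigenvalues).
#' @export
pcoa <- function(dist, n_axes = 2) {
  d <- as.matrix(dist)
  n <- nrow(d)
  B <- -0.5 * d^2
  B <- sweep(B, 1, rowMeans(B))
  B <- sweep(B, 2, colMeans(B))
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-12
  if (any(e$values < -max(abs(e$values)) * 1e-8))
    warning("negative eigenvalues dropped (non-Euclidean distances)")
  vals <- e$values[pos]
  k <- min(n_axes, length(vals))
  coords <- e$vectors[, which(pos)[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(vals[seq_len(k)]), k)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(k))
  list(coords = coords, eigenvalues = vals, explained = vals / sum(vals))
}

#' Allele-sharing kinship matrix
#'
#' `k(a, b)` is the mean over loci of the multiset intersection size of the
#' two lines' diploid calls divided by 2 (1 for identical calls, 0.5 for one
#' shared allele, 0 for none). Loci with a missing call in either line are
#' skipped for that pair. If the smallest eigenvalue is negative the matrix
#' is shifted by `+eps I`.
#'
#' @param panel a [genotype_panel()].
#' @param eps diagonal shift applied when the matrix is not PSD.
#' @return list with `line_ids`, `k` (matrix, entries in `[0, 1+eps]`),
#'   `shifted` (logical).
#' @export
kinship <- function(panel, eps = 1e-6) {
  a1 <- panel$a1; a2 <- panel$a2
  n <- nrow(a1)
  hom <- a1 == a2
  k <- matrix(1, n, n, dimnames = list(panel$line_ids, panel$line_ids))
  for (i in seq_len(n - 1)) {
    x1 <- a1[i, ]; x2 <- a2[i, ]; xh <- hom[i, ]
    for (j in (i + 1):n) {
      ok <- !is.na(x1) & !is.na(a1[j, ])
      if (!any(ok)) { k[i, j] <- k[j, i] <- 0; next }
      y1 <- a1[j, ok]; y2 <- a2[j, ok]
      cross <- (x1[ok] == y1) + (x1[ok] == y2) + (x2[ok] == y1) + (x2[ok] == y2)
      # multiset intersection: cross-match count, halved when either call
      # is homozygous (both-het pairs already count each shared allele once)
      inter <- cross / (1 + (xh[ok] | hom[j, ok]))
      k[i, j] <- k[j, i] <- sum(inter) / (2 * sum(ok))
    }
  }
  shifted <- FALSE
  ev <- eigen(k, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0) {
    k <- k + diag(eps, n)
    shifted <- TRUE
  }
  structure(list(line_ids = panel$line_ids, k = k, shifted = shifted),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat("kinship_matrix:", length(x$line_ids), "lines; mean off-diagonal",
      signif(mean(x$k[lower.tri(x$k)]), 3), "\n")
  invisible(x)
}
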