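#' Construct a Q matrix of admixture proportions
#' @param line_ids character vector.
#' @param q numeric lines x K matrix; rows must sum to 1.
#' @return a `q_matrix` object with fields `line_ids`, `K`, `q`.
#' @export
q_matrix <- function(line_ids, q) {
  q <- as.matrix(q)
  if (nrow(q) != length(line_ids)) stop("q rows != line_ids length")
  if (any(q < -1e-9 | q > 1 + 1e-9)) stop("q entries must lie in [0,1]")
  if (max(abs(rowSums(q) - 1)) > 1e-6) stop("q rows must sum to 1")
  q <- q / rowSums(q)
  rownames(q) <- line_ids
  colnames(q) <- paste0("q", seq_len(ncol(q)))
  structure(list(line_ids = as.character(line_ids), K = ncol(q), q = q),
            class = "q_matrix")
}

#' @export
print.q_matrix <- function(x, ...) {
  cat("q_matrix:", length(x$line_ids), "lines, K =", x$K, "\n")
  invisible(x)
}

#' Maximum-likelihood admixture inference by multi-start EM
#'
#' Fits the admixture model in which each allele copy of line `i` at locus
#' `l` is drawn from the mixture `sum_k q[i,k] * p[k,l,allele]` (the same
#' likelihood underlying model-based Bayesian structure inference with
#' correlated allele frequencies; here maximized directly by EM rather than
#' sampled by MCMC). Each restart starts from Dirichlet(1/K) ancestry rows
#' and pooled allele frequencies perturbed by noise; runs are returned
#' sorted by final log-likelihood, best first.
#'
#' @param panel a [genotype_panel()].
#' @param K number of ancestral subpopulations (>= 1).
#' @param restarts number of EM restarts.
#' @param max_iter,tol EM stopping rule (absolute log-likelihood change).
#' @param seed RNG seed for the initializations.
#' @return list of runs; each run has `K`, `restart`, `loglik`,
#'   `loglik_trace`, `n_iter`, `Q` (a [q_matrix()]), `p` (list of K x
#'   alleles frequency matrices per locus).
#' @export
fit_admixture <- function(panel, K, restarts = 5, max_iter = 2000,
                          tol = 1e-6, seed = 1L) {
  n <- length(panel$line_ids)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K exceeds number of lines")
  idx <- panel_allele_index(panel)
  if (sum(idx$n_alleles > 1) < 2) stop("need >= 2 polymorphic loci")
  L <- length(idx$n_alleles)
  # copy-level long representation (0-based for the C++ kernel)
  lev1 <- sweep(idx$i1, 2, idx$offset, `+`)   # global 1-based level
  lev2 <- sweep(idx$i2, 2, idx$offset, `+`)
  line_of <- matrix(seq_len(n), n, L)
  keep <- !is.na(idx$i1)
  line_idx <- c(line_of[keep], line_of[keep]) - 1L
  al_idx <- c(lev1[keep], lev2[keep]) - 1L
  n_levels <- sum(idx$n_alleles)
  al_locus <- rep(seq_len(L), idx$n_alleles) - 1L
  # pooled frequencies as initialization anchor
  pooled <- unlist(allele_frequencies(panel), use.names = FALSE)

  set.seed(seed)
  runs <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    q0 <- t(vapply(seq_len(n), function(i) rdirichlet1(rep(1 / K, K) + 0.05),
                   numeric(K)))
    if (K == 1) q0 <- matrix(1, n, 1)
    p0 <- matrix(0, K, n_levels)
    for (k in seq_len(K)) {
      pert <- pooled * exp(stats::rnorm(n_levels, 0, 0.5))
      for (l in seq_len(L)) {
        block <- which(al_locus == l - 1L)
        p0[k, block] <- pert[block] / sum(pert[block])
      }
    }
    fit <- em_admixture_cpp(line_idx, al_idx, al_locus, n, as.integer(K),
                            as.integer(n_levels), L, q0, p0,
                            as.integer(max_iter), tol)
    pl <- split(seq_len(n_levels), al_locus)
    p_by_locus <- lapply(pl, function(cols) {
      m <- fit$p[, cols, drop = FALSE]
      colnames(m) <- idx$alleles[[al_locus[cols[1]] + 1L]]
      m
    })
    names(p_by_locus) <- panel$markers$marker_id
    runs[[r]] <- list(K = K, restart = r, loglik = fit$loglik,
                      loglik_trace = fit$loglik_trace, n_iter = fit$n_iter,
                      Q = q_matrix(panel$line_ids, fit$q), p = p_by_locus)
  }
  runs[order(vapply(runs, `[[`, numeric(1), "loglik"), decreasing = TRUE)]
}

#' Evanno delta-K model selection over a range of K
#'
#' For replicate model scores L(K) (maximized log-likelihoods), computes
#' `delta K = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))` for
#' interior K; endpoints carry no value. The argmax over interior K is
#' reported as the supported number of subpopulations.
#'
#' @param runs_by_K named list: for each K (consecutive integers), a list of
#'   runs as returned by [fit_admixture()] (>= 2 replicates each). When
#'   replicates are produced as restarts, pass each restart's run.
#' @return data frame `(K, n_rep, mean_L, sd_L, delta_K)` with attribute
#'   `best_K`.
#' @export
evanno_delta_k <- function(runs_by_K) {
  Ks <- vapply(runs_by_K, function(rs) rs[[1]]$K, numeric(1))
  o <- order(Ks)
  Ks <- Ks[o]; runs_by_K <- runs_by_K[o]
  if (length(Ks) < 3 || any(diff(Ks) != 1))
    stop("need >= 3 consecutive K values")
  if (any(vapply(runs_by_K, length, integer(1)) < 2))
    stop("need >= 2 replicate runs per K")
  L_mean <- vapply(runs_by_K, function(rs)
    mean(vapply(rs, `[[`, numeric(1), "loglik")), numeric(1))
  L_sd <- vapply(runs_by_K, function(rs)
    stats::sd(vapply(rs, `[[`, numeric(1), "loglik")), numeric(1))
  nK <- length(Ks)
  dk <- rep(NA_real_, nK)
  for (i in 2:(nK - 1)) {
    second <- abs(L_mean[i + 1] - 2 * L_mean[i] + L_mean[i - 1])
    if (L_sd[i] == 0) {
      warning("sd of L(K) is zero at K = ", Ks[i], "; delta K set to +Inf")
      dk[i] <- Inf
    } else dk[i] <- second / L_sd[i]
  }
  out <- data.frame(K = Ks,
                    n_rep = vapply(runs_by_K, length, integer(1)),
                    mean_L = L_mean, sd_L = L_sd, delta_K = dk)
  interior <- which(!is.na(dk))
  attr(out, "best_K") <- Ks[interior[which.max(dk[interior])]]
  out
}

#' Assign lines to subpopulations from a Q matrix
#'
#' A line is assigned to the subpopulation where its ancestry proportion is
#' maximal, provided that proportion reaches `threshold` (boundary
#' inclusive); otherwise it is labeled `"admixture"`. Groups are renamed
#' `A`, `B`, `C`, ... by decreasing size; ties in a line's maximal q are
#' broken by the lowest subpopulation index.
#'
#' @param Q a [q_matrix()].
#' @param threshold assignment threshold in (0.5, 1].
#' @return data frame `(line, subpop, max_q)`; `subpop` is a factor whose
#'   levels end with `"admixture"`. Attribute `cluster_of_label` maps labels
#'   back to Q columns.
#' @export
assign_subpopulations <- function(Q, threshold = 0.6) {
  if (threshold <= 0.5 || threshold > 1)
    stop("threshold must lie in (0.5, 1]")
  maxq <- apply(Q$q, 1, max)
  which_k <- apply(Q$q, 1, which.max)   # ties -> lowest index
  assigned <- maxq >= threshold
  counts <- tabulate(which_k[assigned], nbins = Q$K)
  # rename clusters by decreasing membership; stable for equal counts
  rank_of <- order(order(-counts, seq_len(Q$K)))
  labels <- LETTERS[rank_of]
  subpop <- ifelse(assigned, labels[which_k], "admixture")
  lev <- c(sort(unique(labels[which_k[assigned]])), "admixture")
  out <- data.frame(line = Q$line_ids,
                    subpop = factor(subpop, levels = lev),
                    max_q = maxq, stringsAsFactors = FALSE)
  m <- match(LETTERS[seq_len(Q$K)], labels)
  names(m) <- LETTERS[seq_len(Q$K)]
  attr(out, "cluster_of_label") <- m[!is.na(m)]
  out
}

#' Align the columns of an inferred Q matrix with a reference
#'
#' Label switching makes mixture components arbitrary in order; this finds
#' the column permutation of `Q` maximizing the summed diagonal correlation
#' with `ref` (full enumeration, K <= 8) and returns the permuted Q.
#'
#' @param Q,ref `q_matrix` objects with equal dimensions.
#' @return list with `Q` (permuted), `perm`, and `mean_diag_cor`.
#' @export
align_q_labels <- function(Q, ref) {
  if (Q$K != ref$K) stop("K mismatch")
  K <- Q$K
  if (K > 8) stop("alignment by enumeration supports K <= 8")
  perms <- permutations_of(K)
  score <- function(pm) {
    sum(vapply(seq_len(K), function(k) {
      x <- Q$q[, pm[k]]; y <- ref$q[, k]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
      stats::cor(x, y)
    }, numeric(1)))
  }
  best <- perms[[which.max(vapply(perms, score, numeric(1)))]]
  qq <- Q$q[, best, drop = FALSE]
  cors <- vapply(seq_len(K), function(k) {
    x <- qq[, k]; y <- ref$q[, k]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  list(Q = q_matrix(Q$line_ids, qq), perm = best,
       mean_diag_cor = mean(cors, na.rm = TRUE))
}

permutations_of <- function(K) {
  if (K == 1) return(list(1L))
  sub <- permutations_of(K - 1)
  out <- list()
  for (pm in sub) for (pos in seq_len(K)) {
    out[[length(out) + 1]] <- append(pm, K, after = pos - 1)
  }
  out
}
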