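#' Configuration for the synthetic panel generator
#'
#' Defaults emulate a biofortification association panel: 130 near-inbred
#' lines, 267 polymorphic SSR loci with 2-5 alleles each, three latent
#' subpopulations with correlated-drift differentiation plus Dirichlet
#' admixture, and grain Fe/Zn phenotypes from three locations x two years x
#' three replicates with broad-sense heritability around 0.8.
#'
#' @param n_lines,n_markers panel dimensions.
#' @param K_true number of latent subpopulations.
#' @param drift_F Balding-Nichols drift parameter per subpopulation.
#' @param admixture_alpha symmetric Dirichlet parameter for per-line ancestry.
#' @param alleles_per_locus_range integer pair, inclusive.
#' @param ancestral_alpha symmetric Dirichlet concentration of ancestral
#'   allele frequencies; 0.3 calibrates pooled Nei gene diversity to the
#'   moderate-diversity regime (mean around 0.35) typical of agarose-scored
#'   SSR panels.
#' @param selfing_rate probability that the second allele copy duplicates the
#'   first (near-inbred panels: 0.9).
#' @param planted_qtls data frame with columns `marker` (locus index),
#'   `allele` (per-locus allele index of the favorable allele), `effect`
#'   (ppm added per favorable-homozygote), `trait` (`"Fe"`/`"Zn"`), or `NULL`
#'   for the default four QTLs (two per trait, marker R-squared roughly
#'   0.10-0.18 at the default variance components).
#' @param planted_freq_range ancestral frequency band from which the
#'   favorable allele's frequency at a planted locus is drawn.
#' @param trait_base_mean named ppm means, default `c(Fe = 59, Zn = 43)`.
#' @param sigma_G2,sigma_GE2,sigma_e2 named (per-trait) or scalar variance
#'   components in ppm^2.
#' @param sigma_env2 variance of location-year mean shifts (ppm^2).
#' @param n_locations,n_years,n_reps trial dimensions (locations are taken
#'   from Delhi, Jodhpur, Dharwad; years from 2014, 2015).
#' @param missing_rate per-call missing probability for genotypes.
#' @param complementary_parents optional integer pair of line indices; the
#'   first is forced homozygous-favorable at every planted Fe QTL (and
#'   non-favorable at Zn QTLs), the second the reverse, giving a pair whose
#'   cross pyramids all planted favorable alleles.
#' @param seed RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_lines = 130, n_markers = 267, K_true = 3,
                       drift_F = 0.15, admixture_alpha = 0.2,
                       alleles_per_locus_range = c(2L, 5L),
                       ancestral_alpha = 0.3,
                       selfing_rate = 0.9,
                       planted_qtls = NULL,
                       planted_freq_range = c(0.3, 0.5),
                       trait_base_mean = c(Fe = 59, Zn = 43),
                       sigma_G2 = c(Fe = 100, Zn = 40),
                       sigma_GE2 = c(Fe = 40, Zn = 15),
                       sigma_e2 = c(Fe = 60, Zn = 25),
                       sigma_env2 = 9,
                       n_locations = 3, n_years = 2, n_reps = 3,
                       missing_rate = 0,
                       complementary_parents = NULL,
                       seed = 1L) {
  if (is.null(planted_qtls)) {
    planted_qtls <- if (n_markers >= 40) data.frame(
      marker = c(10L, 25L, 10L, 40L),
      allele = c(1L, 1L, 1L, 1L),
      effect = c(10, 9, 6.5, 6),
      trait  = c("Fe", "Fe", "Zn", "Zn"),
      stringsAsFactors = FALSE)
    else data.frame(marker = integer(), allele = integer(),
                    effect = numeric(), trait = character(),
                    stringsAsFactors = FALSE)
  }
  expand_vc <- function(x) {
    if (length(x) == 1 && is.null(names(x))) x <- c(Fe = unname(x), Zn = unname(x))
    x[.traits]
  }
  cfg <- list(n_lines = as.integer(n_lines), n_markers = as.integer(n_markers),
              K_true = as.integer(K_true), drift_F = drift_F,
              admixture_alpha = admixture_alpha,
              alleles_per_locus_range = as.integer(alleles_per_locus_range),
              ancestral_alpha = ancestral_alpha,
              selfing_rate = selfing_rate,
              planted_qtls = planted_qtls,
              planted_freq_range = planted_freq_range,
              trait_base_mean = trait_base_mean[.traits],
              sigma_G2 = expand_vc(sigma_G2), sigma_GE2 = expand_vc(sigma_GE2),
              sigma_e2 = expand_vc(sigma_e2), sigma_env2 = sigma_env2,
              n_locations = as.integer(n_locations),
              n_years = as.integer(n_years), n_reps = as.integer(n_reps),
              missing_rate = missing_rate,
              complementary_parents = complementary_parents,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_lines >= 2, cfg$n_markers >= 2, cfg$K_true >= 1,
            cfg$drift_F > 0, cfg$drift_F < 1, cfg$admixture_alpha > 0,
            cfg$selfing_rate >= 0, cfg$selfing_rate <= 1,
            all(cfg$sigma_G2 >= 0), all(cfg$sigma_GE2 >= 0),
            all(cfg$sigma_e2 >= 0), cfg$missing_rate >= 0,
            cfg$missing_rate < 1)
  pq <- cfg$planted_qtls
  if (nrow(pq)) {
    if (any(pq$marker < 1 | pq$marker > cfg$n_markers))
      stop("planted QTL marker index out of range 1..", cfg$n_markers)
    if (anyDuplicated(pq[, c("marker", "trait")]))
      stop("planted QTL markers must be distinct within a trait")
    if (any(!pq$trait %in% .traits)) stop("planted QTL trait must be Fe or Zn")
  }
  if (!is.null(cfg$complementary_parents) &&
      (length(cfg$complementary_parents) != 2 ||
       any(cfg$complementary_parents < 1 |
           cfg$complementary_parents > cfg$n_lines)))
    stop("complementary_parents must be two valid line indices")
  invisible(cfg)
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Simulate a structured SSR panel with multi-environment phenotypes
#'
#' Genotypes follow a correlated-drift admixture model: per-locus ancestral
#' frequencies are symmetric-Dirichlet draws; each subpopulation's
#' frequencies are Dirichlet with mean at the ancestral vector and
#' concentration `(1 - F)/F` (Balding-Nichols); each line's ancestry vector
#' is Dirichlet(`admixture_alpha`); allele copies are drawn from the line's
#' mixture, with `selfing_rate` forcing homozygosity. Phenotypes add planted
#' QTL effects (favorable-allele dosage / 2 x effect), a polygenic value with
#' covariance `sigma_G2 * kinship`, location-year shifts, G x E deviates and
#' replicate residuals.
#'
#' @param config a [sim_config()].
#' @return list with `panel` ([genotype_panel()]), `pheno`
#'   (`phenotype_table`), and `truth` (true Q, subpopulation frequencies,
#'   planted QTLs with realized favorable-allele frequencies, polygenic
#'   values, variance components used).
#' @export
simulate_panel <- function(config = sim_config()) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  n <- cfg$n_lines; L <- cfg$n_markers; K <- cfg$K_true
  rng <- cfg$alleles_per_locus_range
  n_alleles <- sample(seq(rng[1], rng[2]), L, replace = TRUE)
  planted <- cfg$planted_qtls
  planted_loci <- unique(planted$marker)
  # at planted loci make sure the favorable allele index exists
  if (nrow(planted))
    n_alleles[planted$marker] <- pmax(n_alleles[planted$marker], planted$allele + 1L)

  anc <- vector("list", L)    # ancestral frequencies
  pop <- vector("list", L)    # K x n_alleles subpop frequencies
  for (j in seq_len(L)) {
    pj <- rdirichlet1(rep(cfg$ancestral_alpha, n_alleles[j]))
    if (j %in% planted_loci) {
      # pin the favorable allele's ancestral frequency into the stated band
      fav <- planted$allele[match(j, planted$marker)]
      f <- stats::runif(1, cfg$planted_freq_range[1], cfg$planted_freq_range[2])
      pj[-fav] <- pj[-fav] / sum(pj[-fav]) * (1 - f)
      pj[fav] <- f
    }
    anc[[j]] <- pj
    conc <- (1 - cfg$drift_F) / cfg$drift_F
    pop[[j]] <- t(vapply(seq_len(K),
                         function(k) rdirichlet1(pj * conc),
                         numeric(n_alleles[j])))
  }

  q <- t(vapply(seq_len(n), function(i)
    rdirichlet1(rep(cfg$admixture_alpha, K)), numeric(K)))

  draw_copy <- function(i, j) {
    k <- sample.int(K, 1, prob = q[i, ])
    sample.int(n_alleles[j], 1, prob = pop[[j]][k, ])
  }
  i1 <- matrix(0L, n, L); i2 <- matrix(0L, n, L)
  for (j in seq_len(L)) for (i in seq_len(n)) {
    c1 <- draw_copy(i, j)
    c2 <- if (stats::runif(1) < cfg$selfing_rate) c1 else draw_copy(i, j)
    i1[i, j] <- c1; i2[i, j] <- c2
  }

  if (!is.null(cfg$complementary_parents) && nrow(planted)) {
    par_fe <- cfg$complementary_parents[1]
    par_zn <- cfg$complementary_parents[2]
    for (r in seq_len(nrow(planted))) {
      j <- planted$marker[r]; fav <- planted$allele[r]
      carrier <- if (planted$trait[r] == "Fe") par_fe else par_zn
      other <- setdiff(cfg$complementary_parents, carrier)
      i1[carrier, j] <- i2[carrier, j] <- fav
      alt <- if (n_alleles[j] > fav) fav + 1L else fav - 1L
      i1[other, j] <- i2[other, j] <- alt
    }
  }

  # allele index -> amplicon size (bp): locus-specific ladder, 2 bp steps
  sizes <- lapply(seq_len(L), function(j)
    sort(sample(seq(120L, 320L, by = 2L), n_alleles[j])))
  a1 <- matrix(NA_integer_, n, L); a2 <- matrix(NA_integer_, n, L)
  for (j in seq_len(L)) {
    a1[, j] <- sizes[[j]][i1[, j]]
    a2[, j] <- sizes[[j]][i2[, j]]
  }
  if (cfg$missing_rate > 0) {
    drop <- matrix(stats::runif(n * L) < cfg$missing_rate, n, L)
    # never blank a whole locus
    for (j in seq_len(L)) if (all(drop[, j])) drop[1, j] <- FALSE
    a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
  }
  line_ids <- sprintf("L%03d", seq_len(n))
  marker_ids <- sprintf("M%03d", seq_len(L))
  lg <- sprintf("LG%d", 1 + (seq_len(L) - 1) %% 7)
  markers <- data.frame(marker_id = marker_ids, linkage_group = lg,
                        position_cM = round(stats::runif(L, 0, 150), 1),
                        marker_class = sample(c("genomic_ssr", "est_ssr", "genic"),
                                              L, TRUE, prob = c(.7, .25, .05)),
                        stringsAsFactors = FALSE)
  panel <- genotype_panel(line_ids, a1, a2, markers = markers,
                          missing_cap = max(0.2, cfg$missing_rate * 3 + 0.05))

  # ---- phenotypes ----
  km <- kinship(panel)
  # Polygenic kernel: double-centered kinship rescaled to unit mean diagonal,
  # so sigma_G2 is the realized between-line genetic variance (raw
  # allele-sharing kinship carries a large baseline of chance sharing that
  # would otherwise shrink the effective variance well below sigma_G2).
  kc <- km$k
  kc <- sweep(kc, 1, rowMeans(kc))
  kc <- sweep(kc, 2, colMeans(kc))
  kc <- kc / mean(diag(kc))
  ek <- eigen(kc, symmetric = TRUE)
  rootK <- ek$vectors %*% (sqrt(pmax(ek$values, 0)) * t(ek$vectors))
  locs <- .locations[seq_len(cfg$n_locations)]
  years <- (2014:2020)[seq_len(cfg$n_years)]
  envs <- expand.grid(location = locs, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  nE <- nrow(envs)

  recs <- list()
  polygenic <- matrix(0, n, 2, dimnames = list(line_ids, .traits))
  env_effects <- matrix(0, nE, 2, dimnames = list(NULL, .traits))
  for (t in .traits) {
    g <- as.numeric(rootK %*% stats::rnorm(n)) * sqrt(cfg$sigma_G2[[t]])
    polygenic[, t] <- g
    qtl <- rep(0, n)
    pt <- planted[planted$trait == t, , drop = FALSE]
    if (nrow(pt)) for (r in seq_len(nrow(pt))) {
      dose <- (i1[, pt$marker[r]] == pt$allele[r]) +
              (i2[, pt$marker[r]] == pt$allele[r])
      qtl <- qtl + dose / 2 * pt$effect[r]
    }
    envf <- stats::rnorm(nE, 0, sqrt(cfg$sigma_env2))
    env_effects[, t] <- envf
    ge <- matrix(stats::rnorm(n * nE, 0, sqrt(cfg$sigma_GE2[[t]])), n, nE)
    for (e in seq_len(nE)) for (r in seq_len(cfg$n_reps)) {
      val <- cfg$trait_base_mean[[t]] + qtl + g + envf[e] + ge[, e] +
        stats::rnorm(n, 0, sqrt(cfg$sigma_e2[[t]]))
      recs[[length(recs) + 1]] <- data.frame(
        line = line_ids, location = envs$location[e], year = envs$year[e],
        replicate = r, trait = t, value = pmax(val, 1e-3),
        stringsAsFactors = FALSE)
    }
  }
  pheno <- phenotype_table(do.call(rbind, recs))

  planted_out <- planted
  if (nrow(planted_out)) {
    planted_out$marker_id <- marker_ids[planted_out$marker]
    planted_out$allele_size <- vapply(seq_len(nrow(planted_out)), function(r)
      sizes[[planted_out$marker[r]]][planted_out$allele[r]], integer(1))
    planted_out$realized_freq <- vapply(seq_len(nrow(planted_out)), function(r) {
      j <- planted_out$marker[r]
      mean(c(i1[, j], i2[, j]) == planted_out$allele[r])
    }, numeric(1))
  }
  truth <- list(q = q_matrix(line_ids, q),
                subpop_freqs = pop, ancestral_freqs = anc,
                allele_sizes = sizes,
                subpop_label = apply(q, 1, which.max),
                planted_qtls = planted_out,
                polygenic = polygenic,
                env_effects = env_effects,
                variance_components = list(sigma_G2 = cfg$sigma_G2,
                                           sigma_GE2 = cfg$sigma_GE2,
                                           sigma_e2 = cfg$sigma_e2),
                config = cfg)
  list(panel = panel, pheno = pheno, truth = truth)
}
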