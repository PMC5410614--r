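test_that("the 1/n threshold reproduces the printed values", {
  thr <- bonferroni_threshold(267)
  expect_equal(thr$p_threshold, 1 / 267)
  expect_equal(thr$neg_log10, 2.43)
  expect_equal(bonferroni_threshold(1)$p_threshold, 1)
  expect_equal(bonferroni_threshold(267, alpha = 0.05)$p_threshold, 0.05 / 267)
  expect_error(bonferroni_threshold(0), ">= 1")
})

test_that("LD is 1 for perfectly associated loci and 0 for monomorphic", {
  calls <- cbind(rep(c("100", "104"), each = 6),
                 rep(c("200", "208"), each = 6),   # mirrors locus 1
                 rep("300", 12))                   # monomorphic
  panel <- panel_from_calls(calls)
  ld <- ld_matrix(panel, n_perm = 199, seed = 3)
  expect_equal(nrow(ld), 3)                        # C(3,2)
  r12 <- ld[ld$marker1 == "M01" & ld$marker2 == "M02", ]
  expect_equal(r12$r2, 1)
  expect_lt(r12$p, 0.05)
  expect_true(all(ld$monomorphic[ld$marker2 == "M03"]))
  expect_equal(ld$r2[ld$marker2 == "M03"], c(0, 0))
})

test_that("independent loci show near-zero LD and uniform permutation p", {
  panel <- random_panel(80, 25, n_alleles = 3, seed = 12)
  ld <- ld_matrix(panel, n_perm = 99, seed = 5)
  expect_equal(nrow(ld), choose(25, 2))
  expect_lt(mean(ld$r2), 0.05)
  expect_gt(stats::ks.test(ld$p, "punif")$p.value, 0.001)
})

test_that("GLM detects perfect separation and respects structure covariates", {
  calls <- matrix(rep(c("100", "104"), each = 10), 20, 1)
  panel <- panel_from_calls(calls)
  y <- c(rep(40, 10), rep(70, 10)) + seq(-0.5, 0.5, length.out = 20)
  names(y) <- panel$line_ids
  recs <- glm_scan(y, panel, Q = NULL)
  expect_lt(recs$p, 1e-6)
  expect_gt(recs$marker_R2, 0.99)
  # trait fully explained by Q, marker orthogonal to it -> non-significant
  set.seed(8)
  calls2 <- matrix(sample(rep(c("100", "104"), each = 10)), 20, 1)
  panel2 <- panel_from_calls(calls2)
  qcol <- stats::runif(20, 0.05, 0.95)
  Q <- q_matrix(panel2$line_ids, cbind(qcol, 1 - qcol))
  y2 <- 30 + 20 * qcol
  names(y2) <- panel2$line_ids
  recs2 <- glm_scan(y2, panel2, Q)
  expect_gt(recs2$p, 0.05)
})

test_that("structure covariates absorb confounded marker variance", {
  # structured panel whose trait is driven by ancestry alone: adding Q must
  # shrink the apparent marker R2 at structure-differentiated loci
  sim <- simulate_panel(sim_config(n_lines = 60, n_markers = 20,
                                   drift_F = 0.35, admixture_alpha = 0.05,
                                   sigma_G2 = 0, sigma_GE2 = 0, seed = 17))
  q1 <- sim$truth$q$q[, 1]
  y <- 50 + 15 * q1 + stats::rnorm(60, 0, 1)
  names(y) <- sim$panel$line_ids
  bare <- glm_scan(y, sim$panel, Q = NULL)
  withQ <- glm_scan(y, sim$panel, sim$truth$q)
  shared <- intersect(bare$marker_id, withQ$marker_id)
  b <- bare$marker_R2[match(shared, bare$marker_id)]
  w <- withQ$marker_R2[match(shared, withQ$marker_id)]
  expect_true(all(w >= 0 & w <= 1))
  expect_lt(mean(w), mean(b))
  # the most confounded markers deflate strongly
  expect_lt(max(w), max(b))
})

test_that("MLM equals GLM exactly when the polygenic variance is zero", {
  sim <- simulate_panel(sim_config(n_lines = 40, n_markers = 25, seed = 23))
  gm <- build_datasets(sim$pheno, "Fe")$GM
  Q <- sim$truth$q
  km <- kinship(sim$panel)
  g <- glm_scan(gm, sim$panel, Q)
  m0 <- mlm_scan(gm, sim$panel, Q, km, force_lambda = 0)
  expect_equal(m0$p, g$p, tolerance = 1e-8)
  expect_equal(m0$marker_R2, g$marker_R2, tolerance = 1e-8)
})

test_that("null GLM scans hold their type-I error at 5%", {
  set.seed(41)
  n_sig <- 0; n_tot <- 0
  for (s in 1:6) {
    panel <- random_panel(60, 40, n_alleles = 3, seed = 500 + s)
    y <- stats::rnorm(60, 50, 5)
    names(y) <- panel$line_ids
    recs <- glm_scan(y, panel, Q = NULL)
    n_sig <- n_sig + sum(recs$p < 0.05)
    n_tot <- n_tot + nrow(recs)
  }
  band <- stats::qbinom(c(0.0005, 0.9995), n_tot, 0.05)
  expect_gte(n_sig, band[1])
  expect_lte(n_sig, band[2])
})

test_that("QQ data pairs sorted observations with uniform quantiles", {
  expect_equal(qq_data(0.5)$expected, 0.5)
  p <- c(0.9, 0.1, 0.5, 0.2)
  expect_equal(qq_data(p), qq_data(rev(p)))
  expect_equal(qq_data(p)$observed, sort(p))
  set.seed(10)
  u <- stats::runif(500)
  qd <- qq_data(u)
  ks_band <- 1.63 / sqrt(500)   # alpha = 0.01 Kolmogorov band
  expect_lt(max(abs(qd$observed - qd$expected)), ks_band)
  expect_error(qq_data(numeric(0)), "empty")
})

test_that("MTA frequency tallies datasets per marker and trait", {
  recs <- data.frame(
    marker_id = c(rep("Xa", 8), "Xb", "Xb", "Xa"),
    trait = c(rep("Fe", 8), "Fe", "Zn", "Zn"),
    dataset = c(paste0("D", 1:8), "D1", "D2", "D3"),
    p = c(rep(0.001, 8), 0.5, 0.002, 0.003),
    stringsAsFactors = FALSE)
  fr <- mta_frequency(recs, threshold = 1 / 267)
  expect_equal(fr$n_significant[fr$marker_id == "Xa" & fr$trait == "Fe"], 8)
  expect_equal(fr$n_significant[fr$marker_id == "Xa" & fr$trait == "Zn"], 1)
  expect_false(any(fr$marker_id == "Xb" & fr$trait == "Fe"))
  # invariant to record order
  fr2 <- mta_frequency(recs[sample(nrow(recs)), ], threshold = 1 / 267)
  expect_equal(fr, fr2)
  expect_equal(nrow(mta_frequency(recs, threshold = 1e-9)), 0)
})

test_that("two-class subpopulation ANOVA equals the squared-t test", {
  calls <- matrix(rep(c("100", "104"), times = c(7, 7)), 14, 1)
  panel <- panel_from_calls(calls)
  set.seed(33)
  y <- c(stats::rnorm(7, 50, 3), stats::rnorm(7, 55, 3))
  names(y) <- panel$line_ids
  assignment <- data.frame(line = panel$line_ids,
                           subpop = factor(rep("A", 14), levels = c("A", "admixture")))
  res <- subpop_allele_anova(panel, y, assignment, "M01")
  tt <- stats::t.test(y[1:7], y[8:14], var.equal = TRUE)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  expect_equal(res$F, unname(tt$statistic^2), tolerance = 1e-10)
  # exactly equal class means: F = 0, p = 1
  y2 <- c(47:53, 47:53)
  names(y2) <- panel$line_ids
  res2 <- subpop_allele_anova(panel, y2, assignment, "M01")
  expect_equal(res2$F, 0, tolerance = 1e-12)
  expect_equal(res2$p, 1, tolerance = 1e-12)
  # monomorphic subpop is skipped with a note
  mono <- panel_from_calls(matrix("100", 14, 1))
  res3 <- subpop_allele_anova(mono, y, assignment, "M01")
  expect_true(grepl("skipped", res3$note))
})

test_that("well-separated allele classes reach significance within subpops", {
  calls <- matrix(rep(c("100", "104"), times = c(6, 6)), 12, 1)
  panel <- panel_from_calls(calls)
  set.seed(3)
  y <- c(stats::rnorm(6, 50, 1), stats::rnorm(6, 55, 1))  # 5 SD apart
  names(y) <- panel$line_ids
  assignment <- data.frame(line = panel$line_ids,
                           subpop = factor(rep("A", 12), levels = c("A", "admixture")))
  expect_lt(subpop_allele_anova(panel, y, assignment, "M01")$p, 0.01)
})

test_that("the kinship term deflates structure-driven genomic inflation", {
  # phenotype = polygenic only, strong structure: the Q-only GLM inflates,
  # the Q+K MLM should sit nearer the null (median chi-square ratio ~1).
  # 10 seeds keep the check inside the unit-test budget.
  null_q <- data.frame(marker = integer(), allele = integer(),
                       effect = numeric(), trait = character())
  lambda_gc <- function(p) stats::median(stats::qchisq(1 - p, df = 1)) /
    stats::qchisq(0.5, 1)
  wins <- 0
  for (s in seq_len(10)) {
    sim <- simulate_panel(sim_config(seed = 8000 + s, drift_F = 0.3,
                                     admixture_alpha = 0.05, sigma_G2 = 150,
                                     sigma_GE2 = 10, sigma_e2 = 30,
                                     planted_qtls = null_q))
    gm <- build_datasets(sim$pheno, "Fe")$GM
    km <- kinship(sim$panel)
    Q <- fit_admixture(sim$panel, K = 3, restarts = 2, max_iter = 300,
                       tol = 1e-4, seed = s)[[1]]$Q
    g <- glm_scan(gm, sim$panel, Q)
    m <- mlm_scan(gm, sim$panel, Q, km)
    if (abs(lambda_gc(m$p) - 1) < abs(lambda_gc(g$p) - 1)) wins <- wins + 1
  }
  expect_gte(wins, 9)
})
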