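make_full_pheno <- function(n = 12, seed = 1, sd_line = 5) {
  set.seed(seed)
  lines <- sprintf("G%02d", seq_len(n))
  g <- stats::rnorm(n, 50, sd_line)
  names(g) <- lines
  grid <- expand.grid(line = lines, location = c("Delhi", "Jodhpur", "Dharwad"),
                      year = c(2014, 2015), replicate = 1:3, trait = "Fe",
                      stringsAsFactors = FALSE)
  grid$value <- g[grid$line] + stats::rnorm(nrow(grid), 0, 2)
  phenotype_table(grid)
}

test_that("the twelve datasets are assembled with exact pooling", {
  ph <- make_full_pheno()
  ds <- build_datasets(ph, "Fe")
  expect_equal(length(ds), 12)
  expect_setequal(names(ds),
                  c("Del-14", "Del-15", "Jod-14", "Jod-15", "DW-14", "DW-15",
                    "Del-M", "Jod-M", "DW-M", "Y14-M", "Y15-M", "GM"))
  # GM is the mean of the six environment values per line
  envs <- c("Del-14", "Del-15", "Jod-14", "Jod-15", "DW-14", "DW-15")
  for (line in names(ds$GM)) {
    expect_equal(ds$GM[[line]],
                 mean(vapply(envs, function(e) ds[[e]][[line]], numeric(1))),
                 tolerance = 1e-12)
  }
  expect_equal(ds$`Del-M`,
               c((ds$`Del-14` + ds$`Del-15`)[names(ds$`Del-M`)] / 2),
               tolerance = 1e-12)
  expect_equal(ds$`Y14-M`,
               c(((ds$`Del-14` + ds$`Jod-14` + ds$`DW-14`) / 3)[names(ds$`Y14-M`)]),
               tolerance = 1e-12)
  # constant phenotype gives constant datasets
  const <- make_full_pheno(); const$value <- 42
  dc <- build_datasets(phenotype_table(as.data.frame(const)), "Fe")
  expect_true(all(vapply(dc, function(v) all(v == 42), logical(1))))
})

test_that("noiseless additive data recover components exactly", {
  lines <- sprintf("G%02d", 1:10)
  set.seed(2)
  g <- stats::rnorm(10, 50, 6); names(g) <- lines
  envs <- expand.grid(location = c("Delhi", "Jodhpur"), year = c(2014, 2015),
                      stringsAsFactors = FALSE)
  h <- stats::rnorm(4, 0, 3)
  grid <- list()
  for (e in 1:4) for (r in 1:3) {
    grid[[length(grid) + 1]] <- data.frame(
      line = lines, location = envs$location[e], year = envs$year[e],
      replicate = r, trait = "Fe", value = g[lines] + h[e],
      stringsAsFactors = FALSE)
  }
  ph <- phenotype_table(do.call(rbind, grid))
  vc <- combined_anova(ph, "Fe")
  expect_equal(vc$sigma_e2, 0, tolerance = 1e-8)
  expect_equal(vc$sigma_GE2, 0, tolerance = 1e-8)
  # sigma_G2 recovers the realized line variance (df = n - 1)
  expect_equal(vc$sigma_G2, stats::var(g), tolerance = 1e-8)
  expect_error(combined_anova(ph[ph$replicate == 1, ], "Fe"), "replicates")
})

test_that("heritability formulas reproduce direct substitution", {
  vc <- list(sigma_G2 = 1, sigma_GE2 = 0, sigma_e2 = 1, r = 3, n_env = 1)
  expect_equal(heritability(vc, "single"), 0.75)
  vc2 <- list(sigma_G2 = 1, sigma_GE2 = 0.5, sigma_e2 = 1, r = 3, n_env = 3)
  expect_equal(heritability(vc2, "multi"), 1 / (1 + 0.5 / 3 + 1 / 9),
               tolerance = 1e-12)
  expect_equal(round(heritability(vc2, "multi"), 4), 0.7826)
  vc0 <- list(sigma_G2 = 0, sigma_GE2 = 0, sigma_e2 = 2, r = 3, n_env = 2)
  expect_equal(heritability(vc0, "multi"), 0)
  expect_error(heritability(list(sigma_G2 = 0, sigma_GE2 = 0, sigma_e2 = 0,
                                 r = 3, n_env = 2)), "undefined")
  # monotone: increasing in sigma_G2, decreasing in sigma_e2
  h <- vapply(c(1, 2, 4), function(sg)
    heritability(list(sigma_G2 = sg, sigma_GE2 = 0.5, sigma_e2 = 1,
                      r = 3, n_env = 2)), numeric(1))
  expect_true(all(diff(h) > 0))
})

test_that("pure-noise phenotypes clamp genetic variance at zero", {
  hit <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    lines <- sprintf("G%02d", 1:15)
    grid <- expand.grid(line = lines, location = c("Delhi", "Jodhpur"),
                        year = 2014, replicate = 1:3, trait = "Fe",
                        stringsAsFactors = FALSE)
    grid$value <- 50 + stats::rnorm(nrow(grid), 0, 4)
    vc <- combined_anova(phenotype_table(grid), "Fe")
    if (vc$sigma_G2 == 0) hit <- hit + 1
  }
  expect_gte(hit, 5)
})

test_that("structure-trait regression flags structured traits only", {
  set.seed(9)
  q <- t(replicate(40, { x <- stats::rgamma(3, 0.3); x / sum(x) }))
  Q <- q_matrix(sprintf("L%02d", 1:40), q)
  trait <- q[, 1] * 10 + 30
  names(trait) <- Q$line_ids
  res <- structure_trait_correlation(Q, trait)
  expect_gt(res$R2, 0.99)
  expect_lt(res$p, 1e-10)
  # K = 1: nothing to explain
  Q1 <- q_matrix(Q$line_ids, matrix(1, 40, 1))
  expect_equal(structure_trait_correlation(Q1, trait)$R2, 0)
  # permutation null: p-values near-uniform
  pvals <- replicate(100, {
    y <- sample(trait)
    names(y) <- Q$line_ids
    structure_trait_correlation(Q, y)$p
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})
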