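test_that("Nei distance behaves at identity, disjointness and symmetry", {
  p <- panel_from_calls(rbind(c("100", "200"),
                              c("100", "200"),
                              c("102", "204")))
  D <- nei_distance(p)
  expect_equal(unname(D[1, 2]), 0)           # identical lines
  expect_equal(unname(D[1, 3]), 10)          # no shared alleles: capped -ln 0
  expect_equal(D, t(D))
  expect_equal(diag(D), c(L01 = 0, L02 = 0, L03 = 0))
  expect_equal(unname(nei_distance(p, cap = 5)[1, 3]), 5)
  # all-identical monomorphic panel warns
  mono <- panel_from_calls(matrix("100", 3, 2))
  expect_warning(nei_distance(mono), "zero")
})

test_that("NJ recovers an additive four-taxon tree exactly", {
  # tree: ((A:1,B:2):1.5,(C:3,D:4)) with internal edge 1.5
  D <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  D["A", "B"] <- D["B", "A"] <- 3
  D["A", "C"] <- D["C", "A"] <- 5.5
  D["A", "D"] <- D["D", "A"] <- 6.5
  D["B", "C"] <- D["C", "B"] <- 6.5
  D["B", "D"] <- D["D", "B"] <- 7.5
  D["C", "D"] <- D["D", "C"] <- 7
  tr <- nj_tree(D)
  expect_equal(unname(as.matrix(ape::cophenetic.phylo(tr))[rownames(D),
                                                           colnames(D)]),
               unname(D), tolerance = 1e-10)
  nwk <- tempfile(fileext = ".nwk")
  ape::write.tree(tr, nwk)
  back <- ape::read.tree(nwk)
  expect_setequal(back$tip.label, c("A", "B", "C", "D"))
  expect_error(nj_tree(D[1:2, 1:2]), ">= 3")
})

test_that("clamped NJ trees never carry negative branch lengths", {
  set.seed(14)
  for (rep in 1:5) {
    n <- 8
    M <- matrix(stats::runif(n * n), n)
    D <- as.matrix(stats::dist(M))   # metric but not additive
    tr <- nj_tree(D)
    expect_true(all(tr$edge.length >= 0))
    # the shift rule never shortens the tree below the raw NJ total
    raw <- ape::nj(stats::as.dist(D))
    expect_gte(sum(tr$edge.length), sum(raw$edge.length) - 1e-9)
  }
})

test_that("PCoA reproduces Euclidean configurations", {
  set.seed(6)
  X <- cbind(stats::rnorm(12), stats::rnorm(12))
  D <- as.matrix(stats::dist(X))
  pc <- pcoa(D, n_axes = 2)
  expect_equal(as.matrix(stats::dist(pc$coords)), D, ignore_attr = TRUE,
               tolerance = 1e-8)
  # collinear points: one positive eigenvalue carries ~everything
  line_pts <- matrix(seq(0, 10, length.out = 8), ncol = 1)
  pcl <- pcoa(as.matrix(stats::dist(line_pts)), n_axes = 2)
  expect_gt(pcl$explained[1], 0.999)
})

test_that("allele-sharing kinship matches call-level expectations", {
  p <- panel_from_calls(rbind(c("100", "200", "300/304"),
                              c("100", "202", "300/304"),
                              c("102", "204", "302")))
  km <- kinship(p)
  expect_equal(unname(diag(km$k)), rep(1, 3))      # incl. heterozygous self
  # L1 vs L2: share locus1 fully (1), locus2 none (0), locus3 fully (1)
  expect_equal(unname(km$k[1, 2]), 2 / 3)
  expect_equal(unname(km$k[1, 3]), 0)              # nothing shared
  half <- panel_from_calls(rbind("100/104", "100/102"))
  expect_equal(unname(kinship(half)$k[1, 2]), 0.5) # one shared allele
  expect_true(all(km$k >= 0 & km$k <= 1 + 1e-9))
})

test_that("kinship separates simulated subpopulations", {
  sim <- simulate_panel(sim_config(n_lines = 60, n_markers = 80,
                                   drift_F = 0.25, admixture_alpha = 0.05,
                                   seed = 13))
  km <- kinship(sim$panel)
  lab <- sim$truth$subpop_label
  same <- outer(lab, lab, `==`) & upper.tri(km$k)
  diff <- (!outer(lab, lab, `==`)) & upper.tri(km$k)
  expect_gt(mean(km$k[same]), mean(km$k[diff]))
})

test_that("PCoA axes and NJ clades separate simulated subpopulations", {
  sim <- simulate_panel(sim_config(n_lines = 60, n_markers = 80,
                                   drift_F = 0.25, admixture_alpha = 0.05,
                                   seed = 13))
  lab <- sim$truth$subpop_label
  D <- nei_distance(sim$panel)
  # silhouette of the true labels in the first two PCoA axes
  xy <- pcoa(D, n_axes = 2)$coords
  d2 <- as.matrix(stats::dist(xy))
  sil <- vapply(seq_along(lab), function(i) {
    a <- mean(d2[i, lab == lab[i] & seq_along(lab) != i])
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(g) mean(d2[i, lab == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.2)
  # cutting the NJ tree into its three deepest clades recovers the groups
  tr <- nj_tree(D)
  cop <- ape::cophenetic.phylo(tr)[sim$panel$line_ids, sim$panel$line_ids]
  cl <- stats::cutree(stats::hclust(stats::as.dist(cop), "average"), k = 3)
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  agree <- max(vapply(perms, function(pm) mean(pm[cl] == lab), numeric(1)))
  expect_gte(agree, 0.8)
})
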