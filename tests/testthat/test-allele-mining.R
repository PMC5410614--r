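four_line_panel <- function() {
  panel_from_calls(matrix(c("100", "100", "104", "104"), 4, 1),
                   line_ids = paste0("P", 1:4), marker_ids = "M1")
}

test_that("the four-line worked example yields effects of -10 and +10", {
  panel <- four_line_panel()
  y <- c(P1 = 10, P2 = 20, P3 = 30, P4 = 40)
  eff <- allele_effects(panel, y, "M1")
  expect_equal(eff$a_i[eff$allele == 100], -10)
  expect_equal(eff$a_i[eff$allele == 104], 10)
  expect_equal(eff$n_i, c(2, 2))
  # carriers ranked by trait value, best first
  expect_equal(eff$carriers[eff$allele == 104], "P4, P3")
})

test_that("effects satisfy the zero-sum identity on complete data", {
  panel <- random_panel(30, 8, n_alleles = 4, seed = 21)
  set.seed(5)
  y <- stats::rnorm(30, 50, 8)
  names(y) <- panel$line_ids
  eff <- allele_effects(panel, y, panel$markers$marker_id)
  for (m in unique(eff$marker_id)) {
    sub <- eff[eff$marker_id == m, ]
    expect_equal(sum(sub$n_i * sub$a_i), 0, tolerance = 1e-9)
  }
})

test_that("effects are location- and scale-equivariant", {
  panel <- random_panel(20, 5, n_alleles = 3, seed = 8)
  set.seed(6)
  y <- stats::rnorm(20, 40, 6)
  names(y) <- panel$line_ids
  base <- allele_effects(panel, y, panel$markers$marker_id)
  shift <- allele_effects(panel, y + 100, panel$markers$marker_id)
  scale2 <- allele_effects(panel, y * 3, panel$markers$marker_id)
  expect_equal(shift$a_i, base$a_i, tolerance = 1e-10)
  expect_equal(scale2$a_i, base$a_i * 3, tolerance = 1e-10)
})

test_that("monomorphic markers carry a zero effect", {
  panel <- panel_from_calls(matrix("100", 5, 1), marker_ids = "M1")
  y <- stats::setNames(1:5 * 10, panel$line_ids)
  eff <- allele_effects(panel, y, "M1")
  expect_equal(eff$a_i, 0)
})

test_that("heterozygous carriers count once per carried allele class", {
  panel <- panel_from_calls(matrix(c("100/104", "100", "104"), 3, 1),
                            line_ids = paste0("P", 1:3), marker_ids = "M1")
  y <- c(P1 = 60, P2 = 30, P3 = 30)
  eff <- allele_effects(panel, y, "M1")
  # both classes contain the heterozygote's full phenotype
  expect_equal(eff$a_i[eff$allele == 100], mean(c(60, 30)) - 40)
  expect_equal(eff$a_i[eff$allele == 104], mean(c(60, 30)) - 40)
  expect_equal(eff$n_i, c(2, 2))
})

test_that("favorable filtering follows the positive and >= 4 ppm rules", {
  eff <- data.frame(marker_id = "M1", allele = c(100, 104, 108, 112),
                    trait = "Fe", dataset = "GM",
                    a_i = c(5.2, 0.5, -3, 4.0), n_i = 4,
                    carriers = "", stringsAsFactors = FALSE)
  all_pos <- favorable_alleles(eff, min_effect = 0)
  expect_setequal(all_pos$allele, c(100, 104, 112))
  strong <- favorable_alleles(eff, min_effect = 4)
  expect_equal(strong$allele, c(100, 112))   # >= 4, sorted by effect
  expect_equal(nrow(favorable_alleles(eff[0, ])), 0)
})

test_that("inventories count distinct favorable pairs per line", {
  calls <- rbind(c("100", "200", "300"),
                 c("100", "204", "304"),
                 c("104", "204", "300/304"))
  panel <- panel_from_calls(calls, line_ids = paste0("P", 1:3))
  fav <- data.frame(marker_id = c("M01", "M02", "M03", "M03"),
                    allele = c(100, 200, 300, 304),
                    trait = c("Fe", "Fe", "Zn", "Zn"),
                    a_i = c(5, 4, 6, 3), stringsAsFactors = FALSE)
  inv <- genotype_allele_inventory(panel, fav)
  expect_equal(inv$counts$n_total, c(3, 2, 2))
  expect_equal(inv$counts$n_Fe, c(2, 1, 0))
  expect_equal(inv$counts$n_Zn, c(1, 1, 2))   # het P3 carries both M03 alleles
  # invariant to marker order in the favorable list
  inv2 <- genotype_allele_inventory(panel, fav[c(3, 1, 4, 2), ])
  expect_equal(inv2$counts, inv$counts)
})

test_that("cross proposals score unions with lexicographic tie-breaks", {
  sets <- list(
    X1 = data.frame(key = paste0("M", 1:4), trait = "Fe"),
    X2 = data.frame(key = paste0("M", 5:7), trait = "Zn"),
    X3 = data.frame(key = paste0("M", 1:4), trait = "Fe"))
  inv <- list(counts = NULL, sets = sets)
  cr <- propose_crosses(inv, top_n = 3)
  # disjoint 4 + 3 union
  expect_equal(cr$n_total[1], 7)
  expect_equal(cr$parent1[1], "X1")
  expect_equal(cr$parent2[1], "X2")
  # identical parents add nothing
  same <- cr[cr$parent1 == "X1" & cr$parent2 == "X3", ]
  expect_equal(same$n_total, 4)
  # monotonicity: enriching a parent never lowers its crosses
  sets2 <- sets
  sets2$X2 <- rbind(sets2$X2, data.frame(key = "M9", trait = "Fe"))
  cr2 <- propose_crosses(list(sets = sets2), top_n = 3)
  expect_gte(cr2$n_total[cr2$parent1 == "X1" & cr2$parent2 == "X2"],
             cr$n_total[cr$parent1 == "X1" & cr$parent2 == "X2"])
})

test_that("lines carrying planted favorable alleles are counted from truth", {
  cfg <- sim_config(n_lines = 40, n_markers = 60, seed = 31,
                    planted_qtls = data.frame(marker = c(5L, 15L, 25L),
                                              allele = 1L, effect = 8,
                                              trait = "Fe"),
                    complementary_parents = c(1L, 2L))
  sim <- simulate_panel(cfg)
  fav <- data.frame(marker_id = sim$truth$planted_qtls$marker_id,
                    allele = sim$truth$planted_qtls$allele_size,
                    trait = "Fe", stringsAsFactors = FALSE)
  inv <- genotype_allele_inventory(sim$panel, fav)
  # parent 1 was forced homozygous-favorable at all three Fe QTLs
  expect_equal(inv$counts$n_Fe[1], 3)
})
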