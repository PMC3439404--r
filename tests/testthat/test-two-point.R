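test_that("same-parent testcross pairs match the closed-form estimates", {
  p <- testcross_pair(100, 20)
  e <- estimate_two_point(p$a, p$b, "testcross_1to1_P1",
                          "testcross_1to1_P1")
  expect_equal(e$r_hat, 0.20, tolerance = 1e-4)
  lod_expected <- 20 * log10(0.2) + 80 * log10(0.8) - 100 * log10(0.5)
  expect_equal(e$lod, lod_expected, tolerance = 1e-4)
  expect_equal(e$lod, 8.37, tolerance = 1e-2)

  # identical vectors: complete linkage
  e0 <- estimate_two_point(p$a, p$a, "testcross_1to1_P1",
                           "testcross_1to1_P1")
  expect_equal(e0$r_hat, 0, tolerance = 1e-6)
  expect_equal(e0$lod, 100 * log10(2), tolerance = 1e-4)

  # half recombinant: independence
  p50 <- testcross_pair(100, 50)
  e50 <- estimate_two_point(p50$a, p50$b, "testcross_1to1_P1",
                            "testcross_1to1_P1")
  expect_equal(e50$r_hat, 0.5)
  expect_equal(e50$lod, 0)
})

test_that("repulsion-phase pairs are recognized and estimated", {
  p <- testcross_pair(100, 20)
  b_rep <- ifelse(p$b == "1", "0", "1")      # same data, opposite phase
  e <- estimate_two_point(p$a, b_rep, "testcross_1to1_P1",
                          "testcross_1to1_P1")
  expect_equal(e$r_hat, 0.20, tolerance = 1e-4)
  expect_equal(e$phase, "R")
})

test_that("dominant testcross pairs from different parents are uninformative", {
  p <- testcross_pair(100, 20)
  e <- estimate_two_point(p$a, p$b, "testcross_1to1_P1",
                          "testcross_1to1_P2")
  expect_false(e$informative)
  expect_equal(e$lod, 0)
  expect_true(is.na(e$r_hat))
})

test_that("estimates agree with an independent enumeration oracle", {
  g <- linkage_genome()
  configs <- list(
    c("testcross_1to1_P1", "intercross_3to1"),
    c("intercross_3to1", "intercross_3to1"),
    c("fully_informative", "testcross_1to1_P1"),
    c("fully_informative", "fully_informative"))
  set.seed(77)
  for (cfg in configs) {
    for (d_cm in c(5, 20)) {
      truth <- data.frame(scaffold = "Chr01", bp = c(1e6, 1e6 + d_cm * 5e5),
                          class = cfg, phase_P1 = 1L, phase_P2 = 1L)
      cr <- simulate_cross(g, cross_spec(n_progeny = 150, missing_rate = 0,
                                         error_rate = 0,
                                         seed = sample.int(1e6, 1)),
                           marker_truth = truth)
      sa <- cr$genotypes[1, -(1:2)]
      sb <- cr$genotypes[2, -(1:2)]
      est <- estimate_two_point(sa, sb, cfg[1], cfg[2])
      ora <- oracle_two_point(sa, sb, cfg[1], cfg[2])
      # absolute tolerances at the oracle grid resolution (5e-4 in r)
      expect_lt(abs(est$r_hat - ora$r_hat), 1e-3)
      expect_lt(abs(est$lod - ora$lod), 5e-2)
    }
  }
})

test_that("the modeled score error de-biases estimates from noisy data", {
  g <- linkage_genome()
  truth <- data.frame(scaffold = "Chr01", bp = c(1e6, 1e6 + 5e6),
                      class = "testcross_1to1_P1",
                      phase_P1 = 1L, phase_P2 = 1L)   # 10 cM apart
  set.seed(42)
  r_naive <- r_model <- numeric(20)
  for (i in 1:20) {
    cr <- simulate_cross(g, cross_spec(n_progeny = 300, missing_rate = 0,
                                       error_rate = 0.02,
                                       seed = 5000 + i),
                         marker_truth = truth)
    sa <- cr$genotypes[1, -(1:2)]; sb <- cr$genotypes[2, -(1:2)]
    r_naive[i] <- estimate_two_point(sa, sb, "testcross_1to1_P1",
                                     "testcross_1to1_P1")$r_hat
    r_model[i] <- estimate_two_point(sa, sb, "testcross_1to1_P1",
                                     "testcross_1to1_P1",
                                     genotype_error = 0.02)$r_hat
  }
  r_true <- haldane_r(10)
  expect_gt(mean(r_naive) - r_true, 0.02)   # naive estimate inflated
  expect_lt(abs(mean(r_model) - r_true), 0.01)
})

test_that("the screened pair table finds linked pairs and respects forced pairs", {
  g <- linkage_genome()
  cr <- simulate_cross(g, cross_spec(n_progeny = 177,
                                     markers_per_chromosome = 20,
                                     missing_rate = 0, error_rate = 0,
                                     seed = 31))
  classes <- stats::setNames(cr$markers$class, cr$markers$marker_id)
  params <- mapping_params(genotype_error = 0)
  tp <- two_point_table(cr$genotypes, classes, params)
  mk <- cr$markers
  same <- mk$truth_chrom[match(tp$a, mk$marker_id)] ==
    mk$truth_chrom[match(tp$b, mk$marker_id)]
  # high-LOD edges must join markers of the same chromosome
  expect_true(all(same[tp$lod > 15]))

  forced <- two_point_table(cr$genotypes, classes, params,
                            pairs = cbind(mk$marker_id[1], mk$marker_id[2]))
  expect_equal(nrow(forced), 1)
})
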