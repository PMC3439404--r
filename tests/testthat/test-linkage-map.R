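toy_tp <- function(df) {
  df$phase <- "C"
  df$informative <- TRUE
  df
}

test_that("grouping is a transitive closure over strong edges", {
  tp <- toy_tp(data.frame(
    a = c("A", "B", "A"), b = c("B", "C", "C"),
    r_hat = c(0.1, 0.1, 0.18), lod = c(20, 18, 3), n = 100))
  grp <- group_markers(tp, c("A", "B", "C", "D"), mapping_params())
  expect_equal(length(grp$groups), 1)
  expect_setequal(grp$groups[[1]], c("A", "B", "C"))
  expect_equal(grp$ungrouped, "D")
})

test_that("edges above r_max or below the LOD threshold do not group", {
  tp <- toy_tp(data.frame(a = "A", b = "B", r_hat = 0.45, lod = 30,
                          n = 100))
  grp <- group_markers(tp, c("A", "B"), mapping_params())
  expect_equal(length(grp$groups), 0)
  expect_setequal(grp$ungrouped, c("A", "B"))
})

test_that("a three-marker group is ordered correctly with pooled positions", {
  classes <- stats::setNames(rep("testcross_1to1_P1", 3), c("A", "B", "C"))
  tp <- toy_tp(data.frame(
    a = c("A", "B", "A"), b = c("B", "C", "C"),
    r_hat = c(0.1, 0.1, 0.18), lod = c(20, 18, 16), n = 100))
  lg <- order_group(c("A", "B", "C"), tp, classes, mode = "full")
  expect_true(identical(lg$markers$marker_id, c("A", "B", "C")) ||
                identical(lg$markers$marker_id, c("C", "B", "A")))
  expect_equal(lg$markers$position_cm[1], 0)
  expect_true(all(diff(lg$markers$position_cm) >= 0))

  # r(AC) = 0.18 is (to the printed precision) the Haldane-additive
  # combination of two r = 0.1 intervals, so the pooled fit is consistent
  # and the length is exactly 2 * kosambi(0.1) = 20.3 cM
  expect_equal(lg$length_cm, 2 * kosambi_cm(0.1), tolerance = 1e-3)
  expect_equal(lg$length_cm, 20.3, tolerance = 1e-2)
})

test_that("a two-marker group spans the Kosambi distance of its pair", {
  classes <- stats::setNames(rep("testcross_1to1_P1", 2), c("A", "B"))
  tp <- toy_tp(data.frame(a = "A", b = "B", r_hat = 0.1, lod = 20, n = 90))
  lg <- order_group(c("A", "B"), tp, classes, mode = "full")
  expect_equal(lg$length_cm, kosambi_cm(0.1))
  lg1 <- order_group("A", tp, classes, mode = "full")
  expect_equal(lg1$markers$position_cm, 0)
})

test_that("ordering is invariant to the input order of markers", {
  maps <- noisy_maps()
  gr <- maps$full$groups[[1]]
  ids <- gr$markers$marker_id
  set.seed(1)
  lg2 <- order_group(sample(ids), maps$full$tp, maps$classes,
                     mode = "full", params = maps$params)
  expect_equal(lg2$length_cm, gr$length_cm, tolerance = 1e-6)
  same <- identical(lg2$markers$marker_id, gr$markers$marker_id)
  reversed <- identical(lg2$markers$marker_id, rev(gr$markers$marker_id))
  expect_true(same || reversed)
})

test_that("simulated chromosomes are recovered as groups with correct order", {
  maps <- noisy_maps()
  mk <- maps$cross$markers
  big <- Filter(function(g) nrow(g$markers) >= 10, maps$full$groups)
  expect_equal(length(big), 3)     # the three simulated chromosomes
  for (gr in big) {
    tm <- mk[match(gr$markers$marker_id, mk$marker_id), ]
    expect_equal(length(unique(tm$truth_chrom)), 1)
    rho <- abs(cor(gr$markers$position_cm, tm$truth_cm,
                   method = "spearman"))
    expect_gte(rho, 0.95)
    # map length within 25% of the planted length
    truth_len <- diff(range(tm$truth_cm))
    expect_lt(abs(gr$length_cm - truth_len) / truth_len, 0.25)
  }
})

test_that("framework mode defers markers and thins short gaps", {
  maps <- noisy_maps()
  n_full <- sum(vapply(maps$full$groups, function(g) nrow(g$markers), 0L))
  n_fw <- sum(vapply(maps$framework$groups,
                     function(g) nrow(g$markers), 0L))
  expect_lte(n_fw, n_full)
  expect_gt(sum(vapply(maps$framework$groups,
                       function(g) length(g$deferred), 0L)), 0)

  cmp <- compare_maps(maps$full, maps$framework)
  expect_lte(cmp$fraction_below_1cm["framework"],
             cmp$fraction_below_1cm["full"])
  expect_true(cmp$ks_statistic >= 0 && cmp$ks_statistic <= 1)
})
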