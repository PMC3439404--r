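mk_group <- function(ids, pos, group_id = "LG01", mode = "full") {
  structure(list(group_id = group_id, mode = mode,
                 markers = data.frame(marker_id = ids, position_cm = pos,
                                      stringsAsFactors = FALSE),
                 deferred = character(0), length_cm = max(pos)),
            class = "linkage_group")
}

mk_placements <- function(ids, scaffold, bp) {
  data.frame(marker_id = ids, scaffold = scaffold, bp = bp,
             stringsAsFactors = FALSE)
}

test_that("collinearity is orientation-corrected and flags discordant markers", {
  ids <- sprintf("M%02d", 1:10)
  g <- mk_group(ids, seq(0, 90, by = 10))
  pl <- mk_placements(ids, "Chr01", seq(1e6, 10e6, by = 1e6))
  expect_equal(collinearity(g, pl)$rho, 1)

  # fully reversed physical order: |rho| still 1
  pl_rev <- mk_placements(ids, "Chr01", rev(seq(1e6, 10e6, by = 1e6)))
  expect_equal(collinearity(g, pl_rev)$rho, 1)

  # one adjacent swap among 5 markers: rho = 0.9
  ids5 <- sprintf("M%02d", 1:5)
  g5 <- mk_group(ids5, c(0, 10, 20, 30, 40))
  pl5 <- mk_placements(ids5, "Chr01", c(1, 3, 2, 4, 5) * 1e6)
  co <- collinearity(g5, pl5)
  expect_equal(co$rho, 0.9)
  expect_equal(cor(1:5, c(1, 3, 2, 4, 5), method = "spearman"), 0.9)

  # fewer than 3 shared markers: undefined
  g2 <- mk_group(ids5[1:2], c(0, 10))
  expect_true(is.na(collinearity(g2, pl5)$rho))
})

test_that("kbp/cM ratios and genome summaries follow the published arithmetic", {
  # single chromosome: 40.7 Mbp over 114.0 cM
  ids <- c("A", "B")
  g <- mk_group(ids, c(0, 114.0))
  pl <- mk_placements(ids, "Chr01", c(0, 40.7e6))
  rr <- kbp_per_cm(list(g), pl)
  expect_equal(rr$per_chromosome$kbp_per_cm, 40700 / 114.0,
               tolerance = 1e-9)
  expect_equal(rr$per_chromosome$kbp_per_cm, 357.0, tolerance = 1e-3)
  expect_equal(rr$genome_mean, rr$per_chromosome$kbp_per_cm)
  expect_true(is.na(rr$genome_sd))

  # the 11 published ratios: mean 513.4, sd 112.7
  ratios <- reference_map_stats()$per_chromosome$kbp_per_cm
  expect_equal(length(ratios), 11)
  expect_equal(mean(ratios), 513.4, tolerance = 1e-3)
  expect_equal(sd(ratios), 112.7, tolerance = 1e-3)
})

test_that("coverage percentage reproduces the headline figure", {
  expect_equal(coverage_percent(587.5, 605.8)$percent, 96.98, tolerance = 1e-3)
  expect_equal(coverage_percent(587.5, 605.8)$percent_rounded, 97)
  expect_equal(coverage_percent(605.8, 605.8)$percent_rounded, 100)
  expect_equal(coverage_percent(302.9, 605.8)$percent_rounded, 50)
  expect_error(coverage_percent(10, 0), "> 0")
})

test_that("unanchored scaffolds are assigned by their markers, conflicts flagged", {
  mt <- data.frame(marker_id = c("A", "B", "C"),
                   group = c("LG03", "LG03", "LG07"),
                   position_cm = c(5, 10, 3), mode = "full",
                   stringsAsFactors = FALSE)
  pl <- mk_placements(c("A", "B", "C"),
                      c("scf1", "scf2", "scf2"), c(100, 200, 300))
  lens <- c(scf1 = 10000, scf2 = 25000)
  asg <- assign_scaffolds(mt, pl, lens)
  a <- asg$assignments
  expect_equal(a$assigned_group[a$scaffold == "scf1"], "LG03")
  expect_true(a$conflict[a$scaffold == "scf2"])
  expect_true(is.na(a$assigned_group[a$scaffold == "scf2"]))
  expect_equal(asg$total_captured_bp, 10000)
})

test_that("markers on unanchored scaffolds anchor them to their origin group", {
  g <- linkage_genome()
  cr <- simulate_cross(g, cross_spec(n_progeny = 177,
                                     markers_per_chromosome = 60,
                                     missing_rate = 0, error_rate = 0,
                                     n_unanchored_markers = 5, seed = 91))
  seg <- segregation_table(cr)
  seg <- seg[seg$mendelian, ]
  classes <- stats::setNames(seg$class, seg$marker_id)
  params <- mapping_params(genotype_error = 0)
  full <- linkage_map(cr$genotypes, classes, mode = "full", params = params)
  pl <- placements_from_truth(cr)
  scf <- g$scaffolds[!g$scaffolds$is_main, ]
  asg <- assign_scaffolds(full, pl,
                          stats::setNames(scf$length, scf$scaffold))
  expect_gt(nrow(asg$assignments), 0)
  # every conflict-free assignment matches the scaffold's chromosome of
  # origin (identified through the groups' majority chromosomes)
  mt <- map_table(full)
  mk <- cr$markers
  group_chrom <- vapply(full$groups, function(gr) {
    names(which.max(table(mk$truth_chrom[
      match(gr$markers$marker_id, mk$marker_id)])))
  }, "")
  a <- asg$assignments[!asg$assignments$conflict, ]
  origin <- scf$origin_chrom[match(a$scaffold, scf$scaffold)]
  expect_true(all(group_chrom[a$assigned_group] == origin))
})

test_that("map comparison uses the two-sample KS statistic on adjacent gaps", {
  m1 <- list(mk_group(letters[1:4], c(0, 1, 3, 6)))
  expect_equal(compare_maps(m1, m1)$ks_statistic, 0)
  expect_equal(compare_maps(m1, m1)$ks_p, 1)

  m2 <- list(mk_group(letters[1:4], cumsum(c(0, 4, 5, 6))))
  expect_equal(compare_maps(m1, m2)$ks_statistic, 1)  # disjoint supports

  m3 <- list(mk_group(letters[1:5], cumsum(c(0, 1, 2, 3, 4))))
  m4 <- list(mk_group(letters[1:5], cumsum(c(0, 2, 3, 4, 5))))
  expect_equal(compare_maps(m3, m4)$ks_statistic, 0.25)
})
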