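test_that("assembly presets carry the tiered stringency parameters", {
  a1 <- assembly_params("A1")
  a4 <- assembly_params("A4")
  expect_equal(a1$word_length, 18)
  expect_equal(a1$index_word_length, 13)
  expect_equal(a1$max_mismatch_pct, 10)
  expect_equal(a1$max_gap_size, 1)
  expect_equal(a4$word_length, 10)
  expect_equal(a4$max_ambiguities, 16)
  expect_equal(a1$min_overlap, 50)
  expect_equal(a1$min_overlap_identity, 0.98)
  expect_error(assembly_params("A5"), "A1..A4")
  expect_error(assembly_params(word_length = 5, index_word_length = 10))
})

test_that("identical and near-identical sequences merge; short or dissimilar overlaps do not", {
  set.seed(10)
  s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
             collapse = "")
  # identical pair
  cl <- cluster_probes(c(p1 = s, p2 = s), assembly_params("A1"))
  expect_equal(unname(cl["p1"]), unname(cl["p2"]))

  # 6 scattered mismatches over 500 bp: identity 98.8%, merged under A1
  mut <- function(x, pos) {
    sp <- strsplit(x, "")[[1]]
    for (p in pos) sp[p] <- setdiff(c("A", "C", "G", "T"), sp[p])[1]
    paste(sp, collapse = "")
  }
  s6 <- mut(s, seq(40, 490, by = 90))
  cl6 <- cluster_probes(c(a = s, b = s6), assembly_params("A1"))
  expect_equal(unname(cl6["a"]), unname(cl6["b"]))

  # 15 scattered mismatches: identity 97% < 98%, not merged
  s15 <- mut(s, seq(20, 480, by = 33))
  cl15 <- cluster_probes(c(a = s, b = s15), assembly_params("A1"))
  expect_false(cl15[["a"]] == cl15[["b"]])

  # 40 bp perfect overlap only: below the 50 bp minimum
  set.seed(11)
  t1 <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
              collapse = "")
  t2 <- paste0(substr(t1, 261, 300),
               paste(sample(c("A", "C", "G", "T"), 260, replace = TRUE),
                     collapse = ""))
  cl40 <- cluster_probes(c(a = t1, b = t2), assembly_params("A1"))
  expect_false(cl40[["a"]] == cl40[["b"]])

  # a 60 bp perfect overlap merges
  t3 <- paste0(substr(t1, 241, 300),
               paste(sample(c("A", "C", "G", "T"), 240, replace = TRUE),
                     collapse = ""))
  cl60 <- cluster_probes(c(a = t1, b = t3), assembly_params("A1"))
  expect_equal(unname(cl60["a"]), unname(cl60["b"]))
})

test_that("reverse-complement copies are clustered together", {
  set.seed(12)
  s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
             collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  cl <- cluster_probes(c(a = s, b = rc), assembly_params("A1"))
  expect_equal(unname(cl["a"]), unname(cl["b"]))
})

test_that("planted duplicate clusters are recovered exactly at zero mutation", {
  skip_if_not_installed("mclust")
  g <- small_genome()
  p <- plant_probes(g, 120, redundancy_rate = 0.3, mutation_rate = 0,
                    seed = 3)
  cl <- cluster_probes(p, assembly_params("A1"))
  expect_equal(mclust::adjustedRandIndex(cl, p$truth$truth_cluster), 1)
  rep1 <- redundancy_report(cl)
  expect_equal(rep1$n_unique_loci,
               length(unique(p$truth$truth_cluster)))  # 70 planted loci
})

test_that("lightly mutated copies co-cluster under the relaxed preset", {
  g <- small_genome()
  p <- plant_probes(g, 100, redundancy_rate = 0.4, mutation_rate = 0.005,
                    seed = 4)
  cl <- cluster_probes(p, assembly_params("A4"))
  tr <- p$truth
  copies <- tr[tr$is_copy, ]
  parent_id <- tr$probe_id[match(copies$truth_cluster, tr$truth_cluster)]
  co <- mean(cl[copies$probe_id] == cl[parent_id])
  expect_gte(co, 0.95)
})

test_that("redundancy accounting identities hold for any clustering", {
  set.seed(20)
  for (i in 1:20) {
    cl <- sample.int(15, 60, replace = TRUE)
    rep <- redundancy_report(cl)
    expect_equal(rep$n_singletons + rep$n_redundant_members, rep$n_total)
    expect_equal(rep$n_unique_loci, rep$n_singletons + rep$n_clusters)
    expect_equal(rep$redundancy_rate,
                 100 * (rep$n_total - rep$n_unique_loci) / rep$n_total)
  }
  all_single <- redundancy_report(1:30)
  expect_equal(all_single$redundancy_rate, 0)
  expect_equal(all_single$n_unique_loci, 30)
})

test_that("extrapolation scales unique loci to the array size", {
  rep <- redundancy_report(list(n_total = 100, n_singletons = 60,
                                n_clusters = 10))
  expect_equal(extrapolate_unique_loci(100, rep), rep$n_unique_loci)
  expect_equal(extrapolate_unique_loci(150, rep), floor(150 * 70 / 100))
  expect_error(extrapolate_unique_loci(50, rep), "at least")
})

test_that("empty input is rejected", {
  expect_error(cluster_probes(character(0)), "at least one")
  expect_error(cluster_probes(c(a = "ACGT", b = "")), "empty")
})
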