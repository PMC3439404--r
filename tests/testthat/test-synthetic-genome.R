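test_that("genome simulation is deterministic and honors its spec", {
  spec <- genome_spec(n_chromosomes = 2, chromosome_lengths = c(1e6, 1e6),
                      n_unanchored_scaffolds = 4,
                      unanchored_length_range = c(5e3, 2e4),
                      gene_density = 10, seed = 42)
  g1 <- simulate_genome(spec)
  g2 <- simulate_genome(spec)
  expect_identical(as.character(g1$sequences), as.character(g2$sequences))
  expect_identical(g1$genes, g2$genes)
  expect_identical(g1$scaffolds, g2$scaffolds)

  # declared lengths match the sequences
  expect_equal(unname(Biostrings::width(g1$sequences)),
               g1$scaffolds$length)

  # density 10 per Mbp over 2 Mbp: Poisson mean 20, check within 4 sd
  expect_lt(abs(nrow(g1$genes) - 20), 4 * sqrt(20) + 1)

  # gene intervals are non-overlapping within each chromosome
  for (ch in unique(g1$genes$scaffold)) {
    gg <- g1$genes[g1$genes$scaffold == ch, ]
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1) {
      expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))
    }
  }
})

test_that("zero gene density yields an empty annotation", {
  g <- simulate_genome(genome_spec(n_chromosomes = 1,
                                   chromosome_lengths = 1e5,
                                   n_unanchored_scaffolds = 0,
                                   gene_density = 0, seed = 1),
                       with_sequence = FALSE)
  expect_equal(nrow(g$genes), 0)
})

test_that("invalid genome parameters are rejected", {
  expect_error(genome_spec(n_chromosomes = 1, chromosome_lengths = 0))
  expect_error(genome_spec(n_chromosomes = 2, chromosome_lengths = 1e6))
  expect_error(genome_spec(n_chromosomes = 1, chromosome_lengths = 1e6,
                           gc_fraction = 1.2))
})

test_that("planted probes have the requested redundancy structure", {
  g <- small_genome()
  p <- plant_probes(g, 100, redundancy_rate = 0.3, mutation_rate = 0,
                    seed = 3)
  expect_equal(sum(p$truth$is_copy), 30)
  expect_equal(length(unique(p$truth$truth_cluster)), 70)
  # copies are byte-identical to their source probe
  copies <- p$truth[p$truth$is_copy, ]
  src <- as.character(p$sequences[copies$truth_cluster])
  expect_identical(as.character(p$sequences[copies$probe_id]),
                   stats::setNames(src, copies$probe_id))

  p0 <- plant_probes(g, 50, redundancy_rate = 0, seed = 4)
  expect_equal(length(unique(p0$truth$truth_cluster)), 50)
  expect_false(any(p0$truth$is_copy))

  # probe lengths respect the range
  expect_true(all(Biostrings::width(p$sequences) >= 300 &
                    Biostrings::width(p$sequences) <= 500))
})

test_that("copy mutation count matches the binomial expectation", {
  g <- small_genome()
  p <- plant_probes(g, 200, redundancy_rate = 0.5, mutation_rate = 0.01,
                    length_range = c(500, 500), seed = 9)
  copies <- p$truth[p$truth$is_copy, ]
  hd <- vapply(seq_len(nrow(copies)), function(i) {
    a <- as.character(p$sequences[[copies$probe_id[i]]])
    b <- as.character(p$sequences[[
      p$truth$probe_id[copies$truth_cluster[i]]]])
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, 0)
  # 100 replicates of Binomial(500, 0.01): mean of means 5, sd of the mean
  # sqrt(500 * .01 * .99 / 100)
  expect_equal(length(hd), 100)
  expect_lt(abs(mean(hd) - 5), 4 * sqrt(500 * 0.01 * 0.99 / 100))
})

test_that("probe length range exceeding every scaffold is an error", {
  g <- small_genome()
  expect_error(plant_probes(g, 10, length_range = c(4e5, 5e5)),
               "length_range")
})

test_that("PstI-bounded extraction produces motif-flanked probes", {
  g <- small_genome()
  p <- plant_probes(g, 5, length_range = c(300, 3000), seed = 5,
                    require_pst1 = TRUE)
  for (s in as.character(p$sequences)) {
    fwd_ok <- startsWith(s, "CTGCAG") && endsWith(s, "CTGCAG")
    expect_true(fwd_ok)  # motif is its own reverse complement
  }
})
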