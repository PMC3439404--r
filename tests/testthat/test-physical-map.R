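test_that("score threshold rule uses the natural log and a ceiling", {
  expect_equal(compute_threshold(rep(534, 10)), 70L)
  expect_equal(2 * 5.5 * log(534), 69.08, tolerance = 1e-2)
  expect_equal(compute_threshold(exp(1)), 11L)
  # median selection: the middle length drives the threshold
  expect_equal(compute_threshold(c(100, 534, 1000)), 70L)
  expect_error(compute_threshold(c(534, 1)), "> 1")
  expect_error(compute_threshold(numeric(0)))
})

mk_hits <- function(scores, scaffold = "Chr01", starts = NULL) {
  n <- length(scores)
  if (is.null(starts)) starts <- seq(0, by = 5000, length.out = n)
  data.frame(probe_id = rep("P1", n), scaffold = rep(scaffold, n),
             start = starts, end = starts + 500,
             strand = rep("+", n), score = scores,
             is_main = rep(TRUE, n), stringsAsFactors = FALSE)
}

test_that("hit retention keeps hits within T of the best and flags >2 as ambiguous", {
  r1 <- retain_hits(mk_hits(c(450, 400)), 70)
  expect_equal(r1$status, "ok")
  expect_equal(nrow(r1$hits), 2)

  r2 <- retain_hits(mk_hits(c(450, 350)), 70)
  expect_equal(nrow(r2$hits), 1)

  r3 <- retain_hits(mk_hits(c(450, 440, 430)), 70)
  expect_equal(r3$status, "ambiguous")

  r0 <- retain_hits(mk_hits(numeric(0)), 70)
  expect_equal(r0$status, "unmapped")

  # idempotence
  again <- retain_hits(r1$hits, 70)
  expect_equal(again$hits, r1$hits)
  expect_equal(again$status, r1$status)
})

test_that("placement classes follow the overlap and distance rules", {
  two_hits <- function(s1, e1, s2, e2, scf2 = "Chr01", main2 = TRUE) {
    h <- data.frame(probe_id = "P1",
                    scaffold = c("Chr01", scf2),
                    start = c(s1, s2), end = c(e1, e2), strand = "+",
                    score = c(450, 440),
                    is_main = c(TRUE, main2), stringsAsFactors = FALSE)
    classify_placement(list(status = "ok", hits = h))
  }
  # overlapping hits are one locus
  expect_equal(two_hits(1000, 1500, 1200, 1700)$status, "unique_locus")
  # 600 bp gap: tandem duplication
  p <- two_hits(1000, 1500, 2100, 2600)
  expect_equal(p$status, "tandem_proximal")
  expect_equal(p$inter_hit_distance, 600)
  # different chromosomes
  expect_equal(two_hits(1000, 1500, 1000, 1500, scf2 = "Chr05")$status,
               "multi_chromosome")
  expect_equal(two_hits(1000, 1500, 1000, 1500, scf2 = "scaffold_0001",
                        main2 = FALSE)$status, "multi_with_unanchored")

  # boundary behavior at 1 kb (strict <) and 10 kb (strict >)
  gap_status <- function(gap) {
    two_hits(0, 500, 500 + gap, 1000 + gap)$status
  }
  expect_equal(gap_status(999), "tandem_proximal")
  expect_equal(gap_status(1000), "same_scaffold_distal")
  expect_equal(gap_status(1001), "same_scaffold_distal")
  expect_equal(gap_status(10000), "same_scaffold_distal")
  expect_equal(gap_status(10001), "same_scaffold_far")
})

test_that("mapping reliability is the ambiguous fraction to 3 decimals", {
  pl <- data.frame(status = c(rep("unique_locus", 6619),
                              rep("ambiguous", 12)))
  r <- mapping_reliability(pl)
  expect_equal(r$error_rate, 0.002)
  expect_equal(r$n_evaluated, 6631)
  expect_equal(mapping_reliability(
    data.frame(status = rep("unique_locus", 10)))$error_rate, 0)
  expect_equal(mapping_reliability(
    data.frame(status = c(rep("unique_locus", 995),
                          rep("ambiguous", 5))))$error_rate, 0.005)
  expect_error(mapping_reliability(data.frame(status = "unmapped")),
               "no evaluated")
})

test_that("the naive aligner scores exact, mismatched and gapped matches correctly", {
  g <- small_genome()
  chr <- as.character(g$sequences[["Chr01"]])
  probe <- substr(chr, 10001, 10500)           # exact 500 bp
  mut <- probe
  substr(mut, 100, 100) <- chartr("ACGT", "GTAC", substr(mut, 100, 100))
  substr(mut, 300, 300) <- chartr("ACGT", "GTAC", substr(mut, 300, 300))
  del <- paste0(substr(probe, 1, 200), substr(probe, 203, 500))

  hits <- naive_align(c(exact = probe, mm2 = mut, del2 = del), g,
                      scoring_params(threshold_t = 70))
  score_of <- function(id) max(hits$score[hits$probe_id == id])
  expect_equal(score_of("exact"), 500)
  expect_equal(score_of("mm2"), 498 - 6)       # 2 mismatches at b = 3
  expect_equal(score_of("del2"), 498 - (5 + 2 * 2))  # one 2 bp gap
  # recovered coordinates match the planted position
  h <- hits[hits$probe_id == "exact", ][1, ]
  expect_equal(h$scaffold, "Chr01")
  expect_equal(h$start, 10000)
  expect_equal(h$end, 10500)
})

test_that("planted probes align uniquely to their true positions", {
  g <- small_genome()
  p <- plant_probes(g, 80, redundancy_rate = 0, seed = 6, main_only = TRUE)
  hits <- naive_align(p, g)
  pl <- classify_hits(hits, compute_threshold(
    Biostrings::width(p$sequences)), probe_ids = p$truth$probe_id)
  expect_gte(mean(pl$status == "unique_locus"), 0.99)
  m <- merge(pl[pl$status == "unique_locus", ], p$truth, by = "probe_id")
  expect_gte(mean(m$scaffold.x == m$scaffold.y & m$start.x == m$start.y),
             0.99)
})

test_that("planted tandem duplicates classify by their gap", {
  g <- small_genome()
  chr <- as.character(g$sequences[["Chr02"]])
  for (gap in c(999, 1000, 10001)) {
    probe <- substr(chr, 50001, 50400)
    genome2 <- g
    # plant a second copy at the requested gap downstream
    s2 <- 50400 + gap
    seqs <- as.character(g$sequences)
    seqs["Chr02"] <- paste0(substr(chr, 1, s2),
                            probe,
                            substr(chr, s2 + 401, nchar(chr)))
    genome2$sequences <- Biostrings::DNAStringSet(seqs)
    genome2$scaffolds$length[genome2$scaffolds$scaffold == "Chr02"] <-
      nchar(seqs["Chr02"])
    hits <- naive_align(c(P1 = probe), genome2,
                        scoring_params(threshold_t = 70))
    pl <- classify_hits(hits, 70)
    expected <- if (gap < 1000) "tandem_proximal"
      else if (gap > 10000) "same_scaffold_far" else "same_scaffold_distal"
    expect_equal(pl$status, expected)
    expect_equal(pl$inter_hit_distance, gap)
  }
})

test_that("SAM alignments round-trip through the reader", {
  sam <- file.path(tempdir(), "probes_test.sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:Chr01\tLN:300000",
    "@SQ\tSN:scaffold_0001\tLN:30000",
    paste("P00001", 0, "Chr01", 1001, 60, "500M", "*", 0, 0,
          strrep("A", 500), "*", "AS:i:480", sep = "\t"),
    paste("P00001", 256, "scaffold_0001", 2001, 0, "300M2D200M", "*", 0, 0,
          "*", "*", "AS:i:430", sep = "\t"),
    paste("P00002", 4, "*", 0, 0, "*", "*", 0, 0,
          strrep("C", 100), "*", sep = "\t")), sam)
  hits <- read_sam_hits(sam, main_scaffolds = "Chr01")
  expect_equal(nrow(hits), 2)
  expect_equal(hits$start[1], 1000)       # 1-based SAM -> 0-based internal
  expect_equal(hits$end[1], 1500)
  expect_equal(hits$end[2], 2000 + 502)   # deletion consumes reference
  expect_equal(hits$score, c(480, 430))
  expect_equal(hits$is_main, c(TRUE, FALSE))
  pl <- classify_hits(hits, 70)
  expect_equal(pl$status, "multi_with_unanchored")
})
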