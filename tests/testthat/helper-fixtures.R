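# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

with_cache <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# Small sequence-bearing genome for probe/alignment tests.
small_genome <- function() {
  with_cache("small_genome", function() {
    simulate_genome(genome_spec(
      n_chromosomes = 2, chromosome_lengths = c(3e5, 3e5),
      n_unanchored_scaffolds = 3, unanchored_length_range = c(2e4, 5e4),
      gene_density = 50, seed = 2))
  })
}

# Coordinate-only genome for linkage simulations: 3 chromosomes of 50 Mbp
# (100 cM at the planted 500 kbp/cM).
linkage_genome <- function() {
  with_cache("linkage_genome", function() {
    simulate_genome(genome_spec(
      n_chromosomes = 3, chromosome_lengths = rep(5e7, 3),
      n_unanchored_scaffolds = 5, gene_density = 0, seed = 11),
      with_sequence = FALSE)
  })
}

# Simulated cross at the settings of the order/length recovery properties:
# 177 progeny, 100 markers per chromosome, 10% missing, 1% score error.
noisy_cross <- function() {
  with_cache("noisy_cross", function() {
    simulate_cross(linkage_genome(),
                   cross_spec(n_progeny = 177, markers_per_chromosome = 100,
                              missing_rate = 0.1, error_rate = 0.01,
                              seed = 12))
  })
}

# Full and framework maps of noisy_cross (shared across test files).
noisy_maps <- function() {
  with_cache("noisy_maps", function() {
    cr <- noisy_cross()
    seg <- segregation_table(cr)
    seg <- seg[seg$mendelian, ]
    classes <- stats::setNames(seg$class, seg$marker_id)
    params <- mapping_params(genotype_error = 0.01)
    full <- linkage_map(cr$genotypes, classes, mode = "full",
                        params = params)
    fw <- linkage_map(cr$genotypes, classes, mode = "framework",
                      params = params, tp = full$tp)
    list(cross = cr, classes = classes, params = params,
         full = full, framework = fw)
  })
}

# Dominant testcross score vectors with an exact number of recombinant
# patterns (coupling, same parent), parents included as attributes.
testcross_pair <- function(n, n_recombinant) {
  a <- rep(c("1", "0"), length.out = n)
  b <- a
  flip <- seq_len(n_recombinant)
  b[flip] <- ifelse(a[flip] == "1", "0", "1")
  list(a = a, b = b)
}

# Brute-force two-point oracle: enumerate the 16 gamete combinations
# directly (independent of the package's cached-coefficient path) and grid
# search r per phase. Supports dominant and codominant classes.
oracle_two_point <- function(scores_a, scores_b, class_a, class_b,
                             eps = 0) {
  geno <- function(cl) switch(cl,
    testcross_1to1_P1 = list(c("1", "0"), c("0", "0")),
    testcross_1to1_P2 = list(c("0", "0"), c("1", "0")),
    intercross_3to1 = list(c("1", "0"), c("1", "0")),
    f2_1to2to1 = list(c("a", "b"), c("a", "b")),
    fully_informative = list(c("a", "b"), c("c", "d")))
  dominant <- function(cl) cl %in% c("testcross_1to1_P1",
                                     "testcross_1to1_P2",
                                     "intercross_3to1")
  obs <- function(cl, x, y) {
    if (dominant(cl)) (if (x == "1" || y == "1") "1" else "0")
    else paste(sort(c(x, y)), collapse = "")
  }
  ga <- geno(class_a); gb <- geno(class_b)
  probs_for <- function(phase, r) {
    gbp <- gb
    for (p in 1:2) if (phase[p] == "R") gbp[[p]] <- rev(gbp[[p]])
    out <- list()
    for (i1 in 1:2) for (j1 in 1:2) for (i2 in 1:2) for (j2 in 1:2) {
      pr <- (if (i1 == j1) (1 - r) / 2 else r / 2) *
            (if (i2 == j2) (1 - r) / 2 else r / 2)
      key <- paste(obs(class_a, ga[[1]][i1], ga[[2]][i2]),
                   obs(class_b, gbp[[1]][j1], gbp[[2]][j2]), sep = "|")
      out[[key]] <- (if (is.null(out[[key]])) 0 else out[[key]]) + pr
    }
    p <- unlist(out)
    if (eps > 0) {
      keys <- do.call(rbind, strsplit(names(p), "|", fixed = TRUE))
      acc <- list()
      for (k in seq_along(p)) {
        wa <- if (dominant(class_a))

          stats::setNames(c(1 - eps, eps),
                          c(keys[k, 1],
                            ifelse(keys[k, 1] == "1", "0", "1")))
        else stats::setNames(1, keys[k, 1])
        wb <- if (dominant(class_b))
          stats::setNames(c(1 - eps, eps),
                          c(keys[k, 2],
                            ifelse(keys[k, 2] == "1", "0", "1")))
        else stats::setNames(1, keys[k, 2])
        for (na in names(wa)) for (nb in names(wb)) {
          kk <- paste(na, nb, sep = "|")
          acc[[kk]] <- (if (is.null(acc[[kk]])) 0 else acc[[kk]]) +
            p[[k]] * wa[[na]] * wb[[nb]]
        }
      }
      p <- unlist(acc)
    }
    p
  }
  keep <- !is.na(scores_a) & !is.na(scores_b)
  key <- paste(scores_a[keep], scores_b[keep], sep = "|")
  het <- function(x) x[1] != x[2]
  phased <- which(c(het(ga[[1]]) && het(gb[[1]]),
                    het(ga[[2]]) && het(gb[[2]])))
  if (!length(phased)) return(list(informative = FALSE))
  combos <- expand.grid(rep(list(c("C", "R")), length(phased)),
                        stringsAsFactors = FALSE)
  rgrid <- seq(0, 0.4999, by = 0.0005)
  tab <- table(key)
  best <- list(ll = -Inf)
  for (ci in seq_len(nrow(combos))) {
    ph <- c("C", "C"); ph[phased] <- unlist(combos[ci, ])
    ll <- vapply(rgrid, function(r) {
      p <- probs_for(ph, r)
      sum(tab * log(pmax(p[names(tab)], 1e-12)), na.rm = TRUE)
    }, 0)
    if (max(ll) > best$ll) {
      best <- list(ll = max(ll), r = rgrid[which.max(ll)])
    }
  }
  p_half <- probs_for(c("C", "C"), 0.5)
  ll_half <- sum(tab * log(pmax(p_half[names(tab)], 1e-12)), na.rm = TRUE)
  list(informative = TRUE, r_hat = best$r,
       lod = max(0, (best$ll - ll_half) / log(10)))
}
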