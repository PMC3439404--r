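#' Specification for a simulated outbred F1 mapping population
#'
#' Defaults emulate a 177-progeny full-sib family genotyped with a dominant
#' presence/absence array: ~40% of dominant markers heterozygous in both
#' parents (3:1 segregation), ~7% fully informative codominant anchor loci,
#' a genotyping (score flip) error matching a scoring concordance of 99.8%,
#' 10% missing data, and a uniform 500 kbp/cM relationship between physical
#' and genetic distance.
#'
#' @param n_progeny Number of F1 individuals (>= 2).
#' @param markers_per_chromosome Markers planted per pseudochromosome.
#' @param fraction_3to1 Fraction of dominant markers heterozygous in both
#'   parents.
#' @param fraction_codominant Fraction of markers that are fully informative
#'   codominant loci (four distinguishable genotype classes).
#' @param missing_rate Per-score probability of a missing call in progeny.
#' @param error_rate Per-score probability of a wrong call in progeny.
#' @param kbp_per_cm_truth Planted kbp/cM; scalar or one value per
#'   chromosome.
#' @param n_unanchored_markers Markers planted on unanchored scaffolds (their
#'   genetic position comes from the scaffold's latent origin).
#' @param seed Integer seed.
#' @return An object of class `cross_spec`.
#' @export
cross_spec <- function(n_progeny = 177,
                       markers_per_chromosome = 100,
                       fraction_3to1 = 0.40,
                       fraction_codominant = 0.07,
                       missing_rate = 0.10,
                       error_rate = 0.002,
                       kbp_per_cm_truth = 500,
                       n_unanchored_markers = 0,
                       seed = 1L) {
  n_progeny <- check_count(n_progeny, "n_progeny", min = 2)
  markers_per_chromosome <- check_count(markers_per_chromosome,
                                        "markers_per_chromosome", min = 1)
  check_prop(fraction_3to1, "fraction_3to1")
  check_prop(fraction_codominant, "fraction_codominant")
  check_prop(missing_rate, "missing_rate")
  check_prop(error_rate, "error_rate")
  if (any(kbp_per_cm_truth <= 0)) stop("kbp_per_cm_truth must be > 0")
  structure(list(
    n_progeny = n_progeny,
    markers_per_chromosome = markers_per_chromosome,
    fraction_3to1 = fraction_3to1,
    fraction_codominant = fraction_codominant,
    missing_rate = missing_rate,
    error_rate = error_rate,
    kbp_per_cm_truth = kbp_per_cm_truth,
    n_unanchored_markers = check_count(n_unanchored_markers,
                                       "n_unanchored_markers"),
    seed = as.integer(seed)
  ), class = "cross_spec")
}

#' Simulate gametes under a no-interference crossover process
#'
#' One meiosis per gamete: the crossover count on the chromosome is Poisson
#' with mean equal to its length in Morgans, crossover positions are uniform,
#' and the transmitted homolog at each locus follows the crossover patterns
#' (the Haldane model; recombination between loci d cM apart has probability
#' `haldane_r(d)`).
#'
#' @param pos_cm Marker positions in cM (non-negative, any order).
#' @param n Number of gametes.
#' @param length_cm Chromosome length in cM; defaults to `max(pos_cm)`.
#' @return Integer matrix `n x length(pos_cm)` of transmitted homolog
#'   indices (1 or 2).
#' @export
simulate_gametes <- function(pos_cm, n, length_cm = max(pos_cm)) {
  stopifnot(all(pos_cm >= 0), n >= 1, length_cm >= max(pos_cm))
  m <- length(pos_cm)
  out <- matrix(0L, n, m)
  for (g in seq_len(n)) {
    k <- stats::rpois(1, length_cm / 100)
    xo <- if (k > 0) stats::runif(k, 0, length_cm) else numeric(0)
    below <- if (k > 0) vapply(pos_cm, function(p) sum(xo <= p), 0) else
      rep(0, m)
    start <- sample(1:2, 1)
    out[g, ] <- 1L + (start - 1L + below) %% 2L
  }
  out
}

# Assign homolog alleles for one marker in one parent.
# Returns a character vector of length 2 (alleles on homolog 1 and 2).
parent_alleles <- function(class, parent, alleles) {
  switch(class,
    testcross_1to1_P1 = if (parent == 1) alleles else c("0", "0"),
    testcross_1to1_P2 = if (parent == 2) alleles else c("0", "0"),
    intercross_3to1 = alleles,
    fully_informative = alleles,
    stop("unknown marker class: ", class))
}

#' Simulate genotyping of an outbred F1 cross
#'
#' Plants markers along the genome, converts bp to cM through the planted
#' kbp/cM, simulates both parents' meioses with [simulate_gametes()], derives
#' dominant presence/absence scores (and codominant four-class genotypes),
#' and injects missing data and score errors at the requested rates. Parent
#' scores are emitted error-free in the first two genotype columns. Phases
#' (which homolog carries the band/allele) are drawn at random per marker and
#' recorded in the truth map.
#'
#' @param genome A `dart_genome` (sequence not required).
#' @param spec A [cross_spec()].
#' @param marker_truth Optional data.frame overriding random marker planting;
#'   columns `scaffold`, `bp`, `class` and optionally `phase_P1`, `phase_P2`
#'   (homolog index 1/2 carrying the "1" band). Used mainly in tests.
#' @return An object of class `dart_cross`: `genotypes` (character matrix,
#'   markers x individuals, columns `P1`, `P2` then progeny; codes "1"/"0"/NA
#'   for dominant markers, two-letter genotype classes for codominant ones),
#'   `markers` (truth map: marker_id, scaffold, bp, truth_chrom, truth_cm,
#'   class, phase_P1, phase_P2, reproducibility, q_score, call_rate) and
#'   `spec`.
#' @export
simulate_cross <- function(genome, spec, marker_truth = NULL) {
  stopifnot(inherits(genome, "dart_genome"), inherits(spec, "cross_spec"))
  set.seed(spec$seed)
  scf <- genome$scaffolds
  chroms <- scf$scaffold[scf$is_main]
  nchr <- length(chroms)
  kbp_cm <- rep(spec$kbp_per_cm_truth, length.out = nchr)
  names(kbp_cm) <- chroms

  if (is.null(marker_truth)) {
    mk <- do.call(rbind, lapply(seq_len(nchr), function(i) {
      L <- scf$length[scf$scaffold == chroms[i]]
      bp <- sort(floor(stats::runif(spec$markers_per_chromosome) * L))
      data.frame(scaffold = chroms[i], bp = bp, stringsAsFactors = FALSE)
    }))
    if (spec$n_unanchored_markers > 0) {
      un <- scf[!scf$is_main, , drop = FALSE]
      if (nrow(un) == 0) stop("no unanchored scaffolds to plant markers on")
      pick <- sample.int(nrow(un), spec$n_unanchored_markers, replace = TRUE)
      mk <- rbind(mk, data.frame(
        scaffold = un$scaffold[pick],
        bp = floor(stats::runif(spec$n_unanchored_markers) * un$length[pick]),
        stringsAsFactors = FALSE))
    }
    m <- nrow(mk)
    cls <- character(m)
    is_codom <- stats::runif(m) < spec$fraction_codominant
    cls[is_codom] <- "fully_informative"
    dom <- which(!is_codom)
    is31 <- stats::runif(length(dom)) < spec$fraction_3to1
    cls[dom[is31]] <- "intercross_3to1"
    rest <- dom[!is31]
    cls[rest] <- sample(c("testcross_1to1_P1", "testcross_1to1_P2"),
                        length(rest), replace = TRUE)
    mk$class <- cls
    mk$phase_P1 <- sample(1:2, m, replace = TRUE)
    mk$phase_P2 <- sample(1:2, m, replace = TRUE)
  } else {
    mk <- marker_truth
    if (is.null(mk$phase_P1)) mk$phase_P1 <- sample(1:2, nrow(mk), TRUE)
    if (is.null(mk$phase_P2)) mk$phase_P2 <- sample(1:2, nrow(mk), TRUE)
    m <- nrow(mk)
  }

  # genetic position on the chromosome of origin
  org <- match(mk$scaffold, scf$scaffold)
  mk$truth_chrom <- scf$origin_chrom[org]
  mk$truth_cm <- (scf$origin_bp[org] + mk$bp) / (1000 * kbp_cm[mk$truth_chrom])
  m <- nrow(mk)
  mk$marker_id <- sprintf("M%05d", seq_len(m))

  n <- spec$n_progeny
  geno <- matrix(NA_character_, m, n + 2)
  colnames(geno) <- c("P1", "P2", sprintf("I%03d", seq_len(n)))
  rownames(geno) <- mk$marker_id

  for (ch in chroms) {
    idx <- which(mk$truth_chrom == ch)
    if (!length(idx)) next
    idx <- idx[order(mk$truth_cm[idx])]
    pos <- mk$truth_cm[idx]
    Lcm <- scf$length[scf$scaffold == ch] / (1000 * kbp_cm[ch])
    H1 <- simulate_gametes(pos, n, max(Lcm, max(pos)))
    H2 <- simulate_gametes(pos, n, max(Lcm, max(pos)))
    for (j in seq_along(idx)) {
      i <- idx[j]
      cl <- mk$class[i]
      if (cl == "fully_informative") {
        a1 <- if (mk$phase_P1[i] == 1) c("a", "b") else c("b", "a")
        a2 <- if (mk$phase_P2[i] == 1) c("c", "d") else c("d", "c")
      } else {
        a1 <- parent_alleles(cl, 1,
                             if (mk$phase_P1[i] == 1) c("1", "0") else c("0", "1"))
        a2 <- parent_alleles(cl, 2,
                             if (mk$phase_P2[i] == 1) c("1", "0") else c("0", "1"))
      }
      al1 <- a1[H1[, j]]
      al2 <- a2[H2[, j]]
      if (cl == "fully_informative") {
        obs <- paste0(al1, al2)
        geno[i, 1] <- "ab"; geno[i, 2] <- "cd"
        if (spec$error_rate > 0) {
          err <- stats::runif(n) < spec$error_rate
          if (any(err)) {
            classes <- c("ac", "ad", "bc", "bd")
            obs[err] <- vapply(obs[err], function(o)
              sample(setdiff(classes, o), 1), character(1))
          }
        }
      } else {
        obs <- ifelse(al1 == "1" | al2 == "1", "1", "0")
        geno[i, 1] <- if (any(a1 == "1")) "1" else "0"
        geno[i, 2] <- if (any(a2 == "1")) "1" else "0"
        if (spec$error_rate > 0) {
          err <- stats::runif(n) < spec$error_rate
          obs[err] <- ifelse(obs[err] == "1", "0", "1")
        }
      }
      if (spec$missing_rate > 0) {
        obs[stats::runif(n) < spec$missing_rate] <- NA_character_
      }
      geno[i, -(1:2)] <- obs
    }
  }

  mk$reproducibility <- pmin(1, 1 - stats::rbeta(m, 1, 60))
  mk$q_score <- pmin(100, pmax(0, stats::rnorm(m, 80, 6)))
  mk$call_rate <- rowMeans(!is.na(geno[, -(1:2), drop = FALSE]))

  mk <- mk[, c("marker_id", "scaffold", "bp", "truth_chrom", "truth_cm",
               "class", "phase_P1", "phase_P2", "reproducibility",
               "q_score", "call_rate")]
  rownames(mk) <- NULL
  structure(list(genotypes = geno, markers = mk, spec = spec),
            class = "dart_cross")
}

#' @export
print.dart_cross <- function(x, ...) {
  cat("Simulated outbred F1 cross:", nrow(x$markers), "markers x",
      x$spec$n_progeny, "progeny\n")
  print(table(x$markers$class))
  invisible(x)
}
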