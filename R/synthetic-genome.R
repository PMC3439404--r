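#' Specification for a synthetic genome
#'
#' Describes a genome made of chromosome-scale pseudochromosomes plus a set of
#' small unanchored scaffolds, with gene models scattered along the
#' pseudochromosomes. Defaults emulate an 11-chromosome hardwood-tree genome:
#' the per-chromosome lengths are the physical spans (in Mbp) covered by the
#' framework map of the Eucalyptus DArT study, totalling 587.5 Mbp, with a
#' tail of small unanchored scaffolds and a gene density of ~68 models per
#' Mbp (41,204 genes over 605.8 Mbp).
#'
#' Each unanchored scaffold carries a latent "origin" (a chromosome and a
#' position on it) recorded in the truth table; markers simulated on the
#' scaffold inherit their genetic position from that origin, which is what
#' makes scaffold-anchoring recovery testable.
#'
#' @param n_chromosomes Number of pseudochromosomes.
#' @param chromosome_lengths Lengths in bp (recycled/checked against
#'   `n_chromosomes`).
#' @param n_unanchored_scaffolds Number of small unanchored scaffolds.
#' @param unanchored_length_range Length range (bp) for unanchored scaffolds.
#' @param gene_density Gene models per Mbp of pseudochromosome.
#' @param gene_length_range Gene length range in bp.
#' @param gc_fraction GC content for simulated sequence.
#' @param seed Integer seed; identical seeds give identical genomes.
#' @return An object of class `genome_spec` (a validated list).
#' @export
genome_spec <- function(n_chromosomes = 11,
                        chromosome_lengths = round(1e6 * c(
                          40.7, 63.8, 79.7, 41.1, 73.8, 50.3,
                          51.9, 68.4, 38.4, 38.6, 40.8)),
                        n_unanchored_scaffolds = 50,
                        unanchored_length_range = c(5e3, 5e4),
                        gene_density = 68,
                        gene_length_range = c(1e3, 5e3),
                        gc_fraction = 0.39,
                        seed = 1L) {
  n_chromosomes <- check_count(n_chromosomes, "n_chromosomes", min = 1)
  if (length(chromosome_lengths) != n_chromosomes) {
    stop("chromosome_lengths must have length n_chromosomes")
  }
  if (any(chromosome_lengths <= 0)) stop("chromosome lengths must be > 0")
  n_unanchored_scaffolds <- check_count(n_unanchored_scaffolds,
                                        "n_unanchored_scaffolds")
  if (length(unanchored_length_range) != 2 ||
      any(unanchored_length_range <= 0) ||
      diff(unanchored_length_range) < 0) {
    stop("unanchored_length_range must be an increasing positive interval")
  }
  if (gene_density < 0) stop("gene_density must be >= 0")
  if (length(gene_length_range) != 2 || any(gene_length_range <= 0) ||
      diff(gene_length_range) < 0) {
    stop("gene_length_range must be an increasing positive interval")
  }
  check_prop(gc_fraction, "gc_fraction")
  structure(list(
    n_chromosomes = n_chromosomes,
    chromosome_lengths = as.numeric(chromosome_lengths),
    n_unanchored_scaffolds = n_unanchored_scaffolds,
    unanchored_length_range = as.numeric(unanchored_length_range),
    gene_density = gene_density,
    gene_length_range = as.numeric(gene_length_range),
    gc_fraction = gc_fraction,
    seed = as.integer(seed)
  ), class = "genome_spec")
}

# Place `n` non-overlapping intervals of the given lengths uniformly along
# [0, L): cut the free space into n + 1 gaps at uniform break points.
place_nonoverlapping <- function(n, lengths, L) {
  if (n == 0) return(cbind(start = numeric(0), end = numeric(0)))
  total <- sum(lengths)
  while (total >= L && n > 0) {        # degenerate: too dense, drop genes
    n <- n - 1
    lengths <- lengths[seq_len(n)]
    total <- sum(lengths)
  }
  if (n == 0) return(cbind(start = numeric(0), end = numeric(0)))
  free <- L - total
  cuts <- sort(stats::runif(n, 0, free))
  starts <- floor(cuts + cumsum(c(0, lengths[-n])))
  cbind(start = starts, end = starts + lengths)
}

#' Simulate a genome with gene models and a known truth table
#'
#' Generates pseudochromosome and unanchored-scaffold sequences, a
#' non-overlapping gene-model annotation, and machine-readable truth records
#' (scaffold table including the latent origins of unanchored scaffolds, and
#' a gene table). Deterministic for a given `spec$seed`.
#'
#' @param spec A [genome_spec()].
#' @param with_sequence If `FALSE`, skip literal sequence generation and
#'   return only coordinates. Linkage-scale studies over hundreds of Mbp need
#'   coordinates, not bases; sequence-level operations (probe planting,
#'   alignment) require `TRUE`.
#' @return An object of class `dart_genome`: a list with elements
#'   `spec`, `sequences` (a [Biostrings::DNAStringSet] or `NULL`),
#'   `scaffolds` (data.frame: scaffold, length, is_main, origin_chrom,
#'   origin_bp) and `genes` (data.frame: gene_id, scaffold, start, end,
#'   strand; 0-based half-open coordinates).
#' @export
simulate_genome <- function(spec, with_sequence = TRUE) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  chrom_names <- sprintf("Chr%02d", seq_len(spec$n_chromosomes))
  scf_names <- if (spec$n_unanchored_scaffolds > 0) {
    sprintf("scaffold_%04d", seq_len(spec$n_unanchored_scaffolds))
  } else character(0)

  scf_len <- if (spec$n_unanchored_scaffolds > 0) {
    round(stats::runif(spec$n_unanchored_scaffolds,
                       spec$unanchored_length_range[1],
                       spec$unanchored_length_range[2]))
  } else numeric(0)
  origin_chrom <- if (spec$n_unanchored_scaffolds > 0) {
    sample(chrom_names, spec$n_unanchored_scaffolds, replace = TRUE)
  } else character(0)
  origin_bp <- if (spec$n_unanchored_scaffolds > 0) {
    floor(stats::runif(spec$n_unanchored_scaffolds) *
            spec$chromosome_lengths[match(origin_chrom, chrom_names)])
  } else numeric(0)

  scaffolds <- data.frame(
    scaffold = c(chrom_names, scf_names),
    length = c(spec$chromosome_lengths, scf_len),
    is_main = c(rep(TRUE, spec$n_chromosomes),
                rep(FALSE, spec$n_unanchored_scaffolds)),
    origin_chrom = c(chrom_names, origin_chrom),
    origin_bp = c(rep(0, spec$n_chromosomes), origin_bp),
    stringsAsFactors = FALSE
  )

  genes <- do.call(rbind, lapply(seq_len(spec$n_chromosomes), function(i) {
    L <- spec$chromosome_lengths[i]
    n <- stats::rpois(1, spec$gene_density * L / 1e6)
    lens <- round(stats::runif(n, spec$gene_length_range[1],
                               spec$gene_length_range[2]))
    pos <- place_nonoverlapping(n, lens, L)
    if (nrow(pos) == 0) return(NULL)
    data.frame(scaffold = chrom_names[i],
               start = pos[, "start"], end = pos[, "end"],
               strand = sample(c("+", "-"), nrow(pos), replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  if (is.null(genes)) {
    genes <- data.frame(scaffold = character(0), start = numeric(0),
                        end = numeric(0), strand = character(0),
                        stringsAsFactors = FALSE)
  }
  genes <- cbind(gene_id = if (nrow(genes)) sprintf("gene_%05d",
                                                    seq_len(nrow(genes)))
                 else character(0),
                 genes)
  rownames(genes) <- NULL

  sequences <- NULL
  if (with_sequence) {
    sequences <- Biostrings::DNAStringSet(vapply(
      scaffolds$length, random_dna, character(1), gc = spec$gc_fraction))
    names(sequences) <- scaffolds$scaffold
  }

  structure(list(spec = spec, sequences = sequences,
                 scaffolds = scaffolds, genes = genes),
            class = "dart_genome")
}

#' @export
print.dart_genome <- function(x, ...) {
  cat("Synthetic genome:", sum(x$scaffolds$is_main), "pseudochromosomes (",
      round(sum(x$scaffolds$length[x$scaffolds$is_main]) / 1e6, 1), "Mbp ),",
      sum(!x$scaffolds$is_main), "unanchored scaffolds,",
      nrow(x$genes), "gene models\n")
  invisible(x)
}

#' Plant array probes on a synthetic genome
#'
#' Extracts probe sequences from the genome with a controlled amount of
#' redundancy: a fraction `redundancy_rate` of the probes are (optionally
#' mutated) copies of earlier probes. The truth clustering and every probe's
#' source coordinates are recorded so that redundancy clustering and
#' alignment can be validated against known truth.
#'
#' @param genome A `dart_genome` with sequences.
#' @param n_probes Number of probes.
#' @param redundancy_rate Fraction of probes that are copies, in `[0, 1)`.
#' @param mutation_rate Per-base substitution probability applied to copies.
#' @param length_range Probe length range in bp (array probes are typically
#'   ~300-500 bp inserts).
#' @param seed Integer seed.
#' @param genic_fraction If non-`NULL`, this fraction of the unique probes is
#'   planted starting inside a gene model (used to calibrate gene-space
#'   statistics).
#' @param require_pst1 If `TRUE`, probes are cut between CTGCAG (PstI) sites,
#'   mirroring a PstI representation; default off.
#' @param main_only If `TRUE`, plant only on pseudochromosomes.
#' @return A list of class `dart_probes`: `sequences` (DNAStringSet),
#'   `truth` (data.frame: probe_id, scaffold, start, end, strand,
#'   truth_cluster, is_copy; 0-based half-open source coordinates on the
#'   forward strand).
#' @export
plant_probes <- function(genome, n_probes, redundancy_rate = 0,
                         mutation_rate = 0, length_range = c(300, 500),
                         seed = 1L, genic_fraction = NULL,
                         require_pst1 = FALSE, main_only = TRUE) {
  stopifnot(inherits(genome, "dart_genome"))
  if (is.null(genome$sequences)) {
    stop("genome was simulated without sequence; rerun with_sequence = TRUE")
  }
  n_probes <- check_count(n_probes, "n_probes", min = 1)
  check_prop(redundancy_rate, "redundancy_rate", allow_one = FALSE)
  check_prop(mutation_rate, "mutation_rate")
  set.seed(seed)

  scf <- genome$scaffolds
  if (main_only) scf <- scf[scf$is_main, , drop = FALSE]
  if (max(length_range) > max(scf$length)) {
    stop("length_range exceeds every candidate scaffold length")
  }
  scf <- scf[scf$length >= max(length_range), , drop = FALSE]

  n_copy <- round(n_probes * redundancy_rate)
  n_uniq <- n_probes - n_copy

  pst_sites <- NULL
  if (require_pst1) {
    pst_sites <- lapply(seq_len(nrow(scf)), function(i) {
      BiocGenerics::start(Biostrings::matchPattern(
        "CTGCAG", genome$sequences[[scf$scaffold[i]]])) - 1L
    })
  }

  draw_source <- function() {
    if (require_pst1) {
      # fragment runs from one PstI site to the end of a downstream one
      for (try in 1:50) {
        i <- sample.int(nrow(scf), 1, prob = scf$length)
        s <- pst_sites[[i]]
        if (length(s) < 2) next
        a <- sample(s, 1)
        ends <- s[s + 6 - a >= length_range[1] & s + 6 - a <= length_range[2]]
        if (!length(ends)) next
        b <- sample(rep(ends, 2), 1)  # rep() guards length-1 sample()
        return(list(scaffold = scf$scaffold[i], start = a, end = b + 6))
      }
      stop("no PstI-bounded fragment of the requested length found")
    }
    len <- round(stats::runif(1, length_range[1], length_range[2]))
    i <- sample.int(nrow(scf), 1, prob = scf$length)
    start <- floor(stats::runif(1) * (scf$length[i] - len))
    list(scaffold = scf$scaffold[i], start = start, end = start + len)
  }

  draw_genic_source <- function() {
    g <- genome$genes[genome$genes$scaffold %in% scf$scaffold, , drop = FALSE]
    if (nrow(g) == 0) return(draw_source())
    len <- round(stats::runif(1, length_range[1], length_range[2]))
    gi <- g[sample.int(nrow(g), 1), ]
    chrom_len <- scf$length[match(gi$scaffold, scf$scaffold)]
    start <- floor(stats::runif(1, gi$start, min(gi$end - 1, chrom_len - len)))
    start <- max(0, start)
    list(scaffold = gi$scaffold, start = start, end = start + len)
  }

  probe_seq <- character(n_probes)
  truth <- data.frame(probe_id = sprintf("P%05d", seq_len(n_probes)),
                      scaffold = character(n_probes),
                      start = numeric(n_probes), end = numeric(n_probes),
                      strand = character(n_probes),
                      truth_cluster = integer(n_probes),
                      is_copy = logical(n_probes), stringsAsFactors = FALSE)

  n_genic <- if (is.null(genic_fraction)) 0 else round(n_uniq * genic_fraction)
  genic_idx <- if (n_genic > 0) sample.int(n_uniq, n_genic) else integer(0)

  # unique probes are planted at pairwise disjoint loci so that the truth
  # clustering matches what sequence overlap can reveal
  used <- list()
  overlaps_used <- function(src) {
    u <- used[[src$scaffold]]
    !is.null(u) && any(src$start < u[, 2] & src$end > u[, 1])
  }

  for (i in seq_len(n_uniq)) {
    for (try in 1:200) {
      src <- if (i %in% genic_idx) draw_genic_source() else draw_source()
      if (!overlaps_used(src)) break
      if (try == 200) stop("could not place non-overlapping probes; ",
                           "reduce n_probes or enlarge the genome")
    }
    used[[src$scaffold]] <- rbind(used[[src$scaffold]],
                                  c(src$start, src$end))
    strand <- sample(c("+", "-"), 1)
    s <- substr(as.character(genome$sequences[[src$scaffold]]),
                src$start + 1, src$end)
    if (strand == "-") s <- reverse_complement_chr(s)
    probe_seq[i] <- s
    truth$scaffold[i] <- src$scaffold
    truth$start[i] <- src$start
    truth$end[i] <- src$end
    truth$strand[i] <- strand
    truth$truth_cluster[i] <- i
    truth$is_copy[i] <- FALSE
  }

  if (n_copy > 0) {
    parents <- sample.int(n_uniq, n_copy, replace = TRUE)
    for (k in seq_len(n_copy)) {
      i <- n_uniq + k
      p <- parents[k]
      s <- probe_seq[p]
      if (mutation_rate > 0) {
        bases <- strsplit(s, "")[[1]]
        hit <- which(stats::runif(length(bases)) < mutation_rate)
        for (h in hit) {
          bases[h] <- sample(setdiff(c("A", "C", "G", "T"), bases[h]), 1)
        }
        s <- paste(bases, collapse = "")
      }
      probe_seq[i] <- s
      truth$scaffold[i] <- truth$scaffold[p]
      truth$start[i] <- truth$start[p]
      truth$end[i] <- truth$end[p]
      truth$strand[i] <- truth$strand[p]
      truth$truth_cluster[i] <- p
      truth$is_copy[i] <- TRUE
    }
  }

  sequences <- Biostrings::DNAStringSet(probe_seq)
  names(sequences) <- truth$probe_id
  structure(list(sequences = sequences, truth = truth),
            class = "dart_probes")
}
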