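#' Assembly stringency parameters for probe clustering
#'
#' Four tiered presets (A1 most stringent to A4 most relaxed) mirror the
#' assembler settings used to de-replicate array probe libraries. All presets
#' share a minimum overlap of 50 bp and a minimum overlap identity of 98%.
#'
#' @param preset One of "A1".."A4", or `NULL` to specify fields directly.
#' @param word_length Minimum exact word match (bp) required to consider a
#'   pair.
#' @param index_word_length K-mer size used to index sequences for candidate
#'   lookup.
#' @param max_mismatch_pct Maximum mismatches as percent of the overlap.
#' @param max_ambiguities Maximum ambiguity codes tolerated as matches.
#' @param max_gap_pct Maximum gapped columns as percent of the overlap.
#' @param max_gap_size Maximum size of a single gap (bp).
#' @param min_overlap Minimum overlap (bp, fixed 50 in the presets).
#' @param min_overlap_identity Minimum identity in the overlap (fixed 0.98).
#' @return An object of class `assembly_params`.
#' @export
assembly_params <- function(preset = NULL, word_length = 18,
                            index_word_length = 13, max_mismatch_pct = 10,
                            max_ambiguities = 4, max_gap_pct = 10,
                            max_gap_size = 1, min_overlap = 50,
                            min_overlap_identity = 0.98) {
  if (!is.null(preset)) {
    presets <- list(
      A1 = list(18, 13, 10, 4, 10, 1),
      A2 = list(14, 12, 15, 4, 15, 2),
      A3 = list(12, 11, 20, 16, 20, 5),
      A4 = list(10, 10, 20, 16, 20, 5))
    if (!preset %in% names(presets)) stop("preset must be one of A1..A4")
    p <- presets[[preset]]
    word_length <- p[[1]]; index_word_length <- p[[2]]
    max_mismatch_pct <- p[[3]]; max_ambiguities <- p[[4]]
    max_gap_pct <- p[[5]]; max_gap_size <- p[[6]]
  }
  if (word_length < index_word_length) {
    stop("word_length must be >= index_word_length")
  }
  structure(list(preset = preset %||% "custom", word_length = word_length,
                 index_word_length = index_word_length,
                 max_mismatch_pct = max_mismatch_pct,
                 max_ambiguities = max_ambiguities,
                 max_gap_pct = max_gap_pct, max_gap_size = max_gap_size,
                 min_overlap = min_overlap,
                 min_overlap_identity = min_overlap_identity),
            class = "assembly_params")
}

# K-mer index: named list kmer -> sequence indices (uppercase ACGT only).
kmer_index <- function(seqs, k) {
  env <- new.env(parent = emptyenv(), size = 4 * length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    n <- nchar(s)
    if (n < k) next
    kmers <- unique(substring(s, 1:(n - k + 1), k:n))
    kmers <- kmers[!grepl("[^ACGT]", kmers)]
    for (km in kmers) env[[km]] <- c(env[[km]], i)
  }
  env
}

# Candidate pairs sharing index words in either orientation. A qualifying
# 50 bp / 98% identity overlap shares dozens of index words, so requiring a
# handful (3) discards the random single-word collisions that dominate at
# short word lengths without losing any mergeable pair.
candidate_pairs <- function(fwd, rev, k, min_shared = 3) {
  idx <- kmer_index(fwd, k)
  pairs <- list()
  add_hits <- function(query_seqs, i, orient) {
    s <- query_seqs[i]
    n <- nchar(s)
    if (n < k) return()
    kmers <- unique(substring(s, 1:(n - k + 1), k:n))
    all_hits <- unlist(mget(kmers, envir = idx, ifnotfound = list(NULL)))
    all_hits <- all_hits[all_hits < i]
    if (!length(all_hits)) return()
    counts <- table(all_hits)
    hits <- as.integer(names(counts)[counts >= min_shared])
    if (length(hits)) {
      pairs[[length(pairs) + 1]] <<- cbind(hits, i, orient)
    }
  }
  for (i in seq_along(fwd)) {
    add_hits(fwd, i, 1L)
    add_hits(rev, i, 2L)
  }
  if (!length(pairs)) return(matrix(integer(0), 0, 3))
  out <- unique(do.call(rbind, pairs))
  colnames(out) <- c("a", "b", "orient")
  out
}

# Decide whether an overlap alignment of two sequences satisfies the
# assembly parameters. Returns TRUE/FALSE.
overlap_merges <- function(sa, sb, params) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(sa), Biostrings::DNAString(sb),
    type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = FALSE),
    gapOpening = 4, gapExtension = 2)
  pa <- as.character(Biostrings::alignedPattern(al))
  pb <- as.character(Biostrings::alignedSubject(al))
  n <- nchar(pa)
  if (n < params$min_overlap) return(FALSE)
  ca <- strsplit(pa, "")[[1]]
  cb <- strsplit(pb, "")[[1]]
  gap_a <- ca == "-"
  gap_b <- cb == "-"
  gapped <- gap_a | gap_b
  amb <- !gapped & (!(ca %in% c("A", "C", "G", "T")) |
                      !(cb %in% c("A", "C", "G", "T")))
  same <- !gapped & ca == cb
  n_amb_ok <- min(sum(amb), params$max_ambiguities)
  mism <- sum(!gapped & !same & !amb) + max(0, sum(amb) - params$max_ambiguities)
  ident <- (sum(same) + n_amb_ok) / n
  # gap runs and sizes
  runs <- rle(gapped)
  gap_runs <- runs$lengths[runs$values]
  if (ident < params$min_overlap_identity) return(FALSE)
  if (mism > params$max_mismatch_pct / 100 * n) return(FALSE)
  if (sum(gapped) > params$max_gap_pct / 100 * n) return(FALSE)
  if (length(gap_runs) && max(gap_runs) > params$max_gap_size) return(FALSE)
  # require an exact word of the configured length inside the overlap
  match_runs <- rle(same)
  longest <- if (any(match_runs$values)) {
    max(match_runs$lengths[match_runs$values])
  } else 0
  longest >= params$word_length
}

#' Cluster probe sequences by overlap identity
#'
#' Candidate pairs are found through shared exact index words (both
#' orientations), verified by banded overlap alignment against the preset's
#' overlap, identity, mismatch and gap rules, and merged clusters are the
#' transitive closure of accepted pairs. Consensus sequences are not built:
#' only cluster membership feeds the redundancy accounting.
#'
#' @param probes A `dart_probes` object, [Biostrings::DNAStringSet], or
#'   character vector of sequences.
#' @param params An [assembly_params()].
#' @return Integer vector of cluster ids (one per probe, named).
#' @export
cluster_probes <- function(probes, params = assembly_params("A1")) {
  seqs <- if (inherits(probes, "dart_probes")) {
    as.character(probes$sequences)
  } else if (methods::is(probes, "DNAStringSet")) {
    as.character(probes)
  } else {
    stats::setNames(as.character(probes), names(probes))
  }
  if (length(seqs) < 1) stop("at least one probe required")
  if (any(nchar(seqs) == 0)) stop("empty probe sequence")
  if (is.null(names(seqs))) names(seqs) <- sprintf("P%05d", seq_along(seqs))
  fwd <- toupper(seqs)
  rev <- vapply(fwd, reverse_complement_chr, character(1))

  cand <- candidate_pairs(fwd, rev, params$index_word_length)
  parent <- seq_along(seqs)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(cand))) {
    a <- cand[k, 1]; b <- cand[k, 2]
    if (find(a) == find(b)) next          # already merged transitively
    sb <- if (cand[k, 3] == 1L) fwd[b] else rev[b]
    if (overlap_merges(fwd[a], sb, params)) {
      parent[find(a)] <- find(b)
    }
  }
  roots <- vapply(seq_along(seqs), find, 0L)
  cl <- match(roots, unique(roots))
  names(cl) <- names(seqs)
  cl
}

#' Redundancy accounting for a probe clustering
#'
#' @param clustering Integer cluster ids per probe (from [cluster_probes()]),
#'   or a list with counts `n_total`, `n_singletons`, `n_clusters` (used to
#'   reproduce published accounting tables).
#' @return Object of class `redundancy_report`: `n_total`, `n_singletons`,
#'   `n_redundant_members`, `n_clusters`, `n_unique_loci`,
#'   `redundancy_rate` (percent, full precision) and
#'   `redundancy_rate_2dp` (truncated to 2 decimals, the convention of
#'   published accounting tables).
#' @export
redundancy_report <- function(clustering) {
  if (is.list(clustering) && !is.null(clustering$n_total)) {
    n_total <- clustering$n_total
    n_singletons <- clustering$n_singletons
    n_clusters <- clustering$n_clusters
    n_redundant <- n_total - n_singletons
  } else {
    sizes <- table(clustering)
    n_total <- length(clustering)
    n_singletons <- sum(sizes == 1)
    n_clusters <- sum(sizes > 1)
    n_redundant <- sum(sizes[sizes > 1])
  }
  n_unique <- n_singletons + n_clusters
  rate <- 100 * (n_total - n_unique) / n_total
  structure(list(n_total = n_total, n_singletons = n_singletons,
                 n_redundant_members = n_redundant, n_clusters = n_clusters,
                 n_unique_loci = n_unique, redundancy_rate = rate,
                 redundancy_rate_2dp = trunc_dp(rate, 2)),
            class = "redundancy_report")
}

#' @export
print.redundancy_report <- function(x, ...) {
  cat(sprintf(paste0("Redundancy: %d sequences = %d singletons + %d in %d",
                     " clusters\n  unique loci %d, redundancy %.2f%%\n"),
              x$n_total, x$n_singletons, x$n_redundant_members,
              x$n_clusters, x$n_unique_loci, x$redundancy_rate_2dp))
  invisible(x)
}

#' Extrapolate unique loci to the full array
#'
#' Assumes the unsequenced probes carry the same redundancy as the sequenced
#' ones: `floor(array_size * n_unique_loci / n_total)`.
#'
#' @param array_size Total probes on the array (`>= report$n_total`).
#' @param report A [redundancy_report()].
#' @return Integer count of unique loci expected for the whole array.
#' @export
extrapolate_unique_loci <- function(array_size, report) {
  stopifnot(inherits(report, "redundancy_report"))
  if (report$n_total == 0) stop("report covers no sequences")
  if (array_size < report$n_total) {
    stop("array_size must be at least the number of sequenced probes")
  }
  as.integer(floor(array_size * report$n_unique_loci / report$n_total))
}
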