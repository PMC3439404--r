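#' Alignment scoring parameters
#'
#' Affine-gap local alignment scoring used both by the built-in aligner and
#' to interpret external aligner scores: match award a, mismatch penalty b,
#' gap open q, gap extension r (score = a*matches - b*mismatches -
#' sum(q + r*gaplen)). Defaults a=1, b=3, q=5, r=2.
#'
#' @param match_award,mismatch_penalty,gap_open,gap_extend Non-negative
#'   scoring constants.
#' @param threshold_t Retention threshold T; `NULL` means compute it from the
#'   probe length distribution with [compute_threshold()].
#' @return Object of class `scoring_params`.
#' @export
scoring_params <- function(match_award = 1, mismatch_penalty = 3,
                           gap_open = 5, gap_extend = 2,
                           threshold_t = NULL) {
  stopifnot(match_award >= 0, mismatch_penalty >= 0, gap_open >= 0,
            gap_extend >= 0)
  structure(list(match_award = match_award,
                 mismatch_penalty = mismatch_penalty,
                 gap_open = gap_open, gap_extend = gap_extend,
                 threshold_t = threshold_t),
            class = "scoring_params")
}

#' Score threshold from the probe length distribution
#'
#' T = ceiling(2 * median(5.5 * ln(L))) over the probe lengths L. The natural
#' logarithm reproduces the conventional fixed threshold T = 70 at the
#' typical ~534 bp probe length (2 * 5.5 * ln(534) = 69.08); see the methods
#' vignette for why log10 is ruled out.
#'
#' @param probe_lengths Probe lengths in bp, all > 1.
#' @return Integer threshold T.
#' @export
compute_threshold <- function(probe_lengths) {
  if (!length(probe_lengths) || any(probe_lengths <= 1)) {
    stop("probe lengths must all be > 1")
  }
  as.integer(ceiling(2 * stats::median(5.5 * log(probe_lengths))))
}

#' Retain alignment hits within T of the best score
#'
#' Keeps the best hit plus any hit scoring within `T` of it. A probe is a
#' "successful mapping" when at most two hits survive; more than two retained
#' hits mark the probe `ambiguous` (unsuccessful mapping), no hits mark it
#' `unmapped`.
#'
#' @param hits data.frame of hits for one probe: columns `scaffold`, `start`,
#'   `end`, `strand`, `score` (`is_main` optional). Sorted internally.
#' @param threshold_t Score window T.
#' @return list: `status` ("ok", "ambiguous" or "unmapped"), `hits` (the
#'   retained hits, best first; for "ambiguous" all retained hits are kept
#'   for inspection). Idempotent: re-applying to retained hits returns them
#'   unchanged.
#' @export
retain_hits <- function(hits, threshold_t) {
  if (is.null(hits) || nrow(hits) == 0) {
    return(list(status = "unmapped", hits = hits))
  }
  hits <- hits[order(-hits$score), , drop = FALSE]
  keep <- hits$score >= hits$score[1] - threshold_t
  retained <- hits[keep, , drop = FALSE]
  status <- if (nrow(retained) > 2) "ambiguous" else "ok"
  list(status = status, hits = retained)
}

#' Classify a probe placement from its retained hits
#'
#' Zero hits are `unmapped`; one hit, or two hits whose intervals overlap the
#' same locus, are `unique_locus`; two non-overlapping hits on the same
#' scaffold are `tandem_proximal` (gap < 1 kb), `same_scaffold_distal`
#' (1-10 kb) or `same_scaffold_far` (> 10 kb); hits on different scaffolds
#' are `multi_chromosome` when both are main pseudochromosomes, otherwise
#' `multi_with_unanchored`. The inter-hit distance is the gap between the
#' nearest interval ends.
#'
#' @param retained Output of [retain_hits()] (or a list with `status` and
#'   `hits`). Hits need a logical `is_main` column for the multi-scaffold
#'   classes.
#' @param probe_id Identifier carried into the result.
#' @return One-row data.frame: `probe_id`, `status`, `scaffold`, `start`,
#'   `end`, `strand`, `score`, `scaffold2`, `start2`, `end2`,
#'   `inter_hit_distance`.
#' @export
classify_placement <- function(retained, probe_id = NA_character_) {
  status <- retained$status
  hits <- retained$hits
  empty <- data.frame(probe_id = probe_id, status = "unmapped",
                      scaffold = NA_character_, start = NA_real_,
                      end = NA_real_, strand = NA_character_,
                      score = NA_real_, scaffold2 = NA_character_,
                      start2 = NA_real_, end2 = NA_real_,
                      inter_hit_distance = NA_real_, stringsAsFactors = FALSE)
  if (status == "unmapped" || is.null(hits) || nrow(hits) == 0) return(empty)
  if (status == "ambiguous") {
    out <- empty
    out$status <- "ambiguous"
    out$scaffold <- hits$scaffold[1]; out$start <- hits$start[1]
    out$end <- hits$end[1]; out$strand <- hits$strand[1]
    out$score <- hits$score[1]
    return(out)
  }
  if (nrow(hits) > 2) stop("more than two hits: pass through retain_hits()")
  out <- empty
  out$status <- "unique_locus"
  out$scaffold <- hits$scaffold[1]; out$start <- hits$start[1]
  out$end <- hits$end[1]; out$strand <- hits$strand[1]
  out$score <- hits$score[1]
  if (nrow(hits) == 1) return(out)

  h1 <- hits[1, ]; h2 <- hits[2, ]
  out$scaffold2 <- h2$scaffold; out$start2 <- h2$start; out$end2 <- h2$end
  if (h1$scaffold == h2$scaffold) {
    gap <- max(h1$start, h2$start) - min(h1$end, h2$end)
    if (gap <= 0) {
      out$status <- "unique_locus"      # overlapping: same locus
      out$inter_hit_distance <- 0
    } else {
      out$inter_hit_distance <- gap
      out$status <- if (gap < 1000) "tandem_proximal"
        else if (gap > 10000) "same_scaffold_far"
        else "same_scaffold_distal"
    }
  } else {
    main1 <- isTRUE(h1$is_main); main2 <- isTRUE(h2$is_main)
    out$status <- if (main1 && main2) "multi_chromosome"
      else "multi_with_unanchored"
  }
  out
}

#' Mapping reliability from placement statuses
#'
#' @param placements data.frame with a `status` column (from
#'   [classify_placement()] rows), covering all evaluated probes.
#' @return list: `n_evaluated`, `n_ambiguous`, `error_rate` (ambiguous /
#'   evaluated, reported to 3 decimals), `reliability` (1 - error_rate).
#' @export
mapping_reliability <- function(placements) {
  evaluated <- placements$status != "unmapped"
  n <- sum(evaluated)
  if (n == 0) stop("no evaluated placements")
  amb <- sum(placements$status == "ambiguous")
  rate <- round(amb / n, 3)
  list(n_evaluated = n, n_ambiguous = amb, error_rate = rate,
       reliability = 1 - rate)
}

# Locate exact occurrences of a seed k-mer across all scaffolds.
# Returns matrix with columns si (scaffold index) and pos (1-based start).
seed_matches <- function(seed, sequences) {
  hits <- Biostrings::vmatchPattern(seed, sequences)
  out <- do.call(rbind, lapply(seq_along(hits), function(si) {
    s <- BiocGenerics::start(hits[[si]])
    if (!length(s)) return(NULL)
    cbind(si = si, pos = s)
  }))
  out
}

#' Seed-and-extend local alignment of probes to a genome
#'
#' A deliberately simple aligner for synthetic-scale data: exact k-mer seeds
#' (default k = 15) on both strands locate candidate windows, which are
#' extended by affine-gap local alignment under [scoring_params()]
#' (score = a*matches - b*mismatches - sum(q + r*gaplen)); hits scoring below
#' the retention threshold are discarded and overlapping window hits are
#' collapsed to the best-scoring one.
#'
#' @param probes `dart_probes`, DNAStringSet or named character vector.
#' @param genome `dart_genome` with sequences (or a DNAStringSet).
#' @param params [scoring_params()]; if `threshold_t` is `NULL` it is
#'   computed from the probe lengths.
#' @param k Seed length.
#' @return data.frame of hits: `probe_id`, `scaffold`, `start`, `end`
#'   (0-based half-open), `strand`, `score`, `is_main`.
#' @export
naive_align <- function(probes, genome, params = scoring_params(), k = 15) {
  seqs <- if (inherits(probes, "dart_probes")) {
    as.character(probes$sequences)
  } else {
    stats::setNames(as.character(probes), names(probes))
  }
  if (is.null(names(seqs))) names(seqs) <- sprintf("P%05d", seq_along(seqs))
  gseq <- if (inherits(genome, "dart_genome")) genome$sequences else genome
  if (is.null(gseq)) stop("genome has no sequences")
  is_main <- if (inherits(genome, "dart_genome")) {
    stats::setNames(genome$scaffolds$is_main, genome$scaffolds$scaffold)
  } else stats::setNames(rep(TRUE, length(gseq)), names(gseq))

  thr <- params$threshold_t %||% compute_threshold(nchar(seqs))
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match_award, mismatch = -params$mismatch_penalty,
    baseOnly = TRUE)
  gnames <- names(gseq)
  glens <- vapply(seq_along(gseq), function(i) length(gseq[[i]]), 0L)

  out <- list()
  for (pi in seq_along(seqs)) {
    plen <- nchar(seqs[pi])
    if (plen < k) next
    for (strand in c("+", "-")) {
      q <- if (strand == "+") seqs[pi] else reverse_complement_chr(seqs[pi])
      # a handful of spread-out seeds suffices to anchor candidate windows
      pick <- unique(pmax(1L, pmin(plen - k + 1L,
                                   round(seq(1, plen - k + 1, length.out = 5)))))
      seed_hits <- do.call(rbind, lapply(pick, function(j) {
        seed <- substr(q, j, j + k - 1L)
        if (grepl("[^ACGT]", seed)) return(NULL)
        h <- seed_matches(seed, gseq)
        if (is.null(h)) return(NULL)
        cbind(h, diag = h[, "pos"] - j)  # diagonal = genome pos - probe pos
      }))
      if (is.null(seed_hits)) next
      # merge seeds into windows per scaffold with nearby diagonals
      windows <- unique(data.frame(
        si = seed_hits[, 1],
        diag = round(seed_hits[, 3] / 50) * 50))
      for (w in seq_len(nrow(windows))) {
        si <- windows$si[w]
        lo <- max(1L, windows$diag[w] - 60L)
        hi <- min(glens[si], windows$diag[w] + plen + 60L + 50L)
        if (hi - lo + 1 < k) next
        window_seq <- Biostrings::subseq(gseq[[si]], lo, hi)
        al <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(q), window_seq, type = "local",
          substitutionMatrix = submat,
          gapOpening = params$gap_open, gapExtension = params$gap_extend)
        sc <- Biostrings::score(al)
        if (sc < thr) next
        sstart <- lo - 1L + BiocGenerics::start(Biostrings::subject(al)) - 1L
        send <- lo - 1L + BiocGenerics::end(Biostrings::subject(al))
        out[[length(out) + 1]] <- data.frame(
          probe_id = names(seqs)[pi], scaffold = gnames[si],
          start = sstart, end = send, strand = strand, score = sc,
          is_main = unname(is_main[gnames[si]]), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(probe_id = character(0), scaffold = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0), score = numeric(0),
                      is_main = logical(0), stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, out)
  # collapse overlapping hits of the same probe/scaffold to the best one
  hits <- hits[order(hits$probe_id, hits$scaffold, -hits$score), ,
               drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))[-1]) {
    j <- which(keep[seq_len(i - 1)])
    same <- hits$probe_id[j] == hits$probe_id[i] &
      hits$scaffold[j] == hits$scaffold[i] &
      hits$start[j] < hits$end[i] & hits$end[j] > hits$start[i]
    if (any(same)) keep[i] <- FALSE
  }
  hits <- hits[keep, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Read probe alignment hits from a SAM file
#'
#' Primary and secondary alignments are read (via Rsamtools), their `AS`
#' score tags extracted, and 1-based SAM coordinates converted to the
#' package's 0-based half-open convention.
#'
#' @param sam_path Path to a SAM (or BAM) file.
#' @param main_scaffolds Character vector naming the scaffolds to flag as
#'   main pseudochromosomes (`is_main`); default: all.
#' @return data.frame of hits as in [naive_align()].
#' @export
read_sam_hits <- function(sam_path, main_scaffolds = NULL) {
  bam <- sam_path
  if (grepl("\\.sam$", sam_path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(sam_path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "cigar"), tag = "AS")
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  ok <- !is.na(x$pos)
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(x$cigar[ok])
  rname <- as.character(x$rname[ok])
  score <- x$tag$AS[ok]
  if (is.null(score)) score <- rep(NA_real_, sum(ok))
  is_main <- if (is.null(main_scaffolds)) rep(TRUE, sum(ok)) else
    rname %in% main_scaffolds
  data.frame(probe_id = x$qname[ok], scaffold = rname,
             start = x$pos[ok] - 1L, end = x$pos[ok] - 1L + width,
             strand = as.character(x$strand[ok]), score = score,
             is_main = is_main, stringsAsFactors = FALSE)
}

#' Classify all probes from a hit table
#'
#' Applies [retain_hits()] and [classify_placement()] per probe.
#'
#' @param hits Hit table ([naive_align()] / [read_sam_hits()]).
#' @param threshold_t Retention window T, or a [scoring_params()] carrying
#'   `threshold_t`.
#' @param probe_ids Probes evaluated (defaults to those present in `hits`;
#'   pass the full probe set to count unmapped probes).
#' @return data.frame of placements, one row per probe.
#' @export
classify_hits <- function(hits, threshold_t, probe_ids = NULL) {
  if (inherits(threshold_t, "scoring_params")) {
    threshold_t <- threshold_t$threshold_t
  }
  stopifnot(is.numeric(threshold_t))
  ids <- probe_ids %||% unique(hits$probe_id)
  out <- lapply(ids, function(id) {
    h <- hits[hits$probe_id == id, , drop = FALSE]
    classify_placement(retain_hits(h, threshold_t), probe_id = id)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
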