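# Gene-space statistics: fixed-width genome bins, per-bin feature counts,
# rank correlations and nearest-gene distances.

#' Partition chromosomes into fixed-width bins
#'
#' Half-open bins `[start, start + width)` tile each chromosome exactly; the
#' last bin is truncated at the chromosome end. The conventional width is
#' 5 Mbp.
#'
#' @param chromosome_lengths Named vector of chromosome lengths (bp).
#' @param width Bin width in bp (default 5e6).
#' @return data.frame: `chromosome`, `bin` (1-based index within
#'   chromosome), `start`, `end` (0-based half-open).
#' @export
make_bins <- function(chromosome_lengths, width = 5e6) {
  if (width <= 0) stop("width must be > 0")
  if (any(chromosome_lengths <= 0)) stop("chromosome lengths must be > 0")
  if (is.null(names(chromosome_lengths))) {
    names(chromosome_lengths) <- sprintf("Chr%02d",
                                         seq_along(chromosome_lengths))
  }
  out <- do.call(rbind, lapply(names(chromosome_lengths), function(ch) {
    L <- chromosome_lengths[[ch]]
    n <- ceiling(L / width)
    start <- (seq_len(n) - 1) * width
    data.frame(chromosome = ch, bin = seq_len(n), start = start,
               end = pmin(start + width, L), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Count features per bin
#'
#' Each feature is assigned to the bin containing its start coordinate
#' (half-open bins, so a feature starting exactly on a boundary counts in
#' the downstream bin); totals are conserved. Features beyond the chromosome
#' end raise an error.
#'
#' @param bins Bin table from [make_bins()].
#' @param ... Named position tables, each a data.frame with columns
#'   `chromosome` (or `scaffold`) and `start` (or `bp`), e.g.
#'   `probes = `, `markers = `, `genes = `.
#' @return The bin table with one count column (`n_<name>`) per supplied
#'   table.
#' @export
count_features <- function(bins, ...) {
  feats <- list(...)
  stopifnot(length(feats) > 0, !is.null(names(feats)))
  ends <- tapply(bins$end, bins$chromosome, max)
  for (nm in names(feats)) {
    f <- feats[[nm]]
    chrom <- f$chromosome %||% f$scaffold
    pos <- f$start %||% f$bp
    keep <- chrom %in% bins$chromosome
    chrom <- chrom[keep]; pos <- pos[keep]
    if (any(pos < 0 | pos >= ends[chrom])) {
      stop("feature position beyond chromosome end in '", nm, "'")
    }
    counts <- integer(nrow(bins))
    for (ch in unique(chrom)) {
      b <- bins$chromosome == ch
      sel <- chrom == ch
      i <- findInterval(pos[sel], bins$start[b])
      tab <- tabulate(i, nbins = sum(b))
      counts[b] <- tab
    }
    bins[[paste0("n_", nm)]] <- counts
  }
  bins
}

#' Spearman rank correlation between two per-bin count vectors
#'
#' Mid-rank ties, p-value from the t approximation. Constant vectors give
#' `rho = NA` with a reason.
#'
#' @param counts_a,counts_b Equal-length numeric vectors (n >= 4).
#' @return list: `rho`, `p_value`, `n_bins` (and `reason` when undefined).
#' @export
bin_correlation <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == length(counts_b))
  n <- length(counts_a)
  if (n < 4) stop("need at least 4 bins")
  if (length(unique(counts_a)) == 1 || length(unique(counts_b)) == 1) {
    return(list(rho = NA_real_, p_value = NA_real_, n_bins = n,
                reason = "constant count vector"))
  }
  rho <- stats::cor(counts_a, counts_b, method = "spearman")
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(rho = rho, p_value = p, n_bins = n)
}

#' Distance from each probe position to the closest gene model
#'
#' Distance is 0 when the probe interval overlaps any gene model, otherwise
#' the gap between the closest interval ends of the nearest gene on the same
#' chromosome (strand ignored). Probes on chromosomes without any gene model
#' are excluded and counted. Probes with two retained placements contribute
#' one distance per placement.
#'
#' @param placements data.frame with `chromosome`/`scaffold`, `start`, `end`
#'   (bp, 0-based half-open). One row per placement position.
#' @param genes data.frame with `scaffold`/`chromosome`, `start`, `end`.
#' @param edges Distance class edges in bp; the default classes are 0,
#'   (0, 1 kbp], (1, 5], (5, 10], > 10 kbp.
#' @return Object of class `gene_distance_report`: `distances` (per
#'   placement, bp), `n_excluded` (placements on gene-less chromosomes),
#'   `classes` (data.frame: class, n, proportion; proportions sum to 1).
#' @export
nearest_gene_distances <- function(placements, genes,
                                   edges = c(0, 1e3, 5e3, 1e4)) {
  pchrom <- placements$chromosome %||% placements$scaffold
  gchrom <- genes$chromosome %||% genes$scaffold
  pstart <- placements$start; pend <- placements$end %||% placements$start
  ok <- pchrom %in% gchrom
  n_excl <- sum(!ok)
  d <- rep(NA_real_, sum(ok))
  pc <- pchrom[ok]; ps <- pstart[ok]; pe <- pend[ok]
  for (ch in unique(pc)) {
    gi <- gchrom == ch
    gr <- IRanges::IRanges(start = genes$start[gi] + 1, end = genes$end[gi])
    sel <- pc == ch
    pr <- IRanges::IRanges(start = ps[sel] + 1, end = pmax(pe[sel], ps[sel] + 1))
    hit <- IRanges::distanceToNearest(pr, gr)
    dd <- rep(NA_real_, sum(sel))
    dd[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
    d[sel] <- dd
  }
  breaks <- c(-0.5, 0.5, edges[-1], Inf)
  labels <- c("0",
              sprintf("(%g,%g]", edges[-length(edges)] / 1e3,
                      edges[-1] / 1e3),
              sprintf(">%g", edges[length(edges)] / 1e3))
  cls <- cut(d, breaks = breaks, labels = labels)
  tab <- table(cls)
  classes <- data.frame(class = names(tab), n = as.integer(tab),
                        proportion = as.numeric(tab) / length(d),
                        stringsAsFactors = FALSE)
  structure(list(distances = d, n_excluded = n_excl, classes = classes),
            class = "gene_distance_report")
}

#' @export
print.gene_distance_report <- function(x, ...) {
  cat("Nearest-gene distances for", length(x$distances), "placements (",
      x$n_excluded, "excluded, no genes on scaffold )\n")
  print(x$classes, digits = 3)
  invisible(x)
}
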