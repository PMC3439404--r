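# Integration of the genetic (linkage) map with physical placements:
# collinearity, kbp/cM ratios, genome coverage, scaffold anchoring and
# full-vs-framework map comparison.

# Join a linkage group's markers with their physical placements on the
# group's majority chromosome. Returns data.frame(marker_id, position_cm,
# scaffold, bp) or NULL.
group_placements <- function(group, placements) {
  gm <- group$markers
  pl <- placements[match(gm$marker_id, placements$marker_id), , drop = FALSE]
  ok <- !is.na(pl$scaffold)
  if (!any(ok)) return(NULL)
  maj <- names(sort(table(pl$scaffold[ok]), decreasing = TRUE))[1]
  sel <- ok & pl$scaffold == maj
  data.frame(marker_id = gm$marker_id[sel],
             position_cm = gm$position_cm[sel],
             scaffold = maj, bp = pl$bp[sel], stringsAsFactors = FALSE)
}

#' Collinearity between genetic and physical marker order
#'
#' Orientation-corrected Spearman correlation between cM rank and bp rank of
#' the markers of each linkage group that are placed on the group's majority
#' chromosome, with a leave-one-out list of discordant markers (those whose
#' removal most improves the rank agreement).
#'
#' @param group A `linkage_group`.
#' @param placements data.frame with columns `marker_id`, `scaffold`, `bp`
#'   (physical positions; see [placements_from_truth()] or
#'   [classify_hits()]).
#' @return list: `group_id`, `chromosome`, `n`, `rho` (absolute Spearman; NA
#'   with `reason` when fewer than 3 shared markers), `discordant`
#'   (data.frame marker_id, rho_without, improvement).
#' @export
collinearity <- function(group, placements) {
  gp <- group_placements(group, placements)
  if (is.null(gp) || nrow(gp) < 3) {
    return(list(group_id = group$group_id, chromosome = gp$scaffold[1] %||%
                  NA_character_, n = if (is.null(gp)) 0 else nrow(gp),
                rho = NA_real_, reason = "fewer than 3 shared markers",
                discordant = NULL))
  }
  rho <- abs(stats::cor(gp$position_cm, gp$bp, method = "spearman"))
  loo <- vapply(seq_len(nrow(gp)), function(i) {
    abs(stats::cor(gp$position_cm[-i], gp$bp[-i], method = "spearman"))
  }, 0)
  imp <- loo - rho
  disc <- data.frame(marker_id = gp$marker_id, rho_without = loo,
                     improvement = imp, stringsAsFactors = FALSE)
  disc <- disc[disc$improvement > 0, , drop = FALSE]
  disc <- disc[order(-disc$improvement), , drop = FALSE]
  list(group_id = group$group_id, chromosome = gp$scaffold[1],
       n = nrow(gp), rho = rho, reason = NULL, discordant = disc)
}

#' Physical-to-genetic distance ratios per chromosome
#'
#' For each linkage group with at least two markers placed on its majority
#' chromosome: physical span (max - min bp of the placed markers), genetic
#' span (cM span of the same markers) and their ratio in kbp/cM. The
#' genome-wide mean is the unweighted arithmetic mean of the per-chromosome
#' ratios and the sd uses the n-1 denominator.
#'
#' @param map A `dart_linkage_map` (or list of `linkage_group`).
#' @param placements As in [collinearity()].
#' @return Object of class `ratio_report`: `per_chromosome` (data.frame:
#'   group, chromosome, n_markers, physical_span_mbp, genetic_span_cm,
#'   kbp_per_cm), `genome_mean`, `genome_sd`.
#' @export
kbp_per_cm <- function(map, placements) {
  groups <- if (inherits(map, "dart_linkage_map")) map$groups else map
  rows <- lapply(groups, function(g) {
    gp <- group_placements(g, placements)
    if (is.null(gp) || nrow(gp) < 2) return(NULL)
    phys <- (max(gp$bp) - min(gp$bp)) / 1e6
    gen <- max(gp$position_cm) - min(gp$position_cm)
    data.frame(group = g$group_id, chromosome = gp$scaffold[1],
               n_markers = nrow(gp), physical_span_mbp = phys,
               genetic_span_cm = gen,
               kbp_per_cm = if (gen > 0) 1000 * phys / gen else NA_real_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  ratios <- per$kbp_per_cm[!is.na(per$kbp_per_cm)]
  structure(list(per_chromosome = per,
                 genome_mean = mean(ratios),
                 genome_sd = if (length(ratios) > 1) stats::sd(ratios)
                 else NA_real_),
            class = "ratio_report")
}

#' @export
print.ratio_report <- function(x, ...) {
  print(x$per_chromosome, digits = 4)
  cat(sprintf("genome-wide: %.1f +/- %.1f kbp/cM\n", x$genome_mean,
              x$genome_sd))
  invisible(x)
}

#' Genome coverage percentage of the mapped physical spans
#'
#' @param physical_spans_mbp Per-chromosome physical spans covered (Mbp).
#' @param assembled_total_mbp Total assembled length (Mbp).
#' @return list: `percent` (full precision), `percent_rounded` (nearest
#'   integer, the headline figure).
#' @export
coverage_percent <- function(physical_spans_mbp, assembled_total_mbp) {
  if (assembled_total_mbp <= 0) stop("assembled total must be > 0")
  pct <- 100 * sum(physical_spans_mbp) / assembled_total_mbp
  list(percent = pct, percent_rounded = round(pct))
}

#' Assign unanchored scaffolds to linkage groups
#'
#' Every unanchored scaffold carrying at least one linkage-mapped marker is
#' assigned the group of its markers; scaffolds whose markers span more than
#' one group are flagged as conflicts and left unassigned.
#'
#' @param map A `dart_linkage_map` (typically the full map, to maximize the
#'   marker count) or its [map_table()].
#' @param placements data.frame `marker_id`, `scaffold`, `bp` restricted (or
#'   not) to unanchored scaffolds; rows on scaffolds listed in
#'   `scaffold_lengths` are used.
#' @param scaffold_lengths Named vector (or data.frame `scaffold`, `length`)
#'   of unanchored scaffold lengths in bp.
#' @return list: `assignments` (data.frame: scaffold, assigned_group,
#'   n_markers, conflict, scaffold_length), `total_captured_bp` (sum of
#'   lengths of conflict-free assigned scaffolds).
#' @export
assign_scaffolds <- function(map, placements, scaffold_lengths) {
  mt <- if (inherits(map, "dart_linkage_map")) map_table(map) else map
  if (is.data.frame(scaffold_lengths)) {
    scaffold_lengths <- stats::setNames(scaffold_lengths$length,
                                        scaffold_lengths$scaffold)
  }
  pl <- placements[placements$scaffold %in% names(scaffold_lengths), ,
                   drop = FALSE]
  pl <- merge(pl, mt[, c("marker_id", "group")], by = "marker_id")
  if (nrow(pl) == 0) {
    return(list(assignments = data.frame(scaffold = character(0),
                                         assigned_group = character(0),
                                         n_markers = integer(0),
                                         conflict = logical(0),
                                         scaffold_length = numeric(0)),
                total_captured_bp = 0))
  }
  sp <- split(pl, pl$scaffold)
  rows <- lapply(sp, function(d) {
    gs <- unique(d$group)
    conflict <- length(gs) > 1
    data.frame(scaffold = d$scaffold[1],
               assigned_group = if (conflict) NA_character_ else gs,
               n_markers = nrow(d), conflict = conflict,
               scaffold_length = unname(scaffold_lengths[d$scaffold[1]]),
               stringsAsFactors = FALSE)
  })
  assignments <- do.call(rbind, rows)
  rownames(assignments) <- NULL
  list(assignments = assignments,
       total_captured_bp = sum(assignments$scaffold_length[
         !assignments$conflict]))
}

#' Compare adjacent-gap distributions of two map versions
#'
#' Two-sample Kolmogorov-Smirnov test (asymptotic p) on the distributions of
#' distances between consecutive markers, plus the fraction of gaps below
#' 1 cM in each map. Framework maps are expected to have a lower short-gap
#' fraction than full maps.
#'
#' @param full,framework `dart_linkage_map` objects (or lists of
#'   `linkage_group`) over the same population.
#' @return list: `ks_statistic`, `ks_p`, `fraction_below_1cm` (named, one per
#'   map), `n_gaps` (named).
#' @export
compare_maps <- function(full, framework) {
  gaps <- function(m) {
    groups <- if (inherits(m, "dart_linkage_map")) m$groups else m
    unlist(lapply(groups, function(g) diff(g$markers$position_cm)))
  }
  g1 <- gaps(full); g2 <- gaps(framework)
  if (length(g1) < 2 || length(g2) < 2) {
    stop("need at least 2 adjacent gaps in each map")
  }
  ks <- suppressWarnings(stats::ks.test(g1, g2, exact = FALSE))
  list(ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
       fraction_below_1cm = c(full = mean(g1 < 1),
                              framework = mean(g2 < 1)),
       n_gaps = c(full = length(g1), framework = length(g2)))
}

#' Physical placements from a simulation truth map
#'
#' Convenience accessor turning the truth map of a `dart_cross` into the
#' placement table consumed by the integration functions.
#'
#' @param cross A `dart_cross`.
#' @return data.frame: `marker_id`, `scaffold`, `bp`.
#' @export
placements_from_truth <- function(cross) {
  data.frame(marker_id = cross$markers$marker_id,
             scaffold = cross$markers$scaffold,
             bp = cross$markers$bp, stringsAsFactors = FALSE)
}
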