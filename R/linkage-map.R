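#' Linkage mapping parameters
#'
#' @param lod_threshold Grouping threshold: an edge requires LOD above this
#'   value (default 15, a stringent setting appropriate for thousands of
#'   pairwise tests).
#' @param r_max Grouping also requires an estimated recombination fraction
#'   at or below this value (default 0.4).
#' @param ripple_window Ripple window for order refinement (window 1 =
#'   adjacent-swap 2-opt).
#' @param jump_threshold Framework ordering: a marker whose local
#'   goodness-of-fit chi-square jump exceeds this value is deferred
#'   (default 5).
#' @param genotype_error Per-score flip probability modeled in the two-point
#'   likelihood of dominant markers. Default 0.002, the typical scoring
#'   concordance error of a DArT array (reproducibility ~99.8%). Set to 0
#'   for error-free data.
#' @param screen_chisq Association chi-square screen below which pairs are
#'   not ML-estimated when building a full pairwise table (default 20;
#'   LOD > 15 edges have association chi-square an order of magnitude
#'   above this).
#' @param r_metric_max Only pairs with `r_hat` at or below this value (and
#'   LOD >= 3) contribute edges to the path metric used for seriation
#'   (default 0.3): long-range estimates of dominant pairs are too biased to
#'   enter the geometry directly.
#' @param fit_window Pairs spanning at most this many adjacent gaps in the
#'   fitted order enter the pooled least-squares fit of map distances
#'   (default 20). Selecting pairs by rank separation avoids conditioning
#'   the fit on any pair's own noisy estimate.
#' @return An object of class `mapping_params`.
#' @export
mapping_params <- function(lod_threshold = 15, r_max = 0.4,
                           ripple_window = 1, jump_threshold = 5,
                           genotype_error = 0.002, screen_chisq = 20,
                           r_metric_max = 0.3, fit_window = 20) {
  stopifnot(lod_threshold > 0, r_max < 0.5, r_max > 0,
            jump_threshold > 0, screen_chisq >= 0,
            r_metric_max < 0.5, fit_window >= 1)
  check_prop(genotype_error, "genotype_error")
  structure(list(lod_threshold = lod_threshold, r_max = r_max,
                 ripple_window = ripple_window,
                 jump_threshold = jump_threshold,
                 genotype_error = genotype_error,
                 screen_chisq = screen_chisq,
                 r_metric_max = r_metric_max,
                 fit_window = fit_window),
            class = "mapping_params")
}

#' Group markers by two-point linkage
#'
#' Single-linkage transitive closure over edges with `lod > lod_threshold`
#' and `r_hat <= r_max`.
#'
#' @param tp Two-point table from [two_point_table()].
#' @param marker_ids All marker ids under consideration (so that markers with
#'   no strong edge are reported as ungrouped singletons).
#' @param params A [mapping_params()].
#' @return A list: `groups` (list of character vectors, multi-marker groups
#'   ordered by decreasing size, named LG01, LG02, ...), `ungrouped`
#'   (character vector).
#' @export
group_markers <- function(tp, marker_ids, params = mapping_params()) {
  edges <- tp[tp$informative & !is.na(tp$r_hat) &
                tp$lod > params$lod_threshold &
                tp$r_hat <= params$r_max, c("a", "b"), drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = marker_ids))
  comp <- igraph::components(g)
  member <- split(names(comp$membership), comp$membership)
  sizes <- lengths(member)
  groups <- member[sizes > 1]
  groups <- groups[order(-sizes[sizes > 1])]
  names(groups) <- sprintf("LG%02d", seq_along(groups))
  list(groups = groups, ungrouped = unlist(member[sizes == 1],
                                           use.names = FALSE))
}

# Configuration filters. Dominant intercross (3:1) x intercross pairs
# carry almost no linkage information and their ML estimates are badly
# biased at moderate-to-large r; they are excluded from all distance
# estimation (they still contribute to grouping through the LOD screen).
metric_pair <- function(tp, classes) {
  !(classes[tp$a] == "intercross_3to1" & classes[tp$b] == "intercross_3to1")
}


# Symmetric matrices of r, lod, n from a two-point table for a marker set.
tp_matrices <- function(tp, ids) {
  m <- length(ids)
  R <- matrix(NA_real_, m, m, dimnames = list(ids, ids))
  L <- matrix(0, m, m, dimnames = list(ids, ids))
  N <- matrix(0L, m, m, dimnames = list(ids, ids))
  FU <- matrix(NA_real_, m, m, dimnames = list(ids, ids))
  sel <- tp$a %in% ids & tp$b %in% ids & tp$informative & !is.na(tp$r_hat)
  t2 <- tp[sel, , drop = FALSE]
  ia <- match(t2$a, ids); ib <- match(t2$b, ids)
  R[cbind(ia, ib)] <- R[cbind(ib, ia)] <- t2$r_hat
  L[cbind(ia, ib)] <- L[cbind(ib, ia)] <- t2$lod
  N[cbind(ia, ib)] <- N[cbind(ib, ia)] <- t2$n
  if (!is.null(t2$fisher_unit)) {
    FU[cbind(ia, ib)] <- FU[cbind(ib, ia)] <- t2$fisher_unit
  }
  list(R = R, L = L, N = N, FU = FU)
}

# Quorum corroboration of short edge claims. Low-information pair
# configurations (dominant 3:1 x testcross in particular) have r estimates
# with sd ~5x binomial, so among thousands of moderately-distant pairs,
# dozens claim tight linkage with internally consistent likelihoods; left
# in place, one such claim folds the shortest-path metric. A claim
# D0[i, j] <= short_cap is trusted only when at least half of the markers
# in the two endpoints' short neighborhoods lie on a two-hop path of
# commensurate length: a genuine short pair is corroborated by almost all
# of its neighbors, while a spurious one is backed only by the handful of
# partners sharing the same fluke. Claims with fewer than `min_k`
# assessable neighbors are left alone (sparse regions).
distrust_edges <- function(D0, short_cap = 15, nbr = 5, slack = 12,
                           quorum = 0.5, min_k = 3) {
  m <- nrow(D0)
  bad <- matrix(FALSE, m, m)
  claims <- which(!is.na(D0) & D0 <= short_cap & upper.tri(D0),
                  arr.ind = TRUE)
  if (nrow(claims) == 0) return(bad)
  Dw <- D0
  Dw[is.na(Dw)] <- Inf
  diag(Dw) <- Inf
  for (e in seq_len(nrow(claims))) {
    i <- claims[e, 1]; j <- claims[e, 2]
    ks <- which(Dw[i, ] <= nbr | Dw[j, ] <= nbr)
    ks <- setdiff(ks, c(i, j))
    if (length(ks) < min_k) next
    path <- Dw[i, ks] + Dw[ks, j]
    if (mean(path <= D0[i, j] + slack) < quorum) {
      bad[i, j] <- bad[j, i] <- TRUE
    }
  }
  bad
}

# Min-plus (shortest-path) closure of a distance matrix with NA = unknown.
minplus_closure <- function(D) {
  D[is.na(D)] <- Inf
  diag(D) <- 0
  m <- nrow(D)
  for (k in seq_len(m)) {
    cand <- outer(D[, k], D[k, ], "+")
    better <- cand < D
    if (any(better)) D[better] <- cand[better]
  }
  D[!is.finite(D)] <- 200      # disconnected remnants: effectively unlinked
  D
}

# Sampling variance of the Kosambi distance of an r estimate (delta method).
kosambi_var <- function(r, n) {
  rc <- pmin(pmax(r, 0.005), 0.45)
  (100 / (1 - 4 * rc^2))^2 * rc * (1 - rc) / pmax(n, 1)
}

# 1D weighted stress majorization (SMACOF) refining an initial embedding x
# against target distances Dd with weights W (both full matrices, 0 where
# a pair carries no constraint).
smacof_1d <- function(x, Dd, W, iter = 300, tol = 1e-6) {
  wsum <- rowSums(W)
  for (it in seq_len(iter)) {
    DX <- outer(x, x, "-")
    S <- sign(DX); S[S == 0] <- 1
    B <- W * Dd * S
    xnew <- as.vector((W %*% x + rowSums(B)) / pmax(wsum, 1e-9))
    conv <- max(abs(xnew - x))
    x <- xnew
    if (conv < tol) break
  }
  x
}

# Goodness-of-fit jump of marker m between flanking markers x and z:
# 2-class chi-square between the observed recombinant count of the flanking
# pair and the count expected under Kosambi additivity through m. 0 when the
# required estimates are unavailable.
gof_jump <- function(R, N, D, x, m, z) {
  if (is.na(x) || is.na(z)) return(0)
  r_xz <- R[x, z]; n_xz <- N[x, z]
  if (is.na(r_xz) || n_xz < 1) return(0)
  r_add <- kosambi_r(D[x, m] + D[m, z])
  E <- n_xz * min(max(r_add, 0.5 / n_xz), 1 - 0.5 / n_xz)
  O <- n_xz * r_xz
  (O - E)^2 / E + (O - E)^2 / (n_xz - E)
}

# Active-set non-negative weighted least squares: columns fitted negative
# are pinned to zero and the system is re-solved (clipping without
# refitting would inflate the total by the negative mass).
nnls_gaps <- function(A, d, w) {
  free <- rep(TRUE, ncol(A))
  repeat {
    g <- rep(0, ncol(A))
    Af <- A[, free, drop = FALSE]
    gf <- tryCatch(
      solve(crossprod(Af, Af * w) + diag(1e-8, sum(free)),
            crossprod(Af, d * w)),
      error = function(e) rep(0, sum(free)))
    g[free] <- gf
    if (all(gf >= -1e-9)) return(pmax(g, 0))
    free[free][gf < 0] <- FALSE
    if (!any(free)) return(g * 0)
  }
}

# Pooled fit of adjacent gaps given an order. Every informative pair
# spanning at most `fit_window` adjacent gaps in the fitted order
# constrains the sum of the gaps it spans. Distances are pooled on the
# no-interference (Haldane) scale - the scale on which genetic distance is
# exactly additive under a Poisson crossover model - with inverse-variance
# weights built from the configuration's expected Fisher information
# evaluated at the (noise-independent) path-metric r. Fitted gaps, being
# short, convert to Kosambi cM essentially unchanged.
wls_gaps <- function(fit, tp_use, classes, params) {
  ord_ids <- fit$ord_ids
  m <- length(ord_ids)
  sel <- tp_use$a %in% ord_ids & tp_use$b %in% ord_ids &
    tp_use$r_hat <= 0.45
  t3 <- tp_use[sel, , drop = FALSE]
  pa <- match(t3$a, ord_ids); pb <- match(t3$b, ord_ids)
  keep <- abs(pa - pb) <= params$fit_window
  t3 <- t3[keep, , drop = FALSE]
  pa <- pa[keep]; pb <- pb[keep]
  if (nrow(t3) == 0) {
    # sparse group: fall back to path distances between neighbors
    nb <- cbind(match(ord_ids[-m], fit$ids), match(ord_ids[-1], fit$ids))
    return(fit$Dp[nb])
  }
  path_d <- fit$Dp[cbind(match(t3$a, fit$ids), match(t3$b, fit$ids))]
  r_p <- pmin(pmax(kosambi_r(path_d), 0.005), 0.4)
  fisher <- mapply(function(a, b, ph, r) {
    pair_fisher_unit(classes[[a]], classes[[b]], ph, r,
                     params$genotype_error)
  }, t3$a, t3$b, t3$phase, r_p)
  d_prime <- 100 / (1 - 2 * r_p)                  # Haldane slope
  w <- t3$n * fisher / d_prime^2
  lo <- pmin(pa, pb); hi <- pmax(pa, pb)
  A <- matrix(0, nrow(t3), m - 1)
  for (k in seq_len(nrow(t3))) A[k, lo[k]:(hi[k] - 1)] <- 1
  d <- haldane_cm(pmin(t3$r_hat, 0.48))
  g <- nnls_gaps(A, d, w)
  kosambi_cm(haldane_r(g))
}

#' Order a linkage group and assign Kosambi positions
#'
#' Seriation proceeds in three steps. (1) A path metric is built from
#' reliable short-range estimates only (`r_hat <= r_metric_max`, LOD >= 3;
#' dominant 3:1 x 3:1 pairs are excluded throughout as nearly uninformative)
#' and completed by shortest-path closure, which also bridges pairs without
#' shared informative meioses (e.g. testcross markers from different
#' parents). (2) The markers are embedded on a line by principal-coordinate
#' analysis of the path metric and the embedding is refined by weighted
#' 1D stress majorization against the direct pairwise Kosambi distances;
#' the marker order is the order along the refined line, polished by an
#' adjacent-transposition ripple. (3) Adjacent map distances are estimated
#' by non-negative weighted least squares pooling every pair with
#' `r_hat <= r_fit_max`; positions are their cumulative sums (first marker
#' at 0).
#'
#' In `framework` mode, markers whose local goodness-of-fit chi-square jump
#' (observed versus Kosambi-additive expected recombinants across the
#' flanking pair) exceeds `jump_threshold` are deferred and the group is
#' refitted without them; in `full` mode every marker is placed.
#'
#' @param ids Marker ids of one group (from [group_markers()]).
#' @param tp Two-point table covering the group's pairs (the [linkage_map()]
#'   wrapper completes it).
#' @param classes Named segregation classes for the group's markers.
#' @param mode `"full"` or `"framework"`.
#' @param params A [mapping_params()].
#' @param group_id Label carried into the result.
#' @return An object of class `linkage_group`: list with `group_id`, `mode`,
#'   `markers` (data.frame: marker_id, position_cm; positions non-decreasing
#'   from 0), `deferred` (ids deferred in framework mode), `length_cm`.
#' @export
order_group <- function(ids, tp, classes, mode = c("full", "framework"),
                        params = mapping_params(), group_id = "LG01") {
  mode <- match.arg(mode)
  ids <- sort(ids)            # canonical processing order: results do not
                              # depend on the caller's marker order
  make_result <- function(ord_ids, pos, deferred) {
    structure(list(group_id = group_id, mode = mode,
                   markers = data.frame(marker_id = ord_ids,
                                        position_cm = pos,
                                        stringsAsFactors = FALSE),
                   deferred = deferred,
                   length_cm = if (length(pos)) max(pos) else 0),
              class = "linkage_group")
  }
  if (length(ids) == 1) return(make_result(ids, 0, character(0)))

  tpg <- tp[tp$a %in% ids & tp$b %in% ids & tp$informative &
              !is.na(tp$r_hat), , drop = FALSE]
  tpu <- tpg[metric_pair(tpg, classes), , drop = FALSE]
  if (nrow(tpu) == 0) tpu <- tpg      # all-intercross group: use what exists
  if (nrow(tpu) > 0) {
    tpu$fisher_unit <- mapply(function(a, b, ph, r) {
      pair_fisher_unit(classes[[a]], classes[[b]], ph,
                       min(max(r, 0.005), 0.45), params$genotype_error)
    }, tpu$a, tpu$b, tpu$phase, tpu$r_hat)
  }
  if (length(ids) == 2) {
    d <- if (nrow(tpu)) kosambi_cm(min(tpu$r_hat[1], 0.495)) else 0
    return(make_result(ids, c(0, d), character(0)))
  }

  fit_once <- function(ids_fit) {
    m <- length(ids_fit)
    mats <- tp_matrices(tpu, ids_fit)
    R <- mats$R; L <- mats$L; N <- mats$N; FU <- mats$FU
    D0 <- matrix(NA_real_, m, m)
    ok <- !is.na(R) & R <= params$r_metric_max & L >= 3
    D0[ok] <- kosambi_cm(pmin(R[ok], 0.495))
    if (!any(ok)) {
      ok <- !is.na(R)
      D0[ok] <- kosambi_cm(pmin(R[ok], 0.495))
    }
    if (m > 3) {
      bad <- distrust_edges(D0)
      D0[bad] <- NA
      R[bad] <- NA                    # distrusted pairs leave all fits
    }
    Dp <- minplus_closure(D0)
    Dp <- (Dp + t(Dp)) / 2
    x <- tryCatch(stats::cmdscale(stats::as.dist(Dp), k = 1)[, 1],
                  error = function(e) seq_len(m) * 1.0)
    if (length(unique(x)) < 2) x <- x + seq_len(m) * 1e-6
    direct <- !is.na(R) & R <= 0.35
    Dd <- matrix(0, m, m); Dd[direct] <- kosambi_cm(pmin(R[direct], 0.495))
    # inverse-variance weights from each configuration's expected Fisher
    # information (binomial-style variances overstate the precision of
    # low-information configurations several-fold)
    rc <- pmin(pmax(R, 0.005), 0.45)
    dprime2 <- (100 / (1 - 4 * rc^2))^2
    W <- matrix(0, m, m)
    fu <- ifelse(is.na(FU) | FU <= 0, NA, FU)
    W[direct] <- (N * fu / dprime2)[direct]
    W[is.na(W)] <- 0
    diag(W) <- 0
    x <- smacof_1d(x, Dd, W)
    # per-marker embedding stress: the median standardized residual of a
    # marker's constraints. A marker whose score pattern is internally
    # inconsistent (e.g. a fluke shared across its pairs) cannot fit
    # anywhere on the line and shows high stress wherever it is placed.
    res_std <- abs(abs(outer(x, x, "-")) - Dd) * sqrt(W)
    stress <- vapply(seq_len(m), function(i) {
      v <- res_std[i, W[i, ] > 0]
      if (length(v)) stats::median(v) else 0
    }, 0)
    # one robust reweighting pass: drop constraints whose residual exceeds
    # 3.5 standardized units, then refit (guards against tight claims of
    # heavy-tailed configurations that survived the quorum filter)
    drop <- W > 0 & res_std > 3.5
    if (any(drop)) {
      W[drop] <- 0
      x <- smacof_1d(x, Dd, W)
    }
    ord <- order(x)
    # ripple: adjacent transpositions on the path metric
    if (params$ripple_window >= 1) {
      adjsum <- function(o) sum(Dp[cbind(o[-m], o[-1])])
      repeat {
        improved <- FALSE
        for (i in seq_len(m - 1)) {
          cand <- ord
          cand[c(i, i + 1)] <- cand[c(i + 1, i)]
          if (adjsum(cand) < adjsum(ord) - 1e-12) {
            ord <- cand
            improved <- TRUE
          }
        }
        if (!improved) break
      }
    }
    list(ord_ids = ids_fit[ord], ids = ids_fit, R = R, N = N, Dp = Dp,
         perm = ord, stress = stress)
  }

  fit <- fit_once(ids)
  deferred <- character(0)
  if (mode == "framework") {
    oi <- fit$perm
    m <- length(oi)
    jumps <- vapply(seq_len(m), function(i) {
      left <- if (i > 1) oi[i - 1] else NA
      right <- if (i < m) oi[i + 1] else NA
      if (is.na(left)) {
        if (m < 3) return(0)
        gof_jump(fit$R, fit$N, fit$Dp, oi[i], oi[i + 1], oi[i + 2])
      } else if (is.na(right)) {
        if (m < 3) return(0)
        gof_jump(fit$R, fit$N, fit$Dp, oi[i - 2], oi[i - 1], oi[i])
      } else {
        gof_jump(fit$R, fit$N, fit$Dp, left, oi[i], right)
      }
    }, 0)
    # defer on either criterion: local additivity jump, or high embedding
    # stress (a marker that no position on the line can reconcile with its
    # pairwise estimates)
    high_stress <- fit$ids[fit$stress > 2.5]
    deferred <- union(fit$ord_ids[jumps > params$jump_threshold],
                      high_stress)
    keep_ids <- setdiff(ids, deferred)
    if (length(keep_ids) < 2) {
      return(make_result(keep_ids, rep(0, length(keep_ids)), deferred))
    }
    fit <- fit_once(keep_ids)
  }

  gaps <- wls_gaps(fit, tpu, classes, params)
  pos <- cumsum(c(0, gaps))
  make_result(fit$ord_ids, pos, deferred)
}

#' @export
print.linkage_group <- function(x, ...) {
  cat(sprintf("Linkage group %s (%s): %d markers, %.1f cM", x$group_id,
              x$mode, nrow(x$markers), x$length_cm))
  if (length(x$deferred)) cat(",", length(x$deferred), "deferred")
  cat("\n")
  invisible(x)
}

#' Build a linkage map from a genotyped cross
#'
#' Convenience pipeline: segregation classification (unless classes are
#' given), screened two-point table, LOD grouping, within-group table
#' completion and ordering of each group.
#'
#' @param geno Character genotype matrix (markers x individuals, parents in
#'   the first two columns) or a `dart_cross`.
#' @param classes Named segregation classes; if `NULL`, inferred with
#'   [segregation_table()] and restricted to Mendelian markers.
#' @param mode `"full"` or `"framework"`.
#' @param params A [mapping_params()].
#' @param tp Optional precomputed screened two-point table (saves the most
#'   expensive step when building both map versions).
#' @return An object of class `dart_linkage_map`: list with `groups` (list
#'   of `linkage_group`), `ungrouped`, `mode`, `params`, `tp` (the two-point
#'   table including within-group completions), `classes`.
#' @export
linkage_map <- function(geno, classes = NULL, mode = c("full", "framework"),
                        params = mapping_params(), tp = NULL) {
  mode <- match.arg(mode)
  if (inherits(geno, "dart_cross")) geno <- geno$genotypes
  if (is.null(classes)) {
    seg <- segregation_table(geno)
    seg <- seg[seg$mendelian, , drop = FALSE]
    classes <- stats::setNames(seg$class, seg$marker_id)
  }
  ids <- names(classes)
  if (is.null(tp)) tp <- two_point_table(geno, classes, params)
  grp <- group_markers(tp, ids, params)
  groups <- vector("list", length(grp$groups))
  names(groups) <- names(grp$groups)
  for (gi in seq_along(grp$groups)) {
    gids <- grp$groups[[gi]]
    have <- tp$a %in% gids & tp$b %in% gids
    all_pairs <- t(utils::combn(gids, 2))
    # complete only the informative configurations the seriation uses
    cfg_keep <- metric_pair(data.frame(a = all_pairs[, 1],
                                       b = all_pairs[, 2]), classes) &
      !vapply(seq_len(nrow(all_pairs)), function(k) {
        isTRUE(pair_coefficients(classes[[all_pairs[k, 1]]],
                                 classes[[all_pairs[k, 2]]],
                                 params$genotype_error)$uninformative)
      }, TRUE)
    all_pairs <- all_pairs[cfg_keep, , drop = FALSE]
    key_have <- paste(pmin(tp$a[have], tp$b[have]),
                      pmax(tp$a[have], tp$b[have]))
    key_all <- paste(pmin(all_pairs[, 1], all_pairs[, 2]),
                     pmax(all_pairs[, 1], all_pairs[, 2]))
    missing_pairs <- all_pairs[!(key_all %in% key_have), , drop = FALSE]
    tpg <- rbind(tp[have, , drop = FALSE],
                 if (nrow(missing_pairs)) {
                   two_point_table(geno, classes, params,
                                   pairs = missing_pairs)
                 })
    tp <- rbind(tp, tpg[!(paste(pmin(tpg$a, tpg$b), pmax(tpg$a, tpg$b)) %in%
                            key_have), , drop = FALSE])
    groups[[gi]] <- order_group(gids, tpg, classes, mode = mode,
                                params = params,
                                group_id = names(grp$groups)[gi])
  }
  structure(list(groups = groups, ungrouped = grp$ungrouped, mode = mode,
                 params = params, tp = tp, classes = classes),
            class = "dart_linkage_map")
}

#' @export
print.dart_linkage_map <- function(x, ...) {
  cat(sprintf("%s linkage map: %d groups, %d markers placed, %d ungrouped\n",
              x$mode, length(x$groups),
              sum(vapply(x$groups, function(g) nrow(g$markers), 0L)),
              length(x$ungrouped)))
  invisible(x)
}

#' @export
summary.dart_linkage_map <- function(object, ...) {
  df <- do.call(rbind, lapply(object$groups, function(g) {
    data.frame(group = g$group_id, n_markers = nrow(g$markers),
               length_cm = round(g$length_cm, 1),
               n_deferred = length(g$deferred), stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}

#' Flatten a linkage map to a marker table
#'
#' @param map A `dart_linkage_map` or list of `linkage_group`s.
#' @return data.frame: `marker_id`, `group`, `position_cm`, `mode`.
#' @export
map_table <- function(map) {
  groups <- if (inherits(map, "dart_linkage_map")) map$groups else map
  out <- do.call(rbind, lapply(groups, function(g) {
    data.frame(marker_id = g$markers$marker_id, group = g$group_id,
               position_cm = g$markers$position_cm, mode = g$mode,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
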