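# Two-point linkage analysis for an outbred full-sib (CP) family.
#
# Marker segregation classes supported: testcross_1to1_P1 / _P2 (dominant,
# heterozygous in one parent), intercross_3to1 (dominant, heterozygous in
# both), f2_1to2to1 and fully_informative (codominant). The pair likelihood
# is built by enumerating both parents' gamete haplotypes: each parent
# transmits a parental haplotype with probability (1-r)/2 and a recombinant
# with probability r/2, and the observable progeny class collapses the four
# transmitted alleles (dominant markers show only band presence). Because
# each parent's factor is linear in r, every observable-class probability is
# a quadratic in r; the coefficients depend only on the class configuration
# and phase, so they are computed once per configuration and cached.

# Parent homolog alleles under reference ("coupling") phase.
pair_parent_geno <- function(class) {
  switch(class,
    testcross_1to1_P1 = list(P1 = c("1", "0"), P2 = c("0", "0")),
    testcross_1to1_P2 = list(P1 = c("0", "0"), P2 = c("1", "0")),
    intercross_3to1   = list(P1 = c("1", "0"), P2 = c("1", "0")),
    f2_1to2to1        = list(P1 = c("a", "b"), P2 = c("a", "b")),
    fully_informative = list(P1 = c("a", "b"), P2 = c("c", "d")),
    stop("unknown segregation class: ", class))
}

is_dominant_class <- function(class) {
  class %in% c("testcross_1to1_P1", "testcross_1to1_P2", "intercross_3to1")
}

# Observable progeny code from the two transmitted alleles.
pair_observable <- function(class, a1, a2) {
  if (is_dominant_class(class)) {
    if (a1 == "1" || a2 == "1") "1" else "0"
  } else {
    paste(sort(c(a1, a2)), collapse = "")
  }
}

# Which parents are heterozygous at both markers (and hence have a phase)?
pair_phased_parents <- function(class_a, class_b) {
  ga <- pair_parent_geno(class_a)
  gb <- pair_parent_geno(class_b)
  het <- function(x) x[1] != x[2]
  which(c(het(ga$P1) && het(gb$P1), het(ga$P2) && het(gb$P2)))
}

# Raw class-probability table for one phase assignment, at recombination r.
# phase: character vector of length 2, "C"/"R" per parent (ignored for a
# parent without a phase).
pair_probs_at <- function(class_a, class_b, phase, r) {
  ga <- pair_parent_geno(class_a)
  gb <- pair_parent_geno(class_b)
  for (p in 1:2) {
    if (phase[p] == "R") gb[[p]] <- rev(gb[[p]])
  }
  q <- function(i, j) if (i == j) (1 - r) / 2 else r / 2
  probs <- list()
  for (i1 in 1:2) for (j1 in 1:2) for (i2 in 1:2) for (j2 in 1:2) {
    pr <- q(i1, j1) * q(i2, j2)
    oa <- pair_observable(class_a, ga$P1[i1], ga$P2[i2])
    ob <- pair_observable(class_b, gb$P1[j1], gb$P2[j2])
    key <- paste(oa, ob, sep = "|")
    probs[[key]] <- (probs[[key]] %||% 0) + pr
  }
  unlist(probs)
}

# Apply a per-score flip error to dominant-marker margins of the class
# probability table (linear map; preserves the quadratic-in-r structure).
apply_score_error <- function(p, class_a, class_b, eps) {
  if (eps <= 0) return(p)
  keys <- do.call(rbind, strsplit(names(p), "|", fixed = TRUE))
  flip <- function(code) ifelse(code == "1", "0", "1")
  out <- stats::setNames(numeric(length(p)), names(p))
  for (k in seq_along(p)) {
    a <- keys[k, 1]; b <- keys[k, 2]
    wa <- if (is_dominant_class(class_a)) {
      stats::setNames(c(1 - eps, eps), c(a, flip(a)))
    } else stats::setNames(1, a)
    wb <- if (is_dominant_class(class_b)) {
      stats::setNames(c(1 - eps, eps), c(b, flip(b)))
    } else stats::setNames(1, b)
    for (na in names(wa)) for (nb in names(wb)) {
      key <- paste(na, nb, sep = "|")
      cur <- if (key %in% names(out)) out[[key]] else 0
      out[key] <- cur + p[[k]] * wa[[na]] * wb[[nb]]
    }
  }
  out
}

.pair_cache <- new.env(parent = emptyenv())

# Quadratic coefficients of every observable-class probability, per phase
# combination, for a pair configuration. Cached.
pair_coefficients <- function(class_a, class_b, eps = 0) {
  key <- paste(class_a, class_b, format(eps), sep = "/")
  hit <- .pair_cache[[key]]
  if (!is.null(hit)) return(hit)

  phased <- pair_phased_parents(class_a, class_b)
  if (length(phased) == 0) {
    res <- NULL                       # uninformative configuration
    assign(key, list(uninformative = TRUE), envir = .pair_cache)
    return(.pair_cache[[key]])
  }
  combos <- do.call(expand.grid,
                    c(rep(list(c("C", "R")), length(phased)),
                      stringsAsFactors = FALSE))
  phase_labels <- apply(combos, 1, paste, collapse = "")

  tables <- lapply(seq_len(nrow(combos)), function(ci) {
    ph <- c("C", "C")
    ph[phased] <- unlist(combos[ci, ])
    lapply(c(0, 0.25, 0.5), function(r) {
      p <- pair_probs_at(class_a, class_b, ph, r)
      apply_score_error(p, class_a, class_b, eps)
    })
  })
  classes <- sort(unique(unlist(lapply(tables, function(t)
    unlist(lapply(t, names))))))
  get_p <- function(tab, cls) {
    v <- tab[cls]; v[is.na(v)] <- 0; unname(v)
  }
  coef <- lapply(tables, function(t) {
    p0 <- get_p(t[[1]], classes)
    p1 <- get_p(t[[2]], classes)
    p2 <- get_p(t[[3]], classes)
    g <- 8 * (p2 - 2 * p1 + p0)
    b <- 2 * (p2 - p0) - 0.5 * g
    list(a = p0, b = b, g = g)
  })
  res <- list(uninformative = FALSE, classes = classes,
              phases = phase_labels, coef = coef)
  assign(key, res, envir = .pair_cache)
  res
}

# Log-likelihood over a grid of r values for every phase; counts aligned to
# cache$classes. Returns list(ll = matrix phases x r, ll_half = scalar).
pair_loglik_grid <- function(counts, cache, r) {
  ll <- vapply(seq_along(cache$phases), function(ci) {
    cf <- cache$coef[[ci]]
    vapply(r, function(ri) {
      p <- pmax(cf$a + cf$b * ri + cf$g * ri * ri, 1e-12)
      sum(counts * log(p))
    }, 0)
  }, numeric(length(r)))
  matrix(ll, nrow = length(r))
}

# Expected (unit, per-individual) Fisher information about r for a pair
# configuration at a given phase and r. Used to weight pooled distance fits.
pair_fisher_unit <- function(class_a, class_b, phase, r, eps = 0) {
  cache <- pair_coefficients(class_a, class_b, eps)
  if (isTRUE(cache$uninformative)) return(0)
  ci <- match(phase, cache$phases)
  if (is.na(ci)) ci <- 1
  cf <- cache$coef[[ci]]
  p <- pmax(cf$a + cf$b * r + cf$g * r * r, 1e-9)
  dp <- cf$b + 2 * cf$g * r
  sum(dp^2 / p)
}

#' Two-point recombination estimate for a marker pair
#'
#' Maximum-likelihood estimate of the recombination fraction, best-supported
#' linkage phase and LOD score for a pair of markers in an outbred full-sib
#' family. The likelihood is maximized over r in `[0, 0.5)` separately for
#' each admissible phase combination (ties broken toward coupling) by a grid
#' scan refined with golden-section search; LOD compares the maximized
#' likelihood against independence (r = 0.5).
#'
#' Pairs that share no informative meioses (e.g. dominant testcross markers
#' heterozygous in different single parents) are returned with
#' `informative = FALSE`, `r_hat = NA` and `lod = 0`.
#'
#' @param scores_a,scores_b Progeny score vectors (parents excluded).
#' @param class_a,class_b Segregation classes (see [segregation_table()]).
#' @param genotype_error Per-score flip probability modeled in the
#'   likelihood of dominant markers (the array's scoring error; see
#'   [mapping_params()]).
#' @param min_shared Minimum progeny scored for both markers.
#' @return A one-row data.frame: `r_hat`, `phase`, `lod`, `n`,
#'   `informative`.
#' @export
estimate_two_point <- function(scores_a, scores_b, class_a, class_b,
                               genotype_error = 0, min_shared = 20) {
  stopifnot(length(scores_a) == length(scores_b))
  keep <- !is.na(scores_a) & !is.na(scores_b)
  n <- sum(keep)
  cache <- pair_coefficients(class_a, class_b, genotype_error)
  if (isTRUE(cache$uninformative)) {
    return(data.frame(r_hat = NA_real_, phase = "uninformative", lod = 0,
                      n = n, informative = FALSE, stringsAsFactors = FALSE))
  }
  if (n < min_shared) {
    stop("fewer than ", min_shared, " individuals scored for both markers")
  }
  key <- paste(scores_a[keep], scores_b[keep], sep = "|")
  counts <- vapply(cache$classes, function(k) sum(key == k), 0)
  est <- estimate_pair_from_counts(counts, cache)
  data.frame(r_hat = est$r_hat, phase = est$phase, lod = est$lod, n = n,
             informative = TRUE, stringsAsFactors = FALSE)
}

# Core optimizer shared by estimate_two_point and two_point_table.
estimate_pair_from_counts <- function(counts, cache) {
  grid <- seq(0, 0.4999, length.out = 26)
  ll <- pair_loglik_grid(counts, cache, grid)
  best <- arrayInd(which.max(ll), dim(ll))
  gi <- best[1]; ci <- best[2]
  cf <- cache$coef[[ci]]
  negll <- function(r) {
    p <- pmax(cf$a + cf$b * r + cf$g * r * r, 1e-12)
    -sum(counts * log(p))
  }
  lo <- grid[max(1, gi - 1)]
  hi <- grid[min(length(grid), gi + 1)]
  opt <- stats::optimize(negll, c(lo, hi), tol = 1e-6)
  # keep exact boundary optima (r = 0 in particular)
  cand_r <- c(opt$minimum, lo, hi, 0)
  cand_v <- vapply(cand_r, negll, 0)
  r_hat <- cand_r[which.min(cand_v)]
  ll_max <- -min(cand_v)
  ll_half <- -negll(0.5)
  lod <- max(0, (ll_max - ll_half) / log(10))
  if (lod < 1e-10) r_hat <- 0.5
  list(r_hat = r_hat, phase = cache$phases[ci], lod = lod)
}

#' Pairwise two-point table for a set of markers
#'
#' Computes two-point estimates for marker pairs of a genotype matrix. To
#' keep large tables tractable, pairs are first screened with a vectorized
#' 2x2 association chi-square (`screen_chisq`, see [mapping_params()]); only
#' pairs above the screen get a full ML estimate. Edges used for grouping at
#' LOD > 15 have association chi-square far above any sensible screen, so the
#' screen cannot discard true linkage-group edges. Pass `pairs` to force
#' estimation of an explicit pair set (e.g. to complete a group before
#' ordering).
#'
#' @param geno Character genotype matrix (markers x individuals) whose first
#'   two columns are the parents, e.g. `dart_cross$genotypes`.
#' @param classes Named character vector of segregation classes per marker
#'   (names = rownames of `geno`). Markers with other classes are ignored.
#' @param params A [mapping_params()].
#' @param pairs Optional two-column matrix/data.frame of marker ids to
#'   estimate (bypasses the screen).
#' @return A data.frame: `a`, `b`, `r_hat`, `phase`, `lod`, `n`,
#'   `informative`.
#' @export
two_point_table <- function(geno, classes, params = mapping_params(),
                            pairs = NULL) {
  stopifnot(is.matrix(geno))
  ids <- rownames(geno)
  classes <- classes[names(classes) %in% ids]
  keep <- names(classes)[classes %in% c("testcross_1to1_P1",
                                        "testcross_1to1_P2",
                                        "intercross_3to1", "f2_1to2to1",
                                        "fully_informative")]
  geno <- geno[keep, , drop = FALSE]
  classes <- classes[keep]
  prog <- geno[, -(1:2), drop = FALSE]
  eps <- params$genotype_error

  if (is.null(pairs)) {
    pairs <- screen_pairs(prog, classes, params$screen_chisq)
  } else {
    pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
    ok <- pairs[, 1] %in% keep & pairs[, 2] %in% keep
    pairs <- pairs[ok, , drop = FALSE]
  }
  if (nrow(pairs) == 0) {
    return(data.frame(a = character(0), b = character(0),
                      r_hat = numeric(0), phase = character(0),
                      lod = numeric(0), n = integer(0),
                      informative = logical(0), stringsAsFactors = FALSE))
  }

  out <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    cache <- pair_coefficients(classes[[a]], classes[[b]], eps)
    sa <- prog[a, ]; sb <- prog[b, ]
    shared <- !is.na(sa) & !is.na(sb)
    n <- sum(shared)
    if (isTRUE(cache$uninformative) || n < 20) {
      out[[k]] <- list(r_hat = NA_real_, phase = "uninformative", lod = 0,
                       n = n, informative = FALSE)
      next
    }
    keyv <- paste(sa[shared], sb[shared], sep = "|")
    counts <- vapply(cache$classes, function(cl) sum(keyv == cl), 0)
    est <- estimate_pair_from_counts(counts, cache)
    out[[k]] <- list(r_hat = est$r_hat, phase = est$phase, lod = est$lod,
                     n = n, informative = TRUE)
  }
  res <- data.frame(a = pairs[, 1], b = pairs[, 2],
                    r_hat = vapply(out, `[[`, 0, "r_hat"),
                    phase = vapply(out, `[[`, "", "phase"),
                    lod = vapply(out, `[[`, 0, "lod"),
                    n = vapply(out, `[[`, 0L, "n"),
                    informative = vapply(out, `[[`, TRUE, "informative"),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

# Vectorized association screen. Dominant x dominant pairs via indicator
# cross-products; pairs involving codominant markers via per-pair contingency
# chi-square (codominant markers are typically few).
screen_pairs <- function(prog, classes, threshold) {
  ids <- rownames(prog)
  dom <- ids[is_dominant_class_vec(classes[ids])]
  cod <- setdiff(ids, dom)
  res <- list()

  if (length(dom) >= 2) {
    X1 <- matrix(0, length(dom), ncol(prog))
    X0 <- matrix(0, length(dom), ncol(prog))
    pd <- prog[dom, , drop = FALSE]
    X1[which(pd == "1")] <- 1
    X0[which(pd == "0")] <- 1
    n11 <- tcrossprod(X1)
    n10 <- tcrossprod(X1, X0)
    n01 <- tcrossprod(X0, X1)
    n00 <- tcrossprod(X0)
    nn <- n11 + n10 + n01 + n00
    r1 <- n11 + n10; r0 <- n01 + n00
    c1 <- n11 + n01; c0 <- n10 + n00
    num <- (n11 * n00 - n10 * n01)^2 * nn
    den <- r1 * r0 * c1 * c0
    chi <- ifelse(den > 0, num / den, 0)
    sel <- which(upper.tri(chi) & chi >= threshold & nn >= 20, arr.ind = TRUE)
    if (nrow(sel)) {
      res[[length(res) + 1]] <- cbind(dom[sel[, 1]], dom[sel[, 2]])
    }
  }
  if (length(cod) >= 1) {
    # codominant vs every other marker, looped contingency chi-square;
    # codominant-codominant pairs taken once by index order
    for (a in cod) {
      others <- c(dom, cod[match(cod, ids) > match(a, ids)])
      sa <- prog[a, ]
      for (b in others) {
        sb <- prog[b, ]
        shared <- !is.na(sa) & !is.na(sb)
        if (sum(shared) < 20) next
        tab <- table(sa[shared], sb[shared])
        if (nrow(tab) < 2 || ncol(tab) < 2) next
        e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        chi <- sum((tab - e)^2 / pmax(e, 1e-12))
        if (chi >= threshold) {
          res[[length(res) + 1]] <- cbind(a, b)
        }
      }
    }
  }
  if (!length(res)) return(matrix(character(0), 0, 2))
  unique(do.call(rbind, res))
}

is_dominant_class_vec <- function(x) {
  x %in% c("testcross_1to1_P1", "testcross_1to1_P2", "intercross_3to1")
}
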