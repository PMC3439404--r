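#' Marker quality thresholds
#'
#' The three array-level quality filters applied before linkage analysis,
#' with the conventional defaults for dominant hybridization arrays:
#' scoring reproducibility >= 95% (concordance between technical replicates),
#' quality score Q >= 65 (between-cluster variance as percent of total
#' fluorescence variance), call rate >= 75%, and a segregation-test alpha of
#' 0.01. All comparisons are inclusive (`>=`).
#'
#' @param min_reproducibility Minimum reproducibility, proportion.
#' @param min_q Minimum quality score Q, percent.
#' @param min_call_rate Minimum call rate, proportion.
#' @param alpha Significance level for the Mendelian segregation test; a
#'   marker is declared non-Mendelian when its chi-square p-value falls
#'   below `alpha`.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_reproducibility = 0.95, min_q = 65,
                          min_call_rate = 0.75, alpha = 0.01) {
  check_prop(min_reproducibility, "min_reproducibility")
  if (min_q < 0 || min_q > 100) stop("min_q must lie in [0, 100]")
  check_prop(min_call_rate, "min_call_rate")
  check_prop(alpha, "alpha")
  structure(list(min_reproducibility = min_reproducibility, min_q = min_q,
                 min_call_rate = min_call_rate, alpha = alpha),
            class = "qc_thresholds")
}

#' Apply marker quality filters
#'
#' Partitions markers into pass/fail by the three quality criteria
#' (reproducibility, Q, call rate), all inclusive `>=` comparisons, and
#' reports per-criterion and joint (Venn-style) tallies.
#'
#' @param markers A data.frame with columns `marker_id`, `reproducibility`,
#'   `q_score`, `call_rate` (e.g. the `markers` element of a `dart_cross`,
#'   or a table read with [read_genotypes()]).
#' @param thresholds A [qc_thresholds()].
#' @return A list of class `qc_filter`: `markers` (input plus logical columns
#'   `pass_reproducibility`, `pass_q`, `pass_call_rate`, `pass`), `tallies`
#'   (named counts per criterion and jointly) and `venn` (counts for each of
#'   the 8 pass/fail combinations).
#' @export
filter_markers <- function(markers, thresholds = qc_thresholds()) {
  stopifnot(is.data.frame(markers), nrow(markers) > 0,
            inherits(thresholds, "qc_thresholds"))
  need <- c("reproducibility", "q_score", "call_rate")
  if (!all(need %in% names(markers))) {
    stop("markers must have columns: ", paste(need, collapse = ", "))
  }
  if (any(markers$reproducibility < 0 | markers$reproducibility > 1,
          na.rm = TRUE) ||
      any(markers$call_rate < 0 | markers$call_rate > 1, na.rm = TRUE)) {
    stop("reproducibility and call_rate must lie in [0, 1]")
  }
  m <- markers
  m$pass_reproducibility <- m$reproducibility >= thresholds$min_reproducibility
  m$pass_q <- m$q_score >= thresholds$min_q
  m$pass_call_rate <- m$call_rate >= thresholds$min_call_rate
  m$pass <- m$pass_reproducibility & m$pass_q & m$pass_call_rate

  venn <- table(reproducibility = m$pass_reproducibility,
                q = m$pass_q, call_rate = m$pass_call_rate)
  tallies <- c(n = nrow(m),
               pass_reproducibility = sum(m$pass_reproducibility),
               pass_q = sum(m$pass_q),
               pass_call_rate = sum(m$pass_call_rate),
               pass_all = sum(m$pass))
  structure(list(markers = m, tallies = tallies, venn = venn),
            class = "qc_filter")
}

#' @export
print.qc_filter <- function(x, ...) {
  cat("Marker QC:", x$tallies["pass_all"], "of", x$tallies["n"],
      "markers pass all filters\n")
  print(x$tallies[-1])
  invisible(x)
}

# Expected segregation proportions and observable classes per marker class.
segregation_expectation <- function(class) {
  switch(class,
    testcross_1to1_P1 = ,
    testcross_1to1_P2 = list(classes = c("1", "0"), p = c(0.5, 0.5)),
    intercross_3to1 = list(classes = c("1", "0"), p = c(0.75, 0.25)),
    f2_1to2to1 = list(classes = c("aa", "ab", "bb"), p = c(.25, .5, .25)),
    fully_informative = list(classes = c("ac", "ad", "bc", "bd"),
                             p = rep(0.25, 4)),
    stop("unknown segregation class: ", class))
}

# Infer the segregation class from parent scores.
# Dominant codes: "1"/"0". Codominant: two-letter parent genotypes.
infer_class <- function(p1, p2) {
  if (is.na(p1) || is.na(p2)) return("ambiguous")
  if (p1 %in% c("0", "1") && p2 %in% c("0", "1")) {
    if (p1 == "1" && p2 == "1") return("intercross_3to1")
    if (p1 == "1") return("testcross_1to1_P1")
    if (p2 == "1") return("testcross_1to1_P2")
    return("inconsistent")          # no parent carries the fragment
  }
  # codominant: distinct parent genotypes with 4 distinct alleles are fully
  # informative; identical heterozygous genotypes segregate 1:2:1
  a1 <- strsplit(p1, "")[[1]]
  a2 <- strsplit(p2, "")[[1]]
  if (length(unique(c(a1, a2))) == 4) return("fully_informative")
  if (setequal(a1, a2) && length(unique(a1)) == 2) return("f2_1to2to1")
  "ambiguous"
}

#' Classify a marker's segregation type and test Mendelian fit
#'
#' The expected segregation ratio is determined from the parent scores (never
#' chosen as the best-fitting ratio, to avoid multiple-testing bias): both
#' parents carrying the band gives 3:1, exactly one parent 1:1 from that
#' parent; codominant parents give 1:2:1 or a fully informative 1:1:1:1
#' depending on the allele count. A Pearson chi-square goodness-of-fit test
#' (no continuity correction, df = classes - 1) is run on the non-missing
#' progeny scores.
#'
#' @param scores Character vector of progeny scores ("1"/"0"/NA for dominant
#'   markers, genotype classes for codominant ones).
#' @param parent_scores Length-2 character vector: scores of parents 1 and 2.
#' @param alpha Significance level; the marker is Mendelian iff p >= alpha.
#' @param marker_id Optional identifier carried into the result.
#' @param min_scored Minimum scored progeny required (default 20).
#' @return A one-row data.frame: `marker_id`, `class`, `chi_square`, `df`,
#'   `p_value`, `mendelian`. For markers whose parents cannot produce the
#'   observed segregation, `class` is "inconsistent" and the test fields are
#'   `NA` (the marker is excluded from mapping).
#' @export
classify_and_test <- function(scores, parent_scores, alpha = 0.01,
                              marker_id = NA_character_, min_scored = 20) {
  stopifnot(length(parent_scores) == 2)
  obs <- scores[!is.na(scores)]
  cl <- infer_class(parent_scores[1], parent_scores[2])
  if (cl %in% c("inconsistent", "ambiguous")) {
    # inconsistent: progeny segregating a band absent from both parents
    if (cl == "inconsistent" && !any(obs == "1")) cl <- "monomorphic"
    return(data.frame(marker_id = marker_id, class = cl,
                      chi_square = NA_real_, df = NA_integer_,
                      p_value = NA_real_, mendelian = FALSE,
                      stringsAsFactors = FALSE))
  }
  if (length(obs) < min_scored) {
    stop("fewer than ", min_scored, " scored progeny")
  }
  exp <- segregation_expectation(cl)
  counts <- vapply(exp$classes, function(k) sum(obs == k), 0)
  chi <- sum((counts - length(obs) * exp$p)^2 / (length(obs) * exp$p))
  df <- length(exp$classes) - 1L
  p <- stats::pchisq(chi, df, lower.tail = FALSE)
  data.frame(marker_id = marker_id, class = cl, chi_square = chi,
             df = df, p_value = p, mendelian = p >= alpha,
             stringsAsFactors = FALSE)
}

#' Segregation classification and testing for a whole genotype matrix
#'
#' Vectorized wrapper around [classify_and_test()] for a `dart_cross` or any
#' genotype matrix whose first two columns are the parents.
#'
#' @param cross A `dart_cross`, or a character genotype matrix with columns
#'   `P1`, `P2`, then progeny.
#' @param alpha Significance level.
#' @param min_scored Minimum scored progeny per marker.
#' @return A data.frame with one row per marker (see [classify_and_test()]).
#' @export
segregation_table <- function(cross, alpha = 0.01, min_scored = 20) {
  geno <- if (inherits(cross, "dart_cross")) cross$genotypes else cross
  ids <- rownames(geno) %||% sprintf("M%05d", seq_len(nrow(geno)))
  out <- do.call(rbind, lapply(seq_len(nrow(geno)), function(i) {
    classify_and_test(geno[i, -(1:2)], geno[i, 1:2], alpha = alpha,
                      marker_id = ids[i], min_scored = min_scored)
  }))
  rownames(out) <- NULL
  out
}
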