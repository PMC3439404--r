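# Packaged reference tables from the published characterization of the
# Eucalyptus DArT array (a 7,680-probe array mapped in a 177-progeny
# E. grandis x E. urophylla full-sib family against the E. grandis
# reference assembly). Used for regression tests and as worked-example
# inputs; values are the printed table cells.

#' Published mapping statistics of the Eucalyptus DArT consensus maps
#'
#' Per-pseudochromosome marker counts and cM sizes for the full and
#' framework map versions, the framework-to-genome marker counts, the
#' physical distance covered and the kbp/cM ratios, as printed (eleven
#' chromosome rows plus the printed totals row).
#'
#' @return list: `per_chromosome` (11 rows), `totals` (the printed totals
#'   row).
#' @export
reference_map_stats <- function() {
  path <- system.file("extdata", "eucalyptus_dart_map_stats.tsv",
                      package = "dartmap", mustWork = TRUE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  list(per_chromosome = x[x$chromosome != "Total", , drop = FALSE],
       totals = x[x$chromosome == "Total", , drop = FALSE])
}

#' Published redundancy accounting of the Eucalyptus DArT probe library
#'
#' The four assembly-stringency presets (A1 most stringent to A4 most
#' relaxed) with their parameters and the printed accounting of 6,918
#' sequenced probes: unmatched singletons, redundant cluster members,
#' cluster counts, unique loci and redundancy rates.
#'
#' @return data.frame, one row per preset.
#' @export
reference_redundancy <- function() {
  path <- system.file("extdata", "eucalyptus_dart_redundancy.tsv",
                      package = "dartmap", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
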