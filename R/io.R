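# Readers and writers for the package's plain-text interchange formats.
# Sequence and annotation formats go through Biostrings / rtracklayer;
# tabular formats are plain TSV.

#' Write a synthetic genome to FASTA and GFF3
#'
#' @param genome A `dart_genome` with sequences.
#' @param fasta_path Output FASTA path.
#' @param gff3_path Optional output GFF3 path for the gene models (feature
#'   type "gene", 1-based inclusive coordinates).
#' @return Invisibly, the paths written.
#' @export
write_genome <- function(genome, fasta_path, gff3_path = NULL) {
  stopifnot(inherits(genome, "dart_genome"))
  if (is.null(genome$sequences)) stop("genome has no sequences")
  Biostrings::writeXStringSet(genome$sequences, fasta_path)
  if (!is.null(gff3_path)) write_genes_gff3(genome$genes, gff3_path)
  invisible(c(fasta_path, gff3_path))
}

#' Write gene models to GFF3
#'
#' Internal 0-based half-open intervals are emitted as 1-based inclusive
#' GFF3 "gene" features.
#'
#' @param genes data.frame: `gene_id`, `scaffold`, `start`, `end`, `strand`.
#' @param path Output path.
#' @export
write_genes_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$scaffold,
    ranges = IRanges::IRanges(start = genes$start + 1, end = genes$end),
    strand = genes$strand)
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' @param path GFF3 path.
#' @param feature_type Feature type to keep (default "gene").
#' @return data.frame: `gene_id`, `scaffold`, `start`, `end` (0-based
#'   half-open), `strand`.
#' @export
read_genes_gff3 <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == feature_type]
  data.frame(gene_id = gr$ID %||% sprintf("gene_%05d", seq_along(gr)),
             scaffold = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1,
             end = BiocGenerics::end(gr),
             strand = as.character(BiocGenerics::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write probe sequences to FASTA
#'
#' @param probes A `dart_probes` object or DNAStringSet.
#' @param path Output path.
#' @export
write_probes <- function(probes, path) {
  seqs <- if (inherits(probes, "dart_probes")) probes$sequences else probes
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read probe sequences from FASTA
#'
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_probes <- function(path) Biostrings::readDNAStringSet(path)

#' Write / read a genotype matrix with quality metrics
#'
#' Rows are markers; the first columns carry the marker id and quality
#' metrics, then parent scores `P1`, `P2`, then progeny scores. Missing
#' scores are written as `NA`.
#'
#' @param cross A `dart_cross` (or list with `genotypes` and `markers`).
#' @param path Output TSV path.
#' @export
write_genotypes <- function(cross, path) {
  g <- cross$genotypes
  mk <- cross$markers
  df <- data.frame(marker_id = rownames(g),
                   reproducibility = mk$reproducibility[
                     match(rownames(g), mk$marker_id)],
                   q_score = mk$q_score[match(rownames(g), mk$marker_id)],
                   call_rate = mk$call_rate[match(rownames(g), mk$marker_id)],
                   g, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @return `read_genotypes`: list with `genotypes` (character matrix) and
#'   `markers` (data.frame of quality metrics).
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE,
                          colClasses = "character")
  meta <- c("marker_id", "reproducibility", "q_score", "call_rate")
  geno <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  rownames(geno) <- df$marker_id
  markers <- data.frame(marker_id = df$marker_id,
                        reproducibility = as.numeric(df$reproducibility),
                        q_score = as.numeric(df$q_score),
                        call_rate = as.numeric(df$call_rate),
                        stringsAsFactors = FALSE)
  list(genotypes = geno, markers = markers)
}

#' Write a truth or linkage map table to TSV
#'
#' @param x data.frame (e.g. `dart_cross$markers` or [map_table()] output).
#' @param path Output TSV path.
#' @export
write_map_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map_table
#' @export
read_map_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
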