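# Lossless readers and writers for the pipeline's table formats: counts and
# metadata TSV, module partition TSV, hit tables, precursor intervals as
# GFF3, mature sequences as FASTA, and JSON summaries.

#' Write / read a counts matrix as TSV
#'
#' Tab-separated, features in rows, first column `feature_id`, header row
#' of sample identifiers.
#'
#' @param counts integer feature x sample matrix.
#' @param path file path.
#' @return `read_counts_tsv` returns the integer matrix with dimnames.
#' @export
write_counts_tsv <- function(counts, path) {
  check_counts(counts)
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  check_counts(m)
}

#' Write / read sample metadata as TSV
#' @param metadata data.frame of per-sample design factors.
#' @param path file path.
#' @export
write_metadata_tsv <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata_tsv
#' @export
read_metadata_tsv <- function(path) {
  md <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  rownames(md) <- md$sample_id
  md
}

#' Write / read a module partition as TSV (gene, module)
#' @param partition named integer vector of module labels.
#' @param path file path.
#' @export
write_partition_tsv <- function(partition, path) {
  utils::write.table(data.frame(gene = names(partition),
                                module = as.integer(partition)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition_tsv
#' @export
read_partition_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.integer(df$module), df$gene)
}

#' Write / read a directional hit table as TSV
#' @param hits data.frame with columns query, subject, evalue, bitscore.
#' @param path file path.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
read_hits_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write / read precursor intervals as GFF3
#'
#' Features are written with type `pre_miRNA` and `ID`/`mature_seq`
#' attributes. GFF3 coordinates are 1-based closed, matching the internal
#' GRanges representation, so the round trip is exact.
#'
#' @param loci locus table from [merge_loci()] (or any data.frame with
#'   precursor_id, chrom, start, end, strand, mature_seq).
#' @param path file path.
#' @return `read_gff3_precursors` returns a `GRanges` with `ID` and
#'   `mature_seq` metadata columns.
#' @export
write_gff3_precursors <- function(loci, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start, end = loci$end),
    strand = loci$strand)
  S4Vectors::mcols(gr)$type <- "pre_miRNA"
  S4Vectors::mcols(gr)$ID <- loci$precursor_id
  S4Vectors::mcols(gr)$mature_seq <- loci$mature_seq
  if ("locus_id" %in% names(loci))
    S4Vectors::mcols(gr)$locus_id <- loci$locus_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3_precursors
#' @export
read_gff3_precursors <- function(path) {
  rtracklayer::import(path, format = "gff3")
}

#' Write / read named sequences as FASTA (RNA alphabet)
#' @param seqs named character vector of RNA sequences.
#' @param path file path.
#' @export
write_fasta_rna <- function(seqs, path) {
  x <- Biostrings::RNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta_rna
#' @export
read_fasta_rna <- function(path) {
  x <- Biostrings::readRNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write / read a JSON summary
#' @param x list to serialize.
#' @param path file path.
#' @export
write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_json_summary
#' @export
read_json_summary <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
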