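# File-format helpers.  Coordinates are 1-based inclusive everywhere in the
# package and its TSV reports; conversion to 0-based half-open happens only
# at the BED boundary.

#' Write sequences as FASTA
#'
#' @param seqs Named character vector or DNAStringSet.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(as_seq_character(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub(" .*$", "", names(x)))
}

#' Write intervals as BED
#'
#' Input intervals are 1-based inclusive (`start`, `end`, plus a `contig`
#' column); written as 0-based half-open BED.
#'
#' @param df Data.frame with contig/start/end (and optionally name).
#' @param path Output file.
#' @param names Optional name column values.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path, names = NULL) {
  if (!nrow(df)) {
    file.create(path)
    return(invisible(path))
  }
  bed <- data.frame(chrom = df$contig, start = df$start - 1L, end = df$end,
                    name = if (!is.null(names)) names else ".",
                    stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write gene-copy hits as GFF3
#'
#' @param hits A [find_gene_copies()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gff3_hits <- function(hits, path) {
  if (!nrow(hits)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = hits$contig,
    ranges = IRanges::IRanges(hits$start, hits$end),
    strand = hits$strand)
  S4Vectors::mcols(gr)$source <- "tandemcheck"
  S4Vectors::mcols(gr)$type <- "gene_copy"
  S4Vectors::mcols(gr)$ID <- sprintf("copy%03d", seq_len(nrow(hits)))
  S4Vectors::mcols(gr)$variant_id <- hits$best_variant_id
  S4Vectors::mcols(gr)$identity <- sprintf("%.2f", hits$percent_identity)
  S4Vectors::mcols(gr)$ties <- ifelse(hits$ties == "", NA, hits$ties)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a data.frame as TSV
#'
#' @param df Data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a depth track as wiggle-style TSV
#'
#' Columns contig, pos (1-based), depth.
#'
#' @param track A `depth_track`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(track, path) {
  df <- do.call(rbind, lapply(names(track), function(ctg)
    data.frame(contig = ctg, pos = seq_along(track[[ctg]]),
               depth = track[[ctg]], stringsAsFactors = FALSE)))
  write_tsv(df, path)
}
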