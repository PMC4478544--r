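# k-mer subtraction audit: decompose both the assembly and a high-coverage
# read set into canonical k-mers and flag assembly windows whose k-mer is
# absent from the reads.  With error-free high-coverage reads of the true
# genome, unmatched k-mers point at assembly errors.

#' Build the canonical k-mer set of a read set
#'
#' @param reads A `read_set` or character vector of read sequences.
#' @param k k-mer size (11..26; must not exceed the read length).
#' @return A `read_kmer_set`: list with `k` and `members` (sorted numeric
#'   codes of canonical k-mers).
#' @export
build_read_kmer_set <- function(reads, k = 15) {
  seqs <- if (is.data.frame(reads)) reads$sequence else as_seq_character(reads)
  if (!length(seqs)) stop("empty read set: the audit would flag everything")
  if (k < 11) stop("k must be >= 11")
  if (k > min(nchar(seqs)))
    stop("k exceeds the minimum read length")
  structure(list(k = as.integer(k),
                 members = tc_kmer_set(seqs, as.integer(k))),
            class = "read_kmer_set")
}

#' @export
print.read_kmer_set <- function(x, ...) {
  cat(sprintf("read_kmer_set: %d canonical %d-mers\n", length(x$members), x$k))
  invisible(x)
}

.contigs_of <- function(assembly) {
  if (inherits(assembly, "genome_fixture")) return(assembly$contigs)
  x <- as_seq_character(assembly)
  if (is.null(names(x))) names(x) <- sprintf("contig%d", seq_along(x))
  x
}

#' Audit an assembly against a read k-mer set
#'
#' Tiled mode (the default) tests consecutive non-overlapping k-windows
#' (positions 1, k+1, ...; a trailing remainder shorter than k is ignored),
#' so a point error yields one reported unmatched k-mer; sliding mode tests
#' every offset.  With `single_copy_filter`, windows whose canonical k-mer
#' occurs more than once in the assembly are skipped.
#'
#' @param assembly Named character vector / DNAStringSet of contigs, or a
#'   `genome_fixture`.
#' @param readset A [build_read_kmer_set()] object.
#' @param mode `"tiled"` or `"sliding"`.
#' @param single_copy_filter Skip multi-copy assembly k-mers.
#' @return An `unmatched_kmer_report`: list with `positions` (data.frame:
#'   contig, pos -- 1-based window starts, strictly increasing per contig),
#'   `summary` (per contig: contig, audited_from, audited_to, n_unmatched),
#'   `n_unmatched`, `k`, `mode`, `single_copy_filter`.
#' @export
audit_assembly <- function(assembly, readset, mode = c("tiled", "sliding"),
                           single_copy_filter = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(readset, "read_kmer_set"))
  contigs <- .contigs_of(assembly)
  k <- readset$k
  if (any(nchar(contigs) < k)) stop("all contigs must be at least k long")
  filt <- if (single_copy_filter) tc_kmer_counts(unname(contigs), k)
          else list(codes = numeric(), counts = integer())
  pos_l <- lapply(names(contigs), function(ctg) {
    p <- tc_kmer_audit(contigs[[ctg]], k, readset$members,
                       mode == "sliding", single_copy_filter,
                       filt$codes, filt$counts)
    if (length(p)) data.frame(contig = ctg, pos = p,
                              stringsAsFactors = FALSE) else NULL
  })
  positions <- do.call(rbind, pos_l)
  if (is.null(positions))
    positions <- data.frame(contig = character(), pos = integer())
  summary <- data.frame(
    contig = names(contigs),
    audited_from = 1L,
    audited_to = ifelse(mode == "sliding", nchar(contigs) - k + 1L,
                        (nchar(contigs) %/% k) * k),
    n_unmatched = vapply(names(contigs), function(ctg)
      sum(positions$contig == ctg), integer(1)),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  structure(list(positions = positions, summary = summary,
                 n_unmatched = nrow(positions), k = k, mode = mode,
                 single_copy_filter = single_copy_filter),
            class = "unmatched_kmer_report")
}

#' @export
print.unmatched_kmer_report <- function(x, ...) {
  cat(sprintf("unmatched_kmer_report (%s, k=%d%s): %d unmatched k-mer window(s)\n",
              x$mode, x$k,
              if (x$single_copy_filter) ", single-copy filter" else "",
              x$n_unmatched))
  print(x$summary)
  invisible(x)
}

#' Unmatched k-mer windows as a GRanges (BED-ready)
#'
#' @param report An `unmatched_kmer_report`.
#' @return A [GenomicRanges::GRanges] of the unmatched windows.
#' @export
unmatched_granges <- function(report) {
  p <- report$positions
  GenomicRanges::GRanges(
    seqnames = if (nrow(p)) p$contig else character(),
    ranges = IRanges::IRanges(start = p$pos, width = report$k))
}
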