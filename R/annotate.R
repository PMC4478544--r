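# Homology annotation of an assembly: enumerate gene copies by
# seed-and-extend search with a panel of gene variants, mask repeats by
# shared k-mers with a TE library, and summarize the array region (span,
# multiplicities, orientation, repeat fraction).

#' Find gene copies in an assembly
#'
#' Seed-and-extend local alignment of every query variant against both
#' strands of the assembly.  Overlapping hits at the same locus are merged
#' and the best variant kept (ties broken by higher identity, then lower
#' variant id); hits below the identity/coverage thresholds are dropped.
#' When several identical queries hit a locus equally well, the hit is
#' assigned to the lexicographically smallest id and the full tie set is
#' recorded.
#'
#' @param assembly Named character vector / DNAStringSet of contigs, or a
#'   `genome_fixture`.
#' @param queries A [make_variant_set()] or named character vector of gene
#'   sequences.
#' @param min_identity Minimum percent identity (default 95).
#' @param min_query_coverage Minimum fraction of the query aligned
#'   (default 0.9).
#' @param seed_len Exact seed length (default 12).
#' @param band Minimum DP half-band width (default 16).
#' @return A `gene_copy_hits` data.frame: contig, start, end (1-based
#'   inclusive), strand, best_variant_id, percent_identity, query_coverage,
#'   ties (comma-separated ids of equally good variants).
#' @export
find_gene_copies <- function(assembly, queries, min_identity = 95,
                             min_query_coverage = 0.9, seed_len = 12,
                             band = 16) {
  contigs <- .contigs_of(assembly)
  qseqs <- if (inherits(queries, "variant_set")) queries$variants
           else as_seq_character(queries)
  if (!length(qseqs)) stop("queries must be non-empty")
  if (is.null(names(qseqs))) names(qseqs) <- sprintf("Q%d", seq_along(qseqs))
  empty <- structure(
    data.frame(contig = character(), start = integer(), end = integer(),
               strand = character(), best_variant_id = character(),
               percent_identity = numeric(), query_coverage = numeric(),
               ties = character(), stringsAsFactors = FALSE),
    class = c("gene_copy_hits", "data.frame"))
  if (!length(contigs) || all(nchar(contigs) < seed_len)) return(empty)
  hits <- tc_search(unname(contigs), unname(qseqs), seed_len = seed_len,
                    stride = 4L, cluster_gap = 40L, min_seed_hits = 2L,
                    band_min = band, band_pad = band, max_edit_frac = 0.35,
                    max_clusters = 100000L)
  if (!nrow(hits)) return(empty)
  hits$identity <- 100 * hits$matches / hits$aln_len
  hits$qcov <- (hits$q_end - hits$q_start + 1L) / nchar(qseqs)[hits$query]
  hits <- hits[hits$identity >= min_identity &
                 hits$qcov >= min_query_coverage, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  # merge hits into loci: overlapping target intervals on the same contig
  hits <- hits[order(hits$target, hits$t_start), , drop = FALSE]
  locus <- integer(nrow(hits)); cur <- 0L; ct <- -1L; ce <- -1L
  for (i in seq_len(nrow(hits))) {
    if (hits$target[i] != ct || hits$t_start[i] > ce) {
      cur <- cur + 1L; ct <- hits$target[i]; ce <- hits$t_end[i]
    } else ce <- max(ce, hits$t_end[i])
    locus[i] <- cur
  }
  rows <- lapply(split(seq_len(nrow(hits)), locus), function(ix) {
    h <- hits[ix, , drop = FALSE]
    h <- h[order(-h$identity, names(qseqs)[h$query]), , drop = FALSE]
    best <- h[1, ]
    tied <- h[h$identity == best$identity & h$edits == best$edits, ,
              drop = FALSE]
    tie_ids <- sort(names(qseqs)[tied$query])
    data.frame(
      contig = names(contigs)[best$target], start = best$t_start,
      end = best$t_end, strand = ifelse(best$strand > 0, "+", "-"),
      best_variant_id = tie_ids[1],
      percent_identity = best$identity, query_coverage = best$qcov,
      ties = if (length(tie_ids) > 1) paste(tie_ids, collapse = ",") else "",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$contig, names(contigs)), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("gene_copy_hits", "data.frame"))
}

#' Mask repeats against a TE library
#'
#' Marks every assembly position covered by a canonical k-mer shared with
#' the library, merging masked intervals across gaps of up to `merge_gap`
#' bp.
#'
#' @param assembly Contigs (or `genome_fixture`).
#' @param te_library Named character vector / DNAStringSet of repeat
#'   elements.
#' @param k Shared k-mer size (default 13).
#' @param merge_gap Merge masked intervals separated by at most this many bp
#'   (default 20).
#' @return A `repeat_mask`: list with `intervals` (data.frame: contig,
#'   start, end), `masked_bp`, `fraction` (per contig) and
#'   `total_fraction`.
#' @export
mask_repeats <- function(assembly, te_library, k = 13, merge_gap = 20) {
  contigs <- .contigs_of(assembly)
  lib <- as_seq_character(te_library)
  if (!length(lib)) stop("TE library must be non-empty")
  libset <- tc_kmer_set(lib, as.integer(k))
  iv <- lapply(names(contigs), function(ctg) {
    pos <- tc_kmer_audit(contigs[[ctg]], as.integer(k), libset,
                         TRUE, FALSE, numeric(), integer())
    # tc_kmer_audit reports UNmatched windows; shared = complement
    all_pos <- seq_len(max(0L, nchar(contigs[[ctg]]) - k + 1L))
    shared <- setdiff(all_pos, pos)
    if (!length(shared)) return(NULL)
    ir <- IRanges::reduce(IRanges::IRanges(shared, width = k),
                          min.gapwidth = merge_gap + 1L)
    data.frame(contig = ctg, start = IRanges::start(ir),
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  intervals <- do.call(rbind, iv)
  if (is.null(intervals))
    intervals <- data.frame(contig = character(), start = integer(),
                            end = integer())
  masked_bp <- vapply(names(contigs), function(c)
    sum(intervals$end[intervals$contig == c] -
          intervals$start[intervals$contig == c] + 1L), numeric(1))
  fraction <- masked_bp / nchar(contigs)
  structure(list(intervals = intervals, masked_bp = masked_bp,
                 fraction = fraction,
                 total_fraction = sum(masked_bp) / sum(nchar(contigs)),
                 k = k, merge_gap = merge_gap),
            class = "repeat_mask")
}

#' @export
print.repeat_mask <- function(x, ...) {
  cat(sprintf("repeat_mask (k=%d): %d interval(s), %.1f%% of assembly masked\n",
              x$k, nrow(x$intervals), 100 * x$total_fraction))
  invisible(x)
}

#' Region report for a gene array
#'
#' Summarizes gene-copy hits into the array-region report: span (first hit
#' start to last hit end, inclusive), copy count, per-variant multiplicity,
#' orientation consistency and repeat fraction within the span.  Hits on
#' several contigs yield one report per contig plus a fragmentation warning.
#'
#' @param hits A [find_gene_copies()] result (>= 1 hit).
#' @param masked Optional [mask_repeats()] result for the repeat fraction.
#' @param contig_lengths Optional named lengths (for bookkeeping).
#' @return A `region_report`: data.frame with one row per contig: contig,
#'   array_span_bp, span_kb (nearest-kb, half up), first_start, last_end,
#'   n_copies, orientation_consistent, repeat_fraction; attribute
#'   `multiplicity` (named list per contig).
#' @export
region_report <- function(hits, masked = NULL, contig_lengths = NULL) {
  if (!nrow(hits)) stop("need at least one gene-copy hit")
  ctgs <- unique(hits$contig)
  if (length(ctgs) > 1)
    warning("gene copies found on ", length(ctgs),
            " contigs: array is fragmented; reporting per contig")
  mult <- list()
  rows <- lapply(ctgs, function(ctg) {
    h <- hits[hits$contig == ctg, , drop = FALSE]
    span <- c(min(h$start), max(h$end))
    span_bp <- span[2] - span[1] + 1L
    m <- table(h$best_variant_id)
    mult[[ctg]] <<- setNames(as.integer(m), names(m))
    rf <- NA_real_
    if (!is.null(masked)) {
      iv <- masked$intervals[masked$intervals$contig == ctg, , drop = FALSE]
      if (nrow(iv)) {
        ir <- IRanges::restrict(
          IRanges::reduce(IRanges::IRanges(iv$start, iv$end)),
          span[1], span[2])
        rf <- sum(IRanges::width(ir)) / span_bp
      } else rf <- 0
    }
    data.frame(contig = ctg, array_span_bp = span_bp,
               span_kb = floor(span_bp / 1000 + 0.5),
               first_start = span[1], last_end = span[2],
               n_copies = nrow(h),
               orientation_consistent = length(unique(h$strand)) == 1L,
               repeat_fraction = rf, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("region_report", "data.frame"),
            multiplicity = mult, fragmented = length(ctgs) > 1)
}

#' @export
print.region_report <- function(x, ...) {
  df <- as.data.frame(x)
  cat("region_report:\n")
  print(df)
  for (ctg in names(attr(x, "multiplicity"))) {
    m <- attr(x, "multiplicity")[[ctg]]
    cat(sprintf("  %s multiplicities: %s\n", ctg,
                paste(sprintf("%s=%d", names(m), m), collapse = " ")))
  }
  invisible(x)
}
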