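# Depth-based audits: read mapping (exact-seed + banded-extension), per-base
# depth, zero-coverage regions, consistent mismatches, and panel-based
# copy-number calls calibrated against diploid depth.

#' Map reads to a reference
#'
#' Exact-seed, banded-extension alignment.  Each read is reported at its
#' minimal-mismatch locus (mismatches = edit distance of the banded
#' alignment); under the `random` tie policy one of the equally best loci is
#' chosen uniformly (seeded); under `all_best` every best locus is reported
#' with weight 1/n_ties.  Reads whose best locus has more than
#' `max_mismatch_frac` mismatches are unmapped.
#'
#' @param reads A `read_set` or character vector of read sequences.
#' @param reference Named character vector / DNAStringSet of contigs, or a
#'   `genome_fixture`.
#' @param tie_policy `"random"` or `"all_best"`.
#' @param seed Seed for random tie-breaking.
#' @param seed_len,stride,band,max_mismatch_frac Aligner tuning: exact seed
#'   length, seed sampling stride on the read, minimum DP half-band, and the
#'   unmapped threshold (default 0.2).
#' @return An `alignment_set` data.frame: read_id, contig, start, end
#'   (1-based inclusive), strand, n_mismatches, weight, is_best.
#' @export
map_reads <- function(reads, reference, tie_policy = c("random", "all_best"),
                      seed = 1, seed_len = 13, stride = 4, band = 8,
                      max_mismatch_frac = 0.2) {
  tie_policy <- match.arg(tie_policy)
  contigs <- .contigs_of(reference)
  if (!length(contigs)) stop("reference is empty")
  seqs <- if (is.data.frame(reads)) reads$sequence else as_seq_character(reads)
  ids <- if (is.data.frame(reads)) reads$read_id else
    sprintf("read%d", seq_along(seqs))
  hits <- tc_search(unname(contigs), seqs, seed_len = seed_len,
                    stride = stride, min_seed_hits = 2L, band_min = band,
                    band_pad = band, max_edit_frac = max_mismatch_frac,
                    max_clusters = 32L, cluster_gap = 40L)
  if (!nrow(hits)) return(.empty_alignments())
  # best loci per read: full-length alignments only, minimal edit distance
  qlen <- nchar(seqs)[hits$query]
  full <- hits$q_end - hits$q_start + 1L >= qlen  # query aligned end to end
  hits <- hits[full, , drop = FALSE]
  if (!nrow(hits)) return(.empty_alignments())
  set.seed(seed)
  # vectorized best-per-query selection: after sorting by (query, edits) the
  # first row of each query block carries the minimum
  hits <- hits[order(hits$query, hits$edits), , drop = FALSE]
  first <- !duplicated(hits$query)
  grp <- cumsum(first)
  qmin <- hits$edits[first][grp]
  best <- hits$edits == qmin
  out <- hits[best, , drop = FALSE]
  grp <- grp[best]
  nties <- tabulate(grp)
  if (tie_policy == "random") {
    ord <- order(grp, runif(nrow(out)))
    out <- out[ord[!duplicated(grp[ord])], , drop = FALSE]
    out$weight <- 1
  } else {
    out$weight <- 1 / nties[grp]
  }
  aln <- data.frame(
    read_id = ids[out$query],
    contig = names(contigs)[out$target],
    start = out$t_start, end = out$t_end,
    strand = ifelse(out$strand > 0, "+", "-"),
    n_mismatches = out$edits,
    weight = out$weight,
    is_best = TRUE,
    q_start = out$q_start, q_end = out$q_end, query = out$query,
    stringsAsFactors = FALSE)
  rownames(aln) <- NULL
  structure(aln, class = c("alignment_set", "data.frame"))
}

.empty_alignments <- function() {
  structure(data.frame(
    read_id = character(), contig = character(), start = integer(),
    end = integer(), strand = character(), n_mismatches = integer(),
    weight = numeric(), is_best = logical(), q_start = integer(),
    q_end = integer(), query = integer(), stringsAsFactors = FALSE),
    class = c("alignment_set", "data.frame"))
}

#' Per-base depth track from alignments
#'
#' `depth[i]` is the sum of alignment weights covering base i.
#'
#' @param alignments An `alignment_set` (from [map_reads()]).
#' @param reference The reference the alignments refer to.
#' @return A `depth_track`: named list of numeric vectors, one per contig.
#' @export
compute_depth <- function(alignments, reference) {
  contigs <- .contigs_of(reference)
  tr <- lapply(names(contigs), function(ctg) {
    a <- alignments[alignments$contig == ctg, , drop = FALSE]
    L <- nchar(contigs[[ctg]])
    if (!nrow(a)) return(numeric(L))
    as.numeric(IRanges::coverage(IRanges::IRanges(a$start, a$end),
                                 weight = a$weight, width = L))
  })
  names(tr) <- names(contigs)
  structure(tr, class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  for (ctg in names(x))
    cat(sprintf("%s: %d bp, mean depth %.2f, %d zero-depth bp\n", ctg,
                length(x[[ctg]]), mean(x[[ctg]]), sum(x[[ctg]] == 0)))
  invisible(x)
}

#' Zero-coverage regions of a depth track
#'
#' Maximal runs of zero depth (contig ends included), per contig.
#'
#' @param track A `depth_track`.
#' @return A `zero_coverage_report`: list with `regions` (data.frame: contig,
#'   start, end, length), `n_regions`, `total_zero_bp`, and a per-contig
#'   `summary` mirroring the audit-table columns (regions with zero coverage,
#'   total bp with zero coverage).
#' @export
find_zero_coverage <- function(track) {
  reg <- do.call(rbind, lapply(names(track), function(ctg) {
    r <- rle(track[[ctg]] == 0)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    z <- r$values
    if (!any(z)) return(NULL)
    data.frame(contig = ctg, start = starts[z], end = ends[z],
               length = r$lengths[z], stringsAsFactors = FALSE)
  }))
  if (is.null(reg))
    reg <- data.frame(contig = character(), start = integer(),
                      end = integer(), length = integer())
  summary <- data.frame(
    contig = names(track),
    n_regions = vapply(names(track), function(c) sum(reg$contig == c),
                       integer(1)),
    total_zero_bp = vapply(names(track), function(c)
      sum(reg$length[reg$contig == c]), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  structure(list(regions = reg, n_regions = nrow(reg),
                 total_zero_bp = sum(reg$length), summary = summary),
            class = "zero_coverage_report")
}

#' @export
print.zero_coverage_report <- function(x, ...) {
  cat(sprintf("zero_coverage_report: %d region(s), %d bp total\n",
              x$n_regions, x$total_zero_bp))
  print(x$summary)
  invisible(x)
}

#' Consistent mismatches between reads and the assembly
#'
#' Pileup of read bases over the assembly; a site is reported where depth is
#' at least `min_depth` and one single non-reference base is supported by at
#' least `min_fraction` of the covering reads.
#'
#' @param alignments An `alignment_set`.
#' @param reads The `read_set` the alignments came from.
#' @param reference The reference.
#' @param min_fraction Minimum supporting fraction (default 0.8).
#' @param min_depth Minimum pileup depth (default 10).
#' @return Data.frame: contig, position, assembly_base, consensus_base,
#'   support_fraction, depth.
#' @export
find_consistent_mismatches <- function(alignments, reads, reference,
                                       min_fraction = 0.8, min_depth = 10) {
  contigs <- .contigs_of(reference)
  empty <- data.frame(contig = character(), position = integer(),
                      assembly_base = character(),
                      consensus_base = character(),
                      support_fraction = numeric(), depth = numeric())
  if (!nrow(alignments)) return(empty)
  seqs <- if (is.data.frame(reads)) reads$sequence else as_seq_character(reads)
  piles <- tc_pileup(unname(contigs), seqs,
                     alignments$query, match(alignments$contig, names(contigs)),
                     alignments$start, alignments$end,
                     alignments$q_start, alignments$q_end,
                     ifelse(alignments$strand == "+", 1L, -1L),
                     alignments$weight)
  bases <- c("A", "C", "G", "T")
  out <- lapply(seq_along(contigs), function(ti) {
    M <- piles[[ti]]
    depth <- colSums(M)
    ref <- strsplit(contigs[[ti]], "", fixed = TRUE)[[1]]
    ref_i <- match(ref, bases)
    cand <- which(depth >= min_depth)
    rows <- lapply(cand, function(p) {
      if (is.na(ref_i[p])) return(NULL)
      cnt <- M[, p]
      alt <- which.max(replace(cnt, ref_i[p], -1))
      frac <- cnt[alt] / depth[p]
      if (alt != ref_i[p] && !is.na(frac) && frac >= min_fraction)
        data.frame(contig = names(contigs)[ti], position = p,
                   assembly_base = ref[p], consensus_base = bases[alt],
                   support_fraction = frac, depth = depth[p],
                   stringsAsFactors = FALSE)
      else NULL
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Depth-calibrated copy-number calls against a gene panel
#'
#' Maps long reads to a panel of near-identical gene variants (all-best
#' policy with fractional weights, so ties among panel entries do not
#' double-count), accumulates per-base depth on each variant, and converts
#' mean depth to an integer copy number against a diploid calibration depth
#' D: `copy_number = round(2 * mean_depth / D)` (half away from zero).
#' Variants with `mean_depth < tau * D / 2` are flagged as artifacts
#' ("essentially zero coverage") and forced to copy number 0.
#'
#' Short reads are rejected: they are too short to be unambiguously assigned
#' to near-identical paralogs.
#'
#' @param reads A long-read `read_set`.
#' @param panel A [make_variant_set()] object or named character vector of
#'   panel gene sequences (pairwise distinct).
#' @param D Diploid calibration depth (x); must be > 0.
#' @param tau Artifact threshold as a fraction of the haploid band D/2
#'   (default 0.1).
#' @param min_instance_cov Minimum fraction of a variant that a read-local
#'   hit must cover to count, unless the hit is clipped at a read end.
#' @param seed_len Exact seed length for the panel search.
#' @return A `copy_number_calls` data.frame: variant_id, length, mean_depth,
#'   copy_number, artifact; attribute `D`.
#' @export
estimate_copy_number <- function(reads, panel, D, tau = 0.1,
                                 min_instance_cov = 0.5, seed_len = 13) {
  if (D <= 0) stop("calibration depth D must be > 0")
  pseqs <- if (inherits(panel, "variant_set")) panel$variants
           else as_seq_character(panel)
  if (anyDuplicated(pseqs)) stop("panel variants must be pairwise distinct")
  if (is.null(names(pseqs))) names(pseqs) <- sprintf("P%d", seq_along(pseqs))
  seqs <- if (is.data.frame(reads)) reads$sequence else as_seq_character(reads)
  plen <- nchar(pseqs)
  short <- plen < 4 * seed_len
  if (any(short)) {
    warning("panel variant(s) shorter than the usable seed span excluded: ",
            paste(names(pseqs)[short], collapse = ", "))
    pseqs <- pseqs[!short]; plen <- plen[!short]
  }
  if (!length(pseqs)) stop("no usable panel variants")
  if (stats::median(nchar(seqs)) < 2 * max(plen))
    stop("reads are too short for unambiguous panel assignment; ",
         "use long reads (median length >= 2x the longest panel gene)")

  # search panel genes inside the reads: targets = reads, queries = variants
  hits <- tc_search(seqs, unname(pseqs), seed_len = seed_len, stride = 4L,
                    cluster_gap = 60L, min_seed_hits = 2L, band_min = 32L,
                    band_pad = 48L, max_edit_frac = 0.35,
                    max_clusters = 1000000L)
  cov <- lapply(plen, numeric)  # per-variant coverage accumulators
  if (nrow(hits)) {
    # fragments covering less than min_instance_cov of a variant are
    # dropped even when clipped at a read end: short overlaps rarely span
    # an informative site, so they cannot distinguish near-identical
    # paralogs and would leak depth onto absent (phantom) panel entries
    hits$qcov <- (hits$q_end - hits$q_start + 1L) / plen[hits$query]
    hits <- hits[hits$qcov >= min_instance_cov, , drop = FALSE]
  }
  if (nrow(hits)) {
    # group hits into read-local gene instances (overlapping read intervals)
    ord <- order(hits$target, hits$t_start)
    hits <- hits[ord, , drop = FALSE]
    inst <- integer(nrow(hits))
    cur <- 0L; cur_t <- -1L; cur_end <- -1L
    for (i in seq_len(nrow(hits))) {
      if (hits$target[i] != cur_t || hits$t_start[i] > cur_end) {
        cur <- cur + 1L
        cur_t <- hits$target[i]
        cur_end <- hits$t_end[i]
      } else {
        cur_end <- max(cur_end, hits$t_end[i])
      }
      inst[i] <- cur
    }
    for (rows in split(seq_len(nrow(hits)), inst)) {
      h <- hits[rows, , drop = FALSE]
      h <- h[!duplicated(h$query), , drop = FALSE]  # one hit per variant
      best <- which(h$matches == max(h$matches))
      w <- 1 / length(best)
      for (b in best) {
        v <- h$query[b]
        cov[[v]][h$q_start[b]:h$q_end[b]] <-
          cov[[v]][h$q_start[b]:h$q_end[b]] + w
      }
    }
  }
  mean_depth <- vapply(seq_along(pseqs), function(v) sum(cov[[v]]) / plen[v],
                       numeric(1))
  artifact <- mean_depth < tau * D / 2
  copy_number <- ifelse(artifact, 0L, as.integer(floor(2 * mean_depth / D + 0.5)))
  calls <- data.frame(variant_id = names(pseqs), length = plen,
                      mean_depth = mean_depth, copy_number = copy_number,
                      artifact = artifact, stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  structure(calls, class = c("copy_number_calls", "data.frame"), D = D,
            tau = tau)
}

#' @export
print.copy_number_calls <- function(x, ...) {
  cat(sprintf("copy_number_calls (D = %gx, tau = %g):\n", attr(x, "D"),
              attr(x, "tau")))
  print(as.data.frame(x))
  invisible(x)
}
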