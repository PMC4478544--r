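# Shared fixtures, built once per test run and memoised.

.fx_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx_cache[[key]])) .fx_cache[[key]] <- force(expr)
  .fx_cache[[key]]
}

# Small fixture: 4 variants, multiplicities 3/2/1/1 (7 copies), compact
# geometry -- fast enough for mapping and copy-number unit tests.
small_locus <- function() memo("small_locus", make_source_locus(2400, seed = 1))

small_variants <- function() memo("small_variants",
  make_variant_set(small_locus(), 4, 0.005, 1, seed = 7))

small_spec <- function()
  array_spec(setNames(c(3L, 2L, 1L, 1L), names(small_variants()$variants)),
             spacer_mean = 800, spacer_sd = 150, te_fraction_target = 0.2,
             flank_length = 1500, diploid_flank = 1500)

small_fixture <- function() memo("small_fixture",
  build_tandem_array(small_variants(), small_spec(), seed = 3,
                     locus = small_locus()))

small_short_reads <- function() memo("small_short_reads",
  simulate_reads(small_fixture(), short_read_config(seed = 11)))

small_short_reads_clean <- function() memo("small_short_reads_clean",
  simulate_reads(small_fixture(),
                 short_read_config(substitution_rate = 0, seed = 11)))

small_long_reads <- function() memo("small_long_reads",
  simulate_reads(small_fixture(), long_read_config(seed = 12)))

# Exhaustive error-free "reads": every k2-window of every contig, so every
# true k-mer is guaranteed present.
exhaustive_reads <- function(fixture, k2 = 30) {
  unlist(lapply(unname(fixture$contigs), function(ctg) {
    L <- nchar(ctg)
    starts <- seq(1L, L - k2 + 1L, by = 7L)
    starts <- unique(c(starts, L - k2 + 1L))
    substring(ctg, starts, starts + k2 - 1L)
  }))
}

# Reference-scale fixture mirroring the study conditions: 12 variants,
# multiplicities 3/3/2/2 and eight singletons (18 copies).
paper_locus <- function() memo("paper_locus", make_source_locus(3400, seed = 101))

paper_variants <- function() memo("paper_variants",
  make_variant_set(paper_locus(), 12, 0.005, 7, seed = 102))

paper_multiplicity <- function()
  setNames(c(3L, 3L, 2L, 2L, rep(1L, 8)), names(paper_variants()$variants))

paper_fixture <- function() memo("paper_fixture",
  build_tandem_array(paper_variants(),
                     array_spec(paper_multiplicity()), seed = 103,
                     locus = paper_locus()))

paper_long_reads <- function() memo("paper_long_reads",
  simulate_reads(paper_fixture(), long_read_config(seed = 104)))

# Six chimeric "phantom gene" sequences pasted from genuine variants,
# including one complementary pair (A,B)/(B,A) from the same crossover
# interval, mirroring how PCR artifacts arise.
paper_artifact_panel <- function() memo("paper_artifact_panel", {
  v <- paper_variants()$variants
  genuine <- c(v, source = paper_variants()$source)
  # a phantom must be a well-supported mosaic (>= 3 informative sites per
  # side) AND clearly absent from the genome (>= 3 substitutions from every
  # genuine sequence, source locus included)
  try_mk <- function(a, b, bp = NULL) {
    chi <- tryCatch(make_recombinant(v, a, b, breakpoint = bp),
                    error = function(e) NULL)
    if (is.null(chi)) return(NULL)
    if (min(adist(as.character(chi), genuine)) < 3) return(NULL)
    chi
  }
  ids <- names(v)
  art <- character(0); bps <- integer(0)
  # first a reciprocal pair from one crossover interval, then singles
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i == j || length(art) >= 2) next
      x <- try_mk(ids[i], ids[j])
      if (is.null(x)) next
      y <- try_mk(ids[j], ids[i], attr(x, "breakpoint"))
      if (is.null(y) || identical(as.character(x), as.character(y))) next
      art <- c(A1 = as.character(x), A2 = as.character(y))
      bps <- c(attr(x, "breakpoint"), attr(y, "breakpoint"))
    }
  }
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i == j || length(art) >= 6) next
      x <- try_mk(ids[i], ids[j])
      if (is.null(x) || as.character(x) %in% art) next
      art[sprintf("A%d", length(art) + 1L)] <- as.character(x)
      bps <- c(bps, attr(x, "breakpoint"))
    }
  }
  stopifnot(length(art) == 6, !art %in% genuine, !duplicated(art))
  attr(art, "breakpoints") <- bps
  art
})

# Independent R-side canonical k-mer encoder (oracle for the C++ set).
oracle_canonical_codes <- function(seqs, k) {
  enc1 <- function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    v <- match(ch, c("A", "C", "G", "T")) - 1
    if (anyNA(v)) return(NA_real_)
    sum(v * 4^(rev(seq_along(v)) - 1))
  }
  codes <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(numeric())
    ws <- substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(ws)))
    vapply(seq_along(ws), function(i) {
      a <- enc1(ws[i]); b <- enc1(rc[i])
      if (is.na(a) || is.na(b)) NA_real_ else min(a, b)
    }, numeric(1))
  }))
  sort(unique(codes[!is.na(codes)]))
}
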