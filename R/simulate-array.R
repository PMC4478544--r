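# Tandem-array fixture builder: a haploid contig carrying the array (each
# copy = a gene variant embedded in its full source-locus context, all on the
# plus strand, separated by TE-rich spacers) and a diploid contig carrying the
# intact autosomal source locus.  Ground truth (copy coordinates, TE
# intervals, segment tiling) is recorded for downstream verification.

#' Array specification
#'
#' @param multiplicity Named integer vector, variant id -> copy count.
#' @param spacer_mean,spacer_sd Normal parameters (bp) for inter-copy spacer
#'   lengths (truncated at 200 bp).  Defaults give spacers large enough to
#'   host the default TE budget.
#' @param te_fraction_target Target fraction of the array span (first gene
#'   start to last gene end) covered by transposable-element sequence drawn
#'   from `te_library` (default 0.48).
#' @param flank_length Non-array sequence on each side of the array (bp).
#' @param diploid_flank Flank around the source locus on the diploid contig.
#' @return An `array_spec` list.
#' @export
array_spec <- function(multiplicity, spacer_mean = 3800, spacer_sd = 800,
                       te_fraction_target = 0.48, flank_length = 5000,
                       diploid_flank = 5000) {
  if (is.null(names(multiplicity)) || any(names(multiplicity) == ""))
    stop("multiplicity must be a named vector (variant ids)")
  if (any(multiplicity < 1) || any(multiplicity != round(multiplicity)))
    stop("multiplicities must be positive integers")
  if (te_fraction_target < 0 || te_fraction_target > 1)
    stop("te_fraction_target must be in [0, 1]")
  structure(list(
    multiplicity = setNames(as.integer(multiplicity), names(multiplicity)),
    spacer_mean = spacer_mean, spacer_sd = spacer_sd,
    te_fraction_target = te_fraction_target,
    flank_length = as.integer(flank_length),
    diploid_flank = as.integer(diploid_flank)
  ), class = "array_spec")
}

#' Bundled synthetic retroelement library
#'
#' Loads the small synthetic "retroelement" library shipped with the package
#' (random sequences generated once with a fixed seed; no real transposable
#' element content), used to fill array spacers and as the masking library.
#'
#' @return A named character vector of element sequences.
#' @export
default_te_library <- function() {
  path <- system.file("extdata", "te_library.fasta", package = "tandemcheck")
  as_seq_character(Biostrings::readDNAStringSet(path))
}

# Build one spacer of the given length containing ~te_bp bases of TE library
# segments interleaved with random linker.  Returns list(seq, te), where te
# is a data.frame of TE intervals relative to the spacer (1-based).
.build_spacer <- function(len, te_bp, te_library) {
  if (len <= 0) return(list(seq = "", te = NULL))
  te_bp <- min(te_bp, len)
  segs <- list()       # list of (seq, is_te, element)
  remaining_te <- te_bp
  remaining_len <- len
  while (remaining_len > 0) {
    if (remaining_te > 0) {
      el <- sample(seq_along(te_library), 1L)
      elseq <- te_library[[el]]
      take <- min(nchar(elseq), remaining_te, remaining_len)
      off <- sample.int(nchar(elseq) - take + 1L, 1L)
      segs[[length(segs) + 1L]] <- list(
        seq = substring(elseq, off, off + take - 1L), is_te = TRUE,
        element = names(te_library)[el])
      remaining_te <- remaining_te - take
      remaining_len <- remaining_len - take
    }
    if (remaining_len > 0) {
      linker_budget <- remaining_len - remaining_te
      if (linker_budget <= 0) next
      take <- if (remaining_te > 0)
        sample.int(min(linker_budget, 200L), 1L) else linker_budget
      segs[[length(segs) + 1L]] <- list(
        seq = random_dna(take), is_te = FALSE, element = NA_character_)
      remaining_len <- remaining_len - take
    }
  }
  lens <- vapply(segs, function(s) nchar(s$seq), integer(1))
  starts <- cumsum(c(1L, lens))[seq_along(segs)]
  is_te <- vapply(segs, function(s) s$is_te, logical(1))
  te <- if (any(is_te)) data.frame(
    start = starts[is_te], end = starts[is_te] + lens[is_te] - 1L,
    element = vapply(segs[is_te], function(s) s$element, character(1)),
    stringsAsFactors = FALSE) else NULL
  list(seq = paste(vapply(segs, function(s) s$seq, character(1)),
                   collapse = ""), te = te)
}

#' Build a tandem-array genome fixture
#'
#' Assembles a haploid (ploidy-1) contig carrying `sum(multiplicity)` copies
#' of the gene variants, each embedded in its full source-locus context and
#' all in the same orientation, separated by spacers whose TE content is
#' budgeted so that the realized TE fraction of the array span matches
#' `spec$te_fraction_target`; plus a diploid (ploidy-2) contig carrying the
#' intact source locus.
#'
#' @param variants A [make_variant_set()] object.
#' @param spec An [array_spec()].
#' @param seed Integer seed.
#' @param locus The [make_source_locus()] the variants derive from.
#' @param te_library Named character vector of repeat elements
#'   (default [default_te_library()]); `NULL` or empty together with
#'   `te_fraction_target = 0` gives TE-free spacers.
#' @return A `genome_fixture`: list with `contigs` (named character),
#'   `ploidy` (named integer), `truth_copies` (data.frame: contig, start, end,
#'   strand, variant_id, unit_start, unit_end -- gene coordinates 1-based
#'   inclusive), `truth_te` (data.frame of TE intervals), `truth_edits`
#'   (empty data.frame), `segments` (the exact tiling used to build the array
#'   contig), plus the `variants` and `locus` used.
#' @export
build_tandem_array <- function(variants, spec, seed = 1,
                               locus = NULL, te_library = default_te_library()) {
  stopifnot(inherits(variants, "variant_set"), inherits(spec, "array_spec"))
  unknown <- setdiff(names(spec$multiplicity), names(variants$variants))
  if (length(unknown))
    stop("multiplicity references unknown variant(s): ",
         paste(unknown, collapse = ", "))
  if (is.null(locus))
    stop("supply the source locus the variants derive from")
  set.seed(seed)

  gene_feat <- locus$features[locus$features$kind == "complete_gene", ]
  gs <- gene_feat$start; ge <- gene_feat$end
  left_ctx <- substring(locus$sequence, 1L, gs - 1L)
  right_ctx <- substring(locus$sequence, ge + 1L, locus$length)

  copy_ids <- rep(names(spec$multiplicity), spec$multiplicity)
  copy_ids <- sample(copy_ids)  # shuffle copy order along the array
  n_copies <- length(copy_ids)

  n_spacers <- n_copies - 1L
  spacer_len <- if (n_spacers > 0)
    pmax(200L, round(rnorm(n_spacers, spec$spacer_mean, spec$spacer_sd)))
  else integer()

  unit_len <- nchar(left_ctx) + nchar(variants$variants[copy_ids]) +
    nchar(right_ctx)
  # TE budget: target fraction of the span (first gene start .. last gene end)
  span_bp <- sum(unit_len) + sum(spacer_len) - (gs - 1L) -
    (nchar(right_ctx))
  te_total <- round(spec$te_fraction_target * span_bp)
  if (te_total > sum(spacer_len)) {
    warning("spacers too short for the TE budget; realized TE fraction ",
            "will fall short of the target")
    te_total <- sum(spacer_len)
  }
  te_per_spacer <- if (n_spacers > 0)
    round(te_total * spacer_len / max(1, sum(spacer_len))) else integer()
  if (spec$te_fraction_target > 0 &&
      (is.null(te_library) || !length(te_library)))
    stop("te_fraction_target > 0 requires a TE library")

  segments <- list()  # (kind, seq, variant_id)
  add_seg <- function(kind, seq, variant_id = NA_character_) {
    segments[[length(segments) + 1L]] <<- list(
      kind = kind, seq = seq, variant_id = variant_id)
  }
  te_rel <- list()  # TE intervals relative to segment, resolved later
  add_seg("flank", random_dna(spec$flank_length))
  for (i in seq_len(n_copies)) {
    unit <- paste0(left_ctx, variants$variants[[copy_ids[i]]], right_ctx)
    add_seg("unit", unit, copy_ids[i])
    if (i <= n_spacers) {
      sp <- .build_spacer(spacer_len[i], te_per_spacer[i], te_library)
      add_seg("spacer", sp$seq)
      te_rel[[length(segments)]] <- sp$te
    }
  }
  add_seg("flank", random_dna(spec$flank_length))

  seqs <- vapply(segments, function(s) s$seq, character(1))
  starts <- cumsum(c(1L, nchar(seqs)))[seq_along(seqs)]
  array_contig <- paste(seqs, collapse = "")

  kinds <- vapply(segments, function(s) s$kind, character(1))
  vids <- vapply(segments, function(s) s$variant_id, character(1))
  seg_df <- data.frame(kind = kinds, start = starts,
                       end = starts + nchar(seqs) - 1L,
                       variant_id = vids, stringsAsFactors = FALSE)

  unit_rows <- which(kinds == "unit")
  truth_copies <- data.frame(
    contig = "array_contig",
    start = starts[unit_rows] + (gs - 1L),
    end = starts[unit_rows] + (gs - 1L) +
      nchar(variants$variants[vids[unit_rows]]) - 1L,
    strand = "+",
    variant_id = vids[unit_rows],
    unit_start = starts[unit_rows],
    unit_end = starts[unit_rows] + nchar(seqs[unit_rows]) - 1L,
    stringsAsFactors = FALSE)
  rownames(truth_copies) <- NULL

  truth_te <- do.call(rbind, lapply(seq_along(segments), function(i) {
    if (i > length(te_rel)) return(NULL)
    te <- te_rel[[i]]
    if (is.null(te)) return(NULL)
    data.frame(contig = "array_contig",
               start = starts[i] + te$start - 1L,
               end = starts[i] + te$end - 1L,
               element = te$element, stringsAsFactors = FALSE)
  }))
  if (is.null(truth_te))
    truth_te <- data.frame(contig = character(), start = integer(),
                           end = integer(), element = character())

  diploid_contig <- paste0(random_dna(spec$diploid_flank), locus$sequence,
                           random_dna(spec$diploid_flank))
  source_interval <- c(spec$diploid_flank + 1L,
                       spec$diploid_flank + locus$length)

  structure(list(
    contigs = c(array_contig = array_contig,
                autosome_contig = diploid_contig),
    ploidy = c(array_contig = 1L, autosome_contig = 2L),
    truth_copies = truth_copies,
    truth_te = truth_te,
    truth_edits = .empty_edits(),
    segments = seg_df,
    segment_seqs = seqs,
    source_interval = source_interval,
    variants = variants,
    locus = locus,
    spec = spec,
    seed = seed
  ), class = "genome_fixture")
}

.empty_edits <- function() {
  data.frame(type = character(), contig = character(), pos = integer(),
             length = integer(), payload = character(),
             detail = character(), stringsAsFactors = FALSE)
}

#' @export
print.genome_fixture <- function(x, ...) {
  cat(sprintf("genome_fixture: %d contigs (%s)\n", length(x$contigs),
              paste(sprintf("%s %d bp ploidy %d", names(x$contigs),
                            nchar(x$contigs), x$ploidy), collapse = "; ")))
  cat(sprintf("  %d gene copies (%d variants), %d TE intervals, %d edits\n",
              nrow(x$truth_copies), length(unique(x$truth_copies$variant_id)),
              nrow(x$truth_te), nrow(x$truth_edits)))
  invisible(x)
}

#' Realized TE fraction of the array span
#'
#' Fraction of the array span (first gene start to last gene end of
#' `truth_copies`) covered by truth TE intervals.
#'
#' @param fixture A `genome_fixture`.
#' @return A number in \[0, 1\].
#' @export
realized_te_fraction <- function(fixture) {
  tc <- fixture$truth_copies
  if (!nrow(tc)) return(0)
  span <- c(min(tc$start), max(tc$end))
  te <- fixture$truth_te
  if (!nrow(te)) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(te$start, te$end))
  ir <- IRanges::restrict(ir, span[1], span[2])
  sum(IRanges::width(ir)) / (span[2] - span[1] + 1)
}
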