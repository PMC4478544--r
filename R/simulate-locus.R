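# Source-locus and variant-set generators.  The simulated unit mimics a small
# autosomal locus carrying one complete gene (with a short intron) nested
# between fragments of two flanking genes; tandem duplication of this unit on
# a haploid chromosome is what the downstream audits are calibrated against.

# Fixed feature geometry (bp).  The complete gene is
# utr5a | intron | utr5b | CDS | utr3, so the CDS stays contiguous and a
# premature stop can be introduced by a single substitution.
.locus_geom <- list(
  exon_a1 = 180L, exon_a2 = 210L, utr_b = 150L,
  utr5a = 30L, intron = 62L, utr5b = 30L, n_codons = 215L, utr3 = 90L,
  min_gap = 30L
)

.gene_length <- function(g = .locus_geom) {
  g$utr5a + g$intron + g$utr5b + 3L * (g$n_codons + 1L) + g$utr3
}

# An open reading frame of n_codons codons: ATG, n_codons - 2 random
# stop-free codons, TAA.
.random_cds <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  bases <- c("A", "C", "G", "T")
  codons <- character(n_codons - 2L)
  for (i in seq_along(codons)) {
    repeat {
      cd <- paste(sample(bases, 3, replace = TRUE), collapse = "")
      if (!cd %in% stops) break
    }
    codons[i] <- cd
  }
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

#' Simulate a source locus
#'
#' Generates a random-composition locus containing, in fixed order along the
#' sequence, an exon fragment of flanking gene A, one complete gene carrying a
#' small intron, a second exon fragment of gene A, and a UTR fragment of
#' flanking gene B.  This is the duplication unit for [build_tandem_array()].
#'
#' @param length Total locus length in bp (default 3400); must be at least
#'   1000 and large enough to host all features.
#' @param seed Integer seed; the locus is deterministic given `(length, seed)`.
#' @return A `source_locus`: list with `sequence` (character), `length`,
#'   `features` (data.frame: name, start, end, strand, kind; 1-based
#'   inclusive) and `gene` (relative sub-structure of the complete gene).
#' @export
make_source_locus <- function(length = 3400, seed = 1) {
  stopifnot_scalar_int(length, "length")
  if (length < 1000) stop("length must be >= 1000 bp")
  g <- .locus_geom
  glen <- .gene_length(g)
  feat_len <- c(g$exon_a1, glen, g$exon_a2, g$utr_b)
  need <- sum(feat_len) + 5L * g$min_gap
  if (length < need)
    stop(sprintf(
      "length %d bp is too small to host all locus features (need >= %d bp)",
      length, need))
  set.seed(seed)
  # split the slack over 5 gaps (leading, 3 internal, trailing)
  slack <- length - sum(feat_len) - 5L * g$min_gap
  cuts <- sort(sample.int(slack + 1L, 4L, replace = TRUE) - 1L)
  gaps <- g$min_gap + diff(c(0L, cuts, slack))

  cds <- .random_cds(g$n_codons + 1L)
  gene_seq <- paste0(
    random_dna(g$utr5a),
    "GT", random_dna(g$intron - 4L), "AG",
    random_dna(g$utr5b),
    cds,
    random_dna(g$utr3))
  pieces <- c(random_dna(gaps[1]), random_dna(g$exon_a1), random_dna(gaps[2]),
              gene_seq, random_dna(gaps[3]), random_dna(g$exon_a2),
              random_dna(gaps[4]), random_dna(g$utr_b), random_dna(gaps[5]))
  seq <- paste(pieces, collapse = "")
  starts <- cumsum(c(1L, nchar(pieces)))[seq_along(pieces)]
  feat_idx <- c(2L, 4L, 6L, 8L)
  features <- data.frame(
    name = c("flankA_exon1", "gene", "flankA_exon2", "flankB_utr"),
    start = starts[feat_idx],
    end = starts[feat_idx] + nchar(pieces[feat_idx]) - 1L,
    strand = "+",
    kind = c("exon_fragment", "complete_gene", "exon_fragment",
             "utr_fragment"),
    stringsAsFactors = FALSE)
  cds_rel_start <- g$utr5a + g$intron + g$utr5b + 1L
  structure(list(
    sequence = seq,
    length = length,
    features = features,
    gene = list(
      sequence = gene_seq,
      length = glen,
      intron_rel = c(g$utr5a + 1L, g$utr5a + g$intron),
      cds_rel = c(cds_rel_start, cds_rel_start + nchar(cds) - 1L)
    ),
    seed = seed
  ), class = "source_locus")
}

#' @export
print.source_locus <- function(x, ...) {
  cat(sprintf("source_locus: %d bp, %d features (gene %d bp with %d-bp intron)\n",
              x$length, nrow(x$features), x$gene$length,
              diff(x$gene$intron_rel) + 1L))
  print(x$features)
  invisible(x)
}

# Introduce a premature stop codon into the CDS of a gene sequence by a single
# substitution; codon chosen in the middle half of the CDS.
.insert_premature_stop <- function(gene_seq, cds_rel) {
  cds <- substring(gene_seq, cds_rel[1], cds_rel[2])
  n_codon <- nchar(cds) %/% 3L
  cand <- sample(seq(max(2L, floor(n_codon * 0.25)),
                     floor(n_codon * 0.75))) # internal codons, shuffled
  stops <- c("TAA", "TAG", "TGA")
  for (ci in cand) {
    cd <- substring(cds, 3L * (ci - 1L) + 1L, 3L * ci)
    for (s in stops) {
      d <- which(strsplit(cd, "")[[1]] != strsplit(s, "")[[1]])
      if (length(d) == 1L) {
        pos <- cds_rel[1] + 3L * (ci - 1L) + d - 1L
        substr(gene_seq, pos, pos) <- substring(s, d, d)
        return(gene_seq)
      }
    }
  }
  # fall back: rewrite one whole internal codon to TAA
  ci <- cand[1]
  a <- cds_rel[1] + 3L * (ci - 1L)
  substr(gene_seq, a, a + 2L) <- "TAA"
  gene_seq
}

#' Derive a set of gene variants from a source locus
#'
#' Each variant is the locus's complete gene sequence with independent
#' per-site substitutions at rate `divergence`; `n_pseudo` of them are turned
#' into pseudogenes by introducing a premature stop codon.
#'
#' @param locus A [make_source_locus()] object.
#' @param n_variants Number of variants to generate.
#' @param divergence Per-site substitution probability used to derive each
#'   variant (default 0.005; must be < 0.5 or variants would not be
#'   recognizably homologous).
#' @param n_pseudo Number of variants flagged as pseudogenes
#'   (`n_pseudo <= n_variants`).
#' @param seed Integer seed.
#' @return A `variant_set`: list with `variants` (named character vector, ids
#'   `"Y1"`, `"Y2"`, ...), `pseudo` (logical, named), `divergence`, `source`
#'   (the ancestral gene sequence).
#' @export
make_variant_set <- function(locus, n_variants, divergence = 0.005,
                             n_pseudo = 0, seed = 1) {
  stopifnot(inherits(locus, "source_locus"))
  if (divergence >= 0.5)
    stop("divergence >= 0.5: variants would not be recognizably homologous")
  if (n_pseudo > n_variants) stop("n_pseudo must be <= n_variants")
  set.seed(seed)
  gene <- locus$gene$sequence
  ids <- paste0("Y", seq_len(n_variants))
  variants <- character(n_variants)
  pseudo_idx <- if (n_pseudo > 0) sort(sample.int(n_variants, n_pseudo)) else integer()
  for (i in seq_len(n_variants)) {
    v <- gene
    for (try in 1:25) {
      v <- mutate_sites(gene, divergence)
      if (i %in% pseudo_idx)
        v <- .insert_premature_stop(v, locus$gene$cds_rel)
      if (!v %in% variants[seq_len(i - 1L)]) break
    }
    if (v %in% variants[seq_len(i - 1L)] && divergence > 0)
      warning("could not make variant ", ids[i], " distinct")
    variants[i] <- v
  }
  names(variants) <- ids
  pseudo <- setNames(seq_len(n_variants) %in% pseudo_idx, ids)
  structure(list(
    variants = variants,
    pseudo = pseudo,
    divergence = divergence,
    source = gene,
    locus_seed = locus$seed,
    seed = seed
  ), class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d variants (%d pseudogenes), divergence %.4g, gene %d bp\n",
              length(x$variants), sum(x$pseudo), x$divergence,
              nchar(x$variants[[1]])))
  invisible(x)
}

#' @export
length.variant_set <- function(x) length(x$variants)
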