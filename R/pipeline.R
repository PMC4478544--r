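# End-to-end orchestration: fixture -> (optional corruption) -> reads ->
# k-mer + depth audits -> copy-number calls -> PCR clones -> chimera calls ->
# annotation -> combined report.  Every stochastic stage receives an
# explicit seed derived from the global seed, so a config reruns
# bit-identically.

#' Pipeline configuration
#'
#' Defaults describe the reference scenario the package is calibrated
#' against: a 3.4-kb source locus, 12 gene variants at divergence 0.005
#' (7 pseudogenes), multiplicities 3/3/2/2 and eight singletons (18 copies
#' total), 48% TE target, short reads at 45x per haploid copy (so ~90x on
#' the diploid contig) and indel-dominated long reads at the same
#' calibration.
#'
#' @param seed Global integer seed; all stage seeds derive from it.
#' @param outdir Output directory (`NULL` = no files written).
#' @param locus_length,n_variants,divergence,n_pseudo Fixture parameters.
#' @param multiplicity Named or unnamed copy counts (unnamed: assigned to
#'   variants in order).
#' @param te_fraction,spacer_mean,spacer_sd,flank_length Array geometry.
#' @param short_reads,long_reads Read simulation configs (seeds are
#'   overridden by derived stage seeds).
#' @param k k-mer size for the k-mer audit.
#' @param tau Artifact threshold for copy-number calls.
#' @param edits Optional list of [edits] to inject before auditing.
#' @param pcr A [pcr_sim_config()] (seed overridden).
#' @param run_pcr Whether to run the PCR/chimera stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, outdir = NULL, locus_length = 3400,
                            n_variants = 12, divergence = 0.005,
                            n_pseudo = 7,
                            multiplicity = c(3, 3, 2, 2, rep(1, 8)),
                            te_fraction = 0.48, spacer_mean = 3800,
                            spacer_sd = 800, flank_length = 5000,
                            short_reads = short_read_config(),
                            long_reads = long_read_config(),
                            k = 15, tau = 0.1, edits = NULL,
                            pcr = pcr_sim_config(), run_pcr = TRUE) {
  if (length(multiplicity) > n_variants)
    stop("more multiplicities than variants")
  structure(list(seed = seed, outdir = outdir, locus_length = locus_length,
                 n_variants = n_variants, divergence = divergence,
                 n_pseudo = n_pseudo, multiplicity = multiplicity,
                 te_fraction = te_fraction, spacer_mean = spacer_mean,
                 spacer_sd = spacer_sd, flank_length = flank_length,
                 short_reads = short_reads, long_reads = long_reads,
                 k = k, tau = tau, edits = edits, pcr = pcr,
                 run_pcr = run_pcr), class = "pipeline_config")
}

#' Run the full validation pipeline
#'
#' Executes simulate -> (optional inject) -> reads -> k-mer audit + depth
#' audit -> copy-number calls -> PCR clones + chimera calls -> annotation,
#' and assembles a combined report (per-contig audit metrics, per-variant
#' copy-number calls with artifact verdicts, chimera calls, region report).
#' Deterministic given the config; if `outdir` is set, report files (TSV,
#' BED, GFF3, FASTA, JSON) are written there.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list; see components.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  sseed <- function(off) derive_seed(config$seed, off)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  locus <- stage("simulate", make_source_locus(config$locus_length, sseed(1)))
  variants <- stage("simulate", make_variant_set(
    locus, config$n_variants, config$divergence, config$n_pseudo, sseed(2)))
  mult <- config$multiplicity
  if (is.null(names(mult)))
    names(mult) <- names(variants$variants)[seq_along(mult)]
  spec <- array_spec(mult, spacer_mean = config$spacer_mean,
                     spacer_sd = config$spacer_sd,
                     te_fraction_target = config$te_fraction,
                     flank_length = config$flank_length)
  fixture <- stage("simulate",
                   build_tandem_array(variants, spec, sseed(3), locus = locus))
  truth_fixture <- fixture
  if (!is.null(config$edits))
    fixture <- stage("inject",
                     inject_misassemblies(fixture, config$edits, sseed(4)))

  src <- config$short_reads; src$seed <- sseed(5)
  short <- stage("reads", simulate_reads(truth_fixture, src))
  lrc <- config$long_reads; lrc$seed <- sseed(6)
  long <- stage("reads", simulate_reads(truth_fixture, lrc))

  kset <- stage("kmer_audit", build_read_kmer_set(short, config$k))
  kmer_report <- stage("kmer_audit", audit_assembly(fixture, kset, "tiled"))

  aln <- stage("depth_audit", map_reads(short, fixture, "random", sseed(7)))
  track <- stage("depth_audit", compute_depth(aln, fixture))
  zero <- stage("depth_audit", find_zero_coverage(track))
  mism <- stage("depth_audit",
                find_consistent_mismatches(aln, short, fixture))

  D <- 2 * config$long_reads$depth
  # panel = Y-array variants plus the autosomal source gene, so reads from
  # the diploid source locus have their own panel home
  panel <- c(variants$variants, source_gene = variants$source)
  cn <- stage("copynum",
              estimate_copy_number(long, panel, D = D, tau = config$tau))

  pcr_res <- NULL; chimera <- NULL; pairs <- NULL
  if (isTRUE(config$run_pcr)) {
    pc <- config$pcr; pc$seed <- sseed(8)
    pcr_res <- stage("chimera",
                     simulate_pcr_clones(variants, pc,
                                         template_counts = mult))
    acc <- pcr_res$accepted
    cand <- acc[acc$provenance != "genuine", , drop = FALSE]
    if (nrow(cand)) {
      cand_seqs <- setNames(cand$sequence, cand$seq_id)
      chimera <- stage("chimera",
                       explain_recombinants(cand_seqs, variants$variants))
      pairs <- detect_complementary_pairs(chimera)
    }
  }

  hits <- stage("annotate", find_gene_copies(fixture, variants))
  mask <- stage("annotate",
                mask_repeats(fixture, default_te_library()))
  region <- stage("annotate", region_report(hits, mask))

  # combined per-variant verdicts: depth class + chimera evidence
  verdicts <- data.frame(
    variant_id = cn$variant_id,
    copy_number = cn$copy_number,
    mean_depth = cn$mean_depth,
    depth_class = ifelse(cn$artifact, "artifact",
                         ifelse(cn$copy_number >= 2, "multi_copy", "haploid")),
    stringsAsFactors = FALSE)

  report <- structure(list(
    config = config, fixture = fixture, truth_fixture = truth_fixture,
    short_reads = short, long_reads = long,
    kmer_report = kmer_report, alignments = aln, depth = track,
    zero_coverage = zero, mismatches = mism, copy_number = cn,
    pcr = pcr_res, chimera_calls = chimera, complementary_pairs = pairs,
    gene_hits = hits, repeat_mask = mask, region = region,
    verdicts = verdicts,
    audit_summary = data.frame(
      contig = kmer_report$summary$contig,
      unmatched_kmers = kmer_report$summary$n_unmatched,
      zero_coverage_regions = zero$summary$n_regions[
        match(kmer_report$summary$contig, zero$summary$contig)],
      zero_coverage_bp = zero$summary$total_zero_bp[
        match(kmer_report$summary$contig, zero$summary$contig)],
      stringsAsFactors = FALSE)
  ), class = "pipeline_report")

  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n===============\n")
  cat("Audit summary (per contig):\n"); print(x$audit_summary)
  cat("\nCopy-number calls:\n"); print(as.data.frame(x$copy_number))
  if (!is.null(x$chimera_calls)) {
    cat("\nChimera calls on accepted non-genuine PCR variants:\n")
    print(attr(x$chimera_calls, "summary"))
  }
  cat("\nRegion report:\n"); print(as.data.frame(x$region))
  invisible(x)
}

#' Write pipeline report files
#'
#' @param report A `pipeline_report`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(outdir, f)
  write_fasta(report$fixture$contigs, fp("assembly.fasta"))
  write_fasta(report$truth_fixture$variants$variants, fp("variants.fasta"))
  write_reads_fastq(report$short_reads, fp("short_reads.fastq"))
  write_tsv(report$truth_fixture$truth_copies, fp("truth_copies.tsv"))
  write_bed(report$truth_fixture$truth_te, fp("truth_te.bed"))
  if (nrow(report$fixture$truth_edits))
    write_tsv(report$fixture$truth_edits, fp("truth_edits.tsv"))
  write_tsv(report$audit_summary, fp("audit_summary.tsv"))
  write_bed(report$zero_coverage$regions, fp("zero_coverage.bed"))
  up <- report$kmer_report$positions
  if (nrow(up)) {
    write_bed(data.frame(contig = up$contig, start = up$pos,
                         end = up$pos + report$kmer_report$k - 1L),
              fp("unmatched_kmers.bed"))
  } else file.create(fp("unmatched_kmers.bed"))
  write_tsv(report$mismatches, fp("consistent_mismatches.tsv"))
  write_tsv(as.data.frame(report$copy_number), fp("copy_number.tsv"))
  if (!is.null(report$chimera_calls))
    write_tsv(attr(report$chimera_calls, "summary"), fp("chimera_calls.tsv"))
  if (!is.null(report$complementary_pairs) &&
      nrow(report$complementary_pairs))
    write_tsv(report$complementary_pairs, fp("complementary_pairs.tsv"))
  write_gff3_hits(report$gene_hits, fp("gene_copies.gff3"))
  write_bed(report$repeat_mask$intervals, fp("repeat_mask.bed"))
  write_tsv(as.data.frame(report$region), fp("region_report.tsv"))
  write_tsv(report$verdicts, fp("verdicts.tsv"))
  json <- list(
    seed = report$config$seed,
    audit = report$audit_summary,
    copy_number = as.data.frame(report$copy_number),
    region = as.data.frame(report$region),
    verdicts = report$verdicts)
  jsonlite::write_json(json, fp("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(outdir)
}
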