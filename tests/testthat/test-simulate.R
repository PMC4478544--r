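# Synthetic-data generator: locus, variants, tandem array, reads.

test_that("source locus is deterministic, feature-ordered and bounded", {
  l1 <- make_source_locus(3400, seed = 1)
  l2 <- make_source_locus(3400, seed = 1)
  expect_identical(l1$sequence, l2$sequence)
  expect_identical(l1$features, l2$features)
  expect_equal(nchar(l1$sequence), 3400)

  f <- l1$features
  expect_equal(nrow(f), 4)
  expect_equal(f$kind, c("exon_fragment", "complete_gene", "exon_fragment",
                         "utr_fragment"))
  expect_true(all(f$start >= 1 & f$end <= 3400 & f$start <= f$end))
  expect_true(all(diff(f$start) > 0))  # fixed order along the sequence

  # the complete gene carries one small intron with canonical boundaries
  g <- substring(l1$sequence, f$start[2], f$end[2])
  expect_identical(g, l1$gene$sequence)
  intron <- substring(g, l1$gene$intron_rel[1], l1$gene$intron_rel[2])
  expect_identical(substring(intron, 1, 2), "GT")
  expect_identical(substring(intron, nchar(intron) - 1, nchar(intron)), "AG")

  l3 <- make_source_locus(3400, seed = 2)
  expect_false(identical(l1$sequence, l3$sequence))

  expect_error(make_source_locus(900), "1000")
  expect_error(make_source_locus(1100), "too small")
})

test_that("variant sets hit the requested divergence and pseudogene count", {
  locus <- paper_locus()
  vs <- make_variant_set(locus, 12, 0.005, 6, seed = 7)
  expect_length(vs$variants, 12)
  expect_false(anyDuplicated(names(vs$variants)) > 0)
  expect_equal(sum(vs$pseudo), 6)

  # pairwise identity over all 66 pairs, via the edit-distance oracle
  L <- nchar(vs$variants[[1]])
  pairs <- combn(12, 2)
  pid <- apply(pairs, 2, function(p) {
    d <- as.integer(adist(vs$variants[[p[1]]], vs$variants[[p[2]]]))
    1 - d / L
  })
  expect_true(all(pid >= 0.98))
  expect_gt(mean(pid), 0.985)
  expect_lt(mean(pid), 0.999)

  # pseudogenes carry a premature stop in frame
  cds_rel <- locus$gene$cds_rel
  has_stop <- vapply(vs$variants, function(v) {
    cds <- substring(v, cds_rel[1], cds_rel[2])
    n <- nchar(cds) %/% 3
    codons <- substring(cds, 3 * (seq_len(n - 1) - 1) + 1, 3 * seq_len(n - 1))
    any(codons[-1] %in% c("TAA", "TAG", "TGA"))
  }, logical(1))
  expect_true(all(has_stop[vs$pseudo]))

  v1 <- make_variant_set(locus, 1, 0.0, 0, seed = 3)
  expect_identical(unname(v1$variants), vs$source)

  expect_error(make_variant_set(locus, 4, 0.6, 0, seed = 1), "homologous")
  expect_error(make_variant_set(locus, 2, 0.01, 3, seed = 1), "n_pseudo")
})

test_that("tandem array records complete, consistent ground truth", {
  fx <- paper_fixture()
  tc <- fx$truth_copies
  expect_equal(nrow(tc), 18)
  expect_true(all(tc$strand == "+"))
  expect_equal(fx$ploidy[["array_contig"]], 1L)
  expect_equal(fx$ploidy[["autosome_contig"]], 2L)

  # truth completeness: the recorded segment tiling reproduces the contig
  expect_identical(paste(fx$segment_seqs, collapse = ""),
                   fx$contigs[["array_contig"]])
  seg <- fx$segments
  expect_equal(seg$start[1], 1L)
  expect_true(all(seg$start[-1] == head(seg$end, -1) + 1L))
  expect_equal(seg$end[nrow(seg)], nchar(fx$contigs[["array_contig"]]))

  # every truth interval lies within its contig; gene inside its unit
  expect_true(all(tc$start >= 1 & tc$end <= nchar(fx$contigs[["array_contig"]])))
  expect_true(all(tc$start >= tc$unit_start & tc$end <= tc$unit_end))

  # the gene interval holds the exact variant sequence
  v <- fx$variants$variants
  ok <- vapply(seq_len(nrow(tc)), function(i)
    substring(fx$contigs[[tc$contig[i]]], tc$start[i], tc$end[i]) ==
      v[[tc$variant_id[i]]], logical(1))
  expect_true(all(ok))

  # arithmetic oracle: array span equals the sum of unit and spacer widths
  units <- seg[seg$kind == "unit", ]
  spacers <- seg[seg$kind == "spacer", ]
  span <- units$end[nrow(units)] - units$start[1] + 1L
  expect_equal(span, sum(units$end - units$start + 1L) +
                 sum(spacers$end - spacers$start + 1L))

  # realized TE fraction within 3 points of target
  expect_lt(abs(realized_te_fraction(fx) - 0.48), 0.03)

  # te_fraction 0 -> no truth TE intervals
  fx0 <- build_tandem_array(
    small_variants(),
    array_spec(setNames(c(1L, 1L), names(small_variants()$variants)[1:2]),
               spacer_mean = 500, spacer_sd = 50, te_fraction_target = 0,
               flank_length = 500),
    seed = 4, locus = small_locus())
  expect_equal(nrow(fx0$truth_te), 0)

  expect_error(build_tandem_array(
    small_variants(), array_spec(c(ZZ = 2L)), seed = 1,
    locus = small_locus()), "unknown variant")
})

test_that("read simulation respects depth, ploidy and error settings", {
  fx <- small_fixture()
  clean <- small_short_reads_clean()

  # zero error rates: every read is an exact substring (or its reverse
  # complement) of its contig
  idx <- seq(1, nrow(clean), by = 97)
  ok <- vapply(idx, function(i) {
    tmpl <- substring(fx$contigs[[clean$contig[i]]], clean$start[i],
                      clean$end[i])
    if (clean$strand[i] == "-")
      tmpl <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(tmpl)))
    identical(tmpl, clean$sequence[i])
  }, logical(1))
  expect_true(all(ok))

  # provenance pileup: realized mean depth close to ploidy x 45, and the
  # diploid:haploid ratio within the ploidy contract
  d <- provenance_mean_depth(clean, fx)
  expect_lt(abs(d[["array_contig"]] - 45) / 45, 0.02)
  expect_lt(abs(d[["autosome_contig"]] - 90) / 90, 0.02)
  expect_true(d[["autosome_contig"]] / d[["array_contig"]] >= 1.8)
  expect_true(d[["autosome_contig"]] / d[["array_contig"]] <= 2.2)

  # determinism
  r2 <- simulate_reads(fx, short_read_config(substitution_rate = 0, seed = 11))
  expect_identical(clean$sequence, r2$sequence)
  expect_identical(clean$start, r2$start)

  # long reads: indel errors change read length relative to the template
  lr <- small_long_reads()
  tlen <- lr$end - lr$start + 1L
  expect_gt(mean(nchar(lr$sequence) != tlen), 0.95)
  dl <- provenance_mean_depth(lr, fx)
  expect_lt(abs(dl[["array_contig"]] - 45) / 45, 0.05)
  expect_lt(abs(dl[["autosome_contig"]] - 90) / 90, 0.05)

  expect_error(short_read_config(depth_per_haploid_copy = 0), "depth")
  expect_error(short_read_config(substitution_rate = 1.2), "rates")
})
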