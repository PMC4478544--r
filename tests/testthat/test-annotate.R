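# Homology annotation: gene-copy enumeration, repeat masking, region report.

test_that("all 18 copies are recovered at truth coordinates with correct
           variants", {
  fx <- paper_fixture()
  hits <- find_gene_copies(fx, paper_variants())
  ah <- hits[hits$contig == "array_contig", ]
  tc <- fx$truth_copies[order(fx$truth_copies$start), ]
  expect_equal(nrow(ah), 18)
  expect_true(all(abs(ah$start - tc$start) <= 5))
  expect_true(all(abs(ah$end - tc$end) <= 5))
  expect_identical(ah$best_variant_id, tc$variant_id)
  expect_true(all(ah$percent_identity >= 99.9))
  expect_true(all(ah$strand == "+"))
  # the diploid source locus is found too, on its own contig
  expect_equal(sum(hits$contig == "autosome_contig"), 1)

  expect_equal(nrow(find_gene_copies(c(empty = strrep("A", 50)),
                                     paper_variants())), 0)
})

test_that("a reverse-complemented copy is reported on the minus strand", {
  fx <- small_fixture()
  tc <- fx$truth_copies[2, ]
  ctg <- fx$contigs[["array_contig"]]
  unit <- substring(ctg, tc$start, tc$end)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(unit)))
  flipped <- paste0(substring(ctg, 1, tc$start - 1), rc,
                    substring(ctg, tc$end + 1, nchar(ctg)))
  hits <- find_gene_copies(c(array_contig = flipped), small_variants())
  hit <- hits[hits$start == tc$start, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$strand, "-")
  rr <- region_report(hits)
  expect_false(rr$orientation_consistent)
})

test_that("repeat masking recovers the TE content of the fixture", {
  lib <- default_te_library()
  set.seed(41)
  bare <- c(plain = random_dna(5000))
  m0 <- mask_repeats(bare, lib)
  expect_equal(m0$total_fraction, 0)

  fx <- paper_fixture()
  mask <- mask_repeats(fx, lib)
  hits <- find_gene_copies(fx, paper_variants())
  rr <- region_report(hits[hits$contig == "array_contig", ], mask)
  expect_lt(abs(rr$repeat_fraction - 0.48), 0.05)

  # masked intervals cover at least 95% of truth TE bases
  te <- fx$truth_te
  iv <- mask$intervals[mask$intervals$contig == "array_contig", ]
  ir_t <- IRanges::reduce(IRanges::IRanges(te$start, te$end))
  ir_m <- IRanges::reduce(IRanges::IRanges(iv$start, iv$end))
  covered <- sum(IRanges::width(IRanges::intersect(ir_t, ir_m)))
  expect_gte(covered / sum(IRanges::width(ir_t)), 0.95)
})

test_that("region report computes spans, multiplicities and collapse
           effects", {
  # span from printed-style coordinates: 85040..180612 -> 95573 bp, 96 kb
  hits <- structure(data.frame(
    contig = "ctgA", start = c(85040L, 180000L), end = c(85900L, 180612L),
    strand = "+", best_variant_id = c("v1", "v2"),
    percent_identity = 100, query_coverage = 1, ties = "",
    stringsAsFactors = FALSE), class = c("gene_copy_hits", "data.frame"))
  rr <- region_report(hits)
  expect_equal(rr$array_span_bp, 95573L)
  expect_equal(rr$span_kb, 96)

  # single hit: span = hit length, one copy
  rr1 <- region_report(hits[1, ])
  expect_equal(rr1$array_span_bp, 861L)
  expect_equal(rr1$n_copies, 1)

  # fixture multiplicities: 3/3/2/2 and eight singletons, 18 copies
  fx <- paper_fixture()
  fhits <- find_gene_copies(fx, paper_variants())
  fr <- region_report(fhits[fhits$contig == "array_contig", ])
  expect_equal(fr$n_copies, 18)
  mult <- attr(fr, "multiplicity")[["array_contig"]]
  expect_equal(sort(unname(mult), decreasing = TRUE),
               c(3, 3, 2, 2, rep(1, 8)))
  expect_equal(unname(mult[names(paper_multiplicity())]),
               unname(paper_multiplicity()))

  # collapsing one unit of a multiplicity-3 variant drops n_copies by one
  v3 <- names(paper_multiplicity())[1]
  col <- inject_misassemblies(fx, list(edit_copy_collapse(v3)), seed = 6)
  chits <- find_gene_copies(col, paper_variants())
  cr <- region_report(chits[chits$contig == "array_contig", ])
  expect_equal(cr$n_copies, 17)
  expect_equal(unname(attr(cr, "multiplicity")[["array_contig"]][v3]), 2L)

  # hits on two contigs: fragmentation warning
  expect_warning(region_report(fhits), "fragmented")
})
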