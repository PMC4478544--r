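# k-mer subtraction audit.

test_that("read k-mer set equals brute-force enumeration and canonicalizes", {
  set.seed(42)
  reads <- vapply(1:30, function(i) random_dna(sample(25:60, 1)), character(1))
  ks <- build_read_kmer_set(reads, 15)
  expect_identical(ks$members, oracle_canonical_codes(reads, 15))

  # a read and its reverse complement give identical sets
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads)))
  expect_identical(build_read_kmer_set(rc, 15)$members, ks$members)

  # single 15-bp read, k = 15 -> one member
  expect_length(build_read_kmer_set("ACGTACGTACGTACG", 15)$members, 1)

  expect_error(build_read_kmer_set(character(), 15), "empty")
  expect_error(build_read_kmer_set(reads, 8), "k must be")
  expect_error(build_read_kmer_set(reads, 61), "read length")
})

test_that("clean assemblies audit clean; point edits are localized", {
  fx <- small_fixture()
  ks <- build_read_kmer_set(exhaustive_reads(fx), 15)

  clean_t <- audit_assembly(fx, ks, "tiled")
  clean_s <- audit_assembly(fx, ks, "sliding")
  expect_equal(clean_t$n_unmatched, 0)
  expect_equal(clean_s$n_unmatched, 0)

  # a substitution in unique sequence: exactly one unmatched tile, and
  # 1..k unmatched sliding windows all overlapping the edit
  pos <- 700L  # inside the unique flank
  cor <- inject_misassemblies(fx, list(edit_substitution(pos = pos)), seed = 2)
  tiled <- audit_assembly(cor, ks, "tiled")
  expect_equal(tiled$n_unmatched, 1)
  tile <- tiled$positions$pos
  expect_true(tile <= pos && pos <= tile + 14)  # the tile containing the edit
  # tile-enumeration oracle: the flagged tile is the unique tile covering pos
  expect_equal(tile, ((pos - 1) %/% 15) * 15 + 1)

  slid <- audit_assembly(cor, ks, "sliding")
  expect_gte(slid$n_unmatched, 1)
  expect_lte(slid$n_unmatched, 15)
  expect_true(all(slid$positions$pos <= pos &
                    slid$positions$pos + 14 >= pos))
})

test_that("unmatched windows overlap injected edits of every class", {
  fx <- small_fixture()
  ks <- build_read_kmer_set(exhaustive_reads(fx), 15)
  k <- 15
  cases <- list(
    list(edit_insertion(pos = 1000, length = 60), at = 1000, len = 60),
    list(edit_deletion(pos = 1000, length = 40), at = 1000, len = 0),
    list(edit_chimeric_join(pos = 1000, length = 200), at = 1000, len = 200))
  for (cs in cases) {
    cor <- inject_misassemblies(fx, list(cs[[1]]), seed = 7)
    rep <- audit_assembly(cor, ks, "sliding")
    expect_gt(rep$n_unmatched, 0)
    # soundness: every unmatched window touches the edited neighbourhood
    lo <- cs$at - k + 1; hi <- cs$at + cs$len + k - 1
    expect_true(all(rep$positions$pos >= lo & rep$positions$pos <= hi))
  }
})

test_that("audit obeys monotonicity, mode ordering and the copy filter", {
  fx <- small_fixture()
  reads_all <- exhaustive_reads(fx)
  cor <- inject_misassemblies(fx, list(edit_substitution(pos = 700)), seed = 2)

  # adding reads never increases the unmatched count
  half <- build_read_kmer_set(reads_all[seq(1, length(reads_all), 2)], 15)
  full <- build_read_kmer_set(reads_all, 15)
  for (mode in c("tiled", "sliding")) {
    n_half <- audit_assembly(cor, half, mode)$n_unmatched
    n_full <- audit_assembly(cor, full, mode)$n_unmatched
    expect_lte(n_full, n_half)
  }
  # tiled count never exceeds sliding count
  expect_lte(audit_assembly(cor, full, "tiled")$n_unmatched,
             audit_assembly(cor, full, "sliding")$n_unmatched)

  # single-copy filter skips windows whose k-mer repeats in the assembly:
  # an edit duplicated in two contigs goes unreported under the filter
  set.seed(8)
  uniq <- random_dna(400)
  dup <- random_dna(100)
  asm <- c(c1 = paste0(uniq, dup), c2 = paste0(random_dna(300), dup))
  ks2 <- build_read_kmer_set(
    exhaustive_reads(list(contigs = c(x = uniq))), 15)
  plain <- audit_assembly(asm, ks2, "sliding", single_copy_filter = FALSE)
  filt <- audit_assembly(asm, ks2, "sliding", single_copy_filter = TRUE)
  expect_gt(plain$n_unmatched, filt$n_unmatched)
  # the repeated segment itself is skipped under the filter: no flagged
  # window lies fully inside the duplicated 100-mer
  inside_dup <- with(filt$positions,
    (contig == "c1" & pos >= 401 & pos <= 500 - 14) |
    (contig == "c2" & pos >= 301 & pos <= 400 - 14))
  expect_false(any(inside_dup))
})
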