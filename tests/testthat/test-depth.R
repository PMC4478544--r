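# Read mapping, depth tracks, zero coverage, consistent mismatches,
# copy-number calls.

test_that("reads map to their source locus; paralogs split ties correctly", {
  set.seed(21)
  uniq <- random_dna(3000)
  read <- substring(uniq, 1201, 1300)
  aln <- map_reads(read, c(ctg = uniq), seed = 1)
  expect_equal(nrow(aln), 1)
  expect_equal(aln$start, 1201)
  expect_equal(aln$end, 1300)
  expect_equal(aln$strand, "+")
  expect_equal(aln$n_mismatches, 0)

  # reverse-complemented read: same locus, opposite strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  aln_rc <- map_reads(rc, c(ctg = uniq), seed = 1)
  expect_equal(aln_rc$start, 1201)
  expect_equal(aln_rc$strand, "-")

  # two identical tandem copies: the read maps to one of the two loci and
  # never elsewhere (exhaustive locus check by construction)
  unit <- random_dna(800)
  two <- paste0(random_dna(500), unit, random_dna(400), unit, random_dna(500))
  p1 <- 501; p2 <- 501 + 800 + 400
  r2 <- substring(unit, 301, 400)
  for (s in 1:5) {
    a <- map_reads(r2, c(ctg = two), seed = s)
    expect_equal(nrow(a), 1)
    expect_true(a$start %in% c(p1 + 300, p2 + 300))
  }
  ab <- map_reads(r2, c(ctg = two), tie_policy = "all_best", seed = 1)
  expect_equal(nrow(ab), 2)
  expect_equal(sort(ab$start), c(p1 + 300, p2 + 300))
  expect_equal(ab$weight, c(0.5, 0.5))
})

test_that("depth track equals the provenance-oracle pileup", {
  set.seed(22)
  ctg <- random_dna(6000)  # repeat-free, so mapping is unambiguous
  fx <- list(contigs = c(solo = ctg), ploidy = c(solo = 1L))
  reads <- simulate_reads(fx, short_read_config(substitution_rate = 0,
                                                depth_per_haploid_copy = 20,
                                                seed = 5))
  aln <- map_reads(reads, fx$contigs, seed = 1)
  expect_equal(nrow(aln), nrow(reads))
  track <- compute_depth(aln, fx$contigs)
  oracle <- numeric(6000)
  for (i in seq_len(nrow(reads)))
    oracle[reads$start[i]:reads$end[i]] <-
      oracle[reads$start[i]:reads$end[i]] + 1
  expect_equal(track[["solo"]], oracle)
})

test_that("zero-coverage regions match a brute-force scan", {
  # hand case: zeros at 5-7 and 20
  tr <- structure(list(c1 = rep(1, 25)), class = "depth_track")
  tr$c1[c(5:7, 20)] <- 0
  z <- find_zero_coverage(tr)
  expect_equal(z$n_regions, 2)
  expect_equal(z$total_zero_bp, 4)
  expect_equal(z$regions$start, c(5, 20))
  expect_equal(z$regions$end, c(7, 20))

  # strictly positive track: nothing
  z0 <- find_zero_coverage(structure(list(c1 = rep(2, 50)),
                                     class = "depth_track"))
  expect_equal(z0$n_regions, 0)

  # random sparse alignments vs linear-scan oracle (contig ends included)
  set.seed(23)
  for (rep in 1:5) {
    L <- 300
    n <- sample(3:10, 1)
    s <- sample(L - 20, n); e <- pmin(s + sample(5:30, n, TRUE), L)
    aln <- data.frame(contig = "c", start = s, end = e, weight = 1)
    track <- compute_depth(aln, c(c = strrep("A", L)))
    z <- find_zero_coverage(track)
    cov <- logical(L)
    for (i in seq_len(n)) cov[s[i]:e[i]] <- TRUE
    r <- rle(!cov)
    expect_equal(z$n_regions, sum(r$values))
    expect_equal(z$total_zero_bp, sum(!cov))
  }
})

test_that("consistent mismatches pinpoint edits and ignore sequencing noise", {
  fx <- small_fixture()
  clean <- small_short_reads_clean()
  pos <- 800L
  cor <- inject_misassemblies(fx, list(edit_substitution(pos = pos)), seed = 3)

  aln0 <- map_reads(clean, fx, seed = 1)
  expect_equal(nrow(find_consistent_mismatches(aln0, clean, fx)), 0)

  aln <- map_reads(clean, cor, seed = 1)
  mm <- find_consistent_mismatches(aln, clean, cor)
  expect_equal(nrow(mm), 1)
  expect_equal(mm$position, pos)
  expect_equal(mm$support_fraction, 1.0)
  expect_identical(
    mm$consensus_base,
    substring(fx$contigs[["array_contig"]], pos, pos))

  # 1% read error on the correct assembly: no site reaches 80% support
  for (s in 1:3) {
    noisy <- simulate_reads(fx, short_read_config(substitution_rate = 0.01,
                                                  seed = s))
    alnn <- map_reads(noisy, fx, seed = s)
    expect_equal(nrow(find_consistent_mismatches(alnn, noisy, fx)), 0)
  }
})

test_that("copy-number calls recover multiplicities and flag phantoms", {
  fx <- small_fixture()
  vs <- small_variants()
  truth <- table(fx$truth_copies$variant_id)
  panel <- c(vs$variants, source_gene = vs$source)
  L <- nchar(vs$source)
  # a phantom panel entry absent from the genome: chimera of two variants
  panel["phantom"] <- paste0(substring(vs$variants[[1]], 1, 400),
                             substring(vs$variants[[2]], 401, L))

  lr <- small_long_reads()
  cn <- estimate_copy_number(lr, panel, D = 90)
  for (v in names(truth))
    expect_equal(cn$copy_number[cn$variant_id == v], as.integer(truth[[v]]),
                 info = v)
  expect_equal(cn$copy_number[cn$variant_id == "source_gene"], 2L)
  expect_true(cn$artifact[cn$variant_id == "phantom"])
  expect_equal(cn$copy_number[cn$variant_id == "phantom"], 0L)
  expect_lt(cn$mean_depth[cn$variant_id == "phantom"], 0.1 * 45)

  # conservation: panel-assigned bases never exceed mapped read bases
  expect_lte(sum(cn$mean_depth * cn$length), sum(nchar(lr$sequence)))

  # short reads are refused for panel copy-number
  expect_error(estimate_copy_number(small_short_reads(), panel, D = 90),
               "long reads")
  expect_error(estimate_copy_number(lr, panel, D = 0), "D must be > 0")
})
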