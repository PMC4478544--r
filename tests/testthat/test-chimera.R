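# Chimera detection: alignment, informative sites, single-crossover
# explanations, complementary pairs.

test_that("variant alignment handles substitutions, indels and rejects
           non-homologs", {
  set.seed(31)
  a <- random_dna(300)
  expect_equal(ncol(align_variants(c(x = a, y = a))), 300)
  expect_equal(sum(align_variants(c(x = a, y = a))["x", ] !=
                     align_variants(c(x = a, y = a))["y", ]), 0)

  b <- a; substr(b, 150, 150) <- if (substring(a, 150, 150) == "A") "C" else "A"
  M <- align_variants(c(x = a, y = b))
  expect_equal(which(M["x", ] != M["y", ]), 150L)

  # an internal deletion becomes a gap column (fifth state)
  d <- paste0(substring(a, 1, 99), substring(a, 103, 300))
  Md <- align_variants(c(x = a, y = d))
  expect_equal(ncol(Md), 300)
  expect_equal(sum(Md["y", ] == "-"), 3)

  expect_error(align_variants(c(x = a, y = random_dna(300))), "identity")
  expect_error(align_variants(c(x = a)), "at least 2")

  # pairwise identities from the alignment match the edit-distance oracle
  vs <- paper_variants()$variants[1:6]
  M6 <- align_variants(vs)
  L <- nchar(vs[[1]])
  for (p in list(c(1, 2), c(3, 5), c(4, 6))) {
    aligned_diff <- sum(M6[p[1], ] != M6[p[2], ])
    oracle <- as.integer(adist(vs[[p[1]]], vs[[p[2]]]))
    expect_equal(aligned_diff, oracle)
  }
})

test_that("informative sites are exactly the differing columns", {
  vs <- paper_variants()$variants
  M <- align_variants(vs[1:4])
  tab <- find_informative_sites(M, "Y1", "Y2")
  truth <- which(strsplit(vs[[1]], "")[[1]] != strsplit(vs[[2]], "")[[1]])
  expect_equal(tab$column, truth)
  expect_true(all(tab$base_a != tab$base_b))
  expect_true(all(diff(tab$column) > 0))

  # symmetry under parent swap
  rev <- find_informative_sites(M, "Y2", "Y1")
  expect_equal(rev$column, tab$column)
  expect_equal(rev$base_a, tab$base_b)

  # identical parents -> empty table
  M2 <- align_variants(c(p = vs[[1]], q = vs[[1]], r = vs[[2]]))
  expect_equal(nrow(find_informative_sites(M2, "p", "q")), 0)
})

test_that("constructed chimeras are explained with the true parents and a
           crossover interval containing the breakpoint", {
  vs <- paper_variants()$variants
  L <- nchar(vs[[1]])
  set.seed(32)
  for (trial in 1:10) {
    pr <- sample(names(vs), 2)
    bp <- sample(seq(100L, L - 100L), 1)
    chi <- paste0(substring(vs[[pr[1]]], 1, bp),
                  substring(vs[[pr[2]]], bp + 1, L))
    if (chi %in% vs) next
    call <- explain_recombinant(c(cand = chi), vs)
    expect_equal(call$verdict, "recombinant_artifact", info = trial)
    expect_equal(call$n_novel, 0L)
    expect_equal(call$n_switches, 1L)
    # breakpoint containment
    expect_true(call$crossover_interval[1] <= bp &&
                  bp <= call$crossover_interval[2] - 1, info = trial)
    # true parents recovered when the pair is unambiguous
    if (is.null(call$ambiguous)) {
      expect_equal(call$parent_a, pr[1], info = trial)
      expect_equal(call$parent_b, pr[2], info = trial)
    } else {
      expect_true(any(call$ambiguous$parent_a == pr[1] &
                        call$ambiguous$parent_b == pr[2]), info = trial)
    }
  }
})

test_that("novel substitutions and genuine variants are never called
           artifacts", {
  vs <- paper_variants()$variants
  L <- nchar(vs[[1]])
  chi <- paste0(substring(vs[["Y3"]], 1, 400), substring(vs[["Y7"]], 401, L))
  pos <- 220L
  old <- substring(chi, pos, pos)
  new <- setdiff(c("A", "C", "G", "T"), old)[1]
  # only a private allele if no parent carries `new` at pos; force it
  while (any(vapply(vs, function(v) substring(v, pos, pos) == new,
                    logical(1)))) {
    pos <- pos + 1L
    old <- substring(chi, pos, pos)
    new <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  substr(chi, pos, pos) <- new
  call <- explain_recombinant(c(cand = chi), vs)
  expect_gte(call$n_novel, 1L)
  expect_false(call$verdict == "recombinant_artifact")

  # candidate equal to a parent -> genuine
  g <- explain_recombinant(c(cand = unname(vs[["Y5"]])), vs)
  expect_equal(g$verdict, "genuine")
  expect_equal(g$parent_a, "Y5")

  # genuine variants with private informative sites: never recombinant
  calls <- lapply(names(vs)[1:6], function(id)
    explain_recombinant(setNames(vs[id], "cand"),
                        vs[setdiff(names(vs), id)]))
  for (cl in calls) expect_false(cl$verdict == "recombinant_artifact")

  expect_error(explain_recombinant(c(cand = vs[[1]]), vs["Y2"]), "2 parents")
})

test_that("complementary pairs from one crossover event are recovered", {
  vs <- paper_variants()$variants
  L <- nchar(vs[[1]])
  bp <- 430L
  x <- paste0(substring(vs[["Y3"]], 1, bp), substring(vs[["Y11"]], bp + 1, L))
  y <- paste0(substring(vs[["Y11"]], 1, bp), substring(vs[["Y3"]], bp + 1, L))
  calls <- explain_recombinants(c(X = x, Y = y), vs)
  pairs <- detect_complementary_pairs(calls)
  expect_equal(nrow(pairs), 1)
  expect_setequal(c(pairs$candidate_x, pairs$candidate_y), c("X", "Y"))

  # reciprocal parents but disjoint crossover intervals: not a pair
  sites <- find_informative_sites(align_variants(vs[c("Y3", "Y11")]),
                                  "Y3", "Y11")$column
  bp_lo <- sites[2]; bp_hi <- sites[length(sites) - 1]
  x2 <- paste0(substring(vs[["Y3"]], 1, bp_lo),
               substring(vs[["Y11"]], bp_lo + 1, L))
  y2 <- paste0(substring(vs[["Y11"]], 1, bp_hi),
               substring(vs[["Y3"]], bp_hi + 1, L))
  calls2 <- explain_recombinants(c(X = x2, Y = y2), vs)
  expect_equal(nrow(detect_complementary_pairs(calls2)), 0)

  # a simulated PCR clone set containing both products of one switching
  # event yields the pair
  vset <- paper_variants()
  found <- FALSE
  for (s in 1:40) {
    res <- simulate_pcr_clones(vset, pcr_sim_config(seed = s),
                               template_counts = paper_multiplicity())
    rec <- res$clones[res$clones$provenance == "recombinant_artifact" &
                        res$clones$n_switches == 1, , drop = FALSE]
    combos <- paste(rec$parent_a, rec$parent_b)
    revs <- paste(rec$parent_b, rec$parent_a)
    hit <- which(combos %in% revs)
    if (length(hit) >= 2) {
      uq <- rec[!duplicated(rec$sequence), , drop = FALSE]
      cand <- setNames(uq$sequence, sprintf("C%d", seq_len(nrow(uq))))
      calls3 <- explain_recombinants(cand, vset$variants)
      if (nrow(detect_complementary_pairs(calls3)) >= 1) { found <- TRUE; break }
    }
  }
  expect_true(found)
})
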