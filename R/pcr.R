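# PCR-cloning simulator.  Molecules replicate along a binary tree: at each
# cycle every molecule produces one copy; the copy acquires point errors and,
# with some probability, switches template at a uniform breakpoint (a
# single-crossover chimera).  Errors in early cycles are inherited by many
# descendants (jackpot).  Rather than materializing 2^n molecules, sampled
# clones are traced backwards through the tree: molecule i at cycle c is
# either molecule i of cycle c-1 (conserved, i <= N[c-1]) or the new copy of
# molecule i - N[c-1] made at cycle c.  Replication events reached by more
# than one sampled clone are memoized, so shared early-cycle mutations are
# exactly shared.

#' PCR simulation config
#'
#' @param n_cycles Number of PCR cycles.
#' @param per_base_per_cycle_error_rate Point-error probability per base per
#'   replication (polymerase fidelity; rarely known precisely, so this
#'   default is a placeholder to be tuned by the caller).
#' @param template_switch_prob_per_cycle Probability that a replication event
#'   switches template at a uniform breakpoint (recombination propensity;
#'   also a placeholder).
#' @param n_clones_sampled Number of clones sequenced at the end
#'   (default 115).
#' @param min_occurrences_accept Minimum number of identical clones required
#'   to accept a sequence variant (default 2).
#' @param seed Integer seed.
#' @return A `pcr_sim_config`.
#' @export
pcr_sim_config <- function(n_cycles = 30,
                           per_base_per_cycle_error_rate = 5e-5,
                           template_switch_prob_per_cycle = 0.02,
                           n_clones_sampled = 115,
                           min_occurrences_accept = 2, seed = 1) {
  if (n_clones_sampled < 1) stop("n_clones_sampled must be >= 1")
  if (min_occurrences_accept < 1) stop("min_occurrences_accept must be >= 1")
  structure(list(n_cycles = as.integer(n_cycles),
                 error_rate = per_base_per_cycle_error_rate,
                 switch_prob = template_switch_prob_per_cycle,
                 n_clones = as.integer(n_clones_sampled),
                 min_accept = as.integer(min_occurrences_accept),
                 seed = seed), class = "pcr_sim_config")
}

#' Simulate PCR amplification, cloning and variant acceptance
#'
#' Amplifies the true gene variants through `n_cycles` of replication with
#' point errors and template switching, samples `n_clones_sampled` final
#' molecules, and builds the accepted-variant table: distinct clone sequences
#' occurring at least `min_occurrences_accept` times, with counts and true
#' provenance (`genuine`, `point_artifact`, or `recombinant_artifact`).
#'
#' @param true_variants A [make_variant_set()] object (at least 2 variants;
#'   template switching needs two templates).
#' @param config A [pcr_sim_config()].
#' @param template_counts Optional named integer vector of genomic template
#'   multiplicities per variant (default 1 each).
#' @return A list with `clones` (data.frame: clone_id, sequence, n_switches,
#'   n_point_errors, provenance, parent_a, parent_b, breakpoint) and
#'   `accepted` (data.frame: seq_id, sequence, count, provenance, parent_a,
#'   parent_b, breakpoint).
#' @export
simulate_pcr_clones <- function(true_variants, config,
                                template_counts = NULL) {
  stopifnot(inherits(true_variants, "variant_set"),
            inherits(config, "pcr_sim_config"))
  vs <- true_variants$variants
  if (length(vs) < 2)
    stop("need at least 2 true variants (template switching needs two templates)")
  tc_full <- setNames(rep(1L, length(vs)), names(vs))
  if (!is.null(template_counts)) {
    unknown <- setdiff(names(template_counts), names(vs))
    if (length(unknown))
      stop("template_counts references unknown variant(s): ",
           paste(unknown, collapse = ", "))
    tc_full[names(template_counts)] <- as.integer(template_counts)
  }
  template_counts <- tc_full
  set.seed(config$seed)

  tmpl_ids <- rep(names(vs), template_counts)
  N0 <- length(tmpl_ids)
  n <- config$n_cycles
  Nc <- N0 * 2^(0:n)  # pool sizes (double precision; exact below 2^53)

  cache <- new.env(parent = emptyenv())  # "c:i" -> molecule record

  # uniform index in [1, N] at full integer precision (runif alone has only
  # 32-bit resolution, which would alias the template lattice for large N)
  rand_index <- function(N) {
    if (N <= 2147483647) return(as.numeric(sample.int(N, 1L)))
    hi <- ceiling(N / 2^20)
    repeat {
      i <- (as.numeric(sample.int(hi, 1L)) - 1) * 2^20 +
        as.numeric(sample.int(2^20, 1L))
      if (i <= N) return(i)
    }
  }

  # molecule record: list(seq, n_switch, n_err, parent_a, parent_b, bp)
  resolve <- function(i, c) {
    # walk down conserved-strand steps to the creation event of molecule i
    while (c > 0 && i <= Nc[c]) c <- c - 1L
    if (c == 0) {
      id <- tmpl_ids[i]
      return(list(seq = vs[[id]], n_switch = 0L, n_err = 0L,
                  parent_a = id, parent_b = NA_character_, bp = NA_integer_))
    }
    key <- sprintf("%d:%.0f", c, i)  # full precision: i can exceed 2^31
    if (!is.null(cache[[key]])) return(cache[[key]])
    parent <- resolve(i - Nc[c], c - 1L)
    rec <- parent
    # template switch at a uniform breakpoint, partner drawn from the
    # cycle c-1 pool
    if (config$switch_prob > 0 && runif(1) < config$switch_prob) {
      partner <- resolve(rand_index(Nc[c]), c - 1L)
      L <- min(nchar(rec$seq), nchar(partner$seq))
      bp <- sample.int(L - 1L, 1L)
      rec <- list(
        seq = paste0(substring(rec$seq, 1L, bp),
                     substring(partner$seq, bp + 1L, nchar(partner$seq))),
        n_switch = rec$n_switch + partner$n_switch + 1L,
        n_err = rec$n_err + partner$n_err,
        parent_a = rec$parent_a,
        parent_b = partner$parent_a,
        bp = bp)
    }
    if (config$error_rate > 0) {
      L <- nchar(rec$seq)
      hit <- which(runif(L) < config$error_rate)
      if (length(hit)) {
        s <- rec$seq
        for (p in hit) {
          old <- substring(s, p, p)
          substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
        }
        rec$seq <- s
        rec$n_err <- rec$n_err + length(hit)
      }
    }
    cache[[key]] <- rec
    rec
  }

  idx <- vapply(seq_len(config$n_clones), function(...) rand_index(Nc[n + 1L]),
                numeric(1))
  clones <- lapply(idx, resolve, c = n)
  truth_seqs <- unname(vs)
  prov <- vapply(clones, function(r) {
    if (r$seq %in% truth_seqs) "genuine"
    else if (r$n_switch >= 1L && r$n_err == 0L) "recombinant_artifact"
    else "point_artifact"
  }, character(1))
  cl <- data.frame(
    clone_id = sprintf("clone%03d", seq_along(clones)),
    sequence = vapply(clones, `[[`, "", "seq"),
    n_switches = vapply(clones, `[[`, 0L, "n_switch"),
    n_point_errors = vapply(clones, `[[`, 0L, "n_err"),
    provenance = prov,
    parent_a = vapply(clones, `[[`, "", "parent_a"),
    parent_b = vapply(clones, function(r)
      if (is.na(r$parent_b)) NA_character_ else r$parent_b, character(1)),
    breakpoint = vapply(clones, function(r)
      if (is.na(r$bp)) NA_integer_ else as.integer(r$bp), integer(1)),
    stringsAsFactors = FALSE)

  tab <- table(cl$sequence)
  keep <- names(tab)[tab >= config$min_accept]
  acc <- do.call(rbind, lapply(keep, function(s) {
    rows <- cl[cl$sequence == s, , drop = FALSE]
    p <- rows$provenance
    best <- if ("genuine" %in% p) "genuine"
            else names(sort(table(p), decreasing = TRUE))[1]
    r1 <- rows[rows$provenance == best, , drop = FALSE][1, ]
    data.frame(sequence = s, count = nrow(rows), provenance = best,
               parent_a = r1$parent_a, parent_b = r1$parent_b,
               breakpoint = r1$breakpoint, stringsAsFactors = FALSE)
  }))
  if (is.null(acc))
    acc <- data.frame(sequence = character(), count = integer(),
                      provenance = character(), parent_a = character(),
                      parent_b = character(), breakpoint = integer())
  acc <- acc[order(-acc$count), , drop = FALSE]
  genuine_match <- match(acc$sequence, truth_seqs)
  acc$seq_id <- ifelse(!is.na(genuine_match),
                       names(vs)[genuine_match],
                       sprintf("novel%02d", cumsum(is.na(genuine_match))))
  acc <- acc[, c("seq_id", "sequence", "count", "provenance", "parent_a",
                 "parent_b", "breakpoint")]
  rownames(acc) <- NULL
  list(clones = cl, accepted = acc)
}
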