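# PCR-chimera detection: decide whether a candidate gene variant is a
# single-crossover mosaic of two validated parents.  A recombination
# artifact carries no novel alleles: at every column it matches at least one
# parent, and along the columns where the two parents differ (informative
# sites) its parent-of-origin switches exactly once.

#' Align a set of near-identical variants
#'
#' Column-consistent alignment of 2 or more sequences with pairwise identity
#' of at least 90%.  Equal-length inputs are aligned positionally; otherwise
#' each sequence is globally aligned to the first (anchor) sequence and
#' insertion columns are merged across sequences.  Gaps are a fifth state.
#'
#' @param sequences Named character vector or DNAStringSet (>= 2 sequences).
#' @return A `variant_alignment`: character matrix, one row per sequence,
#'   one column per alignment column ("-" = gap).
#' @export
align_variants <- function(sequences) {
  seqs <- as_seq_character(sequences)
  if (length(seqs) < 2) stop("need at least 2 sequences")
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_along(seqs))
  if (length(unique(nchar(seqs))) == 1L) {
    M <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(M) <- names(seqs)
  } else {
    M <- .anchor_align(seqs)
  }
  # homology check on the alignment (method assumes recent paralogs)
  n <- nrow(M)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    cols <- M[i, ] != "-" | M[j, ] != "-"
    pid <- mean(M[i, cols] == M[j, cols])
    if (pid < 0.90)
      stop(sprintf("pairwise identity of %s and %s is %.1f%% (< 90%%); %s",
                   rownames(M)[i], rownames(M)[j], 100 * pid,
                   "the method assumes recent, near-identical paralogs"))
  }
  structure(M, class = "variant_alignment")
}

# Anchor-based multiple alignment: global pairwise alignment of every
# sequence to the first one, with per-anchor-gap insertion columns merged.
.anchor_align <- function(seqs) {
  anchor <- seqs[[1]]
  La <- nchar(anchor)
  n <- length(seqs)
  # per sequence: chars at anchor positions 1..La ("-" for deletion) and
  # insertions keyed by the anchor position they follow (0 = before start)
  mat <- matrix("-", n, La)
  ins <- vector("list", n)
  mat[1, ] <- strsplit(anchor, "", fixed = TRUE)[[1]]
  ins[[1]] <- list()
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (i in 2:n) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = seqs[[i]], subject = anchor, type = "global",
      substitutionMatrix = sm, gapOpening = 2, gapExtension = 1)
    p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    ap <- 0L
    ins_i <- list()
    for (col in seq_along(p)) {
      if (s[col] != "-") {
        ap <- ap + 1L
        mat[i, ap] <- p[col]
      } else {
        key <- as.character(ap)
        ins_i[[key]] <- c(ins_i[[key]], p[col])
      }
    }
    ins[[i]] <- ins_i
  }
  ins_keys <- sort(unique(as.integer(unlist(lapply(ins, names)))))
  ins_width <- vapply(ins_keys, function(k)
    max(vapply(ins, function(x) length(x[[as.character(k)]]), integer(1))),
    integer(1))
  # assemble columns: [ins after 0] a1 [ins after 1] a2 ...
  total <- La + sum(ins_width)
  M <- matrix("-", n, total)
  col <- 0L
  for (ap in 0:La) {
    ki <- match(ap, ins_keys)
    if (!is.na(ki)) {
      w <- ins_width[ki]
      for (i in seq_len(n)) {
        v <- ins[[i]][[as.character(ap)]]
        if (length(v)) M[i, col + seq_along(v)] <- v
      }
      col <- col + w
    }
    if (ap < La) {
      col <- col + 1L
      M[, col] <- mat[, ap + 1L]
    }
  }
  rownames(M) <- names(seqs)
  M
}

#' Informative sites between two aligned parents
#'
#' All and only the alignment columns at which the two parents differ
#' (indels count as a fifth state).
#'
#' @param alignment A [align_variants()] matrix.
#' @param parent_a,parent_b Row names of the two parents.
#' @return An `informative_sites` data.frame: column, base_a, base_b;
#'   attributes `parent_a`, `parent_b`.
#' @export
find_informative_sites <- function(alignment, parent_a, parent_b) {
  stopifnot(parent_a %in% rownames(alignment),
            parent_b %in% rownames(alignment))
  a <- alignment[parent_a, ]
  b <- alignment[parent_b, ]
  cols <- which(a != b)
  structure(data.frame(column = cols, base_a = a[cols], base_b = b[cols],
                       stringsAsFactors = FALSE, row.names = NULL),
            parent_a = parent_a, parent_b = parent_b,
            class = c("informative_sites", "data.frame"))
}

# Score candidate against one ordered parent pair on an alignment.
.pair_explanation <- function(M, cand, pa, pb) {
  ca <- M[cand, ]; A <- M[pa, ]; B <- M[pb, ]
  n_novel <- sum(ca != A & ca != B)
  sites <- which(A != B)
  state <- ifelse(ca[sites] == A[sites], "a",
                  ifelse(ca[sites] == B[sites], "b", NA))
  st <- state[!is.na(state)]
  cols <- sites[!is.na(state)]
  if (!length(st))
    return(list(parent_a = pa, parent_b = pb, n_novel = n_novel,
                n_switches = 0L, n_a = 0L, n_b = 0L,
                crossover = c(NA_integer_, NA_integer_)))
  r <- rle(st)
  n_switches <- length(r$values) - 1L
  # orient: a 5'-A / 3'-B paste reads a...a b...b
  crossover <- c(NA_integer_, NA_integer_)
  if (n_switches == 1L && r$values[1] == "a") {
    crossover <- c(cols[r$lengths[1]], cols[r$lengths[1] + 1L])
  }
  list(parent_a = pa, parent_b = pb, n_novel = n_novel,
       n_switches = n_switches, n_a = sum(st == "a"), n_b = sum(st == "b"),
       first_state = r$values[1], crossover = crossover)
}

#' Explain a candidate variant as a PCR recombinant
#'
#' Searches all ordered parent pairs for the explanation minimizing
#' `(n_novel, n_switches)`.  Verdict `recombinant_artifact` requires a
#' single-crossover mosaic with no novel alleles (`n_novel = 0`,
#' `n_switches = 1`) and at least one informative site supporting each
#' parent; `genuine` means the candidate equals one of the parents;
#' anything else is `unexplained` (including multi-switch mosaics).
#'
#' @param candidate Named character vector of length 1 (or unnamed; id
#'   defaults to "candidate").
#' @param parents Named character vector of validated parent sequences
#'   (>= 2; must not contain the candidate id).
#' @return An `artifact_call`: list with candidate_id, verdict,
#'   parent_a/parent_b, crossover_interval (alignment columns), n_novel,
#'   n_switches, n_sites_a, n_sites_b, and `ambiguous` (data.frame of all
#'   equally minimal zero-novel single-switch pairs).
#' @export
explain_recombinant <- function(candidate, parents) {
  cand_seq <- as_seq_character(candidate)
  if (length(cand_seq) != 1) stop("candidate must be a single sequence")
  cand_id <- if (!is.null(names(cand_seq)) && nzchar(names(cand_seq)))
    names(cand_seq) else "candidate"
  parents <- as_seq_character(parents)
  if (length(parents) < 2) stop("need at least 2 parents")
  if (is.null(names(parents))) names(parents) <- sprintf("P%d", seq_along(parents))
  if (cand_id %in% names(parents)) stop("parent set must exclude the candidate")
  all_seqs <- c(setNames(cand_seq, cand_id), parents)
  M <- align_variants(all_seqs)

  # genuine: identical to some parent across all columns
  eq <- vapply(names(parents), function(p) all(M[cand_id, ] == M[p, ]),
               logical(1))
  if (any(eq)) {
    return(structure(list(
      candidate_id = cand_id, verdict = "genuine",
      parent_a = names(parents)[which(eq)[1]], parent_b = NA_character_,
      crossover_interval = c(NA_integer_, NA_integer_), n_novel = 0L,
      n_switches = 0L, n_sites_a = 0L, n_sites_b = 0L,
      ambiguous = NULL), class = "artifact_call"))
  }
  ids <- names(parents)
  expl <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i == j) next
    e <- .pair_explanation(M, cand_id, ids[i], ids[j])
    # keep the orientation whose informative-site pattern starts with a
    if (!is.null(e$first_state) && identical(e$first_state, "a"))
      expl[[length(expl) + 1L]] <- e
  }
  if (!length(expl)) {
    # no oriented explanation at all (e.g. candidate matches neither parent
    # at any informative site): fall back over unordered pairs for scoring
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i >= j) next
      expl[[length(expl) + 1L]] <- .pair_explanation(M, cand_id, ids[i], ids[j])
    }
  }
  score <- vapply(expl, function(e) e$n_novel * 1e6 + e$n_switches, numeric(1))
  best_i <- which(score == min(score))
  # primary explanation: lexicographically smallest (parent_a, parent_b)
  keys <- vapply(expl[best_i], function(e) paste(e$parent_a, e$parent_b),
                 character(1))
  best_i <- best_i[order(keys)]
  e <- expl[[best_i[1]]]
  ok <- e$n_novel == 0L && e$n_switches == 1L && e$n_a >= 1L && e$n_b >= 1L
  amb <- NULL
  if (ok && length(best_i) > 1L) {
    amb <- do.call(rbind, lapply(expl[best_i], function(x)
      data.frame(parent_a = x$parent_a, parent_b = x$parent_b,
                 crossover_start = x$crossover[1],
                 crossover_end = x$crossover[2], stringsAsFactors = FALSE)))
  }
  structure(list(
    candidate_id = cand_id,
    verdict = if (ok) "recombinant_artifact" else "unexplained",
    parent_a = e$parent_a, parent_b = e$parent_b,
    crossover_interval = e$crossover,
    n_novel = e$n_novel, n_switches = e$n_switches,
    n_sites_a = e$n_a, n_sites_b = e$n_b,
    ambiguous = amb), class = "artifact_call")
}

#' @export
print.artifact_call <- function(x, ...) {
  cat(sprintf("artifact_call: %s -> %s", x$candidate_id, x$verdict))
  if (x$verdict == "recombinant_artifact")
    cat(sprintf(" [5' %s + 3' %s, crossover cols %d-%d%s]",
                x$parent_a, x$parent_b, x$crossover_interval[1],
                x$crossover_interval[2],
                if (!is.null(x$ambiguous)) ", ambiguous" else ""))
  cat("\n")
  invisible(x)
}

#' Explain several candidates at once
#'
#' @param candidates Named character vector of candidate sequences.
#' @param parents Named character vector of validated parents.
#' @return List of [explain_recombinant()] calls, plus a `summary`
#'   data.frame attached as attribute.
#' @export
explain_recombinants <- function(candidates, parents) {
  candidates <- as_seq_character(candidates)
  calls <- lapply(names(candidates), function(id)
    explain_recombinant(setNames(candidates[id], id), parents))
  names(calls) <- names(candidates)
  summary <- do.call(rbind, lapply(calls, function(x)
    data.frame(candidate = x$candidate_id, verdict = x$verdict,
               parent_a = x$parent_a, parent_b = x$parent_b,
               crossover_start = x$crossover_interval[1],
               crossover_end = x$crossover_interval[2],
               n_novel = x$n_novel, n_switches = x$n_switches,
               stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  attr(calls, "summary") <- summary
  calls
}

#' Construct a single-crossover recombinant of two parents
#'
#' Pastes the 5' of `parent_a` onto the 3' of `parent_b`.  If no breakpoint
#' is given, the crossover is placed midway between the two informative
#' sites closest to the sequence midpoint, requiring at least `min_sites`
#' informative sites on each side so the mosaic structure is well
#' supported.  Useful for building ground-truth artifact sequences.
#'
#' @param parents Named character vector of parent sequences.
#' @param parent_a,parent_b Parent ids (5' and 3' donor).
#' @param breakpoint Optional 1-based crossover position (last base taken
#'   from `parent_a`).
#' @param min_sites Minimum informative sites required per side when the
#'   breakpoint is chosen automatically.
#' @return The chimeric sequence, with attributes `breakpoint`, `parent_a`,
#'   `parent_b`.
#' @export
make_recombinant <- function(parents, parent_a, parent_b, breakpoint = NULL,
                             min_sites = 3) {
  a <- parents[[parent_a]]; b <- parents[[parent_b]]
  if (is.null(a) || is.null(b)) stop("unknown parent id")
  M <- align_variants(setNames(c(a, b), c("a", "b")))
  sites <- find_informative_sites(M, "a", "b")$column
  if (is.null(breakpoint)) {
    if (length(sites) < 2 * min_sites)
      stop("parents have fewer than ", 2 * min_sites, " informative sites")
    lo <- min_sites; hi <- length(sites) - min_sites
    mid <- nchar(a) / 2
    gaps <- (sites[lo:hi] + sites[(lo + 1):(hi + 1)]) / 2
    breakpoint <- floor(gaps[which.min(abs(gaps - mid))])
  }
  chi <- paste0(substring(a, 1, breakpoint),
                substring(b, breakpoint + 1, nchar(b)))
  structure(chi, breakpoint = breakpoint, parent_a = parent_a,
            parent_b = parent_b)
}

#' Complementary recombinant pairs
#'
#' Pairs of artifact calls where one candidate is explained by parents
#' (A, B) and the other by (B, A), with overlapping crossover intervals:
#' the two reciprocal products of one template-switching event.
#'
#' @param calls A list of `artifact_call`s (e.g. [explain_recombinants()]).
#' @return Data.frame: candidate_x, candidate_y, parent_a, parent_b,
#'   overlap_start, overlap_end.
#' @export
detect_complementary_pairs <- function(calls) {
  rec <- Filter(function(x) x$verdict == "recombinant_artifact", calls)
  out <- list()
  if (length(rec) >= 2) {
    for (i in seq_len(length(rec) - 1L)) for (j in (i + 1L):length(rec)) {
      x <- rec[[i]]; y <- rec[[j]]
      if (identical(x$parent_a, y$parent_b) &&
          identical(x$parent_b, y$parent_a)) {
        lo <- max(x$crossover_interval[1], y$crossover_interval[1])
        hi <- min(x$crossover_interval[2], y$crossover_interval[2])
        if (!is.na(lo) && !is.na(hi) && lo <= hi)
          out[[length(out) + 1L]] <- data.frame(
            candidate_x = x$candidate_id, candidate_y = y$candidate_id,
            parent_a = x$parent_a, parent_b = x$parent_b,
            overlap_start = lo, overlap_end = hi, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(candidate_x = character(), candidate_y = character(),
                      parent_a = character(), parent_b = character(),
                      overlap_start = integer(), overlap_end = integer()))
  do.call(rbind, out)
}
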