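# Small shared helpers.

#' Random DNA sequence
#'
#' Uniform random sequence over A/C/G/T, using the current RNG state.
#'
#' @param n Length in bp.
#' @return A single character string of length `n`.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

subseq_chr <- function(x, start, end) {
  substring(x, start, end)
}

#' @noRd
as_seq_character <- function(x) {
  if (is(x, "DNAStringSet") || is(x, "DNAString")) {
    out <- as.character(x)
  } else if (is.character(x)) {
    out <- x
  } else {
    stop("expected a character vector or DNAStringSet")
  }
  out
}

# Per-site substitution of a sequence: each position mutates to a different
# base with probability `rate`.  Returns the mutated string.
mutate_sites <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  hit <- which(runif(n) < rate)
  if (!length(hit)) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    ch[i] <- sample(setdiff(bases, ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

# Derive a stage seed from a global seed, kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.numeric(seed) * 97L + offset * 131L) %% 2147483647
}

stopifnot_scalar_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x))
    stop(sprintf("'%s' must be a single integer", name))
}
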