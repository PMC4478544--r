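# Read simulators.  Reads are drawn uniformly per contig with expected
# per-base depth = ploidy x depth_per_haploid_copy; provenance (contig,
# start, strand on the reference) is recorded for oracle pileups.

#' Short-read simulation config
#'
#' Fixed-length reads with a substitution-dominated error profile
#' (Illumina-like).
#'
#' @param read_length Read length in bp.
#' @param depth_per_haploid_copy Expected depth per haploid copy (x).
#' @param substitution_rate,insertion_rate,deletion_rate Per-base error rates.
#' @param seed Integer seed.
#' @return A `read_sim_config`.
#' @export
short_read_config <- function(read_length = 100, depth_per_haploid_copy = 45,
                              substitution_rate = 0.001, insertion_rate = 0,
                              deletion_rate = 0, seed = 1) {
  .read_sim_config("short", read_length = read_length,
                   depth = depth_per_haploid_copy,
                   sub = substitution_rate, ins = insertion_rate,
                   del = deletion_rate, seed = seed)
}

#' Long-read simulation config
#'
#' Log-normal read lengths (default mean 8 kb, well above the duplication
#' unit so identical tandem copies are resolvable) with an indel-dominated
#' error profile (raw-PacBio-like, ~12% total by default).
#'
#' @param length_mean,length_sd Mean and standard deviation of the read
#'   length distribution (bp, log-normal).
#' @inheritParams short_read_config
#' @return A `read_sim_config`.
#' @export
long_read_config <- function(length_mean = 8000, length_sd = 4000,
                             depth_per_haploid_copy = 45,
                             substitution_rate = 0.01, insertion_rate = 0.06,
                             deletion_rate = 0.05, seed = 1) {
  .read_sim_config("long", length_mean = length_mean, length_sd = length_sd,
                   depth = depth_per_haploid_copy,
                   sub = substitution_rate, ins = insertion_rate,
                   del = deletion_rate, seed = seed)
}

.read_sim_config <- function(type, depth, sub, ins, del, seed,
                             read_length = NULL, length_mean = NULL,
                             length_sd = NULL) {
  if (depth <= 0) stop("depth_per_haploid_copy must be > 0")
  for (r in c(sub, ins, del))
    if (r < 0 || r >= 1) stop("error rates must be in [0, 1)")
  structure(list(type = type, read_length = read_length,
                 length_mean = length_mean, length_sd = length_sd,
                 depth = depth, sub = sub, ins = ins, del = del,
                 seed = seed), class = "read_sim_config")
}

#' Simulate reads from a genome fixture
#'
#' @param fixture A `genome_fixture` (or any list with `contigs` and
#'   `ploidy`).
#' @param config A [short_read_config()] or [long_read_config()].
#' @return A `read_set`: data.frame with columns `read_id`, `sequence`,
#'   `contig`, `start`, `end`, `strand` (provenance on the reference;
#'   `start`/`end` span the error-free template interval), with the config
#'   attached as attribute `config`.
#' @export
simulate_reads <- function(fixture, config) {
  stopifnot(inherits(config, "read_sim_config"))
  contigs <- fixture$contigs
  ploidy <- fixture$ploidy
  set.seed(config$seed)
  out <- list()
  for (ctg in names(contigs)) {
    L <- nchar(contigs[[ctg]])
    target_bases <- ploidy[[ctg]] * config$depth * L
    if (config$type == "short" && L <= config$read_length)
      stop("contig ", ctg, " is not longer than the read length")
    draw_lens <- function(k) {
      if (config$type == "short") return(rep(as.integer(config$read_length), k))
      mu <- config$length_mean
      sdlog <- sqrt(log(1 + (config$length_sd / mu)^2))
      as.integer(pmin(pmax(round(rlnorm(k, log(mu) - sdlog^2 / 2, sdlog)),
                           200L), L - 1L))
    }
    mean_len <- if (config$type == "short") config$read_length
                else min(config$length_mean, L - 1)
    # templates may overhang contig ends and are clipped, so expected depth
    # is uniform all the way to the first and last base; the base budget is
    # accumulated over CLIPPED lengths
    starts <- integer(); lens <- integer(); tot <- 0
    while (tot < target_bases) {
      k <- max(50L, ceiling(1.1 * (target_bases - tot) / mean_len))
      l <- draw_lens(k)
      s <- vapply(l, function(li) sample.int(L + li - 1L, 1L) - li + 1L,
                  integer(1))
      e <- pmin(s + l - 1L, L)
      s <- pmax(s, 1L)
      cl <- e - s + 1L
      keep <- cl >= 35L
      s <- s[keep]; cl <- cl[keep]
      cum <- tot + cumsum(as.numeric(cl))
      stopi <- which(cum >= target_bases)[1]
      if (!is.na(stopi)) { s <- s[seq_len(stopi)]; cl <- cl[seq_len(stopi)] }
      starts <- c(starts, s); lens <- c(lens, cl)
      tot <- tot + sum(as.numeric(cl))
    }
    n <- length(lens)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    tmpl <- substring(contigs[[ctg]], starts, starts + lens - 1L)
    flip <- strands == "-"
    if (any(flip)) tmpl[flip] <- revcomp_chr(tmpl[flip])
    seqs <- as.character(
      tc_apply_errors(tmpl, config$sub, config$ins, config$del))
    out[[ctg]] <- data.frame(
      read_id = sprintf("%s_r%06d", ctg, seq_len(n)),
      sequence = seqs, contig = ctg, start = starts,
      end = starts + lens - 1L, strand = strands, stringsAsFactors = FALSE)
  }
  rs <- do.call(rbind, out)
  rownames(rs) <- NULL
  structure(rs, class = c("read_set", "data.frame"), config = config)
}

#' @export
print.read_set <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("read_set: %d %s reads, %.3g Mb, contigs: %s\n", nrow(x),
              if (!is.null(cfg)) cfg$type else "?",
              sum(nchar(x$sequence)) / 1e6,
              paste(unique(x$contig), collapse = ", ")))
  invisible(x)
}

#' Mean mapped depth per contig implied by read provenance
#'
#' Oracle pileup from recorded provenance (template intervals), independent of
#' any mapper: mean over the contig of the number of read templates covering
#' each base.
#'
#' @param reads A `read_set`.
#' @param fixture The fixture the reads were simulated from.
#' @return Named numeric vector of mean depths.
#' @export
provenance_mean_depth <- function(reads, fixture) {
  vapply(names(fixture$contigs), function(ctg) {
    r <- reads[reads$contig == ctg, ]
    L <- nchar(fixture$contigs[[ctg]])
    if (!nrow(r)) return(0)
    cov <- IRanges::coverage(IRanges::IRanges(r$start, r$end), width = L)
    mean(as.numeric(cov))
  }, numeric(1))
}

#' Write reads as FASTQ
#'
#' Provenance is kept in the FASTQ comment field as `contig:start:strand`.
#'
#' @param reads A `read_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  s <- Biostrings::DNAStringSet(reads$sequence)
  names(s) <- sprintf("%s %s:%d:%s", reads$read_id, reads$contig,
                      reads$start, reads$strand)
  q <- Biostrings::BStringSet(vapply(
    nchar(reads$sequence), function(n) strrep("I", n), character(1)))
  Biostrings::writeXStringSet(s, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ written by [write_reads_fastq()]
#'
#' @param path FASTQ file.
#' @return A `read_set` (provenance parsed from the comment field when
#'   present).
#' @export
read_reads_fastq <- function(path) {
  s <- Biostrings::readDNAStringSet(path, format = "fastq")
  nm <- names(s)
  id <- sub(" .*$", "", nm)
  com <- ifelse(grepl(" ", nm), sub("^[^ ]+ ", "", nm), NA_character_)
  parts <- strsplit(com, ":", fixed = TRUE)
  ok <- !is.na(com) & lengths(parts) == 3L
  rs <- data.frame(
    read_id = id, sequence = as.character(s),
    contig = ifelse(ok, vapply(parts, `[`, "", 1L), NA_character_),
    start = ifelse(ok, as.integer(vapply(parts, `[`, "", 2L)), NA_integer_),
    end = NA_integer_,
    strand = ifelse(ok, vapply(parts, `[`, "", 3L), NA_character_),
    stringsAsFactors = FALSE)
  structure(rs, class = c("read_set", "data.frame"))
}
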