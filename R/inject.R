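# Misassembly injection: controlled corruption of a fixture's contigs with a
# replayable edit record.  Edit coordinates in `truth_edits` refer to the
# ORIGINAL (uncorrupted) contig; truth_copies/truth_te of the returned
# fixture are shifted to corrupted coordinates so downstream audits can be
# checked against them.

#' Edit constructors for [inject_misassemblies()]
#'
#' `substitution`: replace one base at `pos` (with `base`, or a random
#' different base).  `insertion`: insert `seq` (or `length` random bases)
#' after position `pos - 1`, i.e. the new bases start at `pos`.
#' `deletion`: remove `length` bases starting at `pos`.  `copy_collapse`:
#' remove one whole tandem unit (plus its following spacer) of `variant_id`.
#' `chimeric_join`: splice a foreign segment (`seq`, or `length` random
#' bases, default 500) into the contig at `pos`.
#'
#' @param contig Contig id (defaults to the array contig).
#' @param pos 1-based position.
#' @param base,seq,length,variant_id,copy Edit parameters.
#' @return An `edit` list.
#' @name edits
NULL

#' @rdname edits
#' @export
edit_substitution <- function(pos, base = NULL, contig = "array_contig") {
  structure(list(type = "substitution", contig = contig, pos = pos,
                 base = base), class = "edit")
}

#' @rdname edits
#' @export
edit_insertion <- function(pos, seq = NULL, length = 1,
                           contig = "array_contig") {
  structure(list(type = "insertion", contig = contig, pos = pos, seq = seq,
                 length = length), class = "edit")
}

#' @rdname edits
#' @export
edit_deletion <- function(pos, length = 1, contig = "array_contig") {
  structure(list(type = "deletion", contig = contig, pos = pos,
                 length = length), class = "edit")
}

#' @rdname edits
#' @export
edit_copy_collapse <- function(variant_id, copy = 1L) {
  structure(list(type = "copy_collapse", variant_id = variant_id,
                 copy = copy), class = "edit")
}

#' @rdname edits
#' @export
edit_chimeric_join <- function(pos, seq = NULL, length = 500,
                               contig = "array_contig") {
  structure(list(type = "chimeric_join", contig = contig, pos = pos,
                 seq = seq, length = length), class = "edit")
}

# Resolve an edit to a normalized record with original coordinates and a
# concrete payload.  `span` is the footprint on the original contig used for
# the overlap check ([pos, pos + span - 1]; insertions have span 0).
.resolve_edit <- function(e, fixture) {
  if (e$type == "copy_collapse") {
    tc <- fixture$truth_copies
    rows <- which(tc$variant_id == e$variant_id)
    if (!length(rows))
      stop("copy_collapse: no copies of variant ", e$variant_id)
    if (e$copy > length(rows))
      stop("copy_collapse: variant ", e$variant_id, " has only ",
           length(rows), " copies")
    row <- rows[e$copy]
    seg <- fixture$segments
    # remove the unit plus its following spacer (preceding spacer for the
    # last unit), mimicking a collapse of adjacent copies
    ui <- which(seg$kind == "unit" & seg$start == tc$unit_start[row])
    from <- seg$start[ui]; to <- seg$end[ui]
    if (ui < nrow(seg) && seg$kind[ui + 1L] == "spacer") {
      to <- seg$end[ui + 1L]
    } else if (ui > 1L && seg$kind[ui - 1L] == "spacer") {
      from <- seg$start[ui - 1L]
    }
    return(list(type = "copy_collapse", contig = tc$contig[row],
                pos = from, length = to - from + 1L, payload = "",
                detail = sprintf("%s copy %d", e$variant_id, e$copy),
                span = to - from + 1L))
  }
  ctg_seq <- fixture$contigs[[e$contig]]
  if (is.null(ctg_seq)) stop("unknown contig: ", e$contig)
  L <- nchar(ctg_seq)
  if (e$pos < 1 || e$pos > L) stop("edit position out of bounds")
  switch(e$type,
    substitution = {
      old <- substring(ctg_seq, e$pos, e$pos)
      new <- e$base
      if (is.null(new)) new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      if (new == old) stop("substitution base equals the assembly base")
      list(type = "substitution", contig = e$contig, pos = e$pos,
           length = 1L, payload = new, detail = paste0(old, ">", new),
           span = 1L)
    },
    insertion = {
      payload <- if (!is.null(e$seq)) e$seq else random_dna(e$length)
      list(type = "insertion", contig = e$contig, pos = e$pos,
           length = nchar(payload), payload = payload, detail = "",
           span = 0L)
    },
    deletion = {
      if (e$pos + e$length - 1L > L) stop("deletion runs off the contig")
      list(type = "deletion", contig = e$contig, pos = e$pos,
           length = as.integer(e$length), payload = "", detail = "",
           span = as.integer(e$length))
    },
    chimeric_join = {
      payload <- if (!is.null(e$seq)) e$seq else random_dna(e$length)
      list(type = "chimeric_join", contig = e$contig, pos = e$pos,
           length = nchar(payload), payload = payload, detail = "foreign",
           span = 0L)
    },
    stop("unknown edit type: ", e$type))
}

# Apply one resolved edit to a character sequence.
.apply_edit <- function(seq, ed) {
  switch(ed$type,
    substitution = {
      substr(seq, ed$pos, ed$pos) <- ed$payload
      seq
    },
    insertion = ,
    chimeric_join = paste0(substring(seq, 1L, ed$pos - 1L), ed$payload,
                           substring(seq, ed$pos, nchar(seq))),
    deletion = ,
    copy_collapse = paste0(substring(seq, 1L, ed$pos - 1L),
                           substring(seq, ed$pos + ed$length, nchar(seq))),
    stop("unknown edit type"))
}

#' Inject misassemblies into a fixture
#'
#' Returns a corrupted copy of the fixture with `truth_edits` populated
#' (original coordinates) and truth intervals shifted to the corrupted
#' coordinate system; truth copies destroyed by a `copy_collapse` are
#' dropped.  Overlapping edits are rejected so the truth stays interpretable.
#'
#' @param fixture A `genome_fixture`.
#' @param edits A list of edits built with the [edits] constructors.
#' @param seed Integer seed (used for random payloads/bases).
#' @return A corrupted `genome_fixture`.
#' @export
inject_misassemblies <- function(fixture, edits, seed = 1) {
  if (inherits(edits, "edit")) edits <- list(edits)
  set.seed(seed)
  res <- lapply(edits, .resolve_edit, fixture = fixture)
  ed <- do.call(rbind, lapply(res, function(e)
    data.frame(type = e$type, contig = e$contig, pos = e$pos,
               length = e$length, payload = e$payload, detail = e$detail,
               span = e$span, stringsAsFactors = FALSE)))
  # reject overlaps per contig (insertion points count as width-1 footprints)
  for (ctg in unique(ed$contig)) {
    d <- ed[ed$contig == ctg, ]
    d <- d[order(d$pos), ]
    s <- d$pos; e2 <- d$pos + pmax(d$span, 1L) - 1L
    if (nrow(d) > 1L && any(s[-1L] <= e2[-nrow(d)]))
      stop("overlapping edits on contig ", ctg)
  }
  out <- fixture
  for (ctg in unique(ed$contig)) {
    d <- ed[ed$contig == ctg, ]
    d <- d[order(-d$pos), ]  # right to left: earlier coordinates stay valid
    seq <- out$contigs[[ctg]]
    for (i in seq_len(nrow(d))) seq <- .apply_edit(seq, as.list(d[i, ]))
    out$contigs[[ctg]] <- seq

    shift_of <- function(pos) {
      # coordinate shift at original position pos (after all edits left of it)
      del <- d$type %in% c("deletion", "copy_collapse")
      ins <- d$type %in% c("insertion", "chimeric_join")
      sum(ifelse(ins & d$pos <= pos, d$length, 0L)) -
        sum(ifelse(del & (d$pos + d$length - 1L) < pos, d$length, 0L))
    }
    removed <- d[d$type %in% c("deletion", "copy_collapse"), , drop = FALSE]
    hits_removed <- function(s, e3) {
      if (!nrow(removed)) return(rep(FALSE, length(s)))
      vapply(seq_along(s), function(i)
        any(removed$pos <= e3[i] & (removed$pos + removed$length - 1L) >= s[i]),
        logical(1))
    }
    shift_df <- function(df, scol, ecol) {
      rows <- df$contig == ctg
      if (!any(rows)) return(df)
      drop <- rows & hits_removed(df[[scol]], df[[ecol]])
      df <- df[!drop, , drop = FALSE]
      rows <- df$contig == ctg
      df[[scol]][rows] <- df[[scol]][rows] +
        vapply(df[[scol]][rows], shift_of, numeric(1))
      df[[ecol]][rows] <- df[[ecol]][rows] +
        vapply(df[[ecol]][rows], shift_of, numeric(1))
      df
    }
    out$truth_copies <- shift_df(out$truth_copies, "start", "end")
    if ("unit_start" %in% names(out$truth_copies))
      out$truth_copies <- shift_df(out$truth_copies, "unit_start", "unit_end")
    out$truth_te <- shift_df(out$truth_te, "start", "end")
  }
  ed$span <- NULL
  out$truth_edits <- rbind(fixture$truth_edits, ed)
  out$segments <- NULL       # the tiling no longer describes the contig
  out$segment_seqs <- NULL
  out
}

#' Replay recorded edits against original contigs
#'
#' Applies `truth_edits` (original coordinates) to the original contig
#' sequences; the result must equal the corrupted fixture's contigs.
#'
#' @param contigs Named character vector of original contigs.
#' @param truth_edits The `truth_edits` data.frame of a corrupted fixture.
#' @return Named character vector of corrupted contigs.
#' @export
replay_edits <- function(contigs, truth_edits) {
  for (ctg in unique(truth_edits$contig)) {
    d <- truth_edits[truth_edits$contig == ctg, ]
    d <- d[order(-d$pos), ]
    seq <- contigs[[ctg]]
    for (i in seq_len(nrow(d))) seq <- .apply_edit(seq, as.list(d[i, ]))
    contigs[[ctg]] <- seq
  }
  contigs
}
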