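#' Construct a predicted transcript
#'
#' A transcript is the unit the selector works on: an ordered chain of CDS
#' intervals on one strand of one sequence, together with the identifiers it
#' carried in its input prediction file. Coordinates are 1-based and fully
#' inclusive throughout the package.
#'
#' @param id Transcript identifier, globally unique across input files
#'   (parsers prefix the raw identifier with the input file index).
#' @param gene_id Gene identifier from the input annotation.
#' @param seqname Sequence (chromosome/contig) name.
#' @param strand `"+"` or `"-"`; a CDS has a defined reading direction, so
#'   `"."` is rejected.
#' @param cds Data frame with columns `start`, `end` and optionally `frame`
#'   (character, `"0"`, `"1"`, `"2"` or `"."`). Intervals must be
#'   non-overlapping; they are sorted by `start`.
#' @param file_index Index of the originating prediction file.
#' @param original_id Identifier as it appeared in the input file; defaults
#'   to `id`.
#' @param stop_codon Optional length-2 vector `c(start, end)` of an explicit
#'   stop codon row. When present it is authoritative for the stop-codon
#'   feature; otherwise the terminal three coding nucleotides of the CDS
#'   chain are used (BRAKER-style GTF includes the stop codon in the CDS).
#' @return An object of class `tx_transcript`.
#' @export
new_transcript <- function(id, gene_id, seqname, strand, cds,
                           file_index = 1L, original_id = id,
                           stop_codon = NULL) {
  if (!strand %in% c("+", "-")) {
    stop("transcript '", id, "': strand must be '+' or '-', got '", strand, "'",
      call. = FALSE
    )
  }
  cds <- as.data.frame(cds)
  if (is.null(cds$frame)) cds$frame <- "."
  cds$start <- as.integer(cds$start)
  cds$end <- as.integer(cds$end)
  cds$frame <- as.character(cds$frame)
  if (nrow(cds) == 0L) {
    stop("transcript '", id, "' has no CDS intervals", call. = FALSE)
  }
  if (any(cds$start > cds$end)) {
    stop("transcript '", id, "': CDS with start > end", call. = FALSE)
  }
  cds <- cds[order(cds$start, cds$end), c("start", "end", "frame")]
  rownames(cds) <- NULL
  if (nrow(cds) > 1L && any(cds$start[-1] <= cds$end[-nrow(cds)] + 1L)) {
    stop("transcript '", id, "': overlapping or abutting CDS intervals ",
      "(every intron must be at least 1 nt)",
      call. = FALSE
    )
  }
  structure(
    list(
      id = id, original_id = original_id, gene_id = gene_id,
      seqname = seqname, strand = strand, cds = cds,
      file_index = as.integer(file_index),
      stop_codon = if (!is.null(stop_codon)) as.integer(stop_codon[1:2])
    ),
    class = "tx_transcript"
  )
}

#' @export
print.tx_transcript <- function(x, ...) {
  cat(sprintf(
    "<transcript %s> gene %s, %s:%d-%d(%s), %d CDS\n",
    x$id, x$gene_id, x$seqname, min(x$cds$start), max(x$cds$end),
    x$strand, nrow(x$cds)
  ))
  invisible(x)
}

as_tx_set <- function(txs) {
  if (length(txs) == 0L) {
    return(structure(list(), class = "tx_set"))
  }
  names(txs) <- vapply(txs, `[[`, "", "id")
  structure(txs, class = "tx_set")
}

#' @export
`[.tx_set` <- function(x, i) as_tx_set(unclass(x)[i])

#' @export
print.tx_set <- function(x, ...) {
  cat(sprintf("<tx_set> %d transcripts\n", length(x)))
  invisible(x)
}

# Genomic span of the first or last `n` coding nucleotides in translation
# order, as c(start, end). Walks the CDS chain so codons split by an intron
# are handled.
terminal_codon <- function(cds, strand, end_of_translation = FALSE, n = 3L) {
  ord <- if (strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
  ivs <- cds[ord, , drop = FALSE]
  if (end_of_translation) ivs <- ivs[rev(seq_len(nrow(ivs))), , drop = FALSE]
  from_left <- (strand == "+") != end_of_translation
  need <- n
  pos <- integer(0)
  for (k in seq_len(nrow(ivs))) {
    len <- ivs$end[k] - ivs$start[k] + 1L
    take <- min(need, len)
    pos <- c(pos, if (from_left) {
      ivs$start[k] + seq_len(take) - 1L
    } else {
      ivs$end[k] - seq_len(take) + 1L
    })
    need <- need - take
    if (need == 0L) break
  }
  c(min(pos), max(pos))
}

feature_key <- function(seqname, start, end, type, strand) {
  sprintf("%s\t%d\t%d\t%s\t%s", seqname, as.integer(start), as.integer(end), type, strand)
}

#' Derive the evidence-comparable features of a transcript
#'
#' The features a hint can support are the transcript's introns (the gaps
#' between consecutive CDS intervals) and its start and stop codon positions.
#' The start codon is the first three coding nucleotides in translation
#' order (strand-aware); the stop codon is an explicit `stop_codon` row when
#' the input carried one, otherwise the last three coding nucleotides.
#'
#' A feature is matched against hints on exact identity of sequence name,
#' start, end, feature type and strand — no tolerance window.
#'
#' @param tx A `tx_transcript`.
#' @return A list with `introns` (data frame of `start`,`end`; zero rows for
#'   a single-CDS transcript), `start_codon` and `stop_codon` (length-2
#'   integer vectors), and the match keys `keys_intron` and `keys_stasto`.
#' @export
derive_features <- function(tx) {
  cds <- tx$cds
  n <- nrow(cds)
  introns <- if (n > 1L) {
    data.frame(start = cds$end[-n] + 1L, end = cds$start[-1] - 1L)
  } else {
    data.frame(start = integer(0), end = integer(0))
  }
  start_codon <- terminal_codon(cds, tx$strand, end_of_translation = FALSE)
  stop_codon <- if (!is.null(tx$stop_codon)) {
    tx$stop_codon
  } else {
    terminal_codon(cds, tx$strand, end_of_translation = TRUE)
  }
  list(
    introns = introns,
    start_codon = start_codon,
    stop_codon = stop_codon,
    keys_intron = if (nrow(introns)) {
      feature_key(tx$seqname, introns$start, introns$end, "intron", tx$strand)
    } else {
      character(0)
    },
    keys_stasto = c(
      feature_key(tx$seqname, start_codon[1], start_codon[2], "start", tx$strand),
      feature_key(tx$seqname, stop_codon[1], stop_codon[2], "stop", tx$strand)
    )
  )
}

chain_key <- function(tx) {
  paste(tx$seqname, tx$strand,
    paste(tx$cds$start, tx$cds$end, sep = "-", collapse = ","),
    sep = "|"
  )
}

#' Merge structurally identical transcripts
#'
#' The union of several prediction sets usually contains the same transcript
#' more than once. Transcripts with identical sequence name, strand and
#' ordered CDS coordinate chain are collapsed to a single representative:
#' the one from the lowest input file index (ties broken by identifier).
#'
#' @param transcripts A list or `tx_set` of `tx_transcript` objects.
#' @return A `tx_set` of unique transcripts. The attribute `merged` is a
#'   data frame recording which identifiers were collapsed into which
#'   representative; `n_merged` is the number of dropped duplicates.
#' @export
merge_identical <- function(transcripts) {
  transcripts <- unclass(transcripts)
  if (length(transcripts) == 0L) {
    out <- as_tx_set(list())
    attr(out, "merged") <- data.frame(kept = character(0), dropped = character(0))
    attr(out, "n_merged") <- 0L
    return(out)
  }
  keys <- vapply(transcripts, chain_key, "")
  fidx <- vapply(transcripts, `[[`, 1L, "file_index")
  ids <- vapply(transcripts, `[[`, "", "id")
  ord <- order(keys, fidx, ids)
  keep <- !duplicated(keys[ord])
  kept_idx <- ord[keep]
  rep_of <- kept_idx[match(keys, keys[kept_idx])]
  dropped <- setdiff(seq_along(transcripts), kept_idx)
  out <- as_tx_set(transcripts[sort(kept_idx)])
  attr(out, "merged") <- data.frame(
    kept = ids[rep_of[dropped]],
    dropped = ids[dropped]
  )
  attr(out, "n_merged") <- length(dropped)
  out
}
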