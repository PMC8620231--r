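# Small in-code constructors for transcripts, hints and GTF/GFF text used
# across the tests. Everything is built programmatically; no stored data.

mk_tx <- function(id, starts, ends, strand = "+", seqname = "chr1",
                  gene_id = "g", file_index = 1L, stop_codon = NULL,
                  frame = ".") {
  new_transcript(
    id = id, gene_id = gene_id, seqname = seqname, strand = strand,
    cds = data.frame(start = starts, end = ends, frame = frame),
    file_index = file_index, stop_codon = stop_codon
  )
}

mk_hints <- function(...) {
  rows <- list(...)
  new_hint_set(do.call(rbind, lapply(rows, as.data.frame)))
}

hint_row <- function(seqname, start, end, type, strand, src, mult = 1L) {
  data.frame(
    seqname = seqname, start = start, end = end, type = type,
    strand = strand, src = src, mult = mult
  )
}

# hint on a transcript feature (1-based index into the derived feature list:
# introns in order, then start, then stop)
hints_on <- function(tx, which = "all", src = "E", mult = 1L) {
  f <- derive_features(tx)
  rows <- list()
  add <- function(start, end, type) {
    rows[[length(rows) + 1L]] <<- hint_row(
      tx$seqname, start, end, type, tx$strand, src, mult
    )
  }
  n_i <- nrow(f$introns)
  idx <- if (identical(which, "all")) seq_len(n_i + 2L) else as.integer(which)
  for (k in idx) {
    if (k <= n_i) {
      add(f$introns$start[k], f$introns$end[k], "intron")
    } else if (k == n_i + 1L) {
      add(f$start_codon[1], f$start_codon[2], "start")
    } else {
      add(f$stop_codon[1], f$stop_codon[2], "stop")
    }
  }
  do.call(rbind, rows)
}

write_tmp <- function(lines, ext = ".gtf") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

gtf_line <- function(seqname, feature, start, end, strand, frame, tid, gid = "g1") {
  paste(seqname, "test", feature, start, end, ".", strand, frame,
    sprintf('gene_id "%s"; transcript_id "%s";', gid, tid),
    sep = "\t"
  )
}

gff_hint_line <- function(seqname, type, start, end, strand, attrs) {
  paste(seqname, "src", type, start, end, ".", strand, ".", attrs, sep = "\t")
}

# chains of the surviving transcripts of a selection result, sorted
surviving_chains <- function(x) {
  txs <- if (inherits(x, "gene_cluster_set")) selected_transcripts(x) else x
  sort(vapply(unclass(txs), function(t) {
    paste(t$seqname, t$strand, paste(t$cds$start, t$cds$end, collapse = ","))
  }, ""))
}
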