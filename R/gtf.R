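split_gtf_line <- function(line, path, lineno) {
  fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(fields) != 9L) {
    stop(sprintf(
      "%s:%d: expected 9 tab-separated columns, found %d",
      path, lineno, length(fields)
    ), call. = FALSE)
  }
  fields
}

# Pulls one attribute from a GTF column 9, accepting both the quoted
# Ensembl dialect (transcript_id "t1";) and bare AUGUSTUS-style tokens.
gtf_attribute <- function(attr_field, name) {
  m <- regmatches(
    attr_field,
    regexec(paste0(name, '[ =]+"?([^";]+)"?'), attr_field)
  )[[1]]
  if (length(m) < 2L) NA_character_ else m[2]
}

#' Read a gene prediction file in GTF format
#'
#' Parses a BRAKER/AUGUSTUS-style GTF file into a set of transcripts. Only
#' `CDS` rows define transcript structure; an explicit `stop_codon` row, when
#' present, is kept as the authoritative stop-codon position. Rows of other
#' feature types (`exon`, `gene`, `transcript`, ...) are ignored for
#' structure. Transcripts without any CDS row are skipped with a warning.
#'
#' Transcript identifiers are made globally unique across input files by
#' prefixing them with `file_index` (`"2.t31"`), so that the union of
#' several predictions is collision-free. Set `prefix = FALSE` when
#' re-reading a file whose identifiers are already unique (e.g. this
#' package's own output).
#'
#' @param path Path to the GTF file.
#' @param file_index Index of this file among the input predictions.
#' @param prefix Prefix transcript identifiers with `file_index`?
#' @return A `tx_set` of [new_transcript()] objects.
#' @export
read_predictions <- function(path, file_index = 1L, prefix = TRUE) {
  if (!file.exists(path)) {
    stop("prediction file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  cds_rows <- list()
  stop_rows <- list()
  meta <- list() # per transcript: gene_id
  seen_tid <- character(0) # transcript_ids seen on any feature row
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (line == "" || startsWith(line, "#")) next
    f <- split_gtf_line(line, path, i)
    feature <- f[3]
    if (!feature %in% c(
      "CDS", "exon", "start_codon", "stop_codon",
      "transcript", "gene", "intron", "mRNA"
    )) {
      next
    }
    if (feature == "gene") next
    tid <- gtf_attribute(f[9], "transcript_id")
    if (is.na(tid) && feature %in% c("transcript", "mRNA")) {
      # AUGUSTUS writes the bare id in column 9 for transcript rows
      tid <- if (!grepl("[ \t\"]", f[9])) f[9] else NA_character_
    }
    if (is.na(tid)) {
      stop(sprintf("%s:%d: no transcript_id attribute", path, i), call. = FALSE)
    }
    gid <- gtf_attribute(f[9], "gene_id")
    seen_tid <- c(seen_tid, tid)
    if (!is.null(meta[[tid]])) {
      if (is.na(meta[[tid]]$gene_id) && !is.na(gid)) meta[[tid]]$gene_id <- gid
    } else {
      meta[[tid]] <- list(gene_id = gid)
    }
    if (!feature %in% c("CDS", "stop_codon")) next
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end) || start > end) {
      stop(sprintf("%s:%d: bad coordinates '%s'-'%s'", path, i, f[4], f[5]),
        call. = FALSE
      )
    }
    if (feature == "CDS" && !f[7] %in% c("+", "-")) {
      stop(sprintf("%s:%d: CDS row with strand '%s'", path, i, f[7]),
        call. = FALSE
      )
    }
    row <- list(
      seqname = f[1], start = start, end = end,
      strand = f[7], frame = f[8]
    )
    if (feature == "CDS") {
      cds_rows[[tid]] <- c(cds_rows[[tid]], list(row))
    } else {
      stop_rows[[tid]] <- row
    }
  }
  tids <- unique(seen_tid)
  no_cds <- setdiff(tids, names(cds_rows))
  if (length(no_cds)) {
    warning(
      "skipping ", length(no_cds), " transcript(s) without CDS rows in ",
      path, ": ", paste(utils::head(no_cds, 5), collapse = ", "),
      call. = FALSE
    )
  }
  txs <- lapply(names(cds_rows), function(tid) {
    rows <- cds_rows[[tid]]
    seqnames <- unique(vapply(rows, `[[`, "", "seqname"))
    strands <- unique(vapply(rows, `[[`, "", "strand"))
    if (length(seqnames) > 1L) {
      stop(sprintf(
        "%s: transcript '%s' has CDS rows on multiple sequences (%s)",
        path, tid, paste(seqnames, collapse = ", ")
      ), call. = FALSE)
    }
    if (length(strands) > 1L) {
      stop(sprintf(
        "%s: transcript '%s' has CDS rows on mixed strands", path, tid
      ), call. = FALSE)
    }
    stopr <- stop_rows[[tid]]
    new_transcript(
      id = if (prefix) paste0(file_index, ".", tid) else tid,
      original_id = tid,
      gene_id = {
        g <- meta[[tid]]$gene_id
        if (is.na(g)) tid else g
      },
      seqname = seqnames,
      strand = strands,
      cds = data.frame(
        start = vapply(rows, `[[`, 1L, "start"),
        end = vapply(rows, `[[`, 1L, "end"),
        frame = vapply(rows, `[[`, "", "frame")
      ),
      file_index = file_index,
      stop_codon = if (!is.null(stopr)) c(stopr$start, stopr$end)
    )
  })
  as_tx_set(txs)
}

normalize_hint_type <- function(type) {
  switch(tolower(type),
    "intron" = "intron",
    "start" = ,
    "start_codon" = "start",
    "stop" = ,
    "stop_codon" = "stop",
    NA_character_
  )
}

#' Read extrinsic-evidence hint files
#'
#' Hints are single pieces of extrinsic evidence — intron intervals or
#' start/stop codon positions inferred from RNA-seq or protein alignments —
#' in 9-column GFF with two tokens in the attribute column: `src=`, a
#' single-letter source label (mandatory), and `mult=`, the number of
#' alignments from that source supporting the hint (absent means 1).
#'
#' Hints identical in (sequence name, start, end, feature type, strand,
#' source) are merged by summing their multiplicities, both within and
#' across files. Rows with feature types other than
#' `intron`/`start`/`stop` (and the `_codon` spellings) are skipped with a
#' warning.
#'
#' @param paths Character vector of hint GFF paths.
#' @return An object of class `hint_set`: a data frame with columns
#'   `seqname`, `start`, `end`, `type`, `strand`, `src`, `mult` and the
#'   internal match `key`; attribute `sources` lists the observed source
#'   labels.
#' @export
read_hints <- function(paths) {
  rows <- list()
  skipped <- 0L
  for (path in paths) {
    if (!file.exists(path)) {
      stop("hint file not found: ", path, call. = FALSE)
    }
    lines <- readLines(path, warn = FALSE)
    for (i in seq_along(lines)) {
      line <- lines[i]
      if (line == "" || startsWith(line, "#")) next
      f <- split_gtf_line(line, path, i)
      type <- normalize_hint_type(f[3])
      if (is.na(type)) {
        skipped <- skipped + 1L
        next
      }
      start <- suppressWarnings(as.integer(f[4]))
      end <- suppressWarnings(as.integer(f[5]))
      if (is.na(start) || is.na(end) || start > end) {
        stop(sprintf("%s:%d: bad coordinates '%s'-'%s'", path, i, f[4], f[5]),
          call. = FALSE
        )
      }
      src <- gtf_attribute(f[9], "src")
      if (is.na(src)) {
        stop(sprintf("%s:%d: hint without src= attribute", path, i),
          call. = FALSE
        )
      }
      mult_s <- gtf_attribute(f[9], "mult")
      mult <- if (is.na(mult_s)) 1L else suppressWarnings(as.integer(mult_s))
      if (is.na(mult) || mult < 1L) {
        stop(sprintf("%s:%d: bad mult= value '%s'", path, i, mult_s),
          call. = FALSE
        )
      }
      if (type %in% c("start", "stop") && end - start != 2L) {
        stop(sprintf(
          "%s:%d: %s-codon hint must span 3 nucleotides, got %d-%d",
          path, i, type, start, end
        ), call. = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        seqname = f[1], start = start, end = end, type = type,
        strand = f[7], src = src, mult = mult
      )
    }
  }
  if (skipped > 0L) {
    warning("skipped ", skipped, " hint row(s) with unsupported feature types",
      call. = FALSE
    )
  }
  hints <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(
      seqname = character(0), start = integer(0), end = integer(0),
      type = character(0), strand = character(0), src = character(0),
      mult = integer(0)
    )
  }
  new_hint_set(hints)
}

#' Assemble a hint set from a data frame
#'
#' Lower-level constructor behind [read_hints()], useful for building
#' evidence in code (tests, fixtures). Duplicate (position, type, strand,
#' source) entries are merged by summing `mult`.
#'
#' @param hints Data frame with columns `seqname`, `start`, `end`, `type`
#'   (`intron`/`start`/`stop`), `strand`, `src`, `mult`.
#' @return A `hint_set`.
#' @export
new_hint_set <- function(hints) {
  hints <- as.data.frame(hints)
  needed <- c("seqname", "start", "end", "type", "strand", "src", "mult")
  stopifnot(all(needed %in% names(hints)))
  hints <- hints[needed]
  hints$start <- as.integer(hints$start)
  hints$end <- as.integer(hints$end)
  hints$mult <- as.integer(hints$mult)
  stopifnot(all(hints$mult >= 1L), all(hints$type %in% c("intron", "start", "stop")))
  key_src <- paste(
    feature_key(hints$seqname, hints$start, hints$end, hints$type, hints$strand),
    hints$src,
    sep = "\r"
  )
  if (anyDuplicated(key_src)) {
    mult <- rowsum(hints$mult, key_src)
    first <- !duplicated(key_src)
    hints <- hints[first, , drop = FALSE]
    hints$mult <- as.integer(mult[match(key_src[first], rownames(mult)), 1])
  }
  hints <- hints[order(
    hints$seqname, hints$start, hints$end,
    hints$type, hints$strand, hints$src
  ), , drop = FALSE]
  rownames(hints) <- NULL
  hints$key <- feature_key(hints$seqname, hints$start, hints$end, hints$type, hints$strand)
  structure(hints,
    sources = sort(unique(hints$src)),
    class = c("hint_set", "data.frame")
  )
}

#' Write a combined gene set in GTF format
#'
#' Output is deterministic: genes are sorted by (sequence name, leftmost
#' coordinate, rightmost coordinate) and renumbered `g1`, `g2`, ...; within
#' a gene, transcripts are sorted by coordinate and identifier. Each
#' transcript contributes a `transcript` row followed by its `CDS` rows
#' (original coordinates, strand and frame preserved) and, when the input
#' carried one, its `stop_codon` row.
#'
#' @param clusters A `gene_cluster_set` from [run_selection()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(clusters, path) {
  lines <- c("# txcombine combined gene set")
  for (cl in clusters) {
    for (tx in cl$transcripts) {
      attrs <- sprintf('gene_id "%s"; transcript_id "%s";', cl$gene_id, tx$id)
      lines <- c(
        lines,
        paste(tx$seqname, "txcombine", "transcript",
          min(tx$cds$start, tx$stop_codon), max(tx$cds$end, tx$stop_codon),
          ".", tx$strand, ".", attrs,
          sep = "\t"
        ),
        paste(tx$seqname, "txcombine", "CDS",
          tx$cds$start, tx$cds$end, ".", tx$strand, tx$cds$frame, attrs,
          sep = "\t"
        ),
        if (!is.null(tx$stop_codon)) {
          paste(tx$seqname, "txcombine", "stop_codon",
            tx$stop_codon[1], tx$stop_codon[2], ".", tx$strand, "0", attrs,
            sep = "\t"
          )
        }
      )
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write a transcript set in GTF format
#'
#' Writes transcripts with their original gene and transcript identifiers,
#' one `transcript` row plus `CDS` rows each (and `stop_codon` when
#' present). Used by the fixture generator to emit prediction files.
#'
#' @param transcripts A `tx_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  lines <- character(0)
  for (tx in transcripts) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', tx$gene_id, tx$original_id)
    lines <- c(
      lines,
      paste(tx$seqname, "txcombine", "transcript",
        min(tx$cds$start, tx$stop_codon), max(tx$cds$end, tx$stop_codon),
        ".", tx$strand, ".", attrs,
        sep = "\t"
      ),
      paste(tx$seqname, "txcombine", "CDS",
        tx$cds$start, tx$cds$end, ".", tx$strand, tx$cds$frame, attrs,
        sep = "\t"
      ),
      if (!is.null(tx$stop_codon)) {
        paste(tx$seqname, "txcombine", "stop_codon",
          tx$stop_codon[1], tx$stop_codon[2], ".", tx$strand, "0", attrs,
          sep = "\t"
        )
      }
    )
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write a hint set as a GFF file
#'
#' @param hints A `hint_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hints <- function(hints, path) {
  lines <- if (nrow(hints)) {
    paste(hints$seqname, "txcombine", hints$type, hints$start, hints$end,
      ".", hints$strand, ".", sprintf("mult=%d;src=%s;", hints$mult, hints$src),
      sep = "\t"
    )
  } else {
    character(0)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
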