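# Brute-force reference implementation of the whole selection workflow,
# kept deliberately independent of run_selection(): features are derived by
# enumerating coding positions one nucleotide at a time, hints are matched
# by scanning every row, overlaps are detected on per-nucleotide position
# sets, and all transcript pairs are compared with no interval index or
# early exit. Intended for equivalence testing on small instances.

# coding positions of a transcript in translation order
oracle_positions <- function(tx) {
  pos <- unlist(lapply(seq_len(nrow(tx$cds)), function(k) {
    tx$cds$start[k]:tx$cds$end[k]
  }), use.names = FALSE)
  if (tx$strand == "-") pos <- rev(pos)
  pos
}

oracle_features <- function(tx) {
  pos_tr <- oracle_positions(tx)
  pos_asc <- sort(pos_tr)
  feats <- list()
  # introns: maximal gaps between consecutive coding positions
  gaps <- which(diff(pos_asc) > 1L)
  for (g in gaps) {
    feats[[length(feats) + 1L]] <- list(
      type = "intron",
      start = pos_asc[g] + 1L, end = pos_asc[g + 1L] - 1L
    )
  }
  first3 <- pos_tr[seq_len(min(3L, length(pos_tr)))]
  feats[[length(feats) + 1L]] <- list(
    type = "start", start = min(first3), end = max(first3)
  )
  if (!is.null(tx$stop_codon)) {
    feats[[length(feats) + 1L]] <- list(
      type = "stop", start = tx$stop_codon[1], end = tx$stop_codon[2]
    )
  } else {
    last3 <- pos_tr[seq(to = length(pos_tr), length.out = min(3L, length(pos_tr)))]
    feats[[length(feats) + 1L]] <- list(
      type = "stop", start = min(last3), end = max(last3)
    )
  }
  feats
}

oracle_score <- function(tx, hints, weights) {
  feats <- oracle_features(tx)
  types <- vapply(feats, `[[`, "", "type")
  support <- function(sel) {
    fs <- feats[sel]
    if (length(fs) == 0L) {
      return(c(r = 1.0, a = 0.0))
    }
    n_sup <- 0L
    a <- 0.0
    for (f in fs) {
      matched <- FALSE
      for (h in seq_len(nrow(hints))) {
        if (hints$seqname[h] == tx$seqname &&
          hints$strand[h] == tx$strand &&
          hints$type[h] == f$type &&
          hints$start[h] == f$start &&
          hints$end[h] == f$end) {
          matched <- TRUE
          w <- weights[[hints$src[h]]]
          if (is.null(w) || is.na(w)) {
            stop("no weight for source ", hints$src[h], call. = FALSE)
          }
          a <- a + w * hints$mult[h]
        }
      }
      if (matched) n_sup <- n_sup + 1L
    }
    c(r = n_sup / length(fs), a = a)
  }
  si <- support(types == "intron")
  ss <- support(types != "intron")
  c(s1 = si[["r"]], s2 = ss[["r"]], s3 = si[["a"]], s4 = ss[["a"]])
}

# per-nucleotide overlap test: >= 3 consecutive genomic positions coding in
# both transcripts with equal codon offsets
oracle_overlap <- function(t1, t2) {
  if (t1$seqname != t2$seqname || t1$strand != t2$strand) {
    return(FALSE)
  }
  p1 <- oracle_positions(t1)
  p2 <- oracle_positions(t2)
  o1 <- (seq_along(p1) - 1L) %% 3L
  o2 <- (seq_along(p2) - 1L) %% 3L
  shared <- intersect(p1, p2)
  if (length(shared) < 3L) {
    return(FALSE)
  }
  same <- shared[o1[match(shared, p1)] == o2[match(shared, p2)]]
  if (length(same) < 3L) {
    return(FALSE)
  }
  s <- sort(same)
  d <- diff(s)
  any(d[-length(d)] == 1L & d[-1] == 1L)
}

#' Brute-force reference transcript selector
#'
#' A literal, unoptimized transcription of the selection workflow, written
#' independently of [run_selection()]: per-nucleotide coding-overlap tests,
#' linear scans over all hints for feature support, and comparison of all
#' transcript pairs. Used to validate [run_selection()] by exact set
#' equality on small instances (tens of transcripts).
#'
#' @param transcripts A list or `tx_set` of transcripts.
#' @param hints A `hint_set`.
#' @param hp A `tx_hyperparameters` object.
#' @return A `tx_set` of the surviving transcripts (no gene grouping).
#' @export
oracle_select <- function(transcripts, hints, hp = default_hyperparameters()) {
  txs <- unclass(transcripts)
  n <- length(txs)
  if (n == 0L) {
    return(as_tx_set(list()))
  }
  # step 1: merge identical (pairwise chain comparison)
  drop <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ti <- txs[[i]]
      tj <- txs[[j]]
      if (ti$seqname == tj$seqname && ti$strand == tj$strand &&
        nrow(ti$cds) == nrow(tj$cds) &&
        all(ti$cds$start == tj$cds$start) && all(ti$cds$end == tj$cds$end)) {
        # keep lower file index; break ties by id
        if (tj$file_index < ti$file_index ||
          (tj$file_index == ti$file_index && tj$id < ti$id)) {
          drop[i] <- TRUE
        }
      }
    }
  }
  txs <- txs[!drop]
  n <- length(txs)
  # step 2: score everything
  scores <- lapply(txs, oracle_score, hints = hints, weights = hp$weights)
  # steps 3-4: all pairs, accumulate marks on the original union
  marked <- logical(n)
  if (n >= 2L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        if (!oracle_overlap(txs[[i]], txs[[j]])) next
        v1 <- scores[[i]]
        v2 <- scores[[j]]
        for (k in 1:4) {
          if (abs(v1[[k]] - v2[[k]]) > hp$epsilon[k]) {
            if (v1[[k]] < v2[[k]]) marked[i] <- TRUE else marked[j] <- TRUE
            break
          }
        }
      }
    }
  }
  # steps 5-6: removals
  keep <- !marked
  for (i in seq_len(n)) {
    v <- scores[[i]]
    if (v[["s1"]] < hp$intron_support && v[["s2"]] < hp$stasto_support) {
      keep[i] <- FALSE
    }
  }
  as_tx_set(txs[keep])
}
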