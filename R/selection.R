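#' Pairwise transcript comparison rule
#'
#' Two overlapping transcripts are compared on their score vectors, one
#' score at a time in the order `s1`, `s2`, `s3`, `s4`. At the first index
#' `j` where the absolute difference exceeds the threshold `e_j`, the rule
#' terminates and the transcript with the smaller `s_j` is marked for
#' removal. If every difference is less than or equal to its threshold,
#' neither transcript is marked.
#'
#' The comparison is strict (`> e_j` triggers, equality does not), so with
#' the default `e_1 = 0` any difference in intron support fraction is
#' already decisive.
#'
#' @param v1,v2 Score vectors (numeric, length 4) of the two transcripts.
#' @param hp A `tx_hyperparameters` object, or a numeric vector of the four
#'   thresholds.
#' @return A list with `outcome` (`"none"`, `"first"` or `"second"` — which
#'   transcript is marked) and `decisive` (the index `j` that decided, or
#'   `NA` if none).
#' @export
compare_pair <- function(v1, v2, hp = default_hyperparameters()) {
  eps <- if (inherits(hp, "tx_hyperparameters")) hp$epsilon else as.numeric(hp)
  stopifnot(length(eps) == 4L, length(v1) == 4L, length(v2) == 4L)
  for (j in 1:4) {
    d <- v1[[j]] - v2[[j]]
    if (abs(d) > eps[j]) {
      return(list(
        outcome = if (d < 0) "first" else "second",
        decisive = j
      ))
    }
  }
  list(outcome = "none", decisive = NA_integer_)
}

#' Low evidence support predicate
#'
#' A transcript has low evidence support — and is removed outright,
#' independently of any pairwise comparison — when **both** its supported
#' intron fraction `s1` is below the intron threshold (default 0.75) and
#' its supported start/stop fraction `s2` is below the start/stop threshold
#' (default 1.0). Passing either fraction alone keeps the transcript.
#'
#' @param v Score vector (numeric, length >= 2).
#' @param hp A `tx_hyperparameters` object.
#' @return `TRUE` if the transcript should be removed.
#' @export
low_support <- function(v, hp = default_hyperparameters()) {
  v[[1]] < hp$intron_support && v[[2]] < hp$stasto_support
}

# Cumulative coding length before each CDS interval in translation order;
# offset_at(p, k) %% 3 gives position p's codon offset (0 = first codon
# position) when p lies in interval k of the ascending-sorted chain.
coding_offset <- function(tx, pos, k) {
  len <- tx$cds$end - tx$cds$start + 1L
  if (tx$strand == "+") {
    before <- c(0L, cumsum(len))[k]
    (before + (pos - tx$cds$start[k])) %% 3L
  } else {
    after <- rev(cumsum(rev(len))) - len
    (after[k] + (tx$cds$end[k] - pos)) %% 3L
  }
}

#' Do two transcripts overlap in coding sequence, in frame?
#'
#' Two transcripts overlap — and are therefore candidates for the pairwise
#' comparison rule, and end up in the same gene if both survive — when they
#' share at least three adjacent protein-coding nucleotides on the same
#' strand and in the same reading frame. The frame of a nucleotide is its
#' offset (mod 3) from the transcript's own translation start, accumulated
#' over the CDS chain strand-aware, so two transcripts agree on shared
#' positions exactly when their codon boundaries coincide there.
#'
#' @param t1,t2 `tx_transcript` objects.
#' @return `TRUE` or `FALSE`.
#' @export
coding_overlap <- function(t1, t2) {
  if (t1$seqname != t2$seqname || t1$strand != t2$strand) {
    return(FALSE)
  }
  c1 <- t1$cds
  c2 <- t2$cds
  for (a in seq_len(nrow(c1))) {
    for (b in seq_len(nrow(c2))) {
      lo <- max(c1$start[a], c2$start[b])
      hi <- min(c1$end[a], c2$end[b])
      if (hi - lo + 1L >= 3L &&
        coding_offset(t1, lo, a) == coding_offset(t2, lo, b)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# All unordered index pairs with coding overlap. Candidate pairs are found
# by a span sweep per (seqname, strand) group — a necessary condition of
# coding overlap — then confirmed exactly; contract-identical to all-pairs.
overlap_pairs <- function(transcripts) {
  n <- length(transcripts)
  if (n < 2L) {
    return(matrix(integer(0), ncol = 2))
  }
  seqname <- vapply(transcripts, `[[`, "", "seqname")
  strand <- vapply(transcripts, `[[`, "", "strand")
  span_start <- vapply(transcripts, function(t) min(t$cds$start), 1L)
  span_end <- vapply(transcripts, function(t) max(t$cds$end), 1L)
  pairs <- list()
  for (grp in split(seq_len(n), paste(seqname, strand))) {
    if (length(grp) < 2L) next
    grp <- grp[order(span_start[grp], span_end[grp])]
    for (ii in seq_len(length(grp) - 1L)) {
      i <- grp[ii]
      for (jj in (ii + 1L):length(grp)) {
        j <- grp[jj]
        if (span_start[j] > span_end[i]) break
        if (coding_overlap(transcripts[[i]], transcripts[[j]])) {
          pairs[[length(pairs) + 1L]] <- c(min(i, j), max(i, j))
        }
      }
    }
  }
  if (length(pairs) == 0L) {
    return(matrix(integer(0), ncol = 2))
  }
  do.call(rbind, pairs)
}

union_find <- function(n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  list(
    find = find,
    union = function(a, b) {
      ra <- find(a)
      rb <- find(b)
      if (ra != rb) parent[ra] <<- rb
    }
  )
}

#' Select evidence-supported transcripts and assemble them into genes
#'
#' The full selection workflow over the union of all input predictions:
#'
#' 1. merge structurally identical transcripts ([merge_identical()]);
#' 2. compute every transcript's score vector ([score_vector()]);
#' 3. find all pairs of transcripts with in-frame coding overlap
#'    ([coding_overlap()]);
#' 4. apply the comparison rule ([compare_pair()]) to every such pair,
#'    accumulating removal marks — a transcript already marked is still
#'    compared against all of its overlap partners and may cause the
#'    removal of another transcript, so marks never depend on evaluation
#'    order;
#' 5. remove all marked transcripts;
#' 6. remove transcripts with low evidence support ([low_support()]);
#' 7. cluster the survivors into genes by single linkage over coding
#'    overlap; each cluster is one output gene, its members the gene's
#'    isoforms.
#'
#' @param transcripts A list or `tx_set` of transcripts (the union of all
#'   input prediction files).
#' @param hints A `hint_set` with all extrinsic evidence.
#' @param hp A `tx_hyperparameters` object.
#' @return A `gene_cluster_set`: a list of clusters sorted by (seqname,
#'   leftmost, rightmost coordinate) and renumbered `g1`, `g2`, ...; each
#'   cluster holds `gene_id`, `seqname`, `strand`, `start`, `end` and
#'   `transcripts`. The attribute `stats` records input/merged/marked/
#'   low-support/output counts; `scores` holds the score matrix of the
#'   merged union.
#' @export
run_selection <- function(transcripts, hints, hp = default_hyperparameters()) {
  n_in <- length(transcripts)
  merged <- merge_identical(transcripts)
  n <- length(merged)
  scores <- score_transcripts(merged, hints, hp)
  pairs <- overlap_pairs(merged)
  marked <- logical(n)
  if (nrow(pairs)) {
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]
      j <- pairs[p, 2]
      cmp <- compare_pair(scores[i, ], scores[j, ], hp)
      if (cmp$outcome == "first") marked[i] <- TRUE
      if (cmp$outcome == "second") marked[j] <- TRUE
    }
  }
  low <- vapply(seq_len(n), function(i) low_support(scores[i, ], hp), TRUE)
  keep <- !marked & !low
  survivors <- which(keep)
  # single-linkage clustering of survivors over the precomputed overlaps
  uf <- union_find(n)
  if (nrow(pairs)) {
    for (p in seq_len(nrow(pairs))) {
      if (keep[pairs[p, 1]] && keep[pairs[p, 2]]) {
        uf$union(pairs[p, 1], pairs[p, 2])
      }
    }
  }
  comp <- vapply(survivors, uf$find, 1L)
  clusters <- lapply(split(survivors, comp), function(idx) {
    txs <- unclass(merged)[idx]
    starts <- vapply(txs, function(t) min(t$cds$start), 1L)
    ends <- vapply(txs, function(t) max(t$cds$end), 1L)
    ids <- vapply(txs, `[[`, "", "id")
    txs <- txs[order(starts, ends, ids)]
    list(
      gene_id = NA_character_,
      seqname = txs[[1]]$seqname,
      strand = txs[[1]]$strand,
      start = min(starts),
      end = max(ends),
      transcripts = txs
    )
  })
  ord <- order(
    vapply(clusters, `[[`, "", "seqname"),
    vapply(clusters, `[[`, 1L, "start"),
    vapply(clusters, `[[`, 1L, "end"),
    vapply(clusters, `[[`, "", "strand"),
    vapply(clusters, function(cl) cl$transcripts[[1]]$id, "")
  )
  clusters <- clusters[ord]
  for (k in seq_along(clusters)) clusters[[k]]$gene_id <- paste0("g", k)
  structure(
    clusters,
    class = "gene_cluster_set",
    stats = list(
      n_input = n_in,
      n_merged = attr(merged, "n_merged"),
      n_union = n,
      n_marked = sum(marked),
      n_low_support = sum(low & !marked),
      n_transcripts_out = length(survivors),
      n_genes_out = length(clusters)
    ),
    scores = scores
  )
}

#' Extract the surviving transcripts from a selection result
#'
#' @param clusters A `gene_cluster_set`.
#' @return A `tx_set` of all transcripts across all output genes.
#' @export
selected_transcripts <- function(clusters) {
  as_tx_set(unlist(lapply(clusters, `[[`, "transcripts"), recursive = FALSE))
}

#' @export
print.gene_cluster_set <- function(x, ...) {
  st <- attr(x, "stats")
  cat(sprintf(
    "<gene_cluster_set> %d genes, %d transcripts (from %d input transcripts)\n",
    length(x), st$n_transcripts_out, st$n_input
  ))
  invisible(x)
}
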