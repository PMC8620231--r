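#' Do two CDS intervals agree?
#'
#' Two CDS agree when they lie on the same sequence and strand and both
#' coordinate pairs are identical — exact matching, no tolerance.
#'
#' @param c1,c2 Lists (or one-row data frames) with `seqname`, `strand`,
#'   `start`, `end`.
#' @return `TRUE` or `FALSE`.
#' @export
cds_match <- function(c1, c2) {
  c1$seqname == c2$seqname && c1$strand == c2$strand &&
    c1$start == c2$start && c1$end == c2$end
}

#' Do two transcripts agree on their CDS structure?
#'
#' A reference transcript counts as correctly predicted when prediction and
#' reference agree completely on their sets of CDS: same sequence, strand,
#' and every CDS coordinate pair identical. Identifiers are irrelevant.
#'
#' @param t1,t2 `tx_transcript` objects.
#' @return `TRUE` or `FALSE`.
#' @export
transcript_match <- function(t1, t2) {
  chain_key(t1) == chain_key(t2)
}

#' Is a predicted gene correct with respect to a reference annotation?
#'
#' A predicted gene is correct if at least one of its isoforms exactly
#' matches (per [transcript_match()]) at least one annotated isoform of some
#' reference gene.
#'
#' @param g_pred List of `tx_transcript` isoforms of one predicted gene.
#' @param reference A list or `tx_set` of reference transcripts.
#' @return `TRUE` or `FALSE`.
#' @export
gene_match <- function(g_pred, reference) {
  pred_chains <- vapply(g_pred, chain_key, "")
  ref_chains <- vapply(reference, chain_key, "")
  any(pred_chains %in% ref_chains)
}

split_genes <- function(transcripts) {
  gid <- vapply(transcripts, `[[`, "", "gene_id")
  split(unclass(transcripts), gid)
}

# Greedy one-to-one matching between predicted and reference genes sharing
# at least one identical isoform chain. Edges are processed in an ordering
# symmetric in the two annotations, so the matching size (the gene-level
# TP) is invariant under swapping prediction and reference.
gene_tp <- function(pred_genes, ref_genes) {
  if (length(pred_genes) == 0L || length(ref_genes) == 0L) {
    return(0L)
  }
  pred_chains <- lapply(pred_genes, function(g) vapply(g, chain_key, ""))
  ref_chains <- lapply(ref_genes, function(g) vapply(g, chain_key, ""))
  gene_span <- function(g) {
    c(
      min(vapply(g, function(t) min(t$cds$start), 1L)),
      max(vapply(g, function(t) max(t$cds$end), 1L))
    )
  }
  pred_span <- lapply(pred_genes, gene_span)
  ref_span <- lapply(ref_genes, gene_span)
  pred_seq <- vapply(pred_genes, function(g) g[[1]]$seqname, "")
  ref_seq <- vapply(ref_genes, function(g) g[[1]]$seqname, "")
  # chain -> ref gene indices
  ref_by_chain <- split(
    rep(seq_along(ref_genes), lengths(ref_chains)),
    unlist(ref_chains)
  )
  edges <- list()
  for (p in seq_along(pred_genes)) {
    hits <- unique(unlist(ref_by_chain[pred_chains[[p]]], use.names = FALSE))
    for (r in hits) edges[[length(edges) + 1L]] <- c(p, r)
  }
  if (length(edges) == 0L) {
    return(0L)
  }
  e <- do.call(rbind, edges)
  key <- data.frame(
    seqname = pred_seq[e[, 1]],
    lo = pmin(
      vapply(pred_span[e[, 1]], `[`, 1L, 1),
      vapply(ref_span[e[, 2]], `[`, 1L, 1)
    ),
    hi = pmax(
      vapply(pred_span[e[, 1]], `[`, 1L, 2),
      vapply(ref_span[e[, 2]], `[`, 1L, 2)
    ),
    lo2 = pmax(
      vapply(pred_span[e[, 1]], `[`, 1L, 1),
      vapply(ref_span[e[, 2]], `[`, 1L, 1)
    ),
    hi2 = pmin(
      vapply(pred_span[e[, 1]], `[`, 1L, 2),
      vapply(ref_span[e[, 2]], `[`, 1L, 2)
    )
  )
  ord <- order(key$seqname, key$lo, key$hi, key$lo2, key$hi2)
  used_p <- logical(length(pred_genes))
  used_r <- logical(length(ref_genes))
  tp <- 0L
  for (idx in ord) {
    p <- e[idx, 1]
    r <- e[idx, 2]
    if (!used_p[p] && !used_r[r]) {
      used_p[p] <- TRUE
      used_r[r] <- TRUE
      tp <- tp + 1L
    }
  }
  tp
}

f1_score <- function(sn, sp) {
  if (sn + sp == 0) 0 else 2 * sn * sp / (sn + sp)
}

#' Annotation accuracy at CDS, transcript and gene level
#'
#' Compares a predicted gene set against a reference annotation with
#' exact-match semantics and reports sensitivity (`Sn = TP/reference`),
#' specificity (`Sp = TP/prediction`) and their harmonic mean (F1), each in
#' percent, at three levels:
#'
#' * **CDS** — units are unique (seqname, strand, start, end) intervals
#'   within each annotation; a TP is an interval present in both.
#' * **transcript** — units are unique CDS chains; a TP is a chain present
#'   in both (isoform identifiers play no role).
#' * **gene** — a predicted gene is a TP if at least one of its isoforms
#'   matches an isoform of a reference gene; genes are paired one-to-one
#'   greedily in coordinate order.
#'
#' @param prediction,reference `tx_set` objects (e.g. from
#'   [read_predictions()]), with `gene_id` grouping isoforms.
#' @return An `accuracy_report`: a data frame with one row per level and
#'   columns `level`, `tp`, `n_pred`, `n_ref`, `sn`, `sp`, `f1`.
#' @export
annotation_accuracy <- function(prediction, reference) {
  if (length(reference) == 0L) {
    stop("reference annotation is empty; sensitivity is undefined", call. = FALSE)
  }
  if (length(prediction) == 0L) {
    warning("prediction is empty; specificity reported as 0", call. = FALSE)
  }
  cds_keys <- function(txs) {
    unique(unlist(lapply(txs, function(t) {
      feature_key(t$seqname, t$cds$start, t$cds$end, "cds", t$strand)
    }), use.names = FALSE))
  }
  pred_cds <- cds_keys(prediction)
  ref_cds <- cds_keys(reference)
  pred_chains <- unique(vapply(unclass(prediction), chain_key, ""))
  ref_chains <- unique(vapply(unclass(reference), chain_key, ""))
  pred_genes <- split_genes(prediction)
  ref_genes <- split_genes(reference)
  counts <- data.frame(
    level = c("CDS", "transcript", "gene"),
    tp = c(
      length(intersect(pred_cds, ref_cds)),
      length(intersect(pred_chains, ref_chains)),
      gene_tp(pred_genes, ref_genes)
    ),
    n_pred = c(length(pred_cds), length(pred_chains), length(pred_genes)),
    n_ref = c(length(ref_cds), length(ref_chains), length(ref_genes))
  )
  counts$sn <- 100 * counts$tp / counts$n_ref
  counts$sp <- ifelse(counts$n_pred == 0, 0, 100 * counts$tp / counts$n_pred)
  counts$f1 <- mapply(f1_score, counts$sn, counts$sp)
  structure(counts, class = c("accuracy_report", "data.frame"))
}

#' Evaluate a prediction GTF against a reference GTF
#'
#' File-level wrapper around [annotation_accuracy()].
#'
#' @param pred_path,ref_path Paths to prediction and reference GTF files.
#' @return An `accuracy_report`.
#' @export
evaluate_annotation <- function(pred_path, ref_path) {
  annotation_accuracy(
    read_predictions(pred_path, file_index = 1L, prefix = FALSE),
    read_predictions(ref_path, file_index = 2L, prefix = FALSE)
  )
}

#' Write an accuracy report as tab-separated text
#'
#' @param report An `accuracy_report`.
#' @param path Output path, or `""` for standard output.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path = "") {
  df <- as.data.frame(report)
  df$sn <- sprintf("%.2f", df$sn)
  df$sp <- sprintf("%.2f", df$sp)
  df$f1 <- sprintf("%.2f", df$f1)
  utils::write.table(df,
    file = path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' @export
print.accuracy_report <- function(x, ...) {
  df <- as.data.frame(x)
  df$sn <- sprintf("%.2f", df$sn)
  df$sp <- sprintf("%.2f", df$sp)
  df$f1 <- sprintf("%.2f", df$f1)
  print(df, row.names = FALSE)
  invisible(x)
}
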