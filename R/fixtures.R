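#' Specification for a synthetic test fixture
#'
#' Describes a deterministic synthetic dataset: a set of gene loci with
#' "true" transcripts (optionally with alternative isoforms and duplicates
#' planted in a second prediction file) plus overlapping "decoy"
#' transcripts, and an evidence profile stating how densely hints cover
#' true and decoy features.
#'
#' Loci are non-overlapping coordinate blocks on artificial contig names,
#' so no genome sequence is needed. All CDS lengths are multiples of 3,
#' which guarantees that isoforms sharing a CDS — and decoys shifted by a
#' multiple of 3 — overlap in frame by construction.
#'
#' @param seed Integer seed fixing every random draw.
#' @param n_loci Number of gene loci.
#' @param isoforms Length-2 integer range of isoforms per locus.
#' @param n_cds Length-2 integer range of CDS intervals per transcript.
#' @param decoy_fraction Probability that a locus carries a decoy
#'   transcript overlapping its first true isoform.
#' @param frameshift_fraction Probability that a decoy is shifted out of
#'   frame (it then overlaps in span but not in reading frame, so it is
#'   never compared against the true transcript).
#' @param coverage Named list, one entry per evidence source label, each a
#'   list with `p` (probability that a true-transcript feature receives a
#'   hint from this source) and `mult` (Poisson mean of the multiplicity
#'   above 1).
#' @param decoy_coverage Same, for decoy features.
#' @param duplicates Emit copies of true isoforms in the second prediction
#'   file (exercises merging)?
#' @param seqnames Artificial contig names the loci are spread over.
#' @return A `tx_fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L,
                         n_loci = 6L,
                         isoforms = c(1L, 2L),
                         n_cds = c(1L, 5L),
                         decoy_fraction = 0.5,
                         frameshift_fraction = 0.25,
                         coverage = list(
                           E = list(p = 0.9, mult = 4),
                           P = list(p = 0.6, mult = 1)
                         ),
                         decoy_coverage = list(
                           E = list(p = 0.1, mult = 0)
                         ),
                         duplicates = TRUE,
                         seqnames = c("ctg1", "ctg2")) {
  probs <- c(
    decoy_fraction, frameshift_fraction,
    vapply(coverage, `[[`, 1.0, "p"),
    vapply(decoy_coverage, `[[`, 1.0, "p")
  )
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (n_loci < 0L || (n_loci == 0L && decoy_fraction > 0)) {
    stop("infeasible spec: decoys requested but no loci", call. = FALSE)
  }
  stopifnot(
    length(isoforms) == 2L, isoforms[1] >= 1L, isoforms[1] <= isoforms[2],
    length(n_cds) == 2L, n_cds[1] >= 1L, n_cds[1] <= n_cds[2],
    length(seqnames) >= 1L
  )
  structure(
    list(
      seed = as.integer(seed), n_loci = as.integer(n_loci),
      isoforms = as.integer(isoforms), n_cds = as.integer(n_cds),
      decoy_fraction = decoy_fraction,
      frameshift_fraction = frameshift_fraction,
      coverage = coverage, decoy_coverage = decoy_coverage,
      duplicates = isTRUE(duplicates), seqnames = seqnames
    ),
    class = "tx_fixture_spec"
  )
}

# one CDS chain: lengths multiples of 3, introns >= 60 nt
random_chain <- function(base, n_cds) {
  lens <- 3L * sample(40:100, n_cds, replace = TRUE)
  introns <- if (n_cds > 1L) sample(60:200, n_cds - 1L, replace = TRUE) else integer(0)
  starts <- integer(n_cds)
  ends <- integer(n_cds)
  pos <- base
  for (k in seq_len(n_cds)) {
    starts[k] <- pos
    ends[k] <- pos + lens[k] - 1L
    pos <- ends[k] + 1L + if (k < n_cds) introns[k] else 0L
  }
  data.frame(start = starts, end = ends)
}

# GTF frame column for a chain (strand-aware): number of nucleotides to
# skip at the start of the interval to reach the next codon boundary
chain_frames <- function(cds, strand) {
  len <- cds$end - cds$start + 1L
  before <- if (strand == "+") {
    c(0L, cumsum(len))[seq_along(len)]
  } else {
    rev(cumsum(rev(len))) - len
  }
  as.character((3L - before %% 3L) %% 3L)
}

draw_hints <- function(features, profile) {
  rows <- list()
  for (src in names(profile)) {
    p <- profile[[src]]$p
    lambda <- profile[[src]]$mult
    for (f in features) {
      if (stats::runif(1) < p) {
        rows[[length(rows) + 1L]] <- data.frame(
          seqname = f$seqname, start = f$start, end = f$end,
          type = f$type, strand = f$strand, src = src,
          mult = 1L + stats::rpois(1, lambda)
        )
      }
    }
  }
  rows
}

feature_tuples <- function(tx) {
  feats <- derive_features(tx)
  out <- list()
  if (nrow(feats$introns)) {
    for (k in seq_len(nrow(feats$introns))) {
      out[[length(out) + 1L]] <- list(
        seqname = tx$seqname, start = feats$introns$start[k],
        end = feats$introns$end[k], type = "intron", strand = tx$strand
      )
    }
  }
  out[[length(out) + 1L]] <- list(
    seqname = tx$seqname, start = feats$start_codon[1],
    end = feats$start_codon[2], type = "start", strand = tx$strand
  )
  out[[length(out) + 1L]] <- list(
    seqname = tx$seqname, start = feats$stop_codon[1],
    end = feats$stop_codon[2], type = "stop", strand = tx$strand
  )
  out
}

#' Generate a synthetic two-prediction fixture with evidence and truth
#'
#' Builds, entirely in memory and deterministically from the spec's seed:
#' two prediction transcript sets (file 1 holds all true isoforms, file 2
#' holds planted duplicates; decoys are split between the files), a hint
#' set drawn from the coverage profiles, and a truth table. Each
#' transcript's `expected_kept` flag is computed by the brute-force
#' [oracle_select()] reference — never by [run_selection()] — so fixtures
#' can arbitrate between the two.
#'
#' @param spec A [fixture_spec()].
#' @param hp Hyperparameters under which the truth is computed.
#' @return A `tx_fixture` list with elements `predictions` (list of two
#'   `tx_set`s), `transcripts` (their union), `hints`, `truth` (data frame
#'   with `id`, `file`, `original_id`, `role`, `locus`, `expected_kept`),
#'   `spec` and `hp`.
#' @export
generate_fixture <- function(spec, hp = default_hyperparameters()) {
  stopifnot(inherits(spec, "tx_fixture_spec"))
  set.seed(spec$seed)
  file1 <- list()
  file2 <- list()
  hint_rows <- list()
  truth <- list()
  locus_count <- stats::setNames(
    integer(length(spec$seqnames)), spec$seqnames
  )
  add_truth <- function(tx, file, role, locus) {
    truth[[length(truth) + 1L]] <<- data.frame(
      id = tx$id, file = file, original_id = tx$original_id,
      role = role, locus = locus, expected_kept = NA
    )
  }
  for (l in seq_len(spec$n_loci)) {
    seqname <- spec$seqnames[(l - 1L) %% length(spec$seqnames) + 1L]
    locus_count[seqname] <- locus_count[seqname] + 1L
    base <- 1000L + (locus_count[seqname] - 1L) * 20000L
    strand <- sample(c("+", "-"), 1)
    n_iso <- sample(spec$isoforms[1]:spec$isoforms[2], 1)
    gene <- sprintf("gl%d", l)
    isoforms <- list()
    chains_seen <- character(0)
    for (k in seq_len(n_iso)) {
      chain <- if (k == 1L) {
        random_chain(base, sample(spec$n_cds[1]:spec$n_cds[2], 1))
      } else {
        first <- isoforms[[1]]$cds[1, c("start", "end")]
        if (nrow(isoforms[[1]]$cds) == 1L) {
          # single-CDS gene: isoform extends the CDS by whole codons
          data.frame(
            start = first$start,
            end = first$end + 3L * sample(2:10, 1)
          )
        } else {
          # share the first CDS, regenerate the downstream structure
          n_more <- sample(1:max(1L, spec$n_cds[2] - 1L), 1)
          cont <- random_chain(
            first$end + 1L + sample(60:200, 1),
            n_more
          )
          rbind(first, cont)
        }
      }
      key <- paste(chain$start, chain$end, collapse = ",")
      if (key %in% chains_seen) {
        chain$end[nrow(chain)] <- chain$end[nrow(chain)] + 3L
        key <- paste(chain$start, chain$end, collapse = ",")
      }
      chains_seen <- c(chains_seen, key)
      oid <- sprintf("t%d.%d", l, k)
      tx <- new_transcript(
        id = paste0("1.", oid), original_id = oid, gene_id = gene,
        seqname = seqname, strand = strand,
        cds = cbind(chain, frame = chain_frames(chain, strand)),
        file_index = 1L
      )
      isoforms[[k]] <- tx
      file1[[length(file1) + 1L]] <- tx
      add_truth(tx, 1L, "true", l)
      if (spec$duplicates && stats::runif(1) < 0.5) {
        dup <- new_transcript(
          id = paste0("2.", oid), original_id = oid,
          gene_id = gene, seqname = seqname, strand = strand,
          cds = tx$cds, file_index = 2L
        )
        file2[[length(file2) + 1L]] <- dup
        add_truth(dup, 2L, paste0("duplicate-of:", tx$id), l)
      }
      hint_rows <- c(hint_rows, draw_hints(feature_tuples(tx), spec$coverage))
    }
    if (stats::runif(1) < spec$decoy_fraction) {
      shift <- 3L * sample(1:8, 1)
      if (stats::runif(1) < spec$frameshift_fraction) shift <- shift + 1L
      chain <- isoforms[[1]]$cds[c("start", "end")] + shift
      oid <- sprintf("d%d", l)
      to_file2 <- stats::runif(1) < 0.5
      decoy <- new_transcript(
        id = paste0(if (to_file2) "2." else "1.", oid), original_id = oid,
        gene_id = paste0(gene, "d"), seqname = seqname, strand = strand,
        cds = cbind(chain, frame = chain_frames(chain, strand)),
        file_index = if (to_file2) 2L else 1L
      )
      if (to_file2) {
        file2[[length(file2) + 1L]] <- decoy
      } else {
        file1[[length(file1) + 1L]] <- decoy
      }
      add_truth(decoy, if (to_file2) 2L else 1L, "decoy", l)
      hint_rows <- c(
        hint_rows,
        draw_hints(feature_tuples(decoy), spec$decoy_coverage)
      )
    }
  }
  hints <- new_hint_set(if (length(hint_rows)) {
    do.call(rbind, hint_rows)
  } else {
    data.frame(
      seqname = character(0), start = integer(0), end = integer(0),
      type = character(0), strand = character(0), src = character(0),
      mult = integer(0)
    )
  })
  all_tx <- as_tx_set(c(file1, file2))
  truth <- if (length(truth)) {
    do.call(rbind, truth)
  } else {
    data.frame(
      id = character(0), file = integer(0), original_id = character(0),
      role = character(0), locus = integer(0), expected_kept = logical(0)
    )
  }
  kept <- names(oracle_select(all_tx, hints, hp))
  truth$expected_kept <- truth$id %in% kept
  structure(
    list(
      predictions = list(as_tx_set(file1), as_tx_set(file2)),
      transcripts = all_tx,
      hints = hints,
      truth = truth,
      spec = spec,
      hp = hp
    ),
    class = "tx_fixture"
  )
}

#' Write a fixture to disk as GTF/GFF/TSV files
#'
#' @param fx A `tx_fixture`.
#' @param dir Output directory (created if needed).
#' @return Named list of the written paths (`pred1`, `pred2`, `hints`,
#'   `truth`).
#' @export
write_fixture <- function(fx, dir) {
  stopifnot(inherits(fx, "tx_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    pred1 = file.path(dir, "pred1.gtf"),
    pred2 = file.path(dir, "pred2.gtf"),
    hints = file.path(dir, "hints.gff"),
    truth = file.path(dir, "truth.tsv")
  )
  write_gtf(fx$predictions[[1]], paths$pred1)
  write_gtf(fx$predictions[[2]], paths$pred2)
  write_hints(fx$hints, paths$hints)
  utils::write.table(fx$truth,
    file = paths$truth, sep = "\t",
    quote = FALSE, row.names = FALSE
  )
  paths
}

#' Reference GTF of a fixture's true transcripts
#'
#' Writes the planted true isoforms (grouped by locus gene identifiers) as
#' a reference annotation for accuracy evaluation.
#'
#' @param fx A `tx_fixture`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fixture_reference <- function(fx, path) {
  true_ids <- fx$truth$id[fx$truth$role == "true"]
  write_gtf(fx$transcripts[names(fx$transcripts) %in% true_ids], path)
}
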