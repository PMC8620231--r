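check_weights <- function(src, weights) {
  missing <- setdiff(unique(src), names(weights))
  if (length(missing)) {
    stop(
      "no weight configured for evidence source(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
}

#' Relative evidence support of a feature set
#'
#' The fraction of features (introns, or start/stop codons) that are matched
#' by at least one hint from any source:
#' `r_f = |F_f intersect E| / |F_f|`. A feature counts at most once however
#' many sources support it. An empty feature set (a single-CDS transcript
#' has no introns) returns 1.0, so intron-less transcripts are not
#' automatically treated as unsupported.
#'
#' @param feature_keys Character vector of feature match keys
#'   (see [derive_features()]).
#' @param hints A `hint_set`.
#' @return A number in `[0, 1]`.
#' @export
relative_support <- function(feature_keys, hints) {
  if (length(feature_keys) == 0L) {
    return(1.0)
  }
  mean(feature_keys %in% hints$key)
}

#' Absolute (weighted) evidence support of a feature set
#'
#' The weighted sum over all hints matching any feature in the set:
#' `a_f = sum over h in E intersect F_f of w_src(h) * mult(h)`. Every source
#' contributes, scaled by its configured weight and the hint's multiplicity.
#'
#' @param feature_keys Character vector of feature match keys.
#' @param hints A `hint_set`.
#' @param weights Named numeric vector of per-source weights; every source
#'   of a matching hint must have a weight, otherwise an error is raised.
#' @return A non-negative number.
#' @export
absolute_support <- function(feature_keys, hints, weights) {
  hit <- hints$key %in% feature_keys
  if (!any(hit)) {
    return(0)
  }
  src <- hints$src[hit]
  check_weights(src, weights)
  sum(weights[src] * hints$mult[hit])
}

#' Compute the four-component support score vector of a transcript
#'
#' The score vector summarises how well extrinsic evidence supports a
#' transcript's structure:
#' * `s1` — fraction of its introns with at least one matching hint;
#' * `s2` — fraction of its start/stop codons with a matching hint;
#' * `s3` — weighted sum of all hints matching its introns;
#' * `s4` — weighted sum of all hints matching its start/stop codons.
#'
#' `s1`, `s2` lie in `[0, 1]`; `s3`, `s4` are non-negative and scale
#' linearly with hint multiplicities and source weights.
#'
#' @param tx A `tx_transcript`.
#' @param hints A `hint_set`.
#' @param hp A `tx_hyperparameters` object (only the weights are used).
#' @return A named numeric vector `c(s1, s2, s3, s4)` of class
#'   `tx_score_vector`.
#' @export
score_vector <- function(tx, hints, hp = default_hyperparameters()) {
  feats <- derive_features(tx)
  structure(
    c(
      s1 = relative_support(feats$keys_intron, hints),
      s2 = relative_support(feats$keys_stasto, hints),
      s3 = absolute_support(feats$keys_intron, hints, hp$weights),
      s4 = absolute_support(feats$keys_stasto, hints, hp$weights)
    ),
    class = "tx_score_vector"
  )
}

# Score every transcript at once; returns an n x 4 matrix with transcript
# ids as rownames. Hint keys and per-key weighted sums are built once.
score_transcripts <- function(transcripts, hints, hp = default_hyperparameters()) {
  n <- length(transcripts)
  out <- matrix(0, nrow = n, ncol = 4,
    dimnames = list(vapply(transcripts, `[[`, "", "id"), c("s1", "s2", "s3", "s4"))
  )
  if (n == 0L) {
    return(out)
  }
  check_weights(hints$src, hp$weights)
  wsum <- rowsum(hp$weights[hints$src] * hints$mult, hints$key)
  wsum <- stats::setNames(as.numeric(wsum), rownames(wsum))
  for (i in seq_len(n)) {
    feats <- derive_features(transcripts[[i]])
    ki <- feats$keys_intron
    ks <- feats$keys_stasto
    hi <- wsum[ki]
    hs <- wsum[ks]
    out[i, ] <- c(
      if (length(ki) == 0L) 1.0 else mean(!is.na(hi)),
      mean(!is.na(hs)),
      sum(hi, na.rm = TRUE),
      sum(hs, na.rm = TRUE)
    )
  }
  out
}
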