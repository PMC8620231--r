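#' Default hyperparameters
#'
#' The standard parameter set for combining an RNA-seq-supported and a
#' protein-supported gene prediction. It contains three groups:
#'
#' * **source weights** `w_o`, one per evidence source label: protein
#'   database (`P`), EST database (`E`), combined EST/protein database (`C`)
#'   and manually anchored evidence (`M`);
#' * **score thresholds** `e_1..e_4`, one per transcript score, used by the
#'   pairwise comparison rule ([compare_pair()]);
#' * **low-support thresholds**: the minimum fraction of supported introns
#'   (`intron_support`) and of supported start/stop codons
#'   (`stasto_support`) below which a transcript counts as having low
#'   evidence support ([low_support()]).
#'
#' @return An object of class `tx_hyperparameters`: a list with elements
#'   `weights` (named numeric), `epsilon` (numeric of length 4),
#'   `intron_support` and `stasto_support` (scalars).
#' @export
#' @examples
#' hp <- default_hyperparameters()
#' hp$weights
default_hyperparameters <- function() {
  new_hyperparameters(
    weights = c(P = 0.1, E = 10, C = 5, M = 1),
    epsilon = c(0, 0.5, 25, 10),
    intron_support = 0.75,
    stasto_support = 1.0
  )
}

new_hyperparameters <- function(weights, epsilon, intron_support, stasto_support) {
  stopifnot(
    is.numeric(weights), !is.null(names(weights)), all(weights >= 0),
    length(epsilon) == 4, all(epsilon >= 0),
    epsilon[1] <= 1, epsilon[2] <= 1,
    intron_support >= 0, intron_support <= 1,
    stasto_support >= 0, stasto_support <= 1
  )
  structure(
    list(
      weights = weights,
      epsilon = as.numeric(epsilon),
      intron_support = as.numeric(intron_support),
      stasto_support = as.numeric(stasto_support)
    ),
    class = "tx_hyperparameters"
  )
}

#' Read hyperparameters from a configuration file
#'
#' The configuration file is flat text with one `name value` pair per line
#' (whitespace separated; blank lines and lines starting with `#` are
#' ignored). Recognised names are `w_<SRC>` for a source weight (e.g. `w_P`,
#' `w_E`, or a weight for any new source label), `e_1` .. `e_4` for the four
#' score thresholds, and `intron_support` / `stasto_support` for the two
#' low-support thresholds. Any name absent from the file keeps its default
#' value, so an empty file (or `path = NULL`) yields
#' [default_hyperparameters()].
#'
#' @param path Path to the configuration file, or `NULL` for pure defaults.
#' @return A `tx_hyperparameters` object.
#' @export
read_config <- function(path = NULL) {
  hp <- default_hyperparameters()
  if (is.null(path)) {
    return(hp)
  }
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  weights <- hp$weights
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "" || startsWith(line, "#")) next
    tok <- strsplit(line, "[[:space:]]+")[[1]]
    if (length(tok) != 2) {
      stop(sprintf("%s:%d: expected 'name value', got '%s'", path, i, line),
        call. = FALSE
      )
    }
    name <- tok[1]
    value <- suppressWarnings(as.numeric(tok[2]))
    if (is.na(value)) {
      stop(sprintf("%s:%d: non-numeric value for '%s': '%s'", path, i, name, tok[2]),
        call. = FALSE
      )
    }
    if (grepl("^w_[A-Za-z0-9]+$", name)) {
      weights[sub("^w_", "", name)] <- value
    } else if (grepl("^e_[1-4]$", name)) {
      hp$epsilon[as.integer(sub("^e_", "", name))] <- value
    } else if (name == "intron_support") {
      hp$intron_support <- value
    } else if (name == "stasto_support") {
      hp$stasto_support <- value
    } else {
      stop(sprintf("%s:%d: unknown hyperparameter name '%s'", path, i, name),
        call. = FALSE
      )
    }
  }
  new_hyperparameters(weights, hp$epsilon, hp$intron_support, hp$stasto_support)
}

#' @export
print.tx_hyperparameters <- function(x, ...) {
  cat("Hyperparameters\n")
  cat("  weights:       ", paste(sprintf("w_%s=%g", names(x$weights), x$weights),
    collapse = " "
  ), "\n")
  cat("  thresholds:    ", paste(sprintf("e_%d=%g", 1:4, x$epsilon), collapse = " "), "\n")
  cat(sprintf(
    "  low support:    intron < %g and start/stop < %g\n",
    x$intron_support, x$stasto_support
  ))
  invisible(x)
}
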