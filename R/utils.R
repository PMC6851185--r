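## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporarily seeded RNG
#'
#' Saves and restores `.Random.seed` so seeded simulators never disturb the
#' caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Reverse complement on plain character strings.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read / write plain FASTA as a named character vector
#' @param path file path.
#' @return `read_fasta()` returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' @rdname read_fasta
#' @param x named character vector of sequences.
#' @export
write_fasta <- function(x, path) {
  stopifnot(is.character(x), !is.null(names(x)))
  set <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

## 1-based substring of a single string.
substr1 <- function(x, start, end) substr(x, start, end)

is_scalar_int <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x)
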