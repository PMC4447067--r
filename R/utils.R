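#' @importFrom stats cor ppois p.adjust runif
#' @importFrom utils read.table write.table packageVersion modifyList
NULL

# Reverse complement of an ACGTN character string (uppercase).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Wrap a 1-based position onto a circular genome of length n.
wrap_pos <- function(pos, n) {
  ((pos - 1L) %% n) + 1L
}

# Extract a strand-oriented substring from a (possibly circular) sequence.
# `from`/`to` are 1-based inclusive on the forward strand; `to` may exceed
# nchar(seq) or `from` drop below 1 when circular = TRUE.
extract_seq <- function(seq, from, to, circular = FALSE) {
  n <- nchar(seq)
  if (!circular) {
    if (from < 1L || to > n) {
      stop("window [", from, ", ", to, "] outside linear sequence of length ", n)
    }
    return(substr(seq, from, to))
  }
  idx <- wrap_pos(seq.int(from, to), n)
  paste(strsplit(seq, "", fixed = TRUE)[[1]][idx], collapse = "")
}

# Validate a 1-based inclusive interval.
check_interval <- function(start, end, what = "interval") {
  if (any(start < 1L)) stop(what, ": start must be >= 1")
  if (any(end < start)) stop(what, ": end must be >= start")
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
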