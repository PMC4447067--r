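# Reading and writing the standard formats the pipeline touches.
#
# Coordinate convention: every interval inside the package is 1-based and
# inclusive on both ends (the convention the published binding-site tables
# use), so fixture coordinates are storable unchanged. BED files are 0-based
# half-open; the conversion is applied here, at the I/O boundary, and nowhere
# else.

#' Read a FASTA file into a named character vector
#'
#' Sequence identifiers are the first whitespace-delimited token of each
#' header line; sequences are uppercased and validated against the
#' \{A, C, G, T, N\} alphabet.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one uppercased sequence per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("parse error: empty FASTA file ", path)
  is_header <- startsWith(lines, ">")
  if (!is_header[1L]) {
    stop("parse error at line ", line_no[1L], ": expected FASTA header")
  }
  ids <- sub("^>\\s*", "", lines[is_header])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(ids == "")) {
    bad <- line_no[is_header][which(is.na(ids) | ids == "")[1L]]
    stop("parse error at line ", bad, ": malformed FASTA header")
  }
  body <- toupper(lines[!is_header])
  bad <- grepl("[^ACGTN]", body)
  if (any(bad)) {
    stop("parse error at line ", line_no[!is_header][which(bad)[1L]],
         ": illegal character in sequence (alphabet is A/C/G/T/N)")
  }
  rec <- cumsum(is_header)[!is_header]
  seqs <- vapply(split(body, factor(rec, levels = seq_along(ids))),
                 paste, character(1), collapse = "")
  names(seqs) <- ids
  seqs
}

#' Read a gene-level GFF3 annotation
#'
#' Imports the file with \pkg{rtracklayer} and returns a gene table in the
#' package's 1-based inclusive convention, sorted by (chrom, start). Features
#' without an \code{ID} attribute, or with \code{end < start}, are rejected.
#'
#' @param path Path to a GFF3 file.
#' @param feature_types GFF3 \code{type} values treated as gene-level
#'   features.
#' @return A \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}, \code{strand}, \code{gene_id}, \code{kind} and a list-column
#'   \code{tss} (integer TSS positions, possibly empty).
#' @export
read_annotation <- function(path,
                            feature_types = c("gene", "ncRNA", "tRNA",
                                              "pseudogene")) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("parse error in GFF3 ", path, ": ",
                             conditionMessage(e))
  )
  gr <- gr[as.character(gr$type) %in% feature_types]
  if (length(gr) == 0L) stop("no gene-level features in ", path)
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    stop("parse error: gene feature without an ID attribute in ", path)
  }
  tss <- rep(list(integer(0)), length(gr))
  if (!is.null(gr$tss)) {
    raw <- as.character(gr$tss)
    has <- !is.na(raw) & raw != ""
    tss[has] <- lapply(strsplit(raw[has], ","), function(x) as.integer(x))
  }
  ann <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    gene_id = as.character(ids),
    kind = as.character(gr$type),
    stringsAsFactors = FALSE
  )
  ann$kind[ann$kind == "gene"] <- "ORF"
  ann$tss <- tss
  if (any(ann$strand == "*")) stop("gene feature with no strand in ", path)
  ann[order(ann$chrom, ann$start), , drop = FALSE]
}

#' Read genomic intervals from BED or bedGraph
#'
#' BED's 0-based half-open coordinates are converted to the internal 1-based
#' inclusive convention (BED start \code{s}, end \code{e} becomes
#' \code{s + 1 .. e}). bedGraph values are attached as a \code{score} column.
#'
#' @param path Path to the file.
#' @param format \code{"bed"} or \code{"bedGraph"}.
#' @return \code{data.frame} with \code{chrom}, \code{start}, \code{end} and,
#'   for bedGraph (or BED5+), \code{score}.
#' @export
read_intervals <- function(path, format = c("bed", "bedGraph")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- tryCatch(
    read.table(path, header = FALSE, sep = "", comment.char = "#",
               stringsAsFactors = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e))
  )
  if (ncol(tab) < 3L) stop("parse error: fewer than 3 columns in ", path)
  s0 <- suppressWarnings(as.numeric(tab[[2L]]))
  e0 <- suppressWarnings(as.numeric(tab[[3L]]))
  if (anyNA(s0) || anyNA(e0)) stop("parse error: non-numeric coordinate in ", path)
  if (any(s0 < 0) || any(e0 < 0)) stop("parse error: negative coordinate in ", path)
  if (any(e0 <= s0)) {
    stop("parse error: empty (zero-width) interval at line ",
         which(e0 <= s0)[1L], " of ", path)
  }
  out <- data.frame(chrom = as.character(tab[[1L]]),
                    start = as.integer(s0) + 1L,
                    end = as.integer(e0),
                    stringsAsFactors = FALSE)
  score_col <- if (format == "bedGraph") 4L else if (ncol(tab) >= 5L) 5L else NA
  if (!is.na(score_col)) {
    if (ncol(tab) < score_col) stop("parse error: missing score column in ", path)
    sc <- suppressWarnings(as.numeric(tab[[score_col]]))
    if (anyNA(sc)) stop("parse error: non-numeric score in ", path)
    out$score <- sc
  }
  if (format == "bed" && ncol(tab) >= 6L) out$strand <- as.character(tab[[6L]])
  out
}

#' Write called peaks as BED6+
#'
#' Internal 1-based inclusive peak intervals are converted back to BED's
#' 0-based half-open convention. Columns 7 and 8 carry the peak p-value and
#' IP/Input enrichment; a `#`-prefixed header names the columns, so
#' \code{read_peaks(write_peaks(x))} is the identity on intervals and scores.
#'
#' @param peaks A peak \code{data.frame} as returned by [call_peaks()] (needs
#'   \code{chrom}, \code{start}, \code{end}, \code{p_value},
#'   \code{enrichment}; \code{summit} optional).
#' @param path Output path.
#' @return Invisibly, the path written.
#' @export
write_peaks <- function(peaks, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste("#chrom", "start", "end", "name", "score", "strand",
                   "p_value", "enrichment", "summit", sep = "\t"), con)
  if (nrow(peaks) > 0L) {
    check_interval(peaks$start, peaks$end, "peak")
    bed <- data.frame(
      chrom = peaks$chrom,
      start = peaks$start - 1L,
      end = peaks$end,
      name = sprintf("peak_%d", seq_len(nrow(peaks))),
      score = 0L,
      strand = ".",
      p_value = format(peaks$p_value, digits = 17),
      enrichment = format(peaks$enrichment, digits = 17),
      summit = if (is.null(peaks$summit)) NA_integer_ else peaks$summit,
      stringsAsFactors = FALSE
    )
    write.table(bed, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Read peaks written by [write_peaks()]
#'
#' @param path Path to a BED6+ peak file.
#' @return A peak \code{data.frame} in internal 1-based coordinates.
#' @export
read_peaks <- function(path) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), p_value = numeric(0),
                      enrichment = numeric(0), summit = integer(0))
  lines <- readLines(path)
  if (!any(!startsWith(lines, "#"))) return(empty)
  tab <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) return(empty)
  data.frame(chrom = as.character(tab[[1L]]),
             start = as.integer(tab[[2L]]) + 1L,
             end = as.integer(tab[[3L]]),
             p_value = as.numeric(tab[[7L]]),
             enrichment = as.numeric(tab[[8L]]),
             summit = suppressWarnings(as.integer(tab[[9L]])),
             stringsAsFactors = FALSE)
}

#' Write a per-base coverage track as bedGraph
#'
#' Runs of equal depth are merged; output is 0-based half-open as bedGraph
#' requires.
#'
#' @param track A coverage track from [coverage_from_fragments()].
#' @param path Output path.
#' @param chrom Sequence name to write.
#' @return Invisibly, the path.
#' @export
write_bedgraph <- function(track, path, chrom = "chr") {
  r <- rle(track$depth)
  ends <- cumsum(r$lengths)
  starts0 <- c(0L, ends[-length(ends)])
  keep <- r$values != 0
  write.table(data.frame(chrom, starts0[keep], ends[keep], r$values[keep]),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
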