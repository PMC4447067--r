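# -10 element alignment, consensus derivation and sigma-S determinant
# scoring.
#
# Promoter windows are 21-mers covering -20..+1 relative to the TSS, aligned
# so the first base of the -10 hexamer sits at position -12 (the hexamer
# occupies -12..-7). The consensus is reported over -17..-6 (12 letters, the
# region whose sigma-S form is TNTGCYAAACTT). The discriminator is the
# -6..-1 segment between the hexamer and the TSS; its A/T richness favours
# open-complex formation by the stress holoenzyme. The sigma-S specificity
# determinants scored are C at -13 and -12, C at -8, T at -6, and the
# discriminator A/T fraction.

# window index of a promoter position (-20..-1; +1 is index 21)
.wpos <- function(p) {
  stopifnot(all(p >= -20L & p <= -1L))
  p + 21L
}

#' Extract a -20..+1 promoter window from a genome
#'
#' On the minus strand the reverse complement is taken, so position +1 of
#' the returned window is always the template-directed TSS base.
#'
#' @param genome Named character vector (a genome from [read_fasta()] or
#'   [generate_genome()]); circularity is honoured via the
#'   \code{"circular"} attribute or the \code{circular} argument.
#' @param tss 1-based TSS position.
#' @param strand \code{"+"} or \code{"-"}.
#' @param chrom Sequence to use (default: first).
#' @param circular Override the genome's circular flag.
#' @return A 21-character string.
#' @export
extract_promoter_window <- function(genome, tss, strand, chrom = NULL,
                                    circular = NULL) {
  seqs <- genome
  seq1 <- if (is.null(chrom)) seqs[[1L]] else seqs[[chrom]]
  circ <- circular %||% isTRUE(attr(genome, "circular"))
  if (strand == "+") {
    extract_seq(seq1, tss - 20L, tss, circular = circ)
  } else {
    revcomp(extract_seq(seq1, tss, tss + 20L, circular = circ))
  }
}

# IUPAC degenerate letters for base pairs
.iupac2 <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

#' Build a position-frequency model and IUPAC consensus from promoter
#' windows
#'
#' Per position, the consensus letter is the single base when its frequency
#' reaches \code{single_letter_threshold}, else the two-base degenerate code
#' when the top two frequencies sum to \code{pair_threshold}, else N. The
#' reported consensus covers -17..-6 (12 letters).
#'
#' @param windows Character vector of 21-mers (all length 21).
#' @param single_letter_threshold Frequency above which one base wins.
#' @param pair_threshold Combined frequency above which a two-base code
#'   wins.
#' @return List of class \code{consensus_model}: \code{freq} (4 x 21 matrix,
#'   rows A/C/G/T, columns named -20..+1), \code{consensus} (12-letter
#'   IUPAC string over -17..-6), \code{consensus_full} (21 letters),
#'   thresholds, \code{n}.
#' @export
build_consensus <- function(windows, single_letter_threshold = 0.75,
                            pair_threshold = 0.85) {
  if (length(windows) < 2L) stop("need at least 2 promoter windows")
  if (any(nchar(windows) != 21L)) stop("mixed-length windows (need 21-mers)")
  mat <- do.call(rbind, strsplit(toupper(windows), "", fixed = TRUE))
  bases <- c("A", "C", "G", "T")
  freq <- apply(mat, 2L, function(col) {
    tab <- table(factor(col, levels = bases))
    as.numeric(tab) / sum(tab)
  })
  rownames(freq) <- bases
  colnames(freq) <- c(as.character(-20:-1), "+1")
  letter <- function(fr) {
    ord <- order(fr, decreasing = TRUE)
    if (fr[ord[1L]] >= single_letter_threshold) return(bases[ord[1L]])
    if (fr[ord[1L]] + fr[ord[2L]] >= pair_threshold) {
      pair <- paste(sort(bases[ord[1:2]]), collapse = "")
      return(.iupac2[[pair]])
    }
    "N"
  }
  cons_full <- paste(apply(freq, 2L, letter), collapse = "")
  cons <- substr(cons_full, .wpos(-17L), .wpos(-6L))
  structure(list(freq = freq, consensus = cons, consensus_full = cons_full,
                 single_letter_threshold = single_letter_threshold,
                 pair_threshold = pair_threshold, n = length(windows)),
            class = "consensus_model")
}

#' Score sigma-S promoter determinants of one window
#'
#' @param window A 21-mer (-20..+1).
#' @param weights Weights of the four determinant booleans and the
#'   discriminator A/T fraction in the composite score.
#' @return List of class \code{sigmaS_features}: \code{has_m13C},
#'   \code{has_m12C}, \code{has_m8C}, \code{has_m6T},
#'   \code{discriminator_at_fraction}, \code{composite_score},
#'   \code{undefined} (TRUE when a scored position is not A/C/G/T).
#' @export
score_sigmaS_features <- function(window,
                                  weights = c(m13C = 1, m12C = 1, m8C = 1,
                                              m6T = 1, disc = 2)) {
  if (nchar(window) != 21L) stop("window must be a 21-mer")
  b <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  scored <- b[c(.wpos(-13L), .wpos(-12L), .wpos(-8L), .wpos(-6L),
                .wpos(-6L):.wpos(-1L))]
  undefined <- any(!scored %in% c("A", "C", "G", "T"))
  disc <- b[.wpos(-6L):.wpos(-1L)]
  at <- mean(disc %in% c("A", "T"))
  f <- list(has_m13C = b[.wpos(-13L)] == "C",
            has_m12C = b[.wpos(-12L)] == "C",
            has_m8C = b[.wpos(-8L)] == "C",
            has_m6T = b[.wpos(-6L)] == "T",
            discriminator_at_fraction = at)
  f$composite_score <- weights[["m13C"]] * f$has_m13C +
    weights[["m12C"]] * f$has_m12C + weights[["m8C"]] * f$has_m8C +
    weights[["m6T"]] * f$has_m6T + weights[["disc"]] * at
  f$undefined <- undefined
  class(f) <- "sigmaS_features"
  f
}

#' Similarity of a -35 hexamer to the sigma-70 consensus TTGACA
#'
#' Optional feature: fraction of matching positions (the main-text analysis
#' only remarks on -35 conservation; sequences live in supplementary data).
#'
#' @param hexamer A 6-character string.
#' @return Match fraction in [0, 1].
#' @export
minus35_sigma70_match <- function(hexamer) {
  if (nchar(hexamer) != 6L) stop("need a 6-mer")
  mean(strsplit(toupper(hexamer), "")[[1]] == strsplit("TTGACA", "")[[1]])
}

#' Midpoint threshold between two classes of composite scores
#'
#' @param scores_sigmaS,scores_sigma70 Composite scores of calibration
#'   promoters of each class.
#' @return Midpoint of the two class means.
#' @export
calibrate_promoter_threshold <- function(scores_sigmaS, scores_sigma70) {
  (mean(scores_sigmaS) + mean(scores_sigma70)) / 2
}

#' Classify a promoter window as sigma-S-type or sigma-70-type
#'
#' @param features A [score_sigmaS_features()] result (or a bare composite
#'   score).
#' @param threshold Decision threshold on the composite score. The default
#'   is the midpoint of the two class means on the package's synthetic
#'   calibration classes (~5.8 vs ~1.25).
#' @return \code{"predicted_sigmaS"} or \code{"predicted_sigma70"}.
#' @export
classify_promoter <- function(features, threshold = 3.5) {
  score <- if (is.numeric(features)) features else features$composite_score
  if (score >= threshold) "predicted_sigmaS" else "predicted_sigma70"
}

#' Export a consensus model as plain-text tables
#'
#' Writes the position-frequency matrix (positions as rows, consumable by
#' logo renderers) and the consensus line.
#'
#' @param model A [build_consensus()] result.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_consensus <- function(model, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("# consensus(-17..-6)\t", model$consensus), con)
  tab <- data.frame(position = colnames(model$freq), t(model$freq),
                    check.names = FALSE)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
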