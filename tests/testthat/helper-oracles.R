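# Independent oracles used across tests. These deliberately avoid the code
# paths (and the distribution functions) they are checked against.

# Upper-tail Poisson probability P(X >= k) by explicit term-by-term pmf
# summation with the multiplicative recurrence t_{i+1} = t_i * lambda/(i+1),
# summed until terms fall below machine noise.
poisson_upper_tail_oracle <- function(k, lambda) {
  if (k <= 0) return(1)
  term <- exp(k * log(lambda) - lambda - lgamma(k + 1))
  total <- term
  i <- k
  while (term > total * 1e-18 && i < k + 10000) {
    i <- i + 1
    term <- term * lambda / i
    total <- total + term
  }
  total
}

# IUPAC consensus letter applied directly to a frequency vector (A,C,G,T),
# mirroring the published-style rule independently of build_consensus().
iupac_letter_oracle <- function(fr, single = 0.75, pair = 0.85) {
  bases <- c("A", "C", "G", "T")
  codes <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
  ord <- order(fr, decreasing = TRUE)
  if (fr[ord[1]] >= single) return(bases[ord[1]])
  if (fr[ord[1]] + fr[ord[2]] >= pair) {
    return(codes[[paste(sort(bases[ord[1:2]]), collapse = "")]])
  }
  "N"
}

# Minimal single-chromosome annotation builder for constructed layouts.
make_ann <- function(start, end, strand, gene_id = NULL, tss = NULL,
                     chrom = "sim") {
  n <- length(start)
  ann <- data.frame(chrom = chrom, start = as.integer(start),
                    end = as.integer(end), strand = strand,
                    gene_id = gene_id %||% sprintf("g%02d", seq_len(n)),
                    kind = "ORF", stringsAsFactors = FALSE)
  ann$tss <- tss %||% rep(list(integer(0)), n)
  ann
}

`%||%` <- function(a, b) if (is.null(a)) b else a
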