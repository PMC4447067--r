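# Synthetic ChIP-seq experiment generator.
#
# Emulates the statistical structure the analysis assumes: a circular
# bacterial genome with non-overlapping genes on both strands, planted
# polymerase binding sites centred on promoters (rifampicin stalls the
# holoenzyme at the transcription start site, so enrichment is centred
# there), sonication fragments of 100-400 bp, a uniform Input library and an
# IP library drawn from a mixture in which each planted site contributes
# fragments overlapping its centre, calibrated so the expected IP coverage
# at the centre equals enrichment_fold times the local background.

#' Simulation parameters
#'
#' @param genome_length Genome size in bp.
#' @param n_genes Number of genes to place.
#' @param n_sites Number of planted binding sites.
#' @param enrichment_fold Expected IP-over-background coverage fold at a
#'   planted site centre; the published locus control measured ~10-fold.
#' @param fragment_size_range Sonication fragment length range in bp; the
#'   published protocol sheared chromatin to 100-400 bp.
#' @param depth Fragments per library.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param promoter_class_mix Fraction of planted sites given sigma-S-type
#'   promoters (the rest get sigma-70-type promoters).
#' @param divergent_fraction Fraction of planted sites placed between
#'   divergent gene starts (ambiguous layout) instead of upstream of a
#'   single gene (unequivocal layout).
#' @param tss_offset Distance from the gene start to its TSS (bp upstream).
#' @param gene_length Length of each placed gene (bp).
#' @return A list of class \code{sim_params}.
#' @export
sim_params <- function(genome_length = 200000L, n_genes = 40L, n_sites = 10L,
                       enrichment_fold = 10, fragment_size_range = c(100L, 400L),
                       depth = 50000L, seed = 1L, promoter_class_mix = 1,
                       divergent_fraction = 0, tss_offset = 60L,
                       gene_length = 600L) {
  stopifnot(fragment_size_range[1L] >= 50L,
            fragment_size_range[2L] > fragment_size_range[1L],
            enrichment_fold >= 1,
            promoter_class_mix >= 0, promoter_class_mix <= 1)
  if (n_genes * 800L > genome_length) {
    stop("n_genes * 800 bp exceeds genome_length; no room for genes")
  }
  structure(list(genome_length = as.integer(genome_length),
                 n_genes = as.integer(n_genes), n_sites = as.integer(n_sites),
                 enrichment_fold = enrichment_fold,
                 fragment_size_range = as.integer(fragment_size_range),
                 depth = as.integer(depth), seed = as.integer(seed),
                 promoter_class_mix = promoter_class_mix,
                 divergent_fraction = divergent_fraction,
                 tss_offset = as.integer(tss_offset),
                 gene_length = as.integer(gene_length)),
            class = "sim_params")
}

# One promoter window (21-mer, -20..+1, position 21 = TSS base).
# sigma-S class: C at -13/-12, C at -8, T at -6, discriminator (-6..-1)
# A/T fraction >= 0.67. sigma-70 class: T at -12, discriminator A/T
# fraction <= 0.5. Window indices: position p maps to index p + 21.
simulate_promoter_window <- function(class = c("sigmaS", "sigma70")) {
  class <- match.arg(class)
  w <- sample(c("A", "C", "G", "T"), 21L, replace = TRUE)
  if (class == "sigmaS") {
    w[8L] <- "C"            # -13
    w[9L] <- "C"            # -12
    w[13L] <- "C"           # -8
    w[15L] <- "T"           # -6
    n_at <- sample(5:6, 1L) # discriminator A/T count (fraction >= 0.83)
    disc <- c(sample(c("A", "T"), n_at, replace = TRUE),
              sample(c("G", "C"), 6L - n_at, replace = TRUE))
    w[15:20] <- sample(disc)
    w[15L] <- "T"           # keep the -6 determinant after shuffling
  } else {
    w[9L] <- "T"            # canonical sigma-70 -12T
    n_at <- sample(0:3, 1L) # discriminator A/T count (fraction <= 0.5)
    disc <- c(sample(c("A", "T"), n_at, replace = TRUE),
              sample(c("G", "C"), 6L - n_at, replace = TRUE))
    w[15:20] <- sample(disc)
  }
  paste(w, collapse = "")
}

#' Generate a batch of promoter windows of one class
#'
#' @param n Number of windows.
#' @param class \code{"sigmaS"} or \code{"sigma70"}.
#' @param seed Optional seed.
#' @return Character vector of 21-mers.
#' @export
simulate_promoters <- function(n, class = c("sigmaS", "sigma70"), seed = NULL) {
  class <- match.arg(class)
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) simulate_promoter_window(class), character(1))
}

#' Generate a toy annotated genome with planted binding sites
#'
#' Genes are laid out in equal slots across a circular genome, alternating
#' strand so that a slot pair can host a divergent layout. Each planted site
#' is centred on a designated TSS; the promoter 21-mer (-20..+1, class drawn
#' by \code{promoter_class_mix}) is written into the genome sequence in the
#' strand-oriented frame.
#'
#' @param params A [sim_params()] object.
#' @return A list with \code{sequence} (named character, one circular
#'   chromosome \code{"sim"}), \code{annotation} (gene table as from
#'   [read_annotation()]) and \code{sites} (a \code{data.frame} of planted
#'   sites: \code{position} = site centre, \code{tss}, \code{strand},
#'   \code{gene_id}, \code{layout}, \code{promoter_class},
#'   \code{promoter_sequence}, \code{enrichment_fold}).
#' @export
generate_genome <- function(params = sim_params()) {
  p <- params
  set.seed(p$seed)
  n <- p$genome_length
  seq_chars <- sample(c("A", "C", "G", "T"), n, replace = TRUE)

  slot <- n %/% p$n_genes
  margin <- 150L
  if (slot < p$gene_length + 2L * margin) stop("slots too small for genes")
  # genes sit near their slot centre with bounded jitter, so adjacent
  # planted sites stay well separated and their peaks cannot merge
  center_off <- (slot - p$gene_length) %/% 2L
  jitter_max <- min(1000L, center_off - margin)
  gene_start <- (seq_len(p$n_genes) - 1L) * slot + center_off +
    sample.int(2L * jitter_max + 1L, p$n_genes, replace = TRUE) -
    jitter_max - 1L
  gene_end <- gene_start + p$gene_length - 1L

  n_div <- round(p$n_sites * p$divergent_fraction)
  n_unq <- p$n_sites - n_div
  if (n_unq + 2L * n_div > p$n_genes) stop("not enough genes for the requested sites")

  # Divergent layouts use consecutive gene slot pairs (2i-1, 2i): first gene
  # on -, second on +, site centred between their starts. Unequivocal sites
  # use later slots, strand alternating.
  strand <- rep(c("+", "-"), length.out = p$n_genes)
  gidx_div <- if (n_div > 0L) seq_len(2L * n_div) else integer(0)
  if (n_div > 0L) strand[gidx_div] <- rep(c("-", "+"), n_div)
  gidx_unq <- if (n_unq > 0L) 2L * n_div + seq_len(n_unq) else integer(0)

  ann <- data.frame(chrom = "sim", start = gene_start, end = gene_end,
                    strand = strand, gene_id = sprintf("g%03d", seq_len(p$n_genes)),
                    kind = "ORF", stringsAsFactors = FALSE)
  ann$tss <- rep(list(integer(0)), p$n_genes)

  classes <- character(0)
  if (p$n_sites > 0L) {
    classes <- ifelse(runif(p$n_sites) < p$promoter_class_mix, "sigmaS", "sigma70")
  }
  sites <- NULL
  write_window <- function(tss, strand, class) {
    win <- simulate_promoter_window(class)
    bases <- strsplit(win, "", fixed = TRUE)[[1]]
    pos <- if (strand == "+") (tss - 20L):tss else tss:(tss + 20L)
    if (strand == "-") {
      bases <- strsplit(revcomp(win), "", fixed = TRUE)[[1]]
    }
    seq_chars[wrap_pos(pos, n)] <<- bases
    win
  }
  add_site <- function(position, tss, strand, gene_id, layout, class) {
    win <- write_window(tss, strand, class)
    rbind(sites, data.frame(position = as.integer(position),
                            tss = as.integer(tss), strand = strand,
                            gene_id = gene_id, layout = layout,
                            promoter_class = class, promoter_sequence = win,
                            enrichment_fold = p$enrichment_fold,
                            stringsAsFactors = FALSE))
  }
  k <- 0L
  for (i in seq_len(n_unq)) {
    k <- k + 1L
    g <- gidx_unq[i]
    if (ann$strand[g] == "+") {
      tss <- ann$start[g] - p$tss_offset
      ann$tss[[g]] <- tss
      sites <- add_site(tss - 10L, tss, "+", ann$gene_id[g], "unequivocal",
                        classes[k])
    } else {
      tss <- ann$end[g] + p$tss_offset
      ann$tss[[g]] <- tss
      sites <- add_site(tss + 10L, tss, "-", ann$gene_id[g], "unequivocal",
                        classes[k])
    }
  }
  for (i in seq_len(n_div)) {
    k <- k + 1L
    gm <- gidx_div[2L * i - 1L]  # minus-strand gene (left flank)
    gp <- gidx_div[2L * i]       # plus-strand gene (right flank)
    mid <- (ann$end[gm] + ann$start[gp]) %/% 2L
    tss_m <- mid - 30L
    tss_p <- mid + 30L
    ann$tss[[gm]] <- tss_m
    ann$tss[[gp]] <- tss_p
    write_window(tss_m, "-", classes[k])  # left-flank promoter, same class
    sites <- add_site(mid, tss_p, "+",
                      paste(ann$gene_id[gm], ann$gene_id[gp], sep = "|"),
                      "divergent", classes[k])
  }
  if (is.null(sites)) {
    sites <- data.frame(position = integer(0), tss = integer(0),
                        strand = character(0), gene_id = character(0),
                        layout = character(0), promoter_class = character(0),
                        promoter_sequence = character(0),
                        enrichment_fold = numeric(0), stringsAsFactors = FALSE)
  }
  genome <- paste(seq_chars, collapse = "")
  names(genome) <- "sim"
  attr(genome, "circular") <- TRUE
  list(sequence = genome, annotation = ann, sites = sites, params = p)
}

#' Simulate paired IP and Input fragment libraries
#'
#' Input fragments start uniformly on the circular genome with lengths
#' uniform on the sonication range. IP fragments are a mixture: a fragment
#' is site-derived with a per-site probability solved so that the expected
#' IP coverage at the site centre equals \code{enrichment_fold} times the
#' local background coverage; site-derived fragments always overlap the site
#' centre. Each fragment carries a sequencing strand (which end was read),
#' creating the shifted strand profiles cross-correlation detects.
#'
#' @param genome Genome list from [generate_genome()] (or any list with a
#'   single sequence); only its length is used.
#' @param sites \code{data.frame} of planted sites (needs \code{position}
#'   and \code{enrichment_fold}); may have zero rows.
#' @param params A [sim_params()] object.
#' @param seed Optional seed overriding \code{params$seed} (use to draw
#'   independent replicates from one genome).
#' @return List with \code{ip} and \code{input} fragment
#'   \code{data.frame}s (\code{start}, \code{width}, \code{strand};
#'   \code{end = start + width - 1} may wrap past the origin).
#' @export
simulate_libraries <- function(genome, sites, params, seed = NULL) {
  p <- params
  if (p$depth <= 0L) stop("depth must be positive")
  set.seed(seed %||% (p$seed + 104729L))
  n <- p$genome_length
  lens <- p$fragment_size_range
  mean_len <- mean(lens[1L]:lens[2L])

  draw_background <- function(m) {
    data.frame(start = sample.int(n, m, replace = TRUE),
               width = sample.int(lens[2L] - lens[1L] + 1L, m, replace = TRUE) +
                 lens[1L] - 1L,
               stringsAsFactors = FALSE)
  }
  input <- draw_background(p$depth)
  input$strand <- sample(c("+", "-"), p$depth, replace = TRUE)

  k <- nrow(sites)
  if (k == 0L || all(sites$enrichment_fold <= 1)) {
    ip <- draw_background(p$depth)
    ip$strand <- sample(c("+", "-"), p$depth, replace = TRUE)
    return(list(ip = ip, input = input))
  }
  # Per-site expected fragment count n_s solving
  #   n_s = (fold_s - 1) * mean_len / n * n_background
  # with n_background = depth - sum(n_s); for equal folds this reduces to
  # n_s = (fold-1) * mean_len * depth / (n + k (fold-1) mean_len).
  a <- (sites$enrichment_fold - 1) * mean_len / n
  n_s <- a * p$depth / (1 + sum(a))
  prob_site <- n_s / p$depth
  comp <- sample.int(k + 1L, p$depth, replace = TRUE,
                     prob = c(1 - sum(prob_site), prob_site))
  m_bg <- sum(comp == 1L)
  ip <- draw_background(p$depth)
  is_site <- comp > 1L
  if (any(is_site)) {
    centers <- sites$position[comp[is_site] - 1L]
    w <- ip$width[is_site]
    # start uniform in [center - width + 1, center]: fragment covers center
    u <- floor(runif(length(w)) * w) + 1L
    ip$start[is_site] <- wrap_pos(centers - w + u, n)
  }
  ip$strand <- sample(c("+", "-"), p$depth, replace = TRUE)
  list(ip = ip, input = input)
}

#' Per-base coverage track from a fragment set
#'
#' Each fragment adds 1 to every base it covers (wrapping past the origin on
#' a circular genome), so total mass equals the sum of fragment widths. The
#' track also records per-base fragment-midpoint counts (\code{events}),
#' which the window tests use as Poisson counts, and the library size.
#'
#' @param fragments Fragment \code{data.frame} (\code{start}, \code{width},
#'   optional \code{strand}).
#' @param genome_length Genome length in bp.
#' @param circular Wrap fragments past the origin (default TRUE, the
#'   synthetic genomes are circular).
#' @return A list of class \code{coverage_track}: \code{depth} (numeric,
#'   length \code{genome_length}), \code{events} (midpoint counts),
#'   \code{n_fragments}, \code{mean_width}, \code{genome_length}.
#' @export
coverage_from_fragments <- function(fragments, genome_length,
                                    circular = TRUE) {
  n <- as.integer(genome_length)
  start <- as.integer(fragments$start)
  width <- as.integer(fragments$width %||% (fragments$end - fragments$start + 1L))
  if (any(width < 1L)) stop("fragment with non-positive width")
  if (any(start < 1L) || (!circular && any(start + width - 1L > n))) {
    stop("fragment outside genome")
  }
  end <- start + width - 1L
  over <- end > n
  if (any(over) && !circular) stop("fragment outside linear genome")
  ir <- IRanges::IRanges(start = c(start, rep(1L, sum(over))),
                         end = c(pmin(end, n), end[over] - n))
  cov <- as.numeric(IRanges::coverage(ir, width = n))
  mid <- wrap_pos(start + (width - 1L) %/% 2L, n)
  events <- tabulate(mid, nbins = n)
  structure(list(depth = cov, events = events,
                 n_fragments = length(start),
                 mean_width = mean(width), genome_length = n),
            class = "coverage_track")
}

#' Export a simulated experiment to standard files
#'
#' Writes the genome FASTA, a GFF3 gene annotation, fragment BED files, a
#' bedGraph coverage pair and a \code{truth.tsv} of planted sites for
#' recovery scoring.
#'
#' @param genome List from [generate_genome()].
#' @param libs List from [simulate_libraries()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of paths written.
#' @export
export_simulation <- function(genome, libs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "genome.fasta"),
             gff = file.path(dir, "genes.gff3"),
             ip = file.path(dir, "fragments_ip.bed"),
             input = file.path(dir, "fragments_input.bed"),
             truth = file.path(dir, "truth.tsv"))
  seqname <- names(genome$sequence)
  writeLines(c(paste0(">", seqname),
               substring(genome$sequence,
                         seq(1L, nchar(genome$sequence), 70L),
                         pmin(seq(1L, nchar(genome$sequence), 70L) + 69L,
                              nchar(genome$sequence)))),
             paths["fasta"])
  ann <- genome$annotation
  tss_attr <- vapply(ann$tss, function(x)
    if (length(x)) paste0(";tss=", paste(x, collapse = ",")) else "",
    character(1))
  gff <- c("##gff-version 3",
           paste(ann$chrom, "sigchip", "gene", ann$start, ann$end, ".",
                 ann$strand, ".",
                 paste0("ID=", ann$gene_id, tss_attr), sep = "\t"))
  writeLines(gff, paths["gff"])
  write_frag_bed <- function(fr, path) {
    end <- pmin(fr$start + fr$width - 1L, nchar(genome$sequence))
    write.table(data.frame(seqname, fr$start - 1L, end, ".", 0L, fr$strand),
                path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  write_frag_bed(libs$ip, paths["ip"])
  write_frag_bed(libs$input, paths["input"])
  truth <- genome$sites
  truth$promoter_sequence <- as.character(truth$promoter_sequence)
  write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
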