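# Genomic-context classification and the published accounting.

test_that("published example peaks classify as tabulated", {
  fx <- load_fixture()
  ann <- fixture_annotation(fx)

  osmB <- classify_peak(list(chrom = "U00096", start = 1341304L,
                             end = 1341480L), ann)
  expect_equal(osmB$context, "promoter_unequivocal")
  expect_equal(osmB$genes, "osmB")
  expect_true(osmB$tss_contained)

  div <- classify_peak(list(chrom = "U00096", start = 1820250L,
                            end = 1820349L), ann)
  expect_equal(div$context, "promoter_divergent")
  expect_setequal(div$genes, c("osmE", "nadE"))
  expect_true(all(div$tss_contained))

  # the two promoters internal to host ORFs
  int1 <- classify_peak(list(chrom = "U00096", start = 2468677L,
                             end = 2468882L), ann)
  expect_equal(int1$context, "promoter_internal")
  expect_equal(int1$genes, "tfaS")
  int2 <- classify_peak(list(chrom = "U00096", start = 2103850L,
                             end = 2104199L), ann)
  expect_equal(int2$context, "promoter_internal")
  expect_equal(int2$genes, "wbbI")
})

test_that("rule cascade handles intragenic, multi-ORF and oversized peaks", {
  ann <- make_ann(start = c(1000, 3000, 5000, 7000, 9000),
                  end = c(1600, 3600, 5600, 7600, 9600),
                  strand = c("+", "+", "+", "+", "+"))
  # peak in the middle of a gene, no start within reach
  mid <- classify_peak(list(chrom = "sim", start = 1200L, end = 1400L), ann)
  expect_equal(mid$context, "intragenic")
  expect_length(mid$genes, 0L)
  # a huge peak fully containing five ORFs is excluded
  big <- classify_peak(list(chrom = "sim", start = 900L, end = 9700L), ann)
  expect_equal(big$context, "excluded_multiORF")
  # an oversized peak with exactly one candidate is retained
  one <- classify_peak(list(chrom = "sim", start = 1700L, end = 2950L), ann)
  expect_equal(one$context, "promoter_unequivocal")
  expect_equal(one$genes, "g02")
  # oversized with two divergent candidates is excluded
  ann2 <- make_ann(start = c(500, 3100), end = c(900, 3700),
                   strand = c("-", "+"))
  big2 <- classify_peak(list(chrom = "sim", start = 950L, end = 3050L), ann2)
  expect_equal(big2$context, "excluded_multiORF")
})

test_that("TSS containment resolves pairs only against annotated absent TSSs", {
  mk <- function(tss_minus, tss_plus) {
    make_ann(start = c(400, 1900), end = c(900, 2400), strand = c("-", "+"),
             gene_id = c("gm", "gp"),
             tss = list(as.integer(tss_minus), as.integer(tss_plus)))
  }
  peak <- list(chrom = "sim", start = 1000L, end = 1500L)
  # both TSSs inside: divergent
  expect_equal(classify_peak(peak, mk(1100, 1400))$context,
               "promoter_divergent")
  # one inside, partner without TSS data: still divergent
  expect_equal(classify_peak(peak, mk(1100, integer(0)))$context,
               "promoter_divergent")
  # one inside, partner's annotated TSS outside the peak: resolved
  res <- classify_peak(peak, mk(1100, 1800))
  expect_equal(res$context, "promoter_unequivocal")
  expect_equal(res$genes, "gm")
  # the +/-1 bp boundary tolerance
  expect_equal(classify_peak(peak, mk(999, 1501))$context,
               "promoter_divergent")
})

test_that("same-strand conflicts use TSS, then distance, else stay ambiguous", {
  ann <- make_ann(start = c(1600, 1900), end = c(2200, 2500),
                  strand = c("+", "+"), gene_id = c("near", "far"),
                  tss = list(integer(0), 1450L))
  peak <- list(chrom = "sim", start = 1000L, end = 1500L)
  got <- classify_peak(peak, ann)
  expect_equal(got$genes, "far")  # TSS containment overrides distance
  ann$tss <- list(integer(0), integer(0))
  expect_equal(classify_peak(peak, ann)$genes, "near")  # nearer start wins
  tie <- make_ann(start = c(1600, 1600), end = c(2200, 2200),
                  strand = c("+", "+"), gene_id = c("a", "b"))
  expect_equal(classify_peak(peak, tie)$context, "ambiguous")
})

test_that("fixture reclassification reproduces all published categories and counts", {
  fx <- load_fixture()
  ann <- fixture_annotation(fx)
  peaks <- unique(fx[, c("peak_id", "peak_start", "peak_end")])
  annotated <- annotate_peaks(
    data.frame(chrom = "U00096", start = peaks$peak_start,
               end = peaks$peak_end), ann)
  got <- ifelse(annotated$context == "promoter_divergent", "divergent",
                "unequivocal")
  truth <- fx$category_truth[match(peaks$peak_id, fx$peak_id)]
  expect_equal(sum(got == truth), 63L)

  s <- summarize_annotations(annotated, total_called = 78L)
  expect_equal(s$n_promoter, 63L)
  expect_equal(s$n_unequivocal, 50L)
  expect_equal(s$n_divergent, 13L)
  expect_equal(s$n_intergenic, 61L)
  expect_equal(s$pct_nonpromoter, 19)

  ev <- join_prior_evidence(annotated, fixture_evidence_flags(fx))
  expect_equal(ev$n_unequivocal_flagged, 27L)
  expect_equal(ev$n_total_flagged, 36L)
  # contexts partition the peak set
  expect_true(all(annotated$context %in%
                    c("promoter_unequivocal", "promoter_internal",
                      "promoter_divergent")))
})

test_that("summary guards and degenerate inputs behave", {
  ann <- make_ann(1000, 1600, "+")
  one <- annotate_peaks(
    data.frame(chrom = "sim", start = 400L, end = 980L), ann)
  s <- summarize_annotations(one)
  expect_equal(s$n_promoter, 1L)
  expect_equal(s$pct_nonpromoter, 0)
  expect_error(summarize_annotations(one, total_called = 0L), "below")
  flags <- c(g01 = FALSE)
  expect_equal(join_prior_evidence(one, flags)$n_total_flagged, 0L)
  expect_error(join_prior_evidence(one, c(other = TRUE)), "no evidence flag")
  expect_error(classify_peak(list(chrom = "nope", start = 1L, end = 2L), ann),
               "unannotated")
})
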