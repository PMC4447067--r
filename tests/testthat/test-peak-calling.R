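# Poisson window test, peak caller, and the two QC computations.

test_that("window test matches direct pmf summation and handles edges", {
  expect_equal(window_poisson_test(0, 5), 1)
  expect_equal(window_poisson_test(0, 0), 1)
  p5 <- window_poisson_test(5, 2, size_factor = 1)
  expect_equal(p5, poisson_upper_tail_oracle(5, 2), tolerance = 1e-12)
  expect_lt(window_poisson_test(50, 2, 1), 1e-6)
  expect_error(window_poisson_test(5, 2, size_factor = 0), "size_factor")
  expect_error(window_poisson_test(-1, 2), "counts")
})

test_that("window test is monotone in both counts", {
  lam_floor <- 0.25
  for (input in c(1, 5, 20)) {
    p <- window_poisson_test(0:40, input, 1, lam_floor)
    expect_true(all(diff(p) <= 0))
  }
  for (ip in c(5, 15, 40)) {
    p <- window_poisson_test(ip, 1:30, 1, lam_floor)
    expect_true(all(diff(p) >= 0))
  }
})

test_that("identical tracks yield no peaks; planted sites yield one peak each", {
  p <- sim_params(genome_length = 100000L, n_genes = 20L, n_sites = 1L,
                  depth = 50000L, seed = 7L)
  g <- generate_genome(p)
  libs <- simulate_libraries(g, g$sites, p)
  ip <- coverage_from_fragments(libs$ip, p$genome_length)
  input <- coverage_from_fragments(libs$input, p$genome_length)

  expect_equal(nrow(call_peaks(ip, ip)), 0L)  # self-comparison: no enrichment

  pk <- call_peaks(ip, input)
  expect_equal(nrow(pk), 1L)
  expect_true(pk$start <= g$sites$position[1] &&
                pk$end >= g$sites$position[1])
  expect_lte(pk$p_value, 0.01)
  expect_gte(pk$end - pk$start + 1L, 50L)
  expect_true(pk$summit >= pk$start && pk$summit <= pk$end)
  expect_gt(pk$enrichment, 3)
})

test_that("two distant sites are never merged into one peak", {
  # 20 gene slots on 200 kb put consecutive planted sites ~10 kb apart
  p <- sim_params(genome_length = 200000L, n_genes = 20L, n_sites = 2L,
                  depth = 100000L, seed = 13L)
  g <- generate_genome(p)
  expect_gt(abs(diff(g$sites$position)), 5000)
  libs <- simulate_libraries(g, g$sites, p)
  pk <- call_peaks(coverage_from_fragments(libs$ip, p$genome_length),
                   coverage_from_fragments(libs$input, p$genome_length))
  expect_equal(nrow(pk), 2L)
  for (pos in g$sites$position) {
    expect_equal(sum(pk$start <= pos & pk$end >= pos), 1L)
  }
})

test_that("peak widths stay near the fragment scale", {
  p <- sim_params(genome_length = 200000L, n_genes = 20L, n_sites = 5L,
                  depth = 100000L, seed = 21L)
  g <- generate_genome(p)
  libs <- simulate_libraries(g, g$sites, p)
  pk <- call_peaks(coverage_from_fragments(libs$ip, p$genome_length),
                   coverage_from_fragments(libs$input, p$genome_length))
  expect_true(all(pk$end - pk$start + 1L <= 2L * 400L))
})

test_that("null windows keep the nominal test size", {
  # fold = 1: discovery fraction at alpha stays at or below alpha + 2 SE
  fractions <- vapply(1:4, function(s) {
    p <- sim_params(genome_length = 200000L, n_sites = 0L, depth = 50000L,
                    seed = s)
    g <- generate_genome(p)
    libs <- simulate_libraries(g, g$sites, p)
    scan <- window_scan(coverage_from_fragments(libs$ip, p$genome_length),
                        coverage_from_fragments(libs$input, p$genome_length))
    c(mean(scan$p_value <= 0.01), mean(scan$p_value <= 0.05),
      nrow(scan))
  }, numeric(3))
  n <- sum(fractions[3, ])
  for (a in c(0.01, 0.05)) {
    frac <- sum(fractions[if (a == 0.01) 1 else 2, ] * fractions[3, ]) / n
    expect_lte(frac, a + 2 * sqrt(a * (1 - a) / n))
  }
})

test_that("cross-correlation recovers a constructed fragment length", {
  set.seed(31)
  src <- sample.int(200000L, 300L)
  fr <- data.frame(start = rep(src - 100L, each = 6L), width = 250L)
  fr$strand <- rep(c("+", "-"), length.out = nrow(fr))
  cc <- cross_correlation(fr, 200000L, bin = 5L)
  expect_lte(abs(cc$fragment_length_estimate - 250L), 5L)
  expect_true(all(abs(cc$profile) <= 1))

  # a strand-balanced set is invariant under swapping strand labels
  fr2 <- rbind(fr, transform(fr, strand = ifelse(strand == "+", "-", "+")))
  swapped <- transform(fr2, strand = ifelse(strand == "+", "-", "+"))
  expect_identical(cross_correlation(fr2, 200000L)$profile,
                   cross_correlation(swapped, 200000L)$profile)
  expect_error(cross_correlation(fr[fr$strand == "+", ], 200000L),
               "both strands")
})

test_that("locus enrichment ratios behave on uniform and self-referential input", {
  depth <- rep(3, 10000)
  tr <- structure(list(depth = depth, events = rep(0L, 10000),
                       n_fragments = 100L, mean_width = 250,
                       genome_length = 10000L), class = "coverage_track")
  target <- list(start = 1001, end = 1100)
  refs <- list(list(start = 5001, end = 6000), list(start = 8001, end = 9000))
  r <- locus_enrichment_ratio(tr, tr, target, refs)
  expect_equal(unname(r), c(1, 1))
  r2 <- locus_enrichment_ratio(tr, tr, refs[[1]], refs[1])
  expect_equal(unname(r2), c(1, 1))
  tr0 <- tr; tr0$depth <- rep(0, 10000)
  expect_error(locus_enrichment_ratio(tr0, tr, target, refs),
               "zero reference")
})
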