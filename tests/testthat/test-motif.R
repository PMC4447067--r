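# -10 alignment, consensus derivation and sigma-S determinant scoring.

test_that("promoter windows extract strand-aware and survive genome rotation", {
  seqs <- paste(rep(c("A", "C", "G", "T"), 50), collapse = "")
  genome <- c(chr = seqs)
  w_plus <- extract_promoter_window(genome, 100L, "+")
  expect_equal(w_plus, substr(seqs, 80, 100))
  w_minus <- extract_promoter_window(genome, 100L, "-")
  expect_equal(w_minus,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(seqs, 100, 120)))))
  expect_error(extract_promoter_window(genome, 10L, "+"), "outside")

  # rotation oracle on a circular genome
  set.seed(17)
  g <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
             collapse = "")
  rot <- 137L
  g_rot <- paste0(substr(g, rot + 1L, 500L), substr(g, 1L, rot))
  genome1 <- c(chr = g); attr(genome1, "circular") <- TRUE
  genome2 <- c(chr = g_rot); attr(genome2, "circular") <- TRUE
  for (tss in c(5L, 250L, 495L)) {
    tss2 <- ((tss - rot - 1L) %% 500L) + 1L
    expect_equal(extract_promoter_window(genome1, tss, "+"),
                 extract_promoter_window(genome2, tss2, "+"))
    expect_equal(extract_promoter_window(genome1, tss, "-"),
                 extract_promoter_window(genome2, tss2, "-"))
  }
})

test_that("consensus rules give single letters, degenerate codes and N", {
  w <- "CCTATACTTACGCCTATTAT"
  w <- paste0(w, "A")  # 21-mer
  model <- build_consensus(rep(w, 5))
  expect_equal(model$consensus, substr(w, 4, 15))
  expect_true(all(abs(colSums(model$freq) - 1) < 1e-12))

  pos_split <- rep(c(paste0(strrep("A", 10), "C", strrep("A", 10)),
                     paste0(strrep("A", 10), "T", strrep("A", 10))), 3)
  m2 <- build_consensus(pos_split)
  expect_equal(substr(m2$consensus_full, 11, 11), "Y")
  expect_error(build_consensus(c(w, "ACGT")), "length")
  expect_error(build_consensus(w), "at least 2")
})

test_that("consensus of draws from a planted table matches the table's own consensus", {
  # margins sit well inside the 0.75/0.85 thresholds so sampling noise at
  # n = 200 cannot flip a letter
  bases <- c("A", "C", "G", "T")
  planted <- matrix(0, nrow = 4, ncol = 21, dimnames = list(bases, NULL))
  kinds <- rep(c("single", "pair", "any"), length.out = 21)
  for (j in 1:21) {
    planted[, j] <- switch(kinds[j],
      single = { v <- c(0.92, 0.04, 0.02, 0.02); v[order(c(j %% 4, 1:3))] },
      pair = c(0.48, 0.46, 0.04, 0.02)[order(c((j + 1) %% 4, 1:3))],
      any = rep(0.25, 4))
  }
  planted <- apply(planted, 2, function(x) x / sum(x))
  rownames(planted) <- bases
  set.seed(3)
  draws <- vapply(1:200, function(i)
    paste(vapply(1:21, function(j)
      sample(bases, 1, prob = planted[, j]), character(1)), collapse = ""),
    character(1))
  model <- build_consensus(draws)
  oracle <- paste(vapply(4:15, function(j)
    iupac_letter_oracle(planted[, j]), character(1)), collapse = "")
  expect_equal(model$consensus, oracle)
  # record order is irrelevant
  expect_equal(build_consensus(rev(draws))$consensus, model$consensus)
})

test_that("determinant scoring hits both extremes and flags bad characters", {
  # -13C -12C (pos 8,9), -8C (pos 13), -6T (pos 15), discriminator TATTAT
  hi <- paste0(strrep("G", 7), "CC", "GG", "GC", "G", "TATTAT", "A")
  f <- score_sigmaS_features(hi)
  expect_true(f$has_m13C && f$has_m12C && f$has_m8C && f$has_m6T)
  expect_equal(f$discriminator_at_fraction, 1)
  expect_equal(f$composite_score, 6)

  lo <- paste0(strrep("A", 7), "GT", "AA", "GA", "G", "GCGCGC", "A")
  g <- score_sigmaS_features(lo)
  expect_false(g$has_m12C)
  expect_equal(g$discriminator_at_fraction, 0)
  bad <- paste0(strrep("N", 21))
  expect_true(score_sigmaS_features(bad)$undefined)
})

test_that("nudging any determinant toward its sigma-S letter never lowers the score", {
  set.seed(23)
  targets <- c(`8` = "C", `9` = "C", `13` = "C", `15` = "T")
  for (rep_i in 1:25) {
    w <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
               collapse = "")
    base_score <- score_sigmaS_features(w)$composite_score
    for (idx in names(targets)) {
      w2 <- w
      substr(w2, as.integer(idx), as.integer(idx)) <- targets[[idx]]
      expect_gte(score_sigmaS_features(w2)$composite_score, base_score)
    }
    # discriminator positions toward A/T (position 15 is the -6 determinant,
    # whose sigma-S letter is T and is covered above)
    for (idx in 16:20) {
      w3 <- w
      substr(w3, idx, idx) <- "A"
      expect_gte(score_sigmaS_features(w3)$composite_score, base_score)
    }
  }
})

test_that("composite score separates the two synthetic promoter classes", {
  s_class <- simulate_promoters(100, "sigmaS", seed = 11)
  s70 <- simulate_promoters(100, "sigma70", seed = 12)
  sc_s <- vapply(s_class, function(w)
    score_sigmaS_features(w)$composite_score, numeric(1))
  sc_70 <- vapply(s70, function(w)
    score_sigmaS_features(w)$composite_score, numeric(1))
  expect_gt(mean(sc_s), mean(sc_70))
  thr <- calibrate_promoter_threshold(sc_s, sc_70)
  pred <- c(vapply(sc_s, classify_promoter, character(1), threshold = thr),
            vapply(sc_70, classify_promoter, character(1), threshold = thr))
  truth <- rep(c("predicted_sigmaS", "predicted_sigma70"), each = 100)
  expect_gte(mean(pred == truth), 0.9)
  expect_equal(classify_promoter(6), "predicted_sigmaS")
  expect_equal(classify_promoter(0), "predicted_sigma70")
})
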