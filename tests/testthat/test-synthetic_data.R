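test_that("the default design reproduces the studied gene architecture", {
  g <- design_gene()
  expect_equal(g$truncated_aa, 807L)
  expect_equal(g$full_aa, 1129L)
  expect_equal(g$premature_stop, 2422L)
  sites <- call_slippery_sites(g$cds)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$run_length, 11L)
  expect_equal(sites$distance, 28L)
  expect_true(1L %in% sites$restoring_edits[[1]])
})

test_that("designs without a downstream +1 ORF are not +1-restorable", {
  g <- design_gene(gene_design(upstream_codons = 10, plus1_orf_codons = 0,
                               seed = 6), id = "g0")
  sites <- call_slippery_sites(g$cds)
  expect_equal(nrow(sites), 1L)
  expect_false(1L %in% sites$restoring_edits[[1]])
  expect_false(oracle_restores(g$cds$seq, g$run$start, g$run$length,
                               g$premature_stop, 1L))
})

test_that("generated genes satisfy every design invariant over a seed sweep", {
  for (seed in 1:100) {
    d <- random_small_design(seed)
    g <- design_gene(d, id = paste0("g", seed))
    x <- g$cds
    # exactly the designed run, nothing else scannable
    runs <- find_runs(x, "A", min_length = min(8L, d$run_length))
    expect_equal(nrow(runs), 1L)
    expect_equal(runs$start, g$run$start)
    expect_equal(runs$length, d$run_length)
    expect_equal(nrow(find_runs(x, "T", min_length = 8)), 0L)
    # the designed premature stop is the first frame-0 stop
    expect_equal(find_premature_stop(x), g$premature_stop)
    # truncated product length follows from the stop position
    expect_equal(translate_cds(x)$length_aa, (g$premature_stop - 1L) %/% 3L)
    # +1 restoration iff a +1 ORF was designed
    expect_equal(oracle_restores(x$seq, g$run$start, g$run$length,
                                 g$premature_stop, 1L),
                 d$plus1_orf_codons > 0L)
  }
})

test_that("gene generation is deterministic under the design seed", {
  d <- gene_design(upstream_codons = 30, plus1_orf_codons = 10, seed = 123)
  expect_identical(design_gene(d)$cds$seq, design_gene(d)$cds$seq)
  d2 <- gene_design(upstream_codons = 30, plus1_orf_codons = 10, seed = 124)
  expect_false(identical(design_gene(d)$cds$seq, design_gene(d2)$cds$seq))
})

test_that("slippage models normalize onto k = 0 and validate probabilities", {
  m <- slippage_model()
  expect_equal(m$p[m$k == 1], 0.25)
  expect_equal(m$p[m$k == 0], 0.75)
  expect_equal(sum(m$p), 1)
  m2 <- slippage_model(c("-1" = 0.1, "1" = 0.2, "2" = 0.1))
  expect_equal(m2$p[m2$k == 0], 0.6)
  expect_error(slippage_model(c("9" = 0.1)), "support")
  expect_error(slippage_model(c("1" = 1.5)), "more than 1")
})

test_that("a degenerate model yields a single unedited species", {
  g <- design_gene(gene_design(upstream_codons = 10, plus1_orf_codons = 5,
                               seed = 2), id = "g")
  pop <- simulate_transcription(g, slippage_model(c("0" = 1)), n = 500, seed = 1)
  expect_equal(length(pop$a_count_counts), 1L)
  expect_equal(names(pop$a_count_counts), as.character(g$run$length))
  expect_equal(nrow(pop$variants), 1L)
  expect_equal(pop$true_restoring_fraction, 0)
})

test_that("simulated populations follow binomial sampling of the +1 fraction", {
  g <- design_gene(gene_design(upstream_codons = 10, plus1_orf_codons = 5,
                               seed = 2), id = "g")
  pop <- simulate_transcription(g, slippage_model(), n = 10000, seed = 42)
  expect_equal(sum(pop$variants$count), 10000L)
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(pop$true_restoring_fraction - 0.25), 3 * se)
  # support of simulated a_counts is within {native + k : p(k) > 0}
  m <- slippage_model(c("-1" = 0.05, "1" = 0.2, "4" = 0.05))
  pop2 <- simulate_transcription(g, m, n = 2000, seed = 7)
  allowed <- g$run$length + m$k[m$p > 0]
  expect_true(all(as.integer(names(pop2$a_count_counts)) %in% allowed))
  # reproducible under a fixed seed
  pop3 <- simulate_transcription(g, slippage_model(), n = 10000, seed = 42)
  expect_identical(pop$variants, pop3$variants)
})

test_that("noiseless westerns reproduce the exact count ratio", {
  g <- design_gene(gene_design(upstream_codons = 10, plus1_orf_codons = 5,
                               seed = 2), id = "g")
  pop <- simulate_transcription(g, slippage_model(), n = 10000, seed = 5)
  b <- simulate_western(pop, noise_sigma = 0, seed = 1)
  long <- sum(pop$variants$count[pop$variants$restored])
  expect_equal(b$intensity_long / (b$intensity_long + b$intensity_short),
               long / 10000)
  expect_true(b$intensity_long >= 0 && b$intensity_short >= 0)
})

test_that("western estimates recover the slippage frequency end to end", {
  g <- design_gene(gene_design(upstream_codons = 10, plus1_orf_codons = 5,
                               seed = 2), id = "g")
  pop <- simulate_transcription(g, slippage_model(), n = 10000, seed = 11)
  est <- western_frequency(simulate_western(pop, noise_sigma = 0.05, seed = 21))
  expect_lt(abs(est$f_hat - 0.25), 0.03)
  # intensities non-negative across seeds
  for (s in 1:10)
    expect_true(simulate_western(pop, 0.1, seed = s)$intensity_long >= 0)
})

test_that("reporter simulation is exact without noise and recovers f with it", {
  r <- simulate_reporters(0.2, noise_sigma = 0, seed = 1)
  expect_equal(gfp_frequency(r)$f_hat, 0.2)
  r0 <- simulate_reporters(0, noise_sigma = 0.01, seed = 2)
  expect_lt(abs(r0$f_test - r0$f_neg) / (r0$f_max - r0$f_neg), 0.05)
  # recovery within 3 se over a sweep of seeds (se from noise propagation)
  m <- 3L; sigma <- 0.05
  sd_f <- sigma * sqrt((1 + (1 - 0.2)^2 + 0.2^2) / m)
  for (s in 1:50) {
    est <- gfp_frequency(simulate_reporters(0.2, noise_sigma = sigma,
                                            replicates = m, seed = s))
    expect_lt(abs(est$f_hat - 0.2), 3 * sd_f)
  }
  expect_error(simulate_reporters(1.2), "0, 1")
})
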