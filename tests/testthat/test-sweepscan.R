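# Null distributions, logP scoring and top-K region calling.

make_null <- function(ratios) {
  structure(list(ratio_pi = sort(ratios), ratio_theta = sort(ratios),
                 R = length(ratios), window_bp = 5e5, n_redrawn = 0L),
            class = "sweep_null")
}

make_track <- function(chrom, start, ratio_pi, ratio_theta = ratio_pi,
                       window = 5e5, step = 2e4) {
  tr <- data.frame(chrom = chrom, start = start, end = start + window,
                   truncated = FALSE, ratio_pi = ratio_pi,
                   ratio_theta = ratio_theta)
  class(tr) <- c("window_track", "data.frame")
  attr(tr, "window") <- window
  attr(tr, "step") <- step
  tr
}

test_that("logP follows the pseudocount arithmetic exactly", {
  null <- make_null(seq(0.001, 1, length.out = 999))
  # 10 of R = 999 simulations at or below the observed ratio
  tr <- make_track("c1", 0, ratio_pi = null$ratio_pi[10])
  sc <- score_windows(tr, null)
  expect_equal(sc$logp_pi, -log10(11 / 1000), tolerance = 1e-12)
  # observed above every simulated value: p = 1, logP = 0
  tr <- make_track("c1", 0, ratio_pi = 2)
  expect_equal(score_windows(tr, null)$logp_pi, 0)
  # observed below all R = 99,999: p = 1e-5, logP = 5
  big <- make_null(seq(1e-4, 1, length.out = 99999))
  tr <- make_track("c1", 0, ratio_pi = 1e-6)
  expect_equal(score_windows(tr, big)$logp_pi, 5)
  # undefined ratios stay undefined
  tr <- make_track("c1", 0, ratio_pi = NA_real_)
  expect_true(is.na(score_windows(tr, null)$logp_pi))
  # mismatched window sizes are an error
  tr <- make_track("c1", 0, 0.5, window = 1e5)
  expect_error(score_windows(tr, null), "window size")
})

test_that("logP is monotone in the observed ratio and bounded by log10(R+1)", {
  null <- make_null(runif(500))
  obs <- sort(runif(200))
  tr <- make_track("c1", seq_along(obs) * 1e5, ratio_pi = obs)
  sc <- score_windows(tr, null)
  expect_true(all(diff(sc$logp_pi[order(obs)]) <= 1e-12))
  expect_true(all(sc$logp_pi <= log10(501) + 1e-12))
})

test_that("null construction is deterministic and tracks the bottleneck", {
  m_mild <- demographic_model(N0 = 1e4, N1 = 5e3, T1 = 1000, mu = 2.5e-8,
                              rec = 1e-8, s_wild = 0, s_cult = 0)
  m_severe <- demographic_model(N0 = 1e4, N1 = 200, T1 = 1000, mu = 2.5e-8,
                                rec = 1e-8, s_wild = 0, s_cult = 0)
  n1 <- suppressWarnings(build_null_distribution(m_mild, 6, 8, 1e5, R = 400,
                                                 seed = 5))
  n2 <- suppressWarnings(build_null_distribution(m_mild, 6, 8, 1e5, R = 400,
                                                 seed = 5))
  expect_identical(n1$ratio_pi, n2$ratio_pi)
  n3 <- suppressWarnings(build_null_distribution(m_severe, 6, 8, 1e5,
                                                 R = 400, seed = 5))
  expect_lt(mean(n3$ratio_pi), mean(n1$ratio_pi))
  # near-degenerate split: ratio centred at 1
  m_null <- demographic_model(N0 = 1e4, N1 = 1e4, T1 = 2, mu = 2.5e-8,
                              rec = 1e-8, s_wild = 0, s_cult = 0)
  n4 <- suppressWarnings(build_null_distribution(m_null, 8, 8, 1e5, R = 400,
                                                 seed = 6))
  expect_lt(abs(mean(n4$ratio_pi) - 1), 0.1)
})

test_that("region calling applies the both-measures top-K and merge rules", {
  # 20 windows; a run of 6 overlapping qualifying windows around 1.0-1.1 Mb
  starts <- seq(0, 19) * 2e4 + 1e6
  rp <- rep(0.8, 20); rt <- rep(0.8, 20)
  rp[5:10] <- 0.01 * (1:6); rt[5:10] <- 0.01 * (6:1)
  null <- make_null(seq(0.05, 1, length.out = 999))
  tr <- make_track("c1", starts, ratio_pi = rp, ratio_theta = rt)
  sc <- score_windows(tr, null)
  reg <- call_sweep_regions(sc, K = 6)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, starts[5])
  expect_equal(reg$end, starts[10] + 5e5)
  expect_equal(reg$n_windows, 6)
  expect_equal(reg$label, "S01")

  # a window in the top-K by pi but not by theta is excluded
  rp2 <- rep(0.8, 20); rt2 <- rep(0.8, 20)
  rp2[3] <- 0.001                            # top by pi only
  rp2[15] <- 0.002; rt2[15] <- 0.002         # top by both
  tr2 <- make_track("c1", starts, ratio_pi = rp2, ratio_theta = rt2)
  reg2 <- call_sweep_regions(score_windows(tr2, null), K = 2)
  expect_equal(nrow(reg2), 1)
  expect_equal(reg2$start, starts[15])

  # all-undefined track yields an empty region list
  tr3 <- make_track("c1", starts, ratio_pi = NA_real_)
  expect_equal(nrow(call_sweep_regions(score_windows(tr3, null))), 0)
})

test_that("planted sweeps are recalled on a small synthetic genome", {
  sweeps <- list(sweep_spec("chr1", 1e6, 1.5e5))
  cfg <- genome_config(chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
                       qtl_per_chrom = 5, sweeps = sweeps)
  ds <- synthesize_genome(cfg, demographic_model(), seed = 61)
  panel <- apply_snp_filters(ds$panel)$panel
  genes <- ds$annotation$genes
  tr <- diversity_ratio_track(panel, ds$popmap,
                              callable_regions = data.frame(
                                chrom = genes$chrom, start = genes$start,
                                end = genes$end))
  null <- build_null_distribution(ds$model, 10, 22, R = 2000, seed = 62)
  reg <- call_sweep_regions(score_windows(tr, null), K = 15)
  hit <- reg$chrom == "chr1" & reg$start <= 1e6 & reg$end > 1e6
  expect_true(any(hit))
  # and the unswept chromosome contributes no region
  expect_false(any(reg$chrom == "chr2"))
})
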