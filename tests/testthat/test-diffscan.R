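# Windowed F_ST differentiation scans.

# Panel of unlinked binomial sites with a planted fixed-difference interval.
make_diff_panel <- function(n_a = 8, n_b = 8, n_sites = 400, len = 2e6,
                            diff_start = NA, diff_end = NA, seed = 1) {
  set.seed(seed)
  samples <- c(sprintf("A%02d", seq_len(n_a)), sprintf("B%02d", seq_len(n_b)))
  pos <- sort(sample.int(len, n_sites))
  geno <- sapply(seq_len(n_sites), function(j) {
    p <- runif(1, 0.1, 0.9)
    g <- rbinom(n_a + n_b, 1, p)
    if (!is.na(diff_start) && pos[j] >= diff_start && pos[j] < diff_end)
      g <- c(rep(0L, n_a), rep(1L, n_b))
    g
  })
  keep <- colSums(geno) > 0 & colSums(geno) < n_a + n_b
  rownames(geno) <- samples
  p <- genotype_panel(geno[, keep], chrom = rep("chr1", sum(keep)),
                      pos = pos[keep] - 1L, ref = rep("A", sum(keep)),
                      alt = rep("T", sum(keep)), samples = samples,
                      chrom_lengths = c(chr1 = len))
  pm <- population_map(samples, c(rep("indica", n_a),
                                  rep("japonica_temperate", n_b)))
  list(panel = p, popmap = pm)
}

test_that("random halves of one population give window F_ST near zero", {
  d <- make_diff_panel(seed = 8)
  tr <- fst_scan(d$panel, d$popmap, c("indica", "japonica"))
  expect_lt(abs(mean(tr$fst, na.rm = TRUE)), 0.05)
  expect_true(any(tr$fst < 0))  # negatives retained, not clipped
})

test_that("a planted fixed-difference interval attains the track maximum", {
  d <- make_diff_panel(diff_start = 1.2e6, diff_end = 1.4e6, seed = 9)
  tr <- fst_scan(d$panel, d$popmap, c("indica", "japonica"))
  best <- tr[which.max(tr$fst), ]
  expect_true(best$start <= 1.4e6 && best$end > 1.2e6)
  reg <- top_fst_regions(tr, K = 1)
  expect_equal(nrow(reg), 1)
  # recovered within one window step of the planted interval
  expect_lt(abs(reg$start - (1.2e6 - attr(tr, "window") + attr(tr, "step"))),
            attr(tr, "window"))
  expect_true(reg$start <= 1.4e6 && reg$end > 1.2e6)
  expect_gt(reg$peak_fst, 0.5)
})

test_that("windows with an all-missing group are undefined", {
  d <- make_diff_panel(n_sites = 50, len = 4e5, seed = 10)
  d$panel$geno[sprintf("B%02d", 1:8), d$panel$sites$pos < 2e5] <- NA_integer_
  tr <- fst_scan(d$panel, d$popmap, c("indica", "japonica"),
                 size = 2e5, step = 2e5)
  expect_true(is.na(tr$fst[tr$start == 0]))
  expect_false(is.na(tr$fst[tr$start == 2e5]))
})

test_that("equal peaks break ties toward the leftmost region", {
  tr <- data.frame(chrom = "chr1", start = c(0, 2e5, 6e5, 8e5),
                   end = c(2e5, 4e5, 8e5, 10e5), truncated = FALSE,
                   n_sites = 5, fst = c(0.9, 0.1, 0.9, 0.1))
  class(tr) <- c("window_track", "data.frame")
  reg <- top_fst_regions(tr, K = 1, quantile_floor = 0.75)
  expect_equal(reg$start, 0)
  expect_error(fst_scan(make_diff_panel(seed = 1)$panel,
                        make_diff_panel(seed = 1)$popmap,
                        c("indica", "nosuchpop")))
})

test_that("planted differentiation exceeds the permutation threshold", {
  d <- make_diff_panel(diff_start = 1.2e6, diff_end = 1.4e6, seed = 12)
  tr <- fst_scan(d$panel, d$popmap, c("indica", "japonica"))
  thr <- fst_permutation_threshold(d$panel, d$popmap,
                                   c("indica", "japonica"),
                                   n_perm = 5, seed = 13)
  expect_gt(max(tr$fst, na.rm = TRUE), thr$threshold[[1]])
})
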