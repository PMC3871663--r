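# Diversity estimators, windows, F_ST, LD.

test_that("site_pi matches hand-enumerated pairwise differences", {
  expect_equal(site_pi(c(0, 0, 1, 1)), 2 / 3)      # 4 differing pairs / 6
  expect_equal(site_pi(c(0, 0, 0, 0)), 0)          # monomorphic
  expect_equal(site_pi(c(0, 1)), 1)                # single differing pair
  expect_true(is.na(site_pi(c(0, NA))))            # < 2 calls
  expect_equal(site_pi(c(0, 1, NA, NA, 1)), 2 * 1 * 2 / (3 * 2))
})

test_that("windowed Watterson's theta matches the harmonic-number formula", {
  # 1000-site window, n = 10 everywhere, S = 16 segregating sites
  n <- 10; S <- 16
  geno <- matrix(0L, n, S)
  for (j in seq_len(S)) geno[seq_len(1 + (j %% (n - 1))), j] <- 1L
  p <- genotype_panel(geno, chrom = rep("c1", S),
                      pos = as.integer(seq(10, 990, length.out = S)),
                      ref = rep("A", S), alt = rep("T", S),
                      samples = sprintf("W%02d", 1:n),
                      chrom_lengths = c(c1 = 1000))
  pm <- population_map(sprintf("W%02d", 1:n), rep("rufipogon", n))
  wd <- window_diversity(p, pm, "c1", "rufipogon",
                         grid = data.frame(start = 0, end = 1000,
                                           truncated = FALSE))
  a9 <- sum(1 / (1:9))
  expect_equal(wd$theta_w, 16 / (a9 * 1000), tolerance = 1e-12)
  expect_equal(wd$S, 16)
  # S = 0 window
  wd0 <- window_diversity(p, pm, "c1", "rufipogon",
                          grid = data.frame(start = 2000, end = 3000,
                                            truncated = FALSE))
  expect_equal(wd0$theta_w, 0)
})

test_that("genome-wide Watterson estimate reproduces the published rice value", {
  d <- rice_diversity_summary()
  all_row <- d[d$group == "all" & d$region == "all", ]
  th <- theta_w_from_counts(all_row$snps, all_row$length_bp, all_row$n)
  expect_equal(round(th * 100, 2), all_row$theta_w_x100)  # 0.39 x 10^-2
})

test_that("published diversity ratios are 60% and 27.5% of wild", {
  d <- rice_diversity_summary()
  pi_of <- function(g) d$pi_x100[d$group == g & d$region == "all"]
  expect_equal(100 * pi_of("sativa") / pi_of("rufipogon"), 60)
  expect_equal(100 * pi_of("japonica") / pi_of("rufipogon"), 27.5)
})

test_that("sliding windows enumerate and truncate correctly", {
  g <- sliding_windows(1e6, 5e5, 2e4)
  expect_equal(nrow(g), 50)
  expect_equal(g$start, seq(0, 980000, by = 2e4))
  expect_true(all(g$truncated == (g$start > 5e5)))
  expect_true(all(g$end <= 1e6))
  # chromosome shorter than the window: one truncated window
  g2 <- sliding_windows(3e5, 5e5, 2e4)
  expect_equal(nrow(g2), 1)
  expect_true(g2$truncated[1])
  expect_equal(g2$end[1], 3e5)
  # step = size tiles without overlap
  g3 <- sliding_windows(1e6, 1e5, 1e5)
  expect_equal(g3$start, seq(0, 9e5, by = 1e5))
  expect_true(all(g3$start[-1] == g3$end[-nrow(g3)]))
  expect_error(sliding_windows(1e6, 1e5, 2e5), "step")
})

test_that("Hudson F_ST matches hand enumeration", {
  mk <- function(ga, gb) {
    samples <- c(sprintf("W%02d", seq_along(ga)),
                 sprintf("C%02d", seq_along(gb)))
    p <- genotype_panel(matrix(c(ga, gb), ncol = 1), chrom = "c1", pos = 1L,
                        ref = "A", alt = "T", samples = samples)
    pm <- population_map(samples, c(rep("rufipogon", length(ga)),
                                    rep("indica", length(gb))))
    hudson_fst(p, pm, "rufipogon", "indica")
  }
  # popA = {A,A,T,T}, popB = {A,A,A,A}: within = 1/3, between = 1/2
  expect_equal(mk(c(0L, 0L, 1L, 1L), c(0L, 0L, 0L, 0L)), 1 / 3)
  # identical sample allele frequencies: never positive (exactly 0 only in
  # the infinite-sample limit, since the within term is the finite-sample
  # mean pairwise difference)
  expect_lte(mk(c(0L, 1L, 0L, 1L), c(1L, 0L, 1L, 0L)), 0)
  # fixed difference, no within-pop variation
  expect_equal(mk(c(0L, 0L, 0L, 0L), c(1L, 1L, 1L, 1L)), 1)
})

test_that("per-site F_ST reproduces the screen's worked example", {
  # cultivated 14/14 allele T; wild 7 called: A x6, T x1 -> F_ST = 5/6
  samples <- c(sprintf("W%02d", 1:7), sprintf("C%02d", 1:14))
  p <- genotype_panel(matrix(c(rep(0L, 6), 1L, rep(1L, 14)), ncol = 1),
                      chrom = "c1", pos = 5L, ref = "A", alt = "T",
                      samples = samples)
  pm <- population_map(samples, c(rep("rufipogon", 7), rep("indica", 14)))
  expect_equal(per_site_fst(p, pm, "rufipogon", "sativa"), 5 / 6)
})

test_that("r2 matches the 2x2 haplotype-table example and duplicated sites", {
  # haplotypes AB, AB, Ab, ab -> D = 0.125, r2 = 1/3
  samples <- sprintf("S%d", 1:4)
  p <- genotype_panel(
    rbind(S1 = c(1L, 1L), S2 = c(1L, 1L), S3 = c(1L, 0L), S4 = c(0L, 0L)),
    chrom = c("c1", "c1"), pos = c(100L, 300L), ref = c("A", "A"),
    alt = c("T", "T"), samples = samples)
  pm <- population_map(samples, rep("indica", 4))
  ld <- ld_r2_decay(p, pm, "indica", max_dist = 1000, bin_bp = 1000)
  expect_equal(ld$mean_r2[ld$n_pairs > 0 & ld$bin_mid > 0], 1 / 3)
  # the same site duplicated (distance 0) -> r2 = 1
  p2 <- genotype_panel(
    rbind(S1 = c(1L, 1L), S2 = c(1L, 1L), S3 = c(0L, 0L), S4 = c(0L, 0L)),
    chrom = c("c1", "c1"), pos = c(100L, 100L), ref = c("A", "A"),
    alt = c("T", "G"), samples = samples)
  ld2 <- ld_r2_decay(p2, pm, "indica", max_dist = 1000, bin_bp = 1000)
  expect_equal(ld2$mean_r2[1], 1)
})

test_that("mean r2 between unlinked sites is near the 1/n sampling bound", {
  set.seed(31)
  n <- 10; S <- 80
  geno <- matrix(rbinom(n * S, 1, 0.5), n, S)
  keep <- colSums(geno) > 0 & colSums(geno) < n
  geno <- geno[, keep]
  samples <- sprintf("S%02d", 1:n)
  rownames(geno) <- samples
  p <- genotype_panel(geno, chrom = rep("c1", ncol(geno)),
                      pos = as.integer(seq_len(ncol(geno)) * 10L),
                      ref = rep("A", ncol(geno)), alt = rep("T", ncol(geno)),
                      samples = samples)
  pm <- population_map(samples, rep("indica", n))
  ld <- ld_r2_decay(p, pm, "indica", max_dist = 1e4, bin_bp = 1e4)
  got <- sum(ld$mean_r2 * ld$n_pairs, na.rm = TRUE) / sum(ld$n_pairs)
  expect_lt(abs(got - 1 / n), 0.04)
})

test_that("per-gene synonymous pi keeps genes with >= 1000 sites and uses the first 1000", {
  # two genes of fourfold-rich codons: 1100 and 990 fourfold sites
  mk_gene <- function(n_codon, offset, chrom_bases) {
    cods <- paste0(sample(c("GG", "CC", "AC", "GT"), n_codon, replace = TRUE),
                   sample(c("A", "C", "G", "T"), n_codon, replace = TRUE))
    cods[1] <- "ATG"; cods[n_codon] <- "TAA"
    seq <- paste(cods, collapse = "")
    chrom_bases[(offset + 1):(offset + nchar(seq))] <- strsplit(seq, "")[[1]]
    list(bases = chrom_bases, start = offset, end = offset + nchar(seq))
  }
  set.seed(77)
  bases <- rep("A", 8000)
  g1 <- mk_gene(1102, 100, bases)     # 1100 interior fourfold sites
  g2 <- mk_gene(992, 4500, g1$bases)  # 990 interior fourfold sites
  ref <- Biostrings::DNAStringSet(setNames(paste(g2$bases, collapse = ""), "c1"))
  ann <- gene_annotation(
    genes = data.frame(gene_id = c("g1", "g2"), chrom = "c1",
                       strand = "+", start = c(g1$start, g2$start),
                       end = c(g1$end, g2$end)),
    cds = data.frame(gene_id = c("g1", "g2"), start = c(g1$start, g2$start),
                     end = c(g1$end, g2$end), phase = 0L))
  ff1 <- fourfold_sites(ann, ref, "g1")
  ff2 <- fourfold_sites(ann, ref, "g2")
  expect_equal(length(ff1), 1100)
  expect_equal(length(ff2), 990)
  # 5 singleton SNPs among the first 1000 synonymous sites, n = 10
  n <- 10
  snp_pos <- ff1[c(3, 100, 400, 700, 999)]
  geno <- matrix(0L, n, 5)
  geno[1, ] <- 1L
  samples <- sprintf("C%02d", 1:n)
  rownames(geno) <- samples
  p <- genotype_panel(geno, chrom = rep("c1", 5), pos = snp_pos,
                      ref = rep("G", 5), alt = rep("A", 5), samples = samples)
  pm <- population_map(samples, rep("indica", n))
  res <- per_gene_synonymous_pi(p, ann, ref, pm, "indica")
  expect_equal(res$pi[res$gene_id == "g1"], 5 * (2 * 1 * 9 / 90) / 1000)
  expect_equal(res$used[res$gene_id == "g1"], 1000L)
  expect_equal(res$reason[res$gene_id == "g2"], "too_few_synonymous_sites")
  expect_true(is.na(res$pi[res$gene_id == "g2"]))
})

test_that("estimators are unchanged by masked-but-absent missing data", {
  m <- fast_model()
  p <- simulate_locus(m, 5, 7, 1e5, seed = 15)
  pm <- attr(p, "popmap")
  d0 <- degrade_panel(p, missing_rate = 0, seed = 1)
  grid <- data.frame(start = 0, end = 1e5, truncated = FALSE)
  w1 <- window_diversity(p, pm, "locus", "sativa", grid = grid)
  w2 <- window_diversity(d0, pm, "locus", "sativa", grid = grid)
  expect_equal(w1$pi, w2$pi)
  expect_equal(w1$theta_w, w2$theta_w)
  expect_equal(hudson_fst(p, pm, "rufipogon", "sativa"),
               hudson_fst(d0, pm, "rufipogon", "sativa"))
})

test_that("neutral window pi and theta_W agree in mean (Tajima balance)", {
  b <- sweepqtl:::sim_batch_scaled(1000, 10, 0, 1e4, theta = 5, rho_w = 10,
                                   seed = 19)
  a9 <- sum(1 / (1:9))
  tt <- t.test(b[, "pi_wild"], b[, "S_wild"] / a9, paired = TRUE)
  expect_gt(tt$p.value, 0.01)
})
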