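# Synthetic-data generator: locus simulator, degradation, genome bundle.

test_that("mu = 0 gives a panel with zero sites", {
  m <- demographic_model(N0 = 1e4, N1 = 2e3, T1 = 500, mu = 0, rec = 0,
                         s_wild = 0, s_cult = 0)
  p <- simulate_locus(m, 3, 3, 1e4, seed = 1)
  expect_equal(n_sites <- nrow(p$sites), 0)
})

test_that("simulation is deterministic given the seed", {
  m <- fast_model()
  p1 <- simulate_locus(m, 5, 5, 5e4, seed = 42)
  p2 <- simulate_locus(m, 5, 5, 5e4, seed = 42)
  p3 <- simulate_locus(m, 5, 5, 5e4, seed = 43)
  expect_identical(p1$geno, p2$geno)
  expect_identical(p1$sites, p2$sites)
  expect_false(identical(p1$sites$pos, p3$sites$pos))
})

test_that("invalid simulation arguments are rejected", {
  m <- fast_model()
  expect_error(simulate_locus(m, 1, 0, 1e4, seed = 1), "n_wild")
  expect_error(simulate_locus(m, 2, 0, 0, seed = 1), "L")
  expect_error(demographic_model(N0 = -5), "N0")
  expect_error(demographic_model(s_cult = 1), "s_cult")
  expect_error(sweep_spec("c", 10, lambda = 0), "lambda")
})

test_that("mean pairwise diversity matches theta for n = 2 (closed form)", {
  # single population, no recombination, theta = 10 per locus
  b <- sweepqtl:::sim_batch_scaled(5000, 2, 0, 1000, theta = 10, seed = 7)
  expect_lt(abs(mean(b[, "pi_wild"]) - 10) / 10, 0.05)
})

test_that("diversity at a fully swept locus matches the star expectation", {
  # mild pre-sweep drift (T1/(2*N1) = 0.04) so pairwise TMRCA ~ t_fix and
  # per-site diversity ~ 2*mu*T1
  m <- demographic_model(N0 = 25000, N1 = 25000, T1 = 2000, mu = 1e-6,
                         rec = 0, s_wild = 0, s_cult = 0)
  sw <- sweep_spec("locus", pos = 1e4, lambda = 1e12, t_fix = 2000)
  b <- simulate_locus_batch(m, 0, 10, 2e4, R = 2000, sweep = sw, seed = 11)
  got <- mean(b[, "pi_cult"]) / 2e4
  expect_lt(abs(got - 2 * 1e-6 * 2000) / (2 * 1e-6 * 2000), 0.1)
})

test_that("sweeps depress cultivated diversity near the center (paired)", {
  m <- fast_model()
  sw <- sweep_spec("locus", pos = 5e4, lambda = 5e4)
  swept <- simulate_locus_batch(m, 0, 12, 1e5, R = 300, sweep = sw, seed = 3)
  neutral <- simulate_locus_batch(m, 0, 12, 1e5, R = 300, seed = 3)
  expect_lt(mean(swept[, "pi_cult"]), mean(neutral[, "pi_cult"]))
  # strictly lower in the large majority of paired replicates
  expect_gt(mean(neutral[, "pi_cult"] > swept[, "pi_cult"]), 0.8)
})

test_that("degradation sets the expected missing fraction and re-enforces segregation", {
  m <- fast_model()
  p <- simulate_locus(m, 5, 5, 2e5, seed = 9)
  expect_gt(nrow(p$sites), 100)
  d0 <- degrade_panel(p, missing_rate = 0, seed = 1)
  expect_identical(d0$geno[, colnames(d0$geno)], p$geno[, colnames(d0$geno)])
  expect_true(all(!is.na(d0$sites$qual)))
  d5 <- degrade_panel(p, missing_rate = 0.5, seed = 2)
  expect_lt(abs(mean(is.na(d5$geno)) - 0.5), 0.05)
  # every surviving site still segregates among non-missing calls
  der <- colSums(d5$geno == 1L, na.rm = TRUE)
  called <- colSums(!is.na(d5$geno))
  expect_true(all(der > 0 & der < called))
  expect_error(degrade_panel(p, missing_rate = 1), "missing_rate")
})

test_that("a site left monomorphic by degradation is removed", {
  p <- genotype_panel(
    rbind(a = c(0L, 1L), b = c(1L, 1L), c = c(0L, 0L)),
    chrom = c("c1", "c1"), pos = c(10L, 20L),
    ref = c("A", "A"), alt = c("T", "T"))
  p$geno[2, 1] <- NA  # site 1 becomes monomorphic among called samples
  out <- sweepqtl:::drop_monomorphic(p)
  expect_equal(out$sites$pos, 20L)
  expect_equal(attr(out, "n_monomorphic_dropped"), 1L)
})

test_that("genome truth bookkeeping is exact", {
  cfg0 <- genome_config(chrom_lengths = c(chr1 = 6e5), chunk_bp = 3e5,
                        qtl_per_chrom = 3, sweeps = list(),
                        plant_causal = FALSE, plant_controls = FALSE)
  ds0 <- synthesize_genome(cfg0, fast_model(), seed = 4)
  expect_equal(nrow(ds0$truth$sweeps), 0)

  sweeps <- list(sweep_spec("chr1", 3e5, 1e5), sweep_spec("chr2", 2e5, 1e5),
                 sweep_spec("chr3", 4e5, 1e5))
  cfg3 <- genome_config(chrom_lengths = c(chr1 = 6e5, chr2 = 6e5, chr3 = 6e5),
                        chunk_bp = 3e5, qtl_per_chrom = 3, sweeps = sweeps)
  ds3 <- synthesize_genome(cfg3, fast_model(), seed = 4)
  expect_equal(nrow(ds3$truth$sweeps), 3)
  for (i in 1:3) {
    tr <- ds3$truth$sweeps[i, ]
    expect_true(tr$pos >= 0 && tr$pos < cfg3$chrom_lengths[tr$chrom])
  }
  expect_error(
    genome_config(chrom_lengths = c(chr1 = 6e5),
                  sweeps = list(sweep_spec("chr1", 7e5, 1e5))),
    "outside")
})

test_that("regenerating with the same seed gives byte-identical VCF output", {
  cfg <- genome_config(chrom_lengths = c(chr1 = 6e5), chunk_bp = 3e5,
                       qtl_per_chrom = 3,
                       sweeps = list(sweep_spec("chr1", 3e5, 8e4)))
  d1 <- tempfile(); d2 <- tempfile()
  export_dataset(synthesize_genome(cfg, fast_model(), seed = 99), d1)
  export_dataset(synthesize_genome(cfg, fast_model(), seed = 99), d2)
  expect_identical(readLines(file.path(d1, "calls.vcf")),
                   readLines(file.path(d2, "calls.vcf")))
  expect_identical(unname(tools::md5sum(file.path(d1, "qtl.tsv"))),
                   unname(tools::md5sum(file.path(d2, "qtl.tsv"))))
})
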