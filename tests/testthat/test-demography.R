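# Simulation-based bottleneck inference.

test_that("all-zero segregating counts drive N0 to the smallest grid value", {
  curve <- estimate_n0(rep(0L, 60), n = 10, L = 1000, mu = 1e-8,
                       n0_grid = c(12.5e3, 25e3, 5e4, 1e5), R = 400, seed = 1)
  expect_equal(curve$mle, 12.5e3)
  expect_true(all(is.finite(curve$logL)))
  expect_error(estimate_n0(5L, 10, 1000, 1e-8, numeric(), R = 100), "grid")
})

test_that("N0 is recovered from data generated at a grid point", {
  N0 <- 5e4; mu <- 1e-8; L <- 1000
  obs <- sweepqtl:::sim_batch_scaled(200, 10, 0, L, theta = 4 * N0 * mu * L,
                                     seed = 23)
  curve <- estimate_n0(obs[, "S_wild"], n = 10, L = L, mu = mu,
                       n0_grid = c(12.5e3, 25e3, 5e4, 1e5, 2e5),
                       R = 2000, seed = 24)
  expect_equal(curve$mle, 5e4)
  # likelihood decreases away from the optimum on both sides
  i <- which(curve$grid == curve$mle)
  expect_true(curve$logL[i] > curve$logL[1])
  expect_true(curve$logL[i] > curve$logL[length(curve$grid)])
})

test_that("conditional smoothing always yields finite log-likelihoods", {
  # observed S values far outside anything the simulations produce
  surf <- bottleneck_likelihood_surface(
    S_wild = c(0L, 45L), S_cult = c(40L, 0L), n_wild = 6, n_cult = 8,
    N0 = 2e4, mu = 1e-8, L = 1000,
    n1_grid = c(2e3, 2e4), t1_grid = c(400, 4000), R = 300, seed = 3)
  expect_true(all(is.finite(surf$logL)))
  expect_gt(surf$n_fallback, 0)
})

test_that("MLE tie-breaking prefers the least extreme bottleneck", {
  surf <- structure(list(
    n1_grid = c(1e3, 1e4), t1_grid = c(100, 1000),
    logL = matrix(c(-5, -1, -1, -7), 2, 2), R = 1, n_loci = 1),
    class = "likelihood_surface")
  # ties at (N1=1e3, T1=1000) and (N1=1e4, T1=100): pick larger N1
  m <- bottleneck_mle(surf)
  expect_equal(m$N1, 1e4)
  expect_equal(m$T1, 100)
  surf$logL <- matrix(NA_real_, 2, 2)
  expect_error(bottleneck_mle(surf), "finite")
})

test_that("bottleneck parameters are recovered within one grid cell", {
  N0 <- 5e4; mu <- 1e-8; L <- 1000
  n1g <- N0 * exp(seq(log(0.02), log(1), length.out = 4))
  t1g <- 4 * N0 * exp(seq(log(0.01), log(0.25), length.out = 4))
  ti <- 2; tj <- 3
  obs <- sweepqtl:::sim_batch_scaled(
    150, 10, 22, L, theta = 4 * N0 * mu * L,
    tau1 = t1g[tj] / (4 * N0), x1 = n1g[ti] / N0, seed = 41)
  surf <- bottleneck_likelihood_surface(
    obs[, "S_wild"], obs[, "S_cult"], 10, 22, N0 = N0, mu = mu, L = L,
    n1_grid = n1g, t1_grid = t1g, R = 1200, seed = 42)
  m <- bottleneck_mle(surf)
  expect_lte(max(abs(m$i - ti), abs(m$j - tj)), 1)
})

test_that("fit_bottleneck returns a coherent model object", {
  N0 <- 5e4; mu <- 1e-8; L <- 1000
  obs <- sweepqtl:::sim_batch_scaled(120, 8, 12, L, theta = 4 * N0 * mu * L,
                                     tau1 = 0.05, x1 = 0.1, seed = 55)
  fit <- fit_bottleneck(data.frame(S_wild = obs[, "S_wild"],
                                   S_cult = obs[, "S_cult"]),
                        n_wild = 8, n_cult = 12, mu = mu, L = L,
                        n0_grid = c(25e3, 5e4, 1e5),
                        n1_grid = N0 * c(0.05, 0.1, 0.3),
                        t1_grid = 4 * N0 * c(0.01, 0.05, 0.2),
                        R = 800, seed = 56)
  co <- coef(fit)
  expect_named(co, c("N0", "N1", "T1"))
  expect_true(all(co > 0))
  expect_s3_class(fit, "bottleneck_fit")
  expect_output(print(fit), "bottleneck")
  expect_true(is.finite(as.numeric(logLik(fit))))
  # increasing R reduces the between-seed variance of a fixed cell
  cell_ll <- function(R, seed) {
    s <- bottleneck_likelihood_surface(
      obs[, "S_wild"], obs[, "S_cult"], 8, 12, N0 = N0, mu = mu, L = L,
      n1_grid = N0 * 0.1, t1_grid = 4 * N0 * 0.05, R = R, seed = seed)
    s$logL[1, 1]
  }
  lo <- vapply(1:6, function(s) cell_ll(150, s), 0)
  hi <- vapply(1:6, function(s) cell_ll(1200, s + 100), 0)
  expect_lt(sd(hi), sd(lo))
})
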