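# Simulation-based composite-likelihood inference of the domestication
# bottleneck from per-locus segregating-site counts on fixed-length loci
# (per-gene "first 1000 synonymous sites").  Loci are treated as freely
# recombining with no recombination inside (composite likelihood); theta
# converts to N via theta = 4*N*mu per site.

#' Estimate the wild population size N0
#'
#' For each candidate `N0`, simulates `R` neutral single-population loci of
#' the observed length and forms the empirical probability mass of the
#' segregating-site count `S` with add-one smoothing; the composite
#' log-likelihood of the observed wild counts is summed over loci.
#'
#' @param S_wild integer vector of per-locus segregating-site counts in the
#'   wild sample.
#' @param n number of wild haploid sequences.
#' @param L locus length in sites (fixed across loci).
#' @param mu mutation rate per site per generation.
#' @param n0_grid candidate values of `N0` (diploid individuals).
#' @param R simulation replicates per grid value.
#' @param seed integer seed.
#' @return Object of class `n0_curve`: `grid`, `logL`, `mle` (ties broken
#'   toward the largest `N0`).
#' @export
estimate_n0 <- function(S_wild, n, L, mu, n0_grid, R = 2000, seed = 1) {
  if (!length(n0_grid)) stop("empty N0 grid")
  S_wild <- as.integer(S_wild)
  if (length(S_wild) < 50)
    warning("fewer than 50 loci; N0 estimate will be noisy")
  logL <- vapply(seq_along(n0_grid), function(i) {
    theta <- 4 * n0_grid[i] * mu * L
    sim <- sim_batch_scaled(R, n_wild = n, n_cult = 0, L = L, theta = theta,
                            seed = derive_seed(seed, paste0("n0_", i)))
    s <- sim[, "S_wild"]
    smax <- max(s, S_wild) + 1L
    pmf <- (tabulate(s + 1L, nbins = smax + 1L) + 1) / (R + smax + 1L)
    sum(log(pmf[S_wild + 1L]))
  }, 0)
  best <- which(logL == max(logL))
  mle <- max(n0_grid[best])  # tie: least drift (largest N0)
  structure(list(grid = n0_grid, logL = logL, mle = mle,
                 n_loci = length(S_wild), R = R, seed = seed),
            class = "n0_curve")
}

#' @export
print.n0_curve <- function(x, ...) {
  cat("<n0_curve> composite log-likelihood over", length(x$grid),
      "N0 values\n")
  cat("  MLE N0 =", format(x$mle, big.mark = ","), "from", x$n_loci,
      "loci\n")
  invisible(x)
}

#' Bottleneck likelihood surface over (N1, T1)
#'
#' With `N0` fixed, simulates `R` two-population loci per grid cell and bins
#' the joint `(S_wild, S_cult)` into an empirical conditional
#' `P(S_cult | S_wild)` with add-one smoothing over the `S_cult` support;
#' the composite log-likelihood sums `log P(S_cult,obs | S_wild,obs)` over
#' loci.  Observed `S_wild` values never seen in a cell's simulations use
#' the nearest simulated stratum (logged in the object).
#'
#' @param S_wild,S_cult per-locus segregating-site counts (equal length).
#' @param n_wild,n_cult haploid sample sizes.
#' @param N0 wild size (typically `estimate_n0(...)$mle`).
#' @param mu mutation rate per site per generation.
#' @param L locus length in sites.
#' @param n1_grid,t1_grid candidate `N1` (individuals) and `T1`
#'   (generations); defaults are geometric grids `N0 x {0.02..1}` and
#'   `4 N0 x {0.0025..0.5}`.  The two default grids deliberately use
#'   *different* geometric step ratios: with proportional grids every
#'   diagonal cell shares the same bottleneck severity `T1/(2 N1)` — the
#'   quantity that dominates the cultivated site-count distribution — and
#'   the likelihood surface is degenerate along that diagonal.
#' @param R replicates per cell (>= 500 recommended).
#' @param seed integer seed.
#' @return Object of class `likelihood_surface` with the `logL` matrix
#'   (rows = `n1_grid`, cols = `t1_grid`).
#' @export
bottleneck_likelihood_surface <- function(S_wild, S_cult, n_wild, n_cult,
                                          N0, mu, L,
                                          n1_grid = NULL, t1_grid = NULL,
                                          R = 2000, seed = 1) {
  stopifnot(length(S_wild) == length(S_cult))
  if (is.null(n1_grid))
    n1_grid <- N0 * exp(seq(log(0.02), log(1), length.out = 5))
  if (is.null(t1_grid))
    t1_grid <- 4 * N0 * exp(seq(log(0.0025), log(0.5), length.out = 5))
  S_wild <- as.integer(S_wild); S_cult <- as.integer(S_cult)
  theta <- 4 * N0 * mu * L
  logL <- matrix(NA_real_, length(n1_grid), length(t1_grid),
                 dimnames = list(signif(n1_grid, 4), signif(t1_grid, 4)))
  n_fallback <- 0L
  for (i in seq_along(n1_grid)) {
    for (j in seq_along(t1_grid)) {
      tau1 <- t1_grid[j] / (4 * N0)
      x1 <- n1_grid[i] / N0
      sim <- sim_batch_scaled(R, n_wild, n_cult, L, theta,
                              tau1 = tau1, x1 = x1,
                              seed = derive_seed(seed, paste0("cell_", i, "_", j)))
      sw <- sim[, "S_wild"]; sc <- sim[, "S_cult"]
      kmax <- max(sc, S_cult) + 1L
      strata <- sort(unique(sw))
      ll <- 0
      for (k in seq_along(S_wild)) {
        target <- S_wild[k]
        if (!target %in% strata) {
          target <- strata[which.min(abs(strata - target))]
          n_fallback <- n_fallback + 1L
        }
        in_str <- sc[sw == target]
        p <- (sum(in_str == S_cult[k]) + 1) / (length(in_str) + kmax + 1L)
        ll <- ll + log(p)
      }
      logL[i, j] <- ll
    }
  }
  structure(list(n1_grid = n1_grid, t1_grid = t1_grid, logL = logL,
                 N0 = N0, mu = mu, L = L, R = R, seed = seed,
                 n_loci = length(S_wild), n_fallback = n_fallback),
            class = "likelihood_surface")
}

#' @export
print.likelihood_surface <- function(x, ...) {
  cat(sprintf("<likelihood_surface> %d x %d grid (N1 x T1), R = %d, %d loci\n",
              length(x$n1_grid), length(x$t1_grid), x$R, x$n_loci))
  m <- bottleneck_mle(x)
  cat(sprintf("  MLE: N1 = %s, T1 = %s generations\n",
              format(round(m$N1), big.mark = ","),
              format(round(m$T1), big.mark = ",")))
  invisible(x)
}

#' Maximum-likelihood bottleneck parameters from a surface
#'
#' Argmax cell of the composite log-likelihood; ties are broken toward the
#' least extreme bottleneck (largest `N1`, then smallest `T1`).
#'
#' @param surface a `likelihood_surface`.
#' @return List with `N1`, `T1`, grid indices `i`/`j`, and the two profile
#'   log-likelihood curves.
#' @export
bottleneck_mle <- function(surface) {
  L <- surface$logL
  if (all(is.na(L))) stop("likelihood surface contains no finite cells")
  best <- which(L == max(L, na.rm = TRUE), arr.ind = TRUE)
  # largest N1, then smallest T1
  best <- best[order(-best[, 1], best[, 2]), , drop = FALSE][1, ]
  list(N1 = surface$n1_grid[best[1]], T1 = surface$t1_grid[best[2]],
       i = unname(best[1]), j = unname(best[2]),
       profile_n1 = apply(L, 1, max, na.rm = TRUE),
       profile_t1 = apply(L, 2, max, na.rm = TRUE))
}

#' Fit the domestication bottleneck model
#'
#' Full two-stage fit: `N0` from the wild segregating-site counts, then the
#' `(N1, T1)` likelihood surface conditional on that `N0`.  Input loci are
#' fixed-length summaries, typically the first 1000 synonymous sites of each
#' gene (see [locus_summaries()]).
#'
#' @param loci data frame with columns `S_wild` and `S_cult` (one row per
#'   locus).
#' @param n_wild,n_cult haploid sample sizes behind the counts.
#' @param mu mutation rate per site per generation.
#' @param L locus length in sites.
#' @param n0_grid grid for the `N0` stage; default geometric
#'   `{12.5, 25, 50, 100, 200, 400} x 1e3`.
#' @param n1_grid,t1_grid grids for the surface stage (defaults as in
#'   [bottleneck_likelihood_surface()]).
#' @param R simulation replicates per grid point.
#' @param seed integer seed.
#' @return Object of class `bottleneck_fit` with `print()`, `summary()`,
#'   `coef()`, `logLik()` and `plot()` methods.
#' @export
fit_bottleneck <- function(loci, n_wild, n_cult, mu, L = 1000,
                           n0_grid = c(12.5e3, 25e3, 50e3, 1e5, 2e5, 4e5),
                           n1_grid = NULL, t1_grid = NULL,
                           R = 2000, seed = 1) {
  stopifnot(all(c("S_wild", "S_cult") %in% names(loci)))
  n0 <- estimate_n0(loci$S_wild, n_wild, L, mu, n0_grid, R = R,
                    seed = derive_seed(seed, "n0"))
  surf <- bottleneck_likelihood_surface(
    loci$S_wild, loci$S_cult, n_wild, n_cult, N0 = n0$mle, mu = mu, L = L,
    n1_grid = n1_grid, t1_grid = t1_grid, R = R,
    seed = derive_seed(seed, "surface"))
  mle <- bottleneck_mle(surf)
  structure(list(n0_curve = n0, surface = surf, mle = mle,
                 n_wild = n_wild, n_cult = n_cult, mu = mu, L = L,
                 n_loci = nrow(loci), seed = seed),
            class = "bottleneck_fit")
}

#' @export
print.bottleneck_fit <- function(x, ...) {
  cat("Domestication bottleneck fit (simulation-based composite likelihood)\n")
  cat(sprintf("  loci: %d (length %d sites), samples %d wild / %d cultivated\n",
              x$n_loci, x$L, x$n_wild, x$n_cult))
  cat(sprintf("  N0 = %s,  N1 = %s,  T1 = %s generations\n",
              format(x$n0_curve$mle, big.mark = ","),
              format(round(x$mle$N1), big.mark = ","),
              format(round(x$mle$T1), big.mark = ",")))
  invisible(x)
}

#' @export
coef.bottleneck_fit <- function(object, ...) {
  c(N0 = object$n0_curve$mle, N1 = object$mle$N1, T1 = object$mle$T1)
}

#' @export
logLik.bottleneck_fit <- function(object, ...) {
  ll <- max(object$surface$logL, na.rm = TRUE)
  attr(ll, "df") <- 3
  class(ll) <- "logLik"
  ll
}

#' @export
summary.bottleneck_fit <- function(object, ...) {
  co <- coef(object)
  cat("Domestication bottleneck fit\n")
  cat(sprintf("  N0 (wild size): %s\n", format(co["N0"], big.mark = ",")))
  cat(sprintf("  N1 (founding size): %s\n",
              format(round(co["N1"]), big.mark = ",")))
  cat(sprintf("  T1 (founding time): %s generations\n",
              format(round(co["T1"]), big.mark = ",")))
  cat(sprintf("  bottleneck severity T1/(2*N1): %.3f\n",
              co["T1"] / (2 * co["N1"])))
  cat(sprintf("  composite logL at MLE: %.2f (R = %d per cell)\n",
              as.numeric(logLik(object)), object$surface$R))
  if (object$surface$n_fallback > 0)
    cat(sprintf("  note: %d locus evaluations used a nearest S_wild stratum\n",
                object$surface$n_fallback))
  invisible(object)
}

#' Plot a bottleneck fit
#'
#' Left: the `N0` composite log-likelihood curve.  Right: the `(N1, T1)`
#' log-likelihood surface with the MLE cell marked.
#'
#' @param x a `bottleneck_fit`.
#' @param ... ignored.
#' @export
plot.bottleneck_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4.5, 4.5, 2, 1))
  on.exit(graphics::par(op))
  plot(x$n0_curve$grid, x$n0_curve$logL, type = "b", log = "x",
       xlab = "N0", ylab = "composite logL", main = "Wild size")
  graphics::abline(v = x$n0_curve$mle, col = 2, lty = 2)
  graphics::image(log10(x$surface$n1_grid), log10(x$surface$t1_grid),
                  x$surface$logL, xlab = "log10 N1", ylab = "log10 T1",
                  main = "Bottleneck surface",
                  col = grDevices::hcl.colors(24, "viridis"))
  graphics::points(log10(x$mle$N1), log10(x$mle$T1), pch = 0, cex = 2,
                   col = "red", lwd = 2)
  invisible(x)
}

#' Per-gene locus summaries for bottleneck inference
#'
#' Counts segregating sites among the first `n_sites_required` synonymous
#' (fourfold-degenerate) sites of each eligible gene, separately for the
#' wild and cultivated samples.
#'
#' @inheritParams per_gene_synonymous_pi
#' @param wild,cult group names for the two samples.
#' @param max_loci optional cap on the number of genes used (genes are taken
#'   in genomic order).
#' @return Data frame: `gene_id`, `S_wild`, `S_cult`, `length`.
#' @export
locus_summaries <- function(panel, annotation, reference, popmap,
                            wild = "rufipogon", cult = "sativa",
                            n_sites_required = 1000, max_loci = NULL) {
  sw_samples <- intersect(pop_samples(popmap, wild), panel$samples)
  sc_samples <- intersect(pop_samples(popmap, cult), panel$samples)
  out <- list()
  for (gid in annotation$genes$gene_id) {
    syn <- fourfold_sites(annotation, reference, gid)
    if (length(syn) < n_sites_required) next
    use <- syn[seq_len(n_sites_required)]
    g <- annotation$genes[annotation$genes$gene_id == gid, ]
    idx <- which(panel$sites$chrom == g$chrom & panel$sites$pos %in% use)
    count_S <- function(samples) {
      if (!length(idx)) return(0L)
      st <- site_stats(panel_subset_sites(panel, idx), samples)
      sum(st$seg)
    }
    out[[length(out) + 1]] <- data.frame(
      gene_id = gid, S_wild = count_S(sw_samples),
      S_cult = count_S(sc_samples), length = n_sites_required)
    if (!is.null(max_loci) && length(out) >= max_loci) break
  }
  res <- do.call(rbind, out) %||%
    data.frame(gene_id = character(), S_wild = integer(),
               S_cult = integer(), length = integer())
  rownames(res) <- NULL
  res
}
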