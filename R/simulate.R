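# Demographic model, sweep specification and single-locus simulation.

#' Two-population domestication bottleneck model
#'
#' Cultivated lineages live in a population of constant diploid effective
#' size `N1` from the present back to the founding time `T1` (generations),
#' when they merge into the wild population of constant size `N0`.  Partial
#' selfing at rate `s` is handled by the standard equilibrium scaling with
#' inbreeding coefficient `F = s/(2-s)`: effective size `N/(1+F)` and
#' effective recombination `r(1-F)`; lineages are treated as haploid
#' thereafter, matching panels of inbred accessions.
#'
#' The defaults describe the study conditions emulated by the synthetic-data
#' generator: a wild size of 180e3 (the maximum-likelihood estimate reported
#' for *O. rufipogon*), selfing of 95% in both taxa, founding ~9,000
#' generations ago with a founding size chosen so that the expected
#' genome-wide diversity ratio of cultivated to wild is close to the observed
#' ~60%, and order-of-magnitude rice mutation/recombination rates.
#'
#' @param N0 wild diploid effective size (individuals).
#' @param N1 cultivated diploid effective size since founding (individuals).
#' @param T1 founding (split) time in generations before present.
#' @param mu mutation rate per bp per generation.
#' @param rec recombination rate per bp per generation.
#' @param s_wild,s_cult selfing rates in `[0, 1)`.
#' @param sweeps list of [sweep_spec()] objects.
#' @return Object of class `demographic_model`.
#' @export
demographic_model <- function(N0 = 180000, N1 = 17000, T1 = 9000,
                              mu = 6.5e-9, rec = 4e-8,
                              s_wild = 0.95, s_cult = 0.95,
                              sweeps = list()) {
  assert_scalar_num(N0, "N0", 0, strict_lower = TRUE)
  assert_scalar_num(N1, "N1", 0, strict_lower = TRUE)
  assert_scalar_num(T1, "T1", 0, strict_lower = TRUE)
  assert_scalar_num(mu, "mu", 0)
  assert_scalar_num(rec, "rec", 0)
  assert_scalar_num(s_wild, "s_wild", 0, 1 - 1e-12)
  assert_scalar_num(s_cult, "s_cult", 0, 1 - 1e-12)
  if (s_wild >= 1 || s_cult >= 1) stop("selfing rates must be < 1")
  stopifnot(is.list(sweeps))
  for (sw in sweeps) stopifnot(inherits(sw, "sweep_spec"))
  structure(list(N0 = N0, N1 = N1, T1 = T1, mu = mu, rec = rec,
                 s_wild = s_wild, s_cult = s_cult, sweeps = sweeps),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("<demographic_model> two-population split with bottleneck\n")
  cat(sprintf("  N0 = %g, N1 = %g, T1 = %g generations\n", x$N0, x$N1, x$T1))
  cat(sprintf("  mu = %g, rec = %g per bp per generation\n", x$mu, x$rec))
  cat(sprintf("  selfing: wild %.2f, cultivated %.2f; %d sweep(s)\n",
              x$s_wild, x$s_cult, length(x$sweeps)))
  invisible(x)
}

#' Completed selective sweep specification
#'
#' A completed sweep in the cultivated population is modelled through its
#' diversity footprint only (star approximation): at fixation time `t_fix`,
#' every cultivated-ancestry lineage keeps an interval around `pos` drawn so
#' that a site at distance `d` escapes the sweep with probability
#' `1 - exp(-d/lambda)`; all non-escaped material coalesces instantaneously.
#'
#' @param chrom chromosome identifier.
#' @param pos sweep center (bp, 0-based).
#' @param lambda characteristic sweep length (bp).
#' @param t_fix fixation time in generations before present; defaults to the
#'   founding time of the model it is used with.
#' @return Object of class `sweep_spec`.
#' @export
sweep_spec <- function(chrom, pos, lambda, t_fix = NULL) {
  # pos may be negative when expressed relative to a sub-locus of a
  # chromosome; genome-level validation happens in genome_config()
  assert_scalar_num(pos, "pos")
  assert_scalar_num(lambda, "lambda", 0, strict_lower = TRUE)
  if (!is.null(t_fix)) assert_scalar_num(t_fix, "t_fix", 0, strict_lower = TRUE)
  structure(list(chrom = as.character(chrom), pos = pos, lambda = lambda,
                 t_fix = t_fix), class = "sweep_spec")
}

# Convert a model in natural units to coalescent-scaled simulator parameters
# for a locus of length L.  Time unit = 4*N0e generations.
scale_model <- function(model, L) {
  Fw <- model$s_wild / (2 - model$s_wild)
  Fc <- model$s_cult / (2 - model$s_cult)
  N0e <- model$N0 / (1 + Fw)
  N1e <- model$N1 / (1 + Fc)
  list(
    N0e = N0e, N1e = N1e,
    theta = 4 * N0e * model$mu * L,
    rho_w = 4 * N0e * model$rec * (1 - Fw) * L,
    rho_c = 4 * N0e * model$rec * (1 - Fc) * L,
    tau1 = model$T1 / (4 * N0e),
    x1 = N1e / N0e,
    time_unit = 4 * N0e
  )
}

#' Simulate one locus under the bottleneck model
#'
#' Runs the exact ancestral-recombination-graph coalescent for `n_wild` wild
#' and `n_cult` cultivated haploid lineages over a locus of `L` bp, with
#' infinite-sites mutation, optionally hit by a completed sweep in the
#' cultivated population.  Deterministic given `seed`.
#'
#' @param model a [demographic_model()].
#' @param n_wild,n_cult haploid sample sizes (total at least 2; `n_cult = 0`
#'   gives a single constant-size population of size `N0`).
#' @param L locus length in bp.
#' @param sweep optional [sweep_spec()]; its `pos` is interpreted on the
#'   locus coordinate system `[0, L)` (positions outside are allowed and
#'   model a sweep centred beyond the locus edge).
#' @param seed integer seed.
#' @param chrom chromosome name given to the returned sites.
#' @return A [genotype_panel()] with ancestral coding (`ref` = ancestral
#'   allele "A", `alt` = derived "T"), positions rounded to integer bp
#'   (collisions re-drawn to the nearest free base), and a `population_map`
#'   attached as attribute `popmap`.
#' @examples
#' m <- demographic_model(N0 = 1e4, N1 = 2e3, T1 = 400, mu = 1e-7, rec = 0)
#' p <- simulate_locus(m, n_wild = 4, n_cult = 4, L = 5e4, seed = 1)
#' @export
simulate_locus <- function(model, n_wild, n_cult, L, sweep = NULL, seed = 1,
                           chrom = "locus") {
  stopifnot(inherits(model, "demographic_model"))
  assert_scalar_num(L, "L", 0, strict_lower = TRUE)
  if (n_wild + n_cult < 2) stop("n_wild + n_cult must be >= 2")
  sc <- scale_model(model, L)
  sw <- !is.null(sweep)
  spos <- 0; slam <- 1; stau <- sc$tau1
  if (sw) {
    stopifnot(inherits(sweep, "sweep_spec"))
    spos <- sweep$pos
    slam <- sweep$lambda
    tf <- sweep$t_fix %||% model$T1
    if (tf <= 0 || tf > model$T1)
      stop("sweep t_fix must lie in (0, T1]")
    stau <- tf / sc$time_unit
  }
  res <- .cpp_sim_locus(as.integer(n_wild), as.integer(n_cult), L,
                        sc$theta, sc$rho_w, sc$rho_c,
                        max(sc$tau1, 1e-12), sc$x1,
                        sw, spos, slam, stau, as.integer(seed))
  pos <- round_positions(res$pos, L)
  keep <- !is.na(pos)
  popmap <- default_popmap(n_wild, n_cult)
  panel <- genotype_panel(
    geno = res$geno[, keep, drop = FALSE],
    chrom = rep(chrom, sum(keep)),
    pos = pos[keep],
    ref = rep("A", sum(keep)),
    alt = rep("T", sum(keep)),
    samples = names(popmap),
    chrom_lengths = setNames(L, chrom)
  )
  attr(panel, "popmap") <- popmap
  attr(panel, "model") <- model
  panel
}

# Round continuous infinite-sites positions to integer bp; collided positions
# are re-drawn deterministically to the nearest free integer within the
# locus.  Sites with no free base (saturated locus) are dropped (NA).
round_positions <- function(pos, L) {
  p <- as.integer(floor(pos))
  p[p < 0L] <- 0L
  p[p >= L] <- as.integer(L - 1)
  if (!anyDuplicated(p)) return(p)
  used <- new.env(hash = TRUE, size = length(p) * 2)
  out <- integer(length(p))
  for (i in seq_along(p)) {
    q <- p[i]
    off <- 0L
    repeat {
      cand <- q + off
      key <- as.character(cand)
      if (cand >= 0L && cand < L && is.null(used[[key]])) {
        used[[key]] <- TRUE
        out[i] <- cand
        break
      }
      # search outward: 0, +1, -1, +2, -2, ...
      off <- if (off >= 0L) -(off + 1L) else -off
      if (abs(off) > L) {
        out[i] <- NA_integer_
        break
      }
    }
  }
  out
}

#' Batch neutral/bottleneck locus summaries
#'
#' Simulates `R` independent loci and returns per-locus summary statistics,
#' the workhorse behind null distributions, likelihood surfaces and
#' calibration checks.  Columns: `pi_wild`, `pi_cult` (per-locus sums of
#' per-site mean pairwise differences), `S_wild`, `S_cult` (segregating sites
#' within each subsample), `dxy` (sum of between-population mean pairwise
#' differences), `S_total`.
#'
#' @inheritParams simulate_locus
#' @param R number of replicate loci.
#' @return Numeric matrix `R x 6`.
#' @export
simulate_locus_batch <- function(model, n_wild, n_cult, L, R, sweep = NULL,
                                 seed = 1) {
  stopifnot(inherits(model, "demographic_model"))
  sc <- scale_model(model, L)
  sw <- !is.null(sweep)
  spos <- 0; slam <- 1; stau <- sc$tau1
  if (sw) {
    spos <- sweep$pos; slam <- sweep$lambda
    stau <- (sweep$t_fix %||% model$T1) / sc$time_unit
  }
  .cpp_sim_batch(as.integer(R), as.integer(n_wild), as.integer(n_cult), L,
                 sc$theta, sc$rho_w, sc$rho_c, max(sc$tau1, 1e-12), sc$x1,
                 sw, spos, slam, stau, as.integer(seed))
}

# Low-level batch in coalescent-scaled units (used by inference, where theta
# is swept over a grid without constructing full models).
sim_batch_scaled <- function(R, n_wild, n_cult, L, theta, rho_w = 0,
                             rho_c = 0, tau1 = 1, x1 = 1, seed = 1) {
  .cpp_sim_batch(as.integer(R), as.integer(n_wild), as.integer(n_cult), L,
                 theta, rho_w, rho_c, tau1, x1,
                 FALSE, 0, 1, tau1, as.integer(seed))
}

#' Degrade a panel with missing calls and quality/depth annotations
#'
#' Emulates the imperfections of a short-read variant-calling pipeline on a
#' clean simulated panel: each call is independently set missing with
#' probability `missing_rate`, and each site receives a quality score and a
#' read depth drawn from simple parametric models.  Sites monomorphic after
#' degradation are dropped (the count is recorded in attribute
#' `n_monomorphic_dropped`).
#'
#' @param panel a [genotype_panel()].
#' @param missing_rate per-call missingness probability in `[0, 1)`.
#' @param qual_model list with `mean` and `sd`: normal quality scores,
#'   truncated at 1.
#' @param depth_model list with `meanlog` and `sdlog`: log-normal depths.
#' @param seed integer seed.
#' @return The degraded [genotype_panel()].
#' @export
degrade_panel <- function(panel, missing_rate = 0.03,
                          qual_model = list(mean = 220, sd = 80),
                          depth_model = list(meanlog = log(25), sdlog = 0.6),
                          seed = 1) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  g <- panel$geno
  if (missing_rate > 0) {
    drop <- matrix(runif(length(g)) < missing_rate, nrow = nrow(g))
    g[drop] <- NA_integer_
  }
  S <- ncol(g)
  panel$geno <- g
  panel$sites$qual <- pmax(1, rnorm(S, qual_model$mean, qual_model$sd))
  panel$sites$depth <- pmax(1, round(rlnorm(S, depth_model$meanlog,
                                            depth_model$sdlog)))
  drop_monomorphic(panel)
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
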