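# Core diversity estimators: per-site pi, windowed pi / Watterson's theta,
# per-gene synonymous diversity, Hudson F_ST, LD decay.

#' Per-site nucleotide diversity from haploid calls
#'
#' Average number of pairwise differences among the non-missing calls at a
#' single site: `(# differing pairs) / C(n_called, 2)`.
#'
#' @param calls vector of haploid-coded calls (0/1, or any two values) with
#'   `NA` for missing.
#' @return Per-site diversity, or `NA` when fewer than 2 calls are present.
#' @examples
#' site_pi(c(0, 0, 1, 1))  # 4 differing pairs / 6 = 2/3
#' @export
site_pi <- function(calls) {
  calls <- calls[!is.na(calls)]
  n <- length(calls)
  if (n < 2) return(NA_real_)
  tab <- table(calls)
  diff_pairs <- (n * (n - 1) / 2) - sum(tab * (tab - 1) / 2)
  diff_pairs / (n * (n - 1) / 2)
}

# Vectorized site-level quantities for a sample subset of a panel.
# Returns a data.frame with n_called, n_derived, pi (mean pairwise diff),
# theta_site (1/a_{n_called - 1} if segregating in the subset else 0), and
# seg (logical).
site_stats <- function(panel, samples) {
  g <- panel$geno[samples, , drop = FALSE]
  n_called <- colSums(!is.na(g))
  n_der <- colSums(g == 1L, na.rm = TRUE)
  seg <- n_der > 0L & n_der < n_called
  pi <- rep(NA_real_, ncol(g))
  ok <- n_called >= 2
  pi[ok] <- 2 * n_der[ok] * (n_called[ok] - n_der[ok]) /
    (n_called[ok] * (n_called[ok] - 1))
  th <- rep(0, ncol(g))
  th[ok & seg] <- 1 / harmonic_number(n_called[ok & seg] - 1)
  data.frame(n_called = n_called, n_derived = n_der, pi = pi,
             theta_site = th, seg = seg)
}

#' Build a sliding window grid
#'
#' Windows `[k*step, k*step + size)` for `k = 0, 1, ...` while the start lies
#' inside the chromosome; windows running past the end are truncated there
#' and flagged.
#'
#' @param chrom_length chromosome length in bp.
#' @param size window size in bp.
#' @param step step between window starts in bp (`0 < step <= size`).
#' @return Data frame with `start`, `end` (0-based half-open) and
#'   `truncated`.
#' @examples
#' nrow(sliding_windows(1e6, 5e5, 2e4))  # 50 windows
#' @export
sliding_windows <- function(chrom_length, size = 5e5, step = 2e4) {
  assert_scalar_num(size, "size", 0, strict_lower = TRUE)
  assert_scalar_num(step, "step", 0, strict_lower = TRUE)
  if (step > size) stop("step must be <= window size")
  if (chrom_length <= size) {
    # degenerate case: one truncated window spanning the whole chromosome
    return(data.frame(start = 0, end = chrom_length,
                      truncated = chrom_length < size))
  }
  starts <- seq(0, max(0, chrom_length - 1), by = step)
  starts <- starts[starts < chrom_length]
  ends <- pmin(starts + size, chrom_length)
  data.frame(start = starts, end = ends, truncated = (starts + size) > chrom_length)
}

#' Windowed diversity for one population
#'
#' Per window: `pi = sum(site_pi) / callable`, `theta_W =
#' sum(1/a_{n_i - 1}) / callable` over segregating sites (monomorphic
#' callable sites contribute 0 to the numerators and 1 to the callable
#' denominator), where `n_i` is the called-sample count at site `i`.
#'
#' @param panel a [genotype_panel()].
#' @param popmap a [population_map()].
#' @param chrom chromosome to scan.
#' @param population group name understood by [pop_samples()].
#' @param grid window grid from [sliding_windows()]; built from the panel's
#'   chromosome length when `NULL`.
#' @param callable_regions optional data frame (`start`, `end`, 0-based
#'   half-open) of surveyed intervals on `chrom` (e.g. gene regions); the
#'   callable denominator of a window is its overlap with these intervals.
#'   When `NULL` the full window width is used.
#' @param size,step window geometry when `grid` is `NULL`.
#' @return Data frame: `chrom`, `start`, `end`, `truncated`, `callable`,
#'   `S`, `pi`, `theta_w` (`NA` for windows with zero callable sites).
#' @export
window_diversity <- function(panel, popmap, chrom, population = "sativa",
                             grid = NULL, callable_regions = NULL,
                             size = 5e5, step = 2e4) {
  samples <- pop_samples(popmap, population)
  samples <- intersect(samples, panel$samples)
  if (!length(samples)) stop("no panel samples in population ", population)
  on_chr <- which(panel$sites$chrom == chrom)
  sub <- panel_subset_sites(panel, on_chr)
  if (is.null(grid)) {
    len <- panel$chrom_lengths[chrom]
    if (is.na(len) || is.null(len))
      len <- if (length(on_chr)) max(sub$sites$pos) + 1 else size
    grid <- sliding_windows(len, size, step)
  }
  st <- site_stats(sub, samples)
  pos <- sub$sites$pos
  cum_pi <- cumsum(ifelse(is.na(st$pi), 0, st$pi))
  cum_th <- cumsum(st$theta_site)
  cum_S <- cumsum(as.integer(st$seg))
  idx <- function(x) findInterval(x - 0.5, pos)
  lo <- idx(grid$start)
  hi <- idx(grid$end)
  pick <- function(cum, i) ifelse(i > 0, cum[pmax(i, 1)], 0)
  w_pi <- pick(cum_pi, hi) - pick(cum_pi, lo)
  w_th <- pick(cum_th, hi) - pick(cum_th, lo)
  w_S <- pick(cum_S, hi) - pick(cum_S, lo)
  callable <- if (is.null(callable_regions)) {
    grid$end - grid$start
  } else {
    interval_overlap_bp(grid$start, grid$end,
                        callable_regions$start, callable_regions$end)
  }
  out <- data.frame(
    chrom = chrom, start = grid$start, end = grid$end,
    truncated = grid$truncated, callable = callable, S = w_S,
    pi = ifelse(callable > 0, w_pi / callable, NA_real_),
    theta_w = ifelse(callable > 0, w_th / callable, NA_real_)
  )
  attr(out, "population") <- population
  out
}

#' Windowed diversity-ratio track for a population pair
#'
#' Computes windowed pi and Watterson's theta for a numerator (cultivated)
#' and denominator (wild) group on every chromosome and forms the ratios
#' `pi_num/pi_den` and `theta_num/theta_den` scanned by the sweep test.
#' Ratios are `NA` where the denominator group has zero diversity in the
#' window.
#'
#' @inheritParams window_diversity
#' @param num,den population/group names for the ratio numerator and
#'   denominator.
#' @param callable_regions optional data frame with `chrom`, `start`, `end`
#'   of surveyed intervals (0-based half-open).
#' @return A `window_track` data frame with per-window diversity for both
#'   groups and the two ratios; window geometry is kept in attributes.
#' @export
diversity_ratio_track <- function(panel, popmap, num = "sativa",
                                  den = "rufipogon", size = 5e5, step = 2e4,
                                  callable_regions = NULL) {
  chroms <- unique(panel$sites$chrom)
  res <- lapply(chroms, function(ch) {
    cr <- if (is.null(callable_regions)) NULL
          else callable_regions[callable_regions$chrom == ch, , drop = FALSE]
    a <- window_diversity(panel, popmap, ch, num, callable_regions = cr,
                          size = size, step = step)
    b <- window_diversity(panel, popmap, ch, den, callable_regions = cr,
                          size = size, step = step)
    data.frame(
      chrom = ch, start = a$start, end = a$end, truncated = a$truncated,
      callable = a$callable,
      S_num = a$S, S_den = b$S,
      pi_num = a$pi, pi_den = b$pi,
      theta_num = a$theta_w, theta_den = b$theta_w,
      ratio_pi = ifelse(!is.na(b$pi) & b$pi > 0, a$pi / b$pi, NA_real_),
      ratio_theta = ifelse(!is.na(b$theta_w) & b$theta_w > 0,
                           a$theta_w / b$theta_w, NA_real_)
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("window_track", "data.frame")
  attr(out, "window") <- size
  attr(out, "step") <- step
  attr(out, "populations") <- c(num = num, den = den)
  out
}

#' Hudson's F_ST for a pair of groups
#'
#' Ratio-of-sums Hudson estimator over the chosen sites:
#' `F_ST = 1 - (sum within) / (sum between)` where the within term averages
#' the two per-population mean pairwise differences per site and the between
#' term is the mean between-population pairwise difference per site.
#'
#' @param panel a [genotype_panel()].
#' @param popmap a [population_map()].
#' @param pop_a,pop_b group names understood by [pop_samples()].
#' @param sites optional integer site indices restricting the computation
#'   (defaults to all sites).
#' @return F_ST value (`NA` when the between-population denominator is 0).
#' @export
hudson_fst <- function(panel, popmap, pop_a, pop_b, sites = NULL) {
  sa <- intersect(pop_samples(popmap, pop_a), panel$samples)
  sb <- intersect(pop_samples(popmap, pop_b), panel$samples)
  if (length(sa) < 2 || length(sb) < 2)
    stop("both populations need >= 2 samples in the panel")
  idx <- sites %||% seq_len(n_sites(panel))
  comp <- fst_components(panel, sa, sb, idx)
  if (comp$between <= 0) return(NA_real_)
  1 - comp$within / comp$between
}

# Within/between sums for Hudson F_ST over the given site indices.
fst_components <- function(panel, samples_a, samples_b, idx) {
  ga <- panel$geno[samples_a, idx, drop = FALSE]
  gb <- panel$geno[samples_b, idx, drop = FALSE]
  na_ <- colSums(!is.na(ga)); xa <- colSums(ga == 1L, na.rm = TRUE)
  nb_ <- colSums(!is.na(gb)); xb <- colSums(gb == 1L, na.rm = TRUE)
  ok <- na_ >= 2 & nb_ >= 2
  pia <- 2 * xa * (na_ - xa) / (na_ * (na_ - 1))
  pib <- 2 * xb * (nb_ - xb) / (nb_ * (nb_ - 1))
  dxy <- (xa * (nb_ - xb) + xb * (na_ - xa)) / (na_ * nb_)
  list(within = sum((pia[ok] + pib[ok]) / 2),
       between = sum(dxy[ok]),
       n_sites = sum(ok))
}

#' Per-site Hudson F_ST values
#'
#' @inheritParams hudson_fst
#' @return Numeric vector, one value per selected site (`NA` where either
#'   group has < 2 calls or the between term is 0).
#' @export
per_site_fst <- function(panel, popmap, pop_a, pop_b, sites = NULL) {
  sa <- intersect(pop_samples(popmap, pop_a), panel$samples)
  sb <- intersect(pop_samples(popmap, pop_b), panel$samples)
  idx <- sites %||% seq_len(n_sites(panel))
  ga <- panel$geno[sa, idx, drop = FALSE]
  gb <- panel$geno[sb, idx, drop = FALSE]
  na_ <- colSums(!is.na(ga)); xa <- colSums(ga == 1L, na.rm = TRUE)
  nb_ <- colSums(!is.na(gb)); xb <- colSums(gb == 1L, na.rm = TRUE)
  pia <- 2 * xa * (na_ - xa) / (na_ * (na_ - 1))
  pib <- 2 * xb * (nb_ - xb) / (nb_ * (nb_ - 1))
  dxy <- (xa * (nb_ - xb) + xb * (na_ - xa)) / (na_ * nb_)
  out <- 1 - ((pia + pib) / 2) / dxy
  out[na_ < 2 | nb_ < 2 | dxy <= 0] <- NA_real_
  out
}

#' Per-gene synonymous nucleotide diversity
#'
#' For each gene, takes the synonymous-class (fourfold-degenerate) reference
#' sites in transcript order from the translation start; genes with at least
#' `n_sites_required` such sites are retained and pi is computed on exactly
#' the first `n_sites_required` of them (segregating or not), correcting for
#' gene-length differences.
#'
#' @param panel a [genotype_panel()] whose site classes are set.
#' @param annotation a `gene_annotation` (see [read_gene_annotation()]).
#' @param reference named `DNAStringSet` reference sequences.
#' @param popmap a [population_map()].
#' @param population group name.
#' @param n_sites_required number of synonymous sites used per gene.
#' @return Data frame: `gene_id`, `n_syn_sites` (available), `used`,
#'   `S`, `pi` (`NA` with `reason` for excluded genes).
#' @export
per_gene_synonymous_pi <- function(panel, annotation, reference, popmap,
                                   population = "sativa",
                                   n_sites_required = 1000) {
  if (is.null(annotation)) stop("gene annotation required")
  samples <- intersect(pop_samples(popmap, population), panel$samples)
  res <- lapply(annotation$genes$gene_id, function(gid) {
    syn <- fourfold_sites(annotation, reference, gid)
    n_avail <- length(syn)
    if (n_avail < n_sites_required)
      return(data.frame(gene_id = gid, n_syn_sites = n_avail, used = 0L,
                        S = NA_integer_, pi = NA_real_,
                        reason = "too_few_synonymous_sites"))
    use <- syn[seq_len(n_sites_required)]
    g <- annotation$genes[annotation$genes$gene_id == gid, ]
    idx <- which(panel$sites$chrom == g$chrom & panel$sites$pos %in% use)
    if (length(idx)) {
      st <- site_stats(panel_subset_sites(panel, idx), samples)
      S <- sum(st$seg)
      pi_sum <- sum(st$pi, na.rm = TRUE)
    } else {
      S <- 0L; pi_sum <- 0
    }
    data.frame(gene_id = gid, n_syn_sites = n_avail,
               used = n_sites_required, S = as.integer(S),
               pi = pi_sum / n_sites_required, reason = NA_character_)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Linkage-disequilibrium decay
#'
#' Mean `r^2` between intra-chromosomal SNP pairs as a function of physical
#' distance, averaged within distance bins.  For each pair, samples called at
#' both sites are used, optionally randomly subsampled to a common size so
#' that populations of different sizes are comparable.
#'
#' @param panel a [genotype_panel()].
#' @param popmap a [population_map()].
#' @param population group name.
#' @param max_dist maximum pair distance in bp.
#' @param bin_bp distance bin width in bp.
#' @param subsample optional common sample size per pair.
#' @param seed integer seed for the per-pair subsampling.
#' @param min_joint minimum number of jointly called samples for a pair.
#' @return Data frame: `bin_start`, `bin_mid`, `mean_r2`, `n_pairs`.
#' @export
ld_r2_decay <- function(panel, popmap, population, max_dist = 1e6,
                        bin_bp = 2000, subsample = NULL, seed = 1,
                        min_joint = 4) {
  samples <- intersect(pop_samples(popmap, population), panel$samples)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  g <- panel$geno[samples, , drop = FALSE]
  chrom <- panel$sites$chrom
  pos <- panel$sites$pos
  nb <- ceiling(max_dist / bin_bp)
  sums <- numeric(nb + 1)  # last bin catches distance-0 duplicated sites
  cnts <- integer(nb + 1)
  r2_sum0 <- 0; n0 <- 0L
  for (ch in unique(chrom)) {
    on_ch <- which(chrom == ch)
    p <- pos[on_ch]
    for (ii in seq_along(on_ch)) {
      i <- on_ch[ii]
      jj <- ii + 1L
      while (jj <= length(on_ch) && p[jj] - p[ii] <= max_dist) {
        j <- on_ch[jj]
        jj <- jj + 1L
        both <- which(!is.na(g[, i]) & !is.na(g[, j]))
        if (length(both) < max(min_joint, subsample %||% 0)) next
        if (!is.null(subsample) && length(both) > subsample)
          both <- sample(both, subsample)
        a <- g[both, i]; b <- g[both, j]
        p1 <- mean(a); p2 <- mean(b)
        if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1) next
        D <- mean(a * b) - p1 * p2
        r2 <- D^2 / (p1 * (1 - p1) * p2 * (1 - p2))
        d <- pos[j] - pos[i]
        if (d == 0) {
          r2_sum0 <- r2_sum0 + r2; n0 <- n0 + 1L
        } else {
          bi <- ceiling(d / bin_bp)
          sums[bi] <- sums[bi] + r2
          cnts[bi] <- cnts[bi] + 1L
        }
      }
    }
  }
  bins <- data.frame(
    bin_start = c(0, (seq_len(nb) - 1) * bin_bp),
    bin_mid = c(0, (seq_len(nb) - 0.5) * bin_bp),
    mean_r2 = c(if (n0 > 0) r2_sum0 / n0 else NA_real_,
                ifelse(cnts[seq_len(nb)] > 0, sums[seq_len(nb)] / cnts[seq_len(nb)], NA_real_)),
    n_pairs = c(n0, cnts[seq_len(nb)])
  )
  bins
}
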