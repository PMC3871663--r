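# Windowed F_ST differentiation scans between subspecies / subgroups and
# extraction of maximal-differentiation regions.

#' Windowed Hudson F_ST scan between two groups
#'
#' Per-window ratio-of-sums Hudson F_ST over every chromosome.  Windows
#' where either group has fewer than 2 called samples at every site (or no
#' sites at all) are marked undefined.  Negative values are retained in the
#' track (they never rank as peaks).
#'
#' @param panel a [genotype_panel()].
#' @param popmap a [population_map()].
#' @param pops length-2 character vector of group names (e.g.
#'   `c("indica", "japonica")` or
#'   `c("japonica_temperate", "japonica_tropical")`).
#' @param size,step window geometry in bp.
#' @return A `window_track` data frame with columns `chrom`, `start`,
#'   `end`, `truncated`, `n_sites` and `fst`.
#' @export
fst_scan <- function(panel, popmap, pops, size = 5e5, step = 2e4) {
  stopifnot(length(pops) == 2)
  sa <- intersect(pop_samples(popmap, pops[1]), panel$samples)
  sb <- intersect(pop_samples(popmap, pops[2]), panel$samples)
  if (length(sa) < 2 || length(sb) < 2)
    stop("both groups need >= 2 panel samples")
  out <- lapply(unique(panel$sites$chrom), function(ch) {
    on_chr <- which(panel$sites$chrom == ch)
    sub <- panel_subset_sites(panel, on_chr)
    len <- panel$chrom_lengths[ch]
    if (is.na(len) || is.null(len))
      len <- if (length(on_chr)) max(sub$sites$pos) + 1 else size
    grid <- sliding_windows(len, size, step)
    ga <- sub$geno[sa, , drop = FALSE]
    gb <- sub$geno[sb, , drop = FALSE]
    na_ <- colSums(!is.na(ga)); xa <- colSums(ga == 1L, na.rm = TRUE)
    nb_ <- colSums(!is.na(gb)); xb <- colSums(gb == 1L, na.rm = TRUE)
    ok <- na_ >= 2 & nb_ >= 2
    w_in <- ifelse(ok, (2 * xa * (na_ - xa) / (na_ * (na_ - 1)) +
                        2 * xb * (nb_ - xb) / (nb_ * (nb_ - 1))) / 2, 0)
    w_bt <- ifelse(ok, (xa * (nb_ - xb) + xb * (na_ - xa)) / (na_ * nb_), 0)
    pos <- sub$sites$pos
    cum_in <- cumsum(w_in); cum_bt <- cumsum(w_bt); cum_n <- cumsum(ok)
    pick <- function(cum, i) ifelse(i > 0, cum[pmax(i, 1)], 0)
    lo <- findInterval(grid$start - 0.5, pos)
    hi <- findInterval(grid$end - 0.5, pos)
    wi <- pick(cum_in, hi) - pick(cum_in, lo)
    bt <- pick(cum_bt, hi) - pick(cum_bt, lo)
    ns <- pick(cum_n, hi) - pick(cum_n, lo)
    data.frame(chrom = ch, start = grid$start, end = grid$end,
               truncated = grid$truncated, n_sites = ns,
               fst = ifelse(ns > 0 & bt > 0, 1 - wi / bt, NA_real_))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("window_track", "data.frame")
  attr(res, "window") <- size
  attr(res, "step") <- step
  attr(res, "populations") <- pops
  res
}

#' Top differentiation regions from an F_ST track
#'
#' Returns the `K` highest-F_ST regions after merging runs of overlapping
#' or abutting peak windows.  Candidate peak windows are those exceeding the
#' `quantile_floor` of the defined window values (so a "region" is a
#' contiguous stretch of elevated differentiation, ranked by its peak).
#' Ties break toward the leftmost region.  Negative-F_ST windows never
#' qualify.
#'
#' @param track output of [fst_scan()].
#' @param K number of regions to return.
#' @param quantile_floor quantile of defined window F_ST above which windows
#'   may support a region.
#' @param include_truncated rank truncated terminal windows too.
#' @return Data frame: `label`, `chrom`, `start`, `end`, `peak_fst`,
#'   `n_windows`, ordered by decreasing `peak_fst`.
#' @export
top_fst_regions <- function(track, K = 1, quantile_floor = 0.99,
                            include_truncated = FALSE) {
  stopifnot("fst" %in% names(track))
  elig <- !is.na(track$fst) & track$fst > 0
  if (!include_truncated) elig <- elig & !track$truncated
  empty <- data.frame(label = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      peak_fst = numeric(), n_windows = integer())
  if (!any(elig)) return(empty)
  thr <- quantile(track$fst[elig], quantile_floor, names = FALSE)
  cand <- which(elig & track$fst >= thr)
  d <- track[cand, , drop = FALSE]
  d <- d[order(d$chrom, d$start), , drop = FALSE]
  grp <- cumsum(c(TRUE, d$chrom[-1] != d$chrom[-nrow(d)] |
                    d$start[-1] > d$end[-nrow(d)]))
  regions <- do.call(rbind, lapply(split(d, grp), function(g) {
    data.frame(chrom = g$chrom[1], start = min(g$start), end = max(g$end),
               peak_fst = max(g$fst), n_windows = nrow(g))
  }))
  regions <- regions[order(-regions$peak_fst, regions$chrom, regions$start), ,
                     drop = FALSE]
  regions <- head(regions, K)
  regions <- cbind(label = sprintf("F%02d", seq_len(nrow(regions))), regions)
  rownames(regions) <- NULL
  regions
}

#' Permutation threshold for window F_ST
#'
#' Empirical null for the differentiation scan: group labels are permuted
#' across the pooled samples and the scan repeated; the given quantile of
#' permuted window F_ST values provides a reference threshold.  This
#' thresholding is an addition of this package (the descriptive peak-picking
#' itself states no significance), and is flagged as such in the output.
#'
#' @inheritParams fst_scan
#' @param n_perm number of label permutations.
#' @param probs quantile(s) to report.
#' @param seed integer seed.
#' @return List with `threshold` (named quantiles of permuted window F_ST)
#'   and `n_perm`; attribute `note` marks it as a package addition.
#' @export
fst_permutation_threshold <- function(panel, popmap, pops, size = 5e5,
                                      step = 2e4, n_perm = 20, probs = 0.99,
                                      seed = 1) {
  sa <- intersect(pop_samples(popmap, pops[1]), panel$samples)
  sb <- intersect(pop_samples(popmap, pops[2]), panel$samples)
  pool <- c(sa, sb)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  vals <- unlist(lapply(seq_len(n_perm), function(i) {
    pa <- sample(pool, length(sa))
    pm <- population_map(pool, ifelse(pool %in% pa, "indica", "rufipogon"))
    tr <- fst_scan(panel, pm, c("indica", "rufipogon"), size, step)
    tr$fst[!is.na(tr$fst)]
  }))
  structure(list(threshold = quantile(vals, probs), n_perm = n_perm,
                 note = "permutation threshold is a package addition"),
            class = "fst_threshold")
}
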