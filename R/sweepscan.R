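# Simulation-null scoring of windowed diversity ratios and top-K region
# calling: the headline sweep-detection statistic.

#' Build the neutral null distribution of windowed diversity ratios
#'
#' Simulates `R` independent window-sized loci under the neutral
#' two-population bottleneck model (exact ARG engine) and records, per
#' replicate, the cultivated/wild ratios of pi and of Watterson's theta.
#' Replicates with zero wild diversity are re-drawn (count logged).
#'
#' @param model a [demographic_model()] — typically the fitted bottleneck
#'   ([fit_bottleneck()]) parameters.
#' @param n_wild,n_cult haploid sample sizes matching the observed panel.
#' @param window_bp window size in bp; must match the scanned track.
#' @param R number of replicates (the full-scale analysis uses 1e5; desk
#'   default 1e4).
#' @param seed integer seed.
#' @return Object of class `sweep_null` holding the two sorted ratio
#'   vectors.
#' @export
build_null_distribution <- function(model, n_wild, n_cult, window_bp = 5e5,
                                    R = 10000, seed = 1) {
  stopifnot(inherits(model, "demographic_model"))
  if (R < 1000) warning("null distribution with R < 1000 is very coarse")
  aw <- harmonic_number(n_wild - 1)
  ac <- harmonic_number(n_cult - 1)
  ratios_pi <- numeric(0)
  ratios_th <- numeric(0)
  n_redrawn <- 0L
  round_i <- 0L
  need <- R
  while (need > 0) {
    round_i <- round_i + 1L
    if (round_i > 50) stop("null simulation kept producing zero wild diversity")
    sim <- simulate_locus_batch(model, n_wild, n_cult, window_bp, R = need,
                                seed = derive_seed(seed, paste0("null", round_i)))
    ok <- sim[, "pi_wild"] > 0 & sim[, "S_wild"] > 0
    n_redrawn <- n_redrawn + sum(!ok)
    ratios_pi <- c(ratios_pi, sim[ok, "pi_cult"] / sim[ok, "pi_wild"])
    ratios_th <- c(ratios_th, (sim[ok, "S_cult"] / ac) / (sim[ok, "S_wild"] / aw))
    need <- R - length(ratios_pi)
  }
  structure(list(ratio_pi = sort(ratios_pi), ratio_theta = sort(ratios_th),
                 R = R, window_bp = window_bp, n_wild = n_wild,
                 n_cult = n_cult, model = model, n_redrawn = n_redrawn,
                 seed = seed),
            class = "sweep_null")
}

#' @export
print.sweep_null <- function(x, ...) {
  cat(sprintf("<sweep_null> R = %d window-sized (%g kb) neutral replicates\n",
              x$R, x$window_bp / 1000))
  cat(sprintf("  mean pi ratio %.3f, mean theta ratio %.3f (%d re-drawn)\n",
              mean(x$ratio_pi), mean(x$ratio_theta), x$n_redrawn))
  invisible(x)
}

#' Score observed windows against a simulation null
#'
#' The empirical p-value of a window is the proportion of null replicates
#' with a ratio at or below the observed one, with a pseudocount:
#' `p = (#\{sim <= obs\} + 1) / (R + 1)`; the score is `logP = -log10(p)`.
#' Windows with undefined ratios get `NA` scores.
#'
#' @param track a `window_track` from [diversity_ratio_track()].
#' @param null a `sweep_null` built with the same window size.
#' @return The track with `logp_pi` and `logp_theta` columns added.
#' @export
score_windows <- function(track, null) {
  stopifnot(inherits(null, "sweep_null"))
  if (!is.null(attr(track, "window")) &&
      !isTRUE(all.equal(attr(track, "window"), null$window_bp)))
    stop("track window size does not match null window size")
  score <- function(obs, sorted_null) {
    cnt <- findInterval(obs, sorted_null)  # replicates <= obs
    p <- (cnt + 1) / (length(sorted_null) + 1)
    ifelse(is.na(obs), NA_real_, -log10(p))
  }
  track$logp_pi <- score(track$ratio_pi, null$ratio_pi)
  track$logp_theta <- score(track$ratio_theta, null$ratio_theta)
  track
}

#' Call candidate sweep regions from scored windows
#'
#' Windows are ranked separately by `logp_pi` and `logp_theta` (descending;
#' ties broken by the lower observed ratio, then the leftmost coordinate).
#' Windows inside the top `K` of *both* rankings are kept and merged into
#' regions when they overlap or abut; regions are labelled `S01`, `S02`, ...
#' in genomic order.
#'
#' @param track a scored track from [score_windows()].
#' @param K rank cutoff applied to each measure.
#' @param include_truncated rank truncated terminal windows too (default
#'   drops them from ranking, though they remain in the track).
#' @return Data frame of class `sweep_regions`: `label`, `chrom`, `start`,
#'   `end`, `n_windows`, `best_logp_pi`, `best_logp_theta`, `best_rank_pi`,
#'   `best_rank_theta`.
#' @export
call_sweep_regions <- function(track, K = 15, include_truncated = FALSE) {
  stopifnot(all(c("logp_pi", "logp_theta") %in% names(track)))
  elig <- !is.na(track$logp_pi) & !is.na(track$logp_theta)
  if (!include_truncated) elig <- elig & !track$truncated
  empty <- data.frame(label = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_windows = integer(), best_logp_pi = numeric(),
                      best_logp_theta = numeric(), best_rank_pi = integer(),
                      best_rank_theta = integer())
  class(empty) <- c("sweep_regions", "data.frame")
  if (!any(elig)) return(empty)
  idx <- which(elig)
  rank_of <- function(logp, ratio) {
    o <- order(-logp[idx], ratio[idx], track$chrom[idx], track$start[idx])
    r <- integer(length(idx)); r[o] <- seq_along(idx)
    r
  }
  r_pi <- rank_of(track$logp_pi, track$ratio_pi)
  r_th <- rank_of(track$logp_theta, track$ratio_theta)
  keep <- idx[r_pi <= K & r_th <= K]
  if (!length(keep)) return(empty)
  kw <- data.frame(chrom = track$chrom[keep], start = track$start[keep],
                   end = track$end[keep],
                   logp_pi = track$logp_pi[keep],
                   logp_theta = track$logp_theta[keep],
                   rank_pi = r_pi[r_pi <= K & r_th <= K],
                   rank_theta = r_th[r_pi <= K & r_th <= K])
  kw <- kw[order(kw$chrom, kw$start), , drop = FALSE]
  # merge overlapping or abutting windows
  regions <- list()
  cur <- kw[1, ]
  acc <- list(cur)
  flush <- function(acc) {
    d <- do.call(rbind, acc)
    data.frame(chrom = d$chrom[1], start = min(d$start), end = max(d$end),
               n_windows = nrow(d), best_logp_pi = max(d$logp_pi),
               best_logp_theta = max(d$logp_theta),
               best_rank_pi = min(d$rank_pi),
               best_rank_theta = min(d$rank_theta))
  }
  out <- list()
  for (i in seq_len(nrow(kw))[-1]) {
    w <- kw[i, ]
    if (w$chrom == cur$chrom && w$start <= cur$end) {
      acc[[length(acc) + 1]] <- w
      cur$end <- max(cur$end, w$end)
    } else {
      out[[length(out) + 1]] <- flush(acc)
      cur <- w
      acc <- list(w)
    }
  }
  out[[length(out) + 1]] <- flush(acc)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  res <- cbind(label = sprintf("S%02d", seq_len(nrow(res))), res)
  rownames(res) <- NULL
  class(res) <- c("sweep_regions", "data.frame")
  res
}

#' Plot a scored sweep-scan track
#'
#' logP along the genome for both measures, with called regions shaded.
#'
#' @param x a scored `window_track`.
#' @param regions optional `sweep_regions` to highlight.
#' @param ... ignored.
#' @export
plot_sweep_scan <- function(x, regions = NULL, ...) {
  stopifnot("logp_pi" %in% names(x))
  chroms <- unique(x$chrom)
  op <- graphics::par(mfrow = c(length(chroms), 1), mar = c(3.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  for (ch in chroms) {
    d <- x[x$chrom == ch, ]
    plot(d$start / 1e6, d$logp_pi, type = "l", ylim = range(
      c(d$logp_pi, d$logp_theta), na.rm = TRUE, finite = TRUE),
      xlab = "position (Mb)", ylab = "logP", main = ch)
    graphics::lines(d$start / 1e6, d$logp_theta, col = "grey50")
    if (!is.null(regions)) {
      r <- regions[regions$chrom == ch, ]
      if (nrow(r))
        graphics::rect(r$start / 1e6, graphics::par("usr")[3], r$end / 1e6,
                       graphics::par("usr")[4],
                       col = grDevices::adjustcolor("red", 0.15), border = NA)
    }
  }
  invisible(x)
}
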