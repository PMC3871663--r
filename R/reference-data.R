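# Bundled reference table.

#' Published diversity summary of the motivating rice panel
#'
#' The genome-wide SNP and nucleotide-diversity summary of the 32-accession
#' wild/cultivated rice resequencing panel that motivates this package: per
#' group (all accessions, *O. rufipogon*, *O. sativa*, *indica*,
#' *japonica*) and per site partition (all gene-region sites, CDS, non-CDS),
#' the sample size, SNP count, pi and Watterson's theta (both x100), and
#' the surveyed length in bp.  Used for the package's printed-arithmetic
#' cross-checks (diversity ratios between groups and the Watterson estimate
#' recomputed from the SNP count).
#'
#' @return Data frame with columns `group`, `n`, `region`, `snps`,
#'   `pi_x100`, `theta_w_x100`, `length_bp`.
#' @examples
#' d <- rice_diversity_summary()
#' all_row <- d[d$group == "all" & d$region == "all", ]
#' # Watterson's theta recomputed from printed S, L, n:
#' theta_w_from_counts(all_row$snps, all_row$length_bp, all_row$n) * 100
#' @export
rice_diversity_summary <- function() {
  path <- system.file("extdata", "rice_panel_diversity.tsv",
                      package = "sweepqtl", mustWork = TRUE)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
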