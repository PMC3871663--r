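# Genotype panel and population map containers.
#
# A panel holds haploid-coded calls for near-homozygous (inbred) accessions:
# 0 = reference/ancestral allele, 1 = alternate/derived allele, NA = missing.
# Coordinates are 0-based half-open internally; conversion to the 1-based
# conventions of VCF/GFF3 happens only at the I/O boundary.

#' Construct a genotype panel
#'
#' @param geno integer matrix, samples x sites; entries 0, 1 or NA.
#' @param chrom character vector of chromosome names, one per site.
#' @param pos integer vector of 0-based site positions.
#' @param ref,alt reference and alternate alleles (single bases for SNPs;
#'   longer strings encode indels).
#' @param qual optional per-site quality scores.
#' @param depth optional per-site read depths.
#' @param class optional per-site functional class, one of `"synonymous"`,
#'   `"nonsynonymous"`, `"UTR"`, `"intron"`, `"intergenic"`, `"unknown"`.
#' @param samples sample names; defaults to `rownames(geno)`.
#' @param chrom_lengths optional named vector of chromosome lengths (bp).
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(geno, chrom, pos, ref, alt,
                           qual = NULL, depth = NULL, class = NULL,
                           samples = rownames(geno), chrom_lengths = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  S <- ncol(geno)
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(nrow(geno)))
  stopifnot(length(chrom) == S, length(pos) == S,
            length(ref) == S, length(alt) == S)
  if (any(geno[!is.na(geno)] != 0L & geno[!is.na(geno)] != 1L))
    stop("genotype calls must be 0, 1 or NA (biallelic haploid coding)")
  sites <- data.frame(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = as.character(ref),
    alt = as.character(alt),
    qual = if (is.null(qual)) rep(NA_real_, S) else as.numeric(qual),
    depth = if (is.null(depth)) rep(NA_real_, S) else as.numeric(depth),
    class = if (is.null(class)) rep(NA_character_, S) else as.character(class),
    stringsAsFactors = FALSE
  )
  o <- order(sites$chrom, sites$pos)
  sites <- sites[o, , drop = FALSE]
  geno <- geno[, o, drop = FALSE]
  if (anyDuplicated(sites[c("chrom", "pos", "alt")]))
    stop("duplicated sites (same chrom, pos and alt allele)")
  rownames(geno) <- samples
  rownames(sites) <- NULL
  structure(
    list(geno = geno, sites = sites, samples = samples,
         chrom_lengths = chrom_lengths),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d samples x %d sites on %d chromosome(s)\n",
              length(x$samples), nrow(x$sites),
              length(unique(x$sites$chrom))))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing calls: %.2f%%; site classes: %s\n", 100 * miss,
              if (all(is.na(x$sites$class))) "unset"
              else paste(names(table(x$sites$class)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$geno)

n_sites <- function(panel) nrow(panel$sites)

#' Subset a panel to a set of site indices (internal order preserved)
#' @noRd
panel_subset_sites <- function(panel, idx) {
  panel$geno <- panel$geno[, idx, drop = FALSE]
  panel$sites <- panel$sites[idx, , drop = FALSE]
  rownames(panel$sites) <- NULL
  panel
}

# Drop sites that are not segregating among non-missing calls.
drop_monomorphic <- function(panel) {
  g <- panel$geno
  n1 <- colSums(g == 1L, na.rm = TRUE)
  nc <- colSums(!is.na(g))
  keep <- n1 > 0L & n1 < nc
  dropped <- sum(!keep)
  panel <- panel_subset_sites(panel, which(keep))
  attr(panel, "n_monomorphic_dropped") <- dropped
  panel
}

# Concatenate panels over sites (same samples, e.g. chunks of a chromosome).
panel_concat <- function(panels) {
  stopifnot(length(panels) >= 1)
  base <- panels[[1]]
  for (p in panels[-1]) stopifnot(identical(p$samples, base$samples))
  genotype_panel(
    geno = do.call(cbind, lapply(panels, `[[`, "geno")),
    chrom = unlist(lapply(panels, function(p) p$sites$chrom)),
    pos = unlist(lapply(panels, function(p) p$sites$pos)),
    ref = unlist(lapply(panels, function(p) p$sites$ref)),
    alt = unlist(lapply(panels, function(p) p$sites$alt)),
    qual = unlist(lapply(panels, function(p) p$sites$qual)),
    depth = unlist(lapply(panels, function(p) p$sites$depth)),
    class = unlist(lapply(panels, function(p) p$sites$class)),
    samples = base$samples,
    chrom_lengths = base$chrom_lengths
  )
}

# ---------------------------------------------------------------------------
# Population map

.POPULATIONS <- c("rufipogon", "indica", "japonica_temperate",
                  "japonica_tropical")

#' Construct a population map
#'
#' Maps each accession to one of the four base populations: wild
#' `rufipogon`, cultivated `indica`, `japonica_temperate` or
#' `japonica_tropical`.  Derived groups are resolved by [pop_samples()]:
#' `japonica` = temperate + tropical, `sativa` (= `cultivated`) = indica +
#' japonica, `wild` = rufipogon.
#'
#' @param samples character vector of sample names.
#' @param populations character vector (same length) of base population
#'   labels.
#' @return A named character vector of class `population_map`.
#' @export
population_map <- function(samples, populations) {
  stopifnot(length(samples) == length(populations))
  populations <- as.character(populations)
  bad <- setdiff(unique(populations), .POPULATIONS)
  if (length(bad))
    stop("unknown population label(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(.POPULATIONS, collapse = ", "))
  if (anyDuplicated(samples)) stop("duplicated sample names in popmap")
  structure(setNames(populations, samples), class = "population_map")
}

#' Resolve a population/group name to sample names
#'
#' @param popmap a [population_map()].
#' @param group one of `rufipogon`/`wild`, `indica`,
#'   `japonica_temperate`, `japonica_tropical`, `japonica`,
#'   `sativa`/`cultivated`, or `all`.
#' @return Character vector of sample names in the group.
#' @export
pop_samples <- function(popmap, group) {
  group <- match.arg(group, c(.POPULATIONS, "japonica", "sativa",
                              "cultivated", "wild", "all"))
  base <- switch(group,
    wild = "rufipogon",
    japonica = c("japonica_temperate", "japonica_tropical"),
    sativa = ,
    cultivated = c("indica", "japonica_temperate", "japonica_tropical"),
    all = .POPULATIONS,
    group
  )
  names(popmap)[unclass(popmap) %in% base]
}

# Default population labelling for simulated panels: wild accessions are
# rufipogon; cultivated accessions split 12:6:4 (indica : temperate japonica :
# tropical japonica), the composition of the motivating 32-accession panel,
# rescaled to n_cult.
default_popmap <- function(n_wild, n_cult) {
  w <- if (n_wild > 0) sprintf("W%02d", seq_len(n_wild)) else character()
  c_ <- if (n_cult > 0) sprintf("C%02d", seq_len(n_cult)) else character()
  pops <- character(n_cult)
  if (n_cult > 0) {
    n_ind <- round(n_cult * 12 / 22)
    n_tmp <- round(n_cult * 6 / 22)
    n_trp <- n_cult - n_ind - n_tmp
    pops <- c(rep("indica", n_ind), rep("japonica_temperate", n_tmp),
              rep("japonica_tropical", n_trp))
  }
  population_map(c(w, c_), c(rep("rufipogon", n_wild), pops))
}

#' @export
print.population_map <- function(x, ...) {
  cat("<population_map>\n")
  print(table(unclass(x)))
  invisible(x)
}
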