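# QTL co-localization, variant-effect classification, and the fixed-variant
# screen with report writing.

.HIGHLIGHT_KEYWORDS <- list(
  shattering = c("shatter"),
  awn = c("awn"),
  dormancy = c("dormanc"),
  quality = c("quality", "amylose", "gel consistency", "gelatinization",
              "protein content", "milling")
)

#' Map QTLs to candidate regions
#'
#' QTLs whose span exceeds `span_limit` are removed (their mapped locations
#' are too imprecise); each surviving QTL is represented by the midpoint of
#' its start/end, and maps to a region iff that midpoint lies within the
#' region extended by `pad` on both sides.  Counts for the highlighted
#' domestication trait categories (shattering, awn length, seed dormancy,
#' grain quality by default) are reported per region.
#'
#' @param qtls a [qtl_table()].
#' @param regions data frame with `label`, `chrom`, `start`, `end` (e.g.
#'   [call_sweep_regions()] output).
#' @param span_limit maximum QTL span in bp (default 5 Mb).
#' @param pad region padding in bp (default 2 Mb).
#' @param highlight named list of lowercase keyword vectors matched (fixed
#'   strings) against QTL trait/category text.
#' @return List: `mapped` (one row per QTL-region pair), `counts` (per
#'   region: total and per highlighted category), `n_qtl_kept` after the
#'   span filter.
#' @export
map_qtls_to_regions <- function(qtls, regions, span_limit = 5e6, pad = 2e6,
                                highlight = .HIGHLIGHT_KEYWORDS) {
  stopifnot(inherits(qtls, "qtl_table"))
  if (nrow(regions)) {
    bad <- setdiff(unique(regions$chrom), unique(qtls$chrom))
    if (length(bad) && nrow(qtls))
      stop("region chromosome(s) absent from QTL table: ",
           paste(bad, collapse = ", "))
  }
  keep <- qtls[qtls$span <= span_limit, , drop = FALSE]
  pairs <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    hit <- keep$chrom == r$chrom &
      keep$midpoint >= (r$start - pad) & keep$midpoint <= (r$end + pad)
    if (any(hit)) {
      h <- keep[hit, , drop = FALSE]
      h$region <- r$label
      pairs[[length(pairs) + 1]] <- h
    }
  }
  mapped <- if (length(pairs)) do.call(rbind, pairs) else
    cbind(keep[0, , drop = FALSE], region = character())
  txt <- tolower(paste(mapped$trait, mapped$category))
  for (cat_name in names(highlight)) {
    kw <- highlight[[cat_name]]
    mapped[[paste0("is_", cat_name)]] <-
      Reduce(`|`, lapply(kw, function(k) grepl(k, txt, fixed = TRUE)),
             accumulate = FALSE) %||% logical(nrow(mapped))
  }
  counts <- do.call(rbind, lapply(regions$label, function(lb) {
    m <- mapped[mapped$region == lb, , drop = FALSE]
    row <- data.frame(region = lb, n_qtl = nrow(m))
    for (cat_name in names(highlight))
      row[[cat_name]] <- sum(m[[paste0("is_", cat_name)]])
    row
  })) %||% data.frame(region = character(), n_qtl = integer())
  rownames(mapped) <- NULL
  list(mapped = mapped, counts = counts, n_qtl_kept = nrow(keep))
}

# Locate the gene whose span (or TSS regulatory window) covers a position.
# Returns the row index in annotation$genes or NA.
find_gene <- function(annotation, chrom, pos, upstream = 200,
                      downstream = 100) {
  g <- annotation$genes
  pad_lo <- ifelse(g$strand == "+", upstream, downstream)
  pad_hi <- ifelse(g$strand == "+", downstream, upstream)
  hit <- which(g$chrom == chrom & pos >= g$start - pad_lo &
                 pos < g$end + pad_hi)
  if (!length(hit)) return(NA_integer_)
  hit[1]
}

#' Classify the functional effect of a variant
#'
#' SNPs inside a CDS are translated (reference vs alternate codon) and
#' classified `replacement` or `silent`; indels inside a CDS are
#' `frameshift` when the length change is not a multiple of 3, otherwise
#' `inframe_indel`; variants within `upstream` bp 5' of the transcription
#' start site are `upstream` and within `downstream` bp 3' of it
#' `downstream` (both strand-aware); everything else in a gene is `genic`
#' and outside genes `other`.  Genes whose CDS length is not divisible by 3
#' yield `unknown` for coding positions.
#'
#' @param chrom,pos variant position (0-based).
#' @param ref,alt reference and alternate alleles (reference-strand
#'   strings; length != 1 encodes an indel).
#' @param annotation a [gene_annotation()].
#' @param reference named `DNAStringSet`.
#' @param upstream,downstream regulatory window sizes in bp around the TSS.
#' @return List with `class` and `gene_id` (NA when intergenic).
#' @export
classify_variant_effect <- function(chrom, pos, ref, alt, annotation,
                                    reference, upstream = 200,
                                    downstream = 100) {
  if (!chrom %in% annotation$genes$chrom)
    stop("variant on unannotated chromosome: ", chrom)
  gi <- find_gene(annotation, chrom, pos, upstream, downstream)
  if (is.na(gi)) return(list(class = "other", gene_id = NA_character_))
  g <- annotation$genes[gi, ]
  cd <- annotation$cds[annotation$cds$gene_id == g$gene_id, , drop = FALSE]
  in_cds <- any(pos >= cd$start & pos < cd$end)
  is_indel <- nchar(ref) != nchar(alt)
  if (in_cds) {
    if (!isTRUE(g$cds_ok))
      return(list(class = "unknown", gene_id = g$gene_id))
    if (is_indel) {
      cls <- if (abs(nchar(ref) - nchar(alt)) %% 3 != 0) "frameshift"
             else "inframe_indel"
      return(list(class = cls, gene_id = g$gene_id))
    }
    tpos <- cds_positions(annotation, g$gene_id)
    t_i <- match(pos, tpos)
    if (is.na(t_i)) return(list(class = "unknown", gene_id = g$gene_id))
    codon_i <- (t_i - 1) %/% 3
    off <- (t_i - 1) %% 3
    cod_pos <- tpos[(codon_i * 3 + 1):(codon_i * 3 + 3)]
    cod <- paste(ref_bases(reference, chrom, cod_pos, g$strand)[
      order(if (g$strand == "+") cod_pos else -cod_pos)], collapse = "")
    alt_base <- if (g$strand == "+") alt else unname(.COMPLEMENT[alt])
    alt_cod <- cod
    substr(alt_cod, off + 1, off + 1) <- alt_base
    cls <- if (translate_codon(alt_cod) == translate_codon(cod)) "silent"
           else "replacement"
    return(list(class = cls, gene_id = g$gene_id))
  }
  # regulatory windows around the TSS (strand-aware)
  d5 <- if (g$strand == "+") g$tss - pos else pos - g$tss  # 5' distance
  if (d5 > 0 && d5 <= upstream)
    return(list(class = "upstream", gene_id = g$gene_id))
  if (d5 <= 0 && -d5 < downstream)
    return(list(class = "downstream", gene_id = g$gene_id))
  list(class = "genic", gene_id = g$gene_id)
}

#' Assign site classes to every SNP in a panel
#'
#' Vectorized classification of panel sites into the diversity-analysis
#' classes: `synonymous`, `nonsynonymous`, `UTR`, `intergenic`, `unknown`
#' (indels and coding sites of broken gene models).
#'
#' @param panel a [genotype_panel()].
#' @param annotation a [gene_annotation()].
#' @param reference named `DNAStringSet`.
#' @return The panel with `sites$class` filled.
#' @export
assign_site_classes <- function(panel, annotation, reference) {
  s <- panel$sites
  cls <- rep("intergenic", nrow(s))
  for (ch in unique(s$chrom)) {
    gi <- annotation$genes[annotation$genes$chrom == ch, , drop = FALSE]
    if (!nrow(gi)) next
    on_ch <- which(s$chrom == ch)
    pos <- s$pos[on_ch]
    g_idx <- findInterval(pos, gi$start)
    inside <- g_idx >= 1 & pos < gi$end[pmax(g_idx, 1)]
    cls[on_ch[inside]] <- "UTR"  # refined below for CDS hits
    for (grow in unique(g_idx[inside])) {
      g <- gi[grow, ]
      cd <- annotation$cds[annotation$cds$gene_id == g$gene_id, , drop = FALSE]
      sel <- on_ch[inside & g_idx == grow]
      p <- s$pos[sel]
      in_cds <- rep(FALSE, length(p))
      for (k in seq_len(nrow(cd)))
        in_cds <- in_cds | (p >= cd$start[k] & p < cd$end[k])
      if (!any(in_cds)) next
      if (!isTRUE(g$cds_ok)) {
        cls[sel[in_cds]] <- "unknown"
        next
      }
      tpos <- cds_positions(annotation, g$gene_id)
      cds_seq <- cds_sequence(annotation, reference, g$gene_id)
      for (m in which(in_cds)) {
        i <- sel[m]
        if (nchar(s$ref[i]) != 1 || nchar(s$alt[i]) != 1) {
          cls[i] <- "unknown"
          next
        }
        t_i <- match(s$pos[i], tpos)
        codon_i <- (t_i - 1) %/% 3
        off <- (t_i - 1) %% 3
        cod <- substr(cds_seq, codon_i * 3 + 1, codon_i * 3 + 3)
        alt_base <- if (g$strand == "+") s$alt[i]
                    else unname(.COMPLEMENT[s$alt[i]])
        alt_cod <- cod
        substr(alt_cod, off + 1, off + 1) <- alt_base
        cls[i] <- if (translate_codon(alt_cod) == translate_codon(cod))
          "synonymous" else "nonsynonymous"
      }
    }
  }
  panel$sites$class <- cls
  panel
}

#' Screen candidate regions for variants fixed in the cultivated group
#'
#' For every panel variant inside a candidate region that falls in a gene
#' (or its TSS regulatory windows), reports the variant iff (i) at least
#' `min_wild` wild and `min_cult` cultivated accessions are called, (ii) all
#' called cultivated accessions carry one identical allele (fixed), (iii)
#' the per-site Hudson F_ST against the wild sample is at least
#' `fst_threshold`, and (iv) the effect class is `replacement`,
#' `frameshift`, `upstream` or `downstream`.
#'
#' @param panel a [genotype_panel()].
#' @param popmap a [population_map()].
#' @param regions data frame with `label`, `chrom`, `start`, `end`.
#' @param annotation a [gene_annotation()].
#' @param reference named `DNAStringSet`.
#' @param fst_threshold minimum per-site F_ST (default 0.7).
#' @param min_wild,min_cult minimum called accessions (defaults 6 / 12; use
#'   `min_cult = 6` with `cult = "indica"` for indica-specific regions).
#' @param wild,cult group names.
#' @return Data frame (one row per reported variant): `region`, `chrom`,
#'   `pos`, `gene_id`, `ref`, `alt`, `class`, `fst`, `n_wild_called`,
#'   `n_cult_called`, `cult_allele`.
#' @export
screen_fixed_variants <- function(panel, popmap, regions, annotation,
                                  reference, fst_threshold = 0.7,
                                  min_wild = 6, min_cult = 12,
                                  wild = "rufipogon", cult = "sativa") {
  sw <- intersect(pop_samples(popmap, wild), panel$samples)
  sc <- intersect(pop_samples(popmap, cult), panel$samples)
  out <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    idx <- which(panel$sites$chrom == r$chrom & panel$sites$pos >= r$start &
                   panel$sites$pos < r$end)
    for (k in idx) {
      gw <- panel$geno[sw, k]
      gc_ <- panel$geno[sc, k]
      nw <- sum(!is.na(gw)); nc_ <- sum(!is.na(gc_))
      if (nw < min_wild || nc_ < min_cult) next
      alleles <- unique(gc_[!is.na(gc_)])
      if (length(alleles) != 1) next  # not fixed in cultivated
      xw <- sum(gw == 1L, na.rm = TRUE)
      xc <- sum(gc_ == 1L, na.rm = TRUE)
      piw <- 2 * xw * (nw - xw) / (nw * (nw - 1))
      pic <- 2 * xc * (nc_ - xc) / (nc_ * (nc_ - 1))
      dxy <- (xw * (nc_ - xc) + xc * (nw - xw)) / (nw * nc_)
      if (dxy <= 0) next
      fst <- 1 - ((piw + pic) / 2) / dxy
      if (is.na(fst) || fst < fst_threshold) next
      eff <- classify_variant_effect(r$chrom, panel$sites$pos[k],
                                     panel$sites$ref[k], panel$sites$alt[k],
                                     annotation, reference)
      if (!eff$class %in% c("replacement", "frameshift", "upstream",
                            "downstream")) next
      out[[length(out) + 1]] <- data.frame(
        region = r$label, chrom = r$chrom, pos = panel$sites$pos[k],
        gene_id = eff$gene_id, ref = panel$sites$ref[k],
        alt = panel$sites$alt[k], class = eff$class, fst = fst,
        n_wild_called = nw, n_cult_called = nc_,
        cult_allele = ifelse(alleles == 1L, panel$sites$alt[k],
                             panel$sites$ref[k]))
    }
  }
  res <- do.call(rbind, out) %||% data.frame(
    region = character(), chrom = character(), pos = integer(),
    gene_id = character(), ref = character(), alt = character(),
    class = character(), fst = numeric(), n_wild_called = integer(),
    n_cult_called = integer(), cult_allele = character())
  res <- res[!duplicated(res[c("chrom", "pos", "alt")]), , drop = FALSE]
  res <- res[order(res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write the report bundle
#'
#' Three TSVs mirroring the supplementary-dataset layout of a sweep study —
#' QTLs mapped per region, genes per region, and the fixed-variant screen —
#' plus a region summary.  Row order is genomic, so re-running on the same
#' inputs is byte-identical.
#'
#' @param dir output directory.
#' @param regions candidate regions (`label`, `chrom`, `start`, `end`, ...).
#' @param qtl_map result of [map_qtls_to_regions()].
#' @param variants result of [screen_fixed_variants()].
#' @param annotation a [gene_annotation()] for the genes-per-region list.
#' @return Invisibly, the written paths.
#' @export
write_reports <- function(dir, regions, qtl_map, variants, annotation) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(regions = file.path(dir, "regions.tsv"),
             qtls = file.path(dir, "region_qtls.tsv"),
             genes = file.path(dir, "region_genes.tsv"),
             variants = file.path(dir, "region_fixed_variants.tsv"))
  wr <- function(d, p) {
    write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  reg <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  if (nrow(qtl_map$counts))
    reg <- merge(reg, qtl_map$counts, by.x = "label", by.y = "region",
                 all.x = TRUE, sort = FALSE)
  wr(reg, paths["regions"])
  m <- qtl_map$mapped
  m <- m[order(m$chrom, m$start), , drop = FALSE]
  wr(m, paths["qtls"])
  genes <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    g <- annotation$genes
    hit <- g$chrom == r$chrom & g$start < r$end & g$end > r$start
    if (!any(hit)) return(NULL)
    cbind(region = r$label, g[hit, c("gene_id", "chrom", "start", "end",
                                     "strand")])
  })) %||% data.frame(region = character(), gene_id = character(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character())
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  wr(genes, paths["genes"])
  wr(variants, paths["variants"])
  invisible(paths)
}
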