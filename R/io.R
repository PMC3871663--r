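# Readers/writers for the standard formats and the SNP-level filters.
# VCF and GFF3 are 1-based on disk; everything internal is 0-based
# half-open, converted only here.

#' Read a VCF + popmap into a genotype panel
#'
#' Homozygous diploid genotypes are collapsed to one haploid allele;
#' heterozygous or half-called genotypes become missing (accessions are
#' inbred, so heterozygous calls are treated as artifacts); multi-allelic
#' sites are dropped with a logged count (attribute `n_multiallelic_dropped`).
#'
#' @param vcf_path path to an uncompressed or gzipped VCF.
#' @param popmap_path path to a tab-separated file with columns `sample`,
#'   `population`.
#' @return List with `panel` ([genotype_panel()]) and `popmap`
#'   ([population_map()]).
#' @export
read_vcf_panel <- function(vcf_path, popmap_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  n_multi <- sum(multi)
  if (n_multi) {
    message(n_multi, " multi-allelic site(s) dropped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v)  # sites x samples, e.g. "0/0", "1|1", "0/1"
  a <- sub("[/|].*", "", gt)
  b <- sub(".*[/|]", "", gt)
  geno <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  ok <- !is.na(gt) & a == b & a %in% c("0", "1")
  geno[ok] <- as.integer(a[ok])
  dp <- suppressWarnings(as.numeric(sub(".*DP=([0-9.]+).*", "\\1", fix$INFO)))
  dp[!grepl("DP=", fix$INFO %||% "")] <- NA
  popmap <- read_popmap(popmap_path)
  missing_samples <- setdiff(colnames(gt), names(popmap))
  if (length(missing_samples))
    stop("sample(s) in VCF absent from popmap: ",
         paste(missing_samples, collapse = ", "))
  contigs <- parse_contig_lengths(v@meta)
  panel <- genotype_panel(
    geno = t(geno),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS) - 1L,
    ref = fix$REF, alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    depth = dp,
    samples = colnames(gt),
    chrom_lengths = contigs
  )
  attr(panel, "n_multiallelic_dropped") <- n_multi
  list(panel = panel, popmap = popmap[colnames(gt)])
}

parse_contig_lengths <- function(meta) {
  m <- grep("^##contig", meta, value = TRUE)
  if (!length(m)) return(NULL)
  id <- sub(".*ID=([^,>]+).*", "\\1", m)
  len <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", m)))
  setNames(len, id)
}

#' Write a genotype panel as an uncompressed VCF
#'
#' Haploid calls are written as homozygous diploid genotypes (`0/0`, `1/1`,
#' `./.`), QUAL from the site quality and per-site depth as `INFO/DP`, with
#' contig header lines taken from the panel's chromosome lengths.
#'
#' @param panel a [genotype_panel()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_vcf_panel <- function(panel, path) {
  s <- panel$sites
  hdr <- c("##fileformat=VCFv4.2",
           "##source=sweepqtl",
           "##INFO=<ID=DP,Number=1,Type=Float,Description=\"Site depth\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (!is.null(panel$chrom_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(panel$chrom_lengths),
                          as.integer(panel$chrom_lengths)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", panel$samples),
                      collapse = "\t"))
  gt <- matrix("./.", nrow = nrow(panel$geno), ncol = ncol(panel$geno))
  gt[which(panel$geno == 0L)] <- "0/0"
  gt[which(panel$geno == 1L)] <- "1/1"
  qual <- ifelse(is.na(s$qual), ".", format(s$qual, digits = 10, trim = TRUE,
                                            scientific = FALSE))
  info <- ifelse(is.na(s$depth), ".",
                 paste0("DP=", format(s$depth, digits = 10, trim = TRUE,
                                      scientific = FALSE)))
  body <- paste(s$chrom, s$pos + 1L, ".", s$ref, s$alt, qual, ".", info,
                "GT", apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write a population map
#'
#' @param path tab-separated file with header columns `sample` and
#'   `population`.
#' @return A [population_map()].
#' @export
read_popmap <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("sample", "population") %in% names(d)))
    stop("popmap needs columns 'sample' and 'population'")
  population_map(d$sample, d$population)
}

#' @rdname read_popmap
#' @param popmap a [population_map()] to write.
#' @export
write_popmap <- function(popmap, path) {
  write.table(data.frame(sample = names(popmap),
                         population = unclass(popmap)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply the SNP-level quality and depth filters
#'
#' Keeps sites with `qual >= min_qual` and `min_depth <= depth <
#' max_depth_exclusive` — the screening used to delineate high-quality SNPs
#' (very high depths flag repetitive regions).  When quality/depth
#' annotations are absent all sites pass, with a warning.
#'
#' @param panel a [genotype_panel()].
#' @param min_qual minimum site quality score.
#' @param min_depth minimum depth (inclusive).
#' @param max_depth_exclusive depth at or above which sites are excluded.
#' @return List with `panel` (filtered) and `report` (data frame of removal
#'   counts by reason).
#' @examples
#' # sites with (qual, depth) = (99,10), (150,2), (150,100), (150,50):
#' # only the last survives
#' @export
apply_snp_filters <- function(panel, min_qual = 100, min_depth = 3,
                              max_depth_exclusive = 100) {
  s <- panel$sites
  if (nrow(s) > 0 && all(is.na(s$qual)) && all(is.na(s$depth))) {
    warning("no quality/depth annotations; all sites pass")
    report <- data.frame(reason = c("low_qual", "low_depth", "high_depth"),
                         removed = c(0L, 0L, 0L))
    return(list(panel = panel, report = report))
  }
  low_q <- !is.na(s$qual) & s$qual < min_qual
  low_d <- !is.na(s$depth) & s$depth < min_depth
  high_d <- !is.na(s$depth) & s$depth >= max_depth_exclusive
  keep <- !(low_q | low_d | high_d)
  report <- data.frame(
    reason = c("low_qual", "low_depth", "high_depth"),
    removed = c(sum(low_q), sum(low_d), sum(high_d))
  )
  list(panel = panel_subset_sites(panel, which(keep)), report = report)
}

# ---------------------------------------------------------------------------
# GFF3

#' Read a GFF3 gene annotation
#'
#' Builds a [gene_annotation()] from `gene` and `CDS` features (CDS rows are
#' linked to genes via their `Parent`/mRNA chain or a shared ID prefix).
#' Genes whose total CDS length is not divisible by 3 are flagged unusable
#' for codon-effect classification (with a warning).
#'
#' @param path GFF3 file path.
#' @return A [gene_annotation()].
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  genes <- df[df$type == "gene", , drop = FALSE]
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  # map CDS Parent (mRNA) -> gene
  mrna_parent <- setNames(as.character(mrna$Parent), mrna$ID)
  cds_parent <- as.character(cds$Parent)
  cds_gene <- ifelse(cds_parent %in% names(mrna_parent),
                     mrna_parent[cds_parent], cds_parent)
  gene_annotation(
    genes = data.frame(gene_id = as.character(genes$ID),
                       chrom = as.character(genes$seqnames),
                       strand = as.character(genes$strand),
                       start = genes$start - 1L, end = genes$end),
    cds = data.frame(gene_id = cds_gene,
                     start = cds$start - 1L, end = cds$end,
                     phase = if (is.null(cds$phase)) 0L else as.integer(cds$phase))
  )
}

#' Write a gene annotation as GFF3
#'
#' @param annotation a [gene_annotation()].
#' @param path output path.
#' @export
write_gene_annotation <- function(annotation, path) {
  g <- annotation$genes
  cd <- annotation$cds
  mk <- function(d, type, id, parent, phase = NA_integer_) {
    GenomicRanges::GRanges(
      seqnames = d$chrom,
      ranges = IRanges::IRanges(start = d$start + 1L, end = d$end),
      strand = d$strand,
      type = type, ID = id, Parent = parent, phase = phase
    )
  }
  cd2 <- merge(cd, g[c("gene_id", "chrom", "strand")], by = "gene_id")
  gr <- c(
    mk(g, "gene", g$gene_id, NA_character_),
    mk(g, "mRNA", paste0(g$gene_id, ".t1"), g$gene_id),
    mk(cd2, "CDS", paste0(cd2$gene_id, ".cds"),
       paste0(cd2$gene_id, ".t1"), cd2$phase)
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# ---------------------------------------------------------------------------
# QTL table

#' Construct / read a QTL table
#'
#' `qtl_table()` validates a data frame with columns `id`, `trait`,
#' `category`, `chrom`, `start`, `end` (0-based half-open internally);
#' records with `start > end` are swapped with a warning.  `read_qtl_table()`
#' reads the on-disk TSV form (1-based inclusive coordinates); rows with
#' non-numeric coordinates are rejected with their line numbers.
#'
#' @param d data frame of QTL records.
#' @return Data frame of class `qtl_table` with `midpoint` (integer floor)
#'   and `span` columns.
#' @export
qtl_table <- function(d) {
  need <- c("id", "trait", "category", "chrom", "start", "end")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("QTL table missing column(s): ", paste(miss, collapse = ", "))
  swap <- d$start > d$end
  if (any(swap)) {
    warning(sum(swap), " QTL record(s) with start > end swapped")
    tmp <- d$start[swap]; d$start[swap] <- d$end[swap]; d$end[swap] <- tmp
  }
  d$midpoint <- floor((d$start + d$end) / 2)
  d$span <- d$end - d$start
  rownames(d) <- NULL
  class(d) <- c("qtl_table", "data.frame")
  d
}

#' @rdname qtl_table
#' @param path TSV path with header `id`, `trait`, `category`, `chrom`,
#'   `start`, `end`.
#' @export
read_qtl_table <- function(path) {
  raw <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, colClasses = "character")
  need <- c("id", "trait", "category", "chrom", "start", "end")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("QTL table missing column(s): ", paste(miss, collapse = ", "))
  s <- suppressWarnings(as.numeric(raw$start))
  e <- suppressWarnings(as.numeric(raw$end))
  bad <- is.na(s) | is.na(e)
  if (any(bad))
    warning("rejected QTL row(s) with non-numeric coordinates at line(s): ",
            paste(which(bad) + 1L, collapse = ", "))
  raw <- raw[!bad, , drop = FALSE]
  qtl_table(data.frame(id = raw$id, trait = raw$trait,
                       category = raw$category, chrom = raw$chrom,
                       start = s[!bad] - 1, end = e[!bad],
                       stringsAsFactors = FALSE))
}

#' @rdname qtl_table
#' @param qtl a `qtl_table` to write (coordinates converted to 1-based
#'   inclusive).
#' @export
write_qtl_table <- function(qtl, path) {
  out <- data.frame(id = qtl$id, trait = qtl$trait, category = qtl$category,
                    chrom = qtl$chrom, start = qtl$start + 1, end = qtl$end)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Dataset bundle export

#' Export a synthetic dataset bundle to standard files
#'
#' Writes `reference.fa`, `genes.gff3`, `calls.vcf`, `qtl.tsv`,
#' `popmap.tsv`, `truth_sweeps.tsv`, `truth_variants.tsv` and `model.yaml`
#' into `dir`.  A round trip through [read_vcf_panel()] reproduces the panel
#' exactly.
#'
#' @param bundle a `sweepqtl_dataset` from [synthesize_genome()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
export_dataset <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sweepqtl_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    reference = file.path(dir, "reference.fa"),
    gff = file.path(dir, "genes.gff3"),
    vcf = file.path(dir, "calls.vcf"),
    qtl = file.path(dir, "qtl.tsv"),
    popmap = file.path(dir, "popmap.tsv"),
    truth_sweeps = file.path(dir, "truth_sweeps.tsv"),
    truth_variants = file.path(dir, "truth_variants.tsv"),
    model = file.path(dir, "model.yaml")
  )
  Biostrings::writeXStringSet(bundle$reference, paths["reference"])
  write_gene_annotation(bundle$annotation, paths["gff"])
  write_vcf_panel(bundle$panel, paths["vcf"])
  write_qtl_table(bundle$qtl, paths["qtl"])
  write_popmap(bundle$popmap, paths["popmap"])
  write.table(bundle$truth$sweeps, paths["truth_sweeps"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bundle$truth$variants, paths["truth_variants"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  m <- bundle$model
  yaml::write_yaml(list(N0 = m$N0, N1 = m$N1, T1 = m$T1, mu = m$mu,
                        rec = m$rec, s_wild = m$s_wild, s_cult = m$s_cult,
                        seed = bundle$truth$seed), paths["model"])
  invisible(paths)
}
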