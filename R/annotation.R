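# Gene annotation container and codon-level sequence helpers.
#
# Coordinates are 0-based half-open internally.  `genes` holds one row per
# gene (single transcript per gene is assumed); `cds` holds one row per CDS
# interval with its phase.

#' Construct a gene annotation
#'
#' @param genes data frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (0-based half-open gene span).
#' @param cds data frame with columns `gene_id`, `start`, `end`, `phase`.
#' @return Object of class `gene_annotation` with a derived `tss` column
#'   (transcription start: `start` on plus strand, `end - 1` on minus) and a
#'   `cds_ok` flag (total CDS length divisible by 3).
#' @export
gene_annotation <- function(genes, cds) {
  need <- c("gene_id", "chrom", "strand", "start", "end")
  stopifnot(all(need %in% names(genes)),
            all(c("gene_id", "start", "end") %in% names(cds)))
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  cds_len <- tapply(cds$end - cds$start, cds$gene_id, sum)
  genes$cds_ok <- (cds_len[genes$gene_id] %% 3) == 0
  bad <- genes$gene_id[!genes$cds_ok & !is.na(genes$cds_ok)]
  if (length(bad))
    warning("CDS length not divisible by 3 for gene(s): ",
            paste(bad, collapse = ", "), "; flagged unusable for codon effects")
  if (is.null(cds$phase)) cds$phase <- 0L
  rownames(genes) <- rownames(cds) <- NULL
  structure(list(genes = genes, cds = cds), class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("<gene_annotation> %d genes on %d chromosome(s)\n",
              nrow(x$genes), length(unique(x$genes$chrom))))
  invisible(x)
}

# CDS genomic positions of one gene in transcript (translation) order.
cds_positions <- function(annotation, gene_id) {
  g <- annotation$genes[annotation$genes$gene_id == gene_id, ]
  if (!nrow(g)) stop("unknown gene: ", gene_id)
  cd <- annotation$cds[annotation$cds$gene_id == gene_id, , drop = FALSE]
  cd <- cd[order(cd$start), , drop = FALSE]
  if (g$strand == "+") {
    unlist(lapply(seq_len(nrow(cd)), function(i) seq(cd$start[i], cd$end[i] - 1)))
  } else {
    unlist(lapply(rev(seq_len(nrow(cd))), function(i) seq(cd$end[i] - 1, cd$start[i])))
  }
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Bases of the reference at 0-based positions of a chromosome, as read on the
# given strand (complemented for "-").
ref_bases <- function(reference, chrom, pos0, strand = "+") {
  seq <- reference[[chrom]]
  b <- strsplit(as.character(Biostrings::subseq(
    seq, start = min(pos0) + 1, end = max(pos0) + 1)), "")[[1]]
  b <- b[pos0 - min(pos0) + 1]
  if (strand == "-") b <- unname(.COMPLEMENT[b])
  b
}

# Coding sequence (5'->3') of a gene from the reference.
cds_sequence <- function(annotation, reference, gene_id) {
  g <- annotation$genes[annotation$genes$gene_id == gene_id, ]
  pos <- cds_positions(annotation, gene_id)
  seq <- as.character(reference[[g$chrom]])
  b <- substring(seq, pos + 1, pos + 1)
  if (g$strand == "-") b <- unname(.COMPLEMENT[b])
  paste(b, collapse = "")
}

genetic_code <- function() Biostrings::GENETIC_CODE

translate_codon <- function(codon) {
  gc <- genetic_code()
  unname(gc[codon])
}

# Is the codon fourfold degenerate at its third position?
fourfold_codon <- function(codon) {
  gc <- genetic_code()
  pre <- substr(codon, 1, 2)
  aas <- gc[paste0(pre, c("A", "C", "G", "T"))]
  length(unique(aas)) == 1
}

#' Fourfold-degenerate (synonymous) sites of a gene
#'
#' Genomic 0-based positions, in transcript order from the translation
#' start, of third codon positions whose codon is fourfold degenerate in the
#' reference — the package's operational definition of a gene's synonymous
#' sites.
#'
#' @param annotation a [gene_annotation()].
#' @param reference named `DNAStringSet`.
#' @param gene_id gene identifier.
#' @return Integer vector of genomic positions (empty for genes whose CDS is
#'   flagged unusable).
#' @export
fourfold_sites <- function(annotation, reference, gene_id) {
  g <- annotation$genes[annotation$genes$gene_id == gene_id, ]
  if (!isTRUE(g$cds_ok)) return(integer())
  pos <- cds_positions(annotation, gene_id)
  cds <- cds_sequence(annotation, reference, gene_id)
  n_codon <- nchar(cds) %/% 3
  if (n_codon == 0) return(integer())
  codons <- substring(cds, 3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon))
  gc <- genetic_code()
  pre <- substr(codons, 1, 2)
  ff <- vapply(unique(pre), function(p) {
    length(unique(gc[paste0(p, c("A", "C", "G", "T"))])) == 1
  }, TRUE)
  is_ff <- ff[pre]
  third_idx <- 3 * seq_len(n_codon)  # transcript index of third position
  pos[third_idx[is_ff]]
}
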