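# Shared fixtures built in code.  Everything is deterministic given the
# seeds fixed here.

# A tiny hand-written panel: 4 wild + 6 cultivated samples, 1 chromosome.
make_toy_panel <- function() {
  samples <- c(sprintf("W%02d", 1:4), sprintf("C%02d", 1:6))
  geno <- rbind(
    W01 = c(0L, 0L, 1L, 0L, 1L),
    W02 = c(0L, 1L, 1L, 0L, 0L),
    W03 = c(1L, 0L, 0L, 0L, 1L),
    W04 = c(0L, 0L, 0L, 0L, NA),
    C01 = c(1L, 1L, 0L, 1L, 0L),
    C02 = c(1L, 1L, 0L, 1L, 0L),
    C03 = c(1L, 0L, 0L, 1L, 0L),
    C04 = c(1L, 1L, 0L, 1L, NA),
    C05 = c(1L, 1L, 0L, 1L, 0L),
    C06 = c(1L, 1L, 0L, 1L, 0L)
  )
  genotype_panel(
    geno,
    chrom = rep("chr1", 5),
    pos = c(100L, 2000L, 35000L, 52000L, 70000L),
    ref = c("A", "C", "G", "T", "A"),
    alt = c("T", "G", "A", "C", "G"),
    qual = c(150, 99, 150, 150, 150),
    depth = c(10, 10, 2, 50, 100),
    samples = samples,
    chrom_lengths = c(chr1 = 100000)
  )
}

make_toy_popmap <- function() {
  population_map(
    c(sprintf("W%02d", 1:4), sprintf("C%02d", 1:6)),
    c(rep("rufipogon", 4), rep("indica", 3),
      "japonica_temperate", "japonica_temperate", "japonica_tropical")
  )
}

# A small annotated reference: one plus-strand and one minus-strand gene
# with known CDS content, suitable for effect-classification tests.
#   gene gp (+): UTR5 [1000,1010), CDS [1010,1040) = ATG GAT CCA AAA GGG
#                TTT CTC GAA CAT TAA, UTR3 [1040,1050)
#   gene gm (-): gene [3000,3050); CDS [3010,3040) encodes the same
#                peptide on the minus strand; TSS = 3049
make_toy_annotation <- function() {
  cds_plus <- "ATGGATCCAAAAGGGTTTCTCGAACATTAA"
  chr_len <- 5000
  bases <- rep("A", chr_len)
  bases[seq(2, chr_len, by = 4)] <- "C"
  bases[seq(3, chr_len, by = 4)] <- "G"
  bases[seq(4, chr_len, by = 4)] <- "T"
  bases[1011:1040] <- strsplit(cds_plus, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bases[3011:3040] <- rev(unname(comp[strsplit(cds_plus, "")[[1]]]))
  ref <- Biostrings::DNAStringSet(setNames(paste(bases, collapse = ""), "chr1"))
  ann <- gene_annotation(
    genes = data.frame(
      gene_id = c("gp", "gm"), chrom = "chr1", strand = c("+", "-"),
      start = c(1000L, 3000L), end = c(1050L, 3050L)),
    cds = data.frame(gene_id = c("gp", "gm"),
                     start = c(1010L, 3010L), end = c(1040L, 3040L),
                     phase = 0L)
  )
  list(annotation = ann, reference = ref)
}

# Model used by fast simulation tests: small sizes so trees are shallow.
fast_model <- function(...) {
  demographic_model(N0 = 10000, N1 = 2000, T1 = 1500, mu = 2.5e-8,
                    rec = 1e-8, s_wild = 0, s_cult = 0, ...)
}
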