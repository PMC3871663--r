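# QTL co-localization, effect classification, fixed-variant screen, reports.

test_that("QTL span filter and midpoint-pad mapping follow the stated rules", {
  q <- qtl_table(data.frame(
    id = c("q1", "q2", "q3", "q4", "q5"),
    trait = c("awn length", "shattering", "grain quality", "yield",
              "seed dormancy"),
    category = c("awn length", "shattering", "grain quality", "yield",
                 "seed dormancy"),
    chrom = "chr1",
    start = c(11.8e6, 9e6, 10.6e6, 50e6, 12.1e6),
    end = c(12.8e6, 15e6, 14.6e6, 54.5e6, 13.1e6)))
  # spans: 1, 6, 4, 4.5, 1 Mb -> q2 removed by the 5 Mb filter
  regions <- data.frame(label = "S01", chrom = "chr1", start = 10.0e6,
                        end = 10.5e6)
  res <- map_qtls_to_regions(q, regions)
  expect_equal(res$n_qtl_kept, 4)
  # midpoints: q1 12.3e6 (maps, = end + pad boundary is 12.5e6),
  # q5 12.6e6 (does not), q3 12.6e6 (does not), q4 52.25e6 (does not)
  expect_equal(sort(res$mapped$id), "q1")
  expect_equal(res$counts$n_qtl[res$counts$region == "S01"], 1)
  expect_equal(res$counts$awn[res$counts$region == "S01"], 1)
  expect_equal(res$counts$quality[res$counts$region == "S01"], 0)
  # enlarging the pad never removes a mapped QTL
  res2 <- map_qtls_to_regions(q, regions, pad = 3e6)
  expect_true(all(res$mapped$id %in% res2$mapped$id))
  # chromosome naming mismatch is an error
  regions_bad <- data.frame(label = "X", chrom = "chrZ", start = 0, end = 1)
  expect_error(map_qtls_to_regions(q, regions_bad), "chrZ")
})

test_that("variant effects classify by codon, frame and TSS windows", {
  toy <- make_toy_annotation()
  ann <- toy$annotation; ref <- toy$reference
  # gp codon 2 is GAT at genomic 1013..1015: GAT->GAA (third base T->A) is
  # Asp->Glu, a replacement
  eff <- classify_variant_effect("chr1", 1015, "T", "A", ann, ref)
  expect_equal(eff$class, "replacement")
  expect_equal(eff$gene_id, "gp")
  # GAT->GAC (T->C) is silent
  expect_equal(classify_variant_effect("chr1", 1015, "T", "C", ann,
                                       ref)$class, "silent")
  # 2-bp deletion inside the CDS is a frameshift; 3-bp is in-frame
  expect_equal(classify_variant_effect("chr1", 1020, "AAA", "A", ann,
                                       ref)$class, "frameshift")
  expect_equal(classify_variant_effect("chr1", 1020, "AAAG", "A", ann,
                                       ref)$class, "inframe_indel")
  # 150 bp 5' of the minus-strand TSS (coordinates above the TSS)
  expect_equal(classify_variant_effect("chr1", 3049 + 150, "A", "C", ann,
                                       ref)$class, "upstream")
  # 50 bp 3' of the plus-strand TSS but before the CDS
  expect_equal(classify_variant_effect("chr1", 1005, "C", "A", ann,
                                       ref)$class, "downstream")
  # intergenic
  expect_equal(classify_variant_effect("chr1", 2500, "A", "C", ann,
                                       ref)$class, "other")
  expect_error(classify_variant_effect("chrZ", 5, "A", "C", ann, ref),
               "chromosome")
})

test_that("minus-strand codons are classified on the coding strand", {
  toy <- make_toy_annotation()
  ann <- toy$annotation; ref <- toy$reference
  # gm mirrors gp: its last CDS base in genomic coordinates (3010) is the
  # third base of the stop codon; codon 2 GAT occupies genomic 3034..3036
  # with the coding-strand third base at genomic 3034
  b <- sweepqtl:::ref_bases(ref, "chr1", 3034)
  expect_equal(b, "A")  # complement of coding-strand T
  eff <- classify_variant_effect("chr1", 3034, "A", "T", ann, ref)
  # coding-strand change T->A: GAT->GAA, Asp->Glu replacement
  expect_equal(eff$class, "replacement")
  expect_equal(eff$gene_id, "gm")
  # coding-strand change T->C: GAT->GAC is silent (alt on ref strand = G)
  expect_equal(classify_variant_effect("chr1", 3034, "A", "G", ann,
                                       ref)$class, "silent")
})

test_that("the fixed-variant screen enforces fixation, coverage and F_ST", {
  toy <- make_toy_annotation()
  ann <- toy$annotation; ref <- toy$reference
  samples <- c(sprintf("W%02d", 1:7), sprintf("C%02d", 1:14))
  pm <- population_map(samples, c(rep("rufipogon", 7), rep("indica", 14)))
  regions <- data.frame(label = "S01", chrom = "chr1", start = 0L,
                        end = 5000L)
  mk_panel <- function(wild, cult, pos = 1013L, ref_a = "G", alt_a = "A") {
    genotype_panel(matrix(c(wild, cult), ncol = 1), chrom = "chr1",
                   pos = pos, ref = ref_a, alt = alt_a, samples = samples)
  }
  # worked example: cultivated 14/14 alt, wild A x6 T x1 -> F_ST = 5/6 >= 0.7,
  # fixed, replacement (GAT -> AAT via first codon base at 1013) -> reported
  p <- mk_panel(c(rep(0L, 6), 1L), rep(1L, 14))
  out <- screen_fixed_variants(p, pm, regions, ann, ref)
  expect_equal(nrow(out), 1)
  expect_equal(out$fst, 5 / 6)
  expect_equal(out$class, "replacement")
  # cultivated 11 called (< 12): skipped regardless of pattern
  p2 <- mk_panel(c(rep(0L, 6), 1L), c(rep(1L, 11), rep(NA_integer_, 3)))
  expect_equal(nrow(screen_fixed_variants(p2, pm, regions, ann, ref)), 0)
  # cultivated 13/14 + 1 ref: not fixed, not reported
  p3 <- mk_panel(c(rep(0L, 6), 1L), c(rep(1L, 13), 0L))
  expect_equal(nrow(screen_fixed_variants(p3, pm, regions, ann, ref)), 0)
  # F_ST below threshold: wild 4/7 alt gives F_ST < 0.7
  p4 <- mk_panel(c(rep(1L, 4), rep(0L, 3)), rep(1L, 14))
  expect_equal(nrow(screen_fixed_variants(p4, pm, regions, ann, ref)), 0)
  # relaxing the threshold grows the report monotonically
  out4 <- screen_fixed_variants(p4, pm, regions, ann, ref, fst_threshold = 0.2)
  expect_equal(nrow(out4), 1)
  # silent variants are never reported even when fixed and divergent
  p5 <- mk_panel(c(rep(0L, 6), 1L), rep(1L, 14), pos = 1015L, ref_a = "T",
                 alt_a = "C")
  expect_equal(nrow(screen_fixed_variants(p5, pm, regions, ann, ref)), 0)
})

test_that("report writing is deterministic with headers-only empty files", {
  toy <- make_toy_annotation()
  regions <- data.frame(label = character(), chrom = character(),
                        start = numeric(), end = numeric())
  qm <- list(mapped = cbind(qtl_table(data.frame(
    id = character(), trait = character(), category = character(),
    chrom = character(), start = numeric(), end = numeric()))[0, ],
    region = character()),
    counts = data.frame(region = character(), n_qtl = integer()),
    n_qtl_kept = 0L)
  vars <- screen_fixed_variants(
    make_toy_panel(), make_toy_popmap(),
    data.frame(label = "x", chrom = "none", start = 0, end = 1),
    toy$annotation, toy$reference)
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_reports(d1, regions, qm, vars, toy$annotation)
  p2 <- write_reports(d2, regions, qm, vars, toy$annotation)
  for (f in names(p1)) {
    lines <- readLines(p1[[f]])
    expect_length(lines, 1)  # header only
    expect_identical(lines, readLines(p2[[f]]))
  }
})
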