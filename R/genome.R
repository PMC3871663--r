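# Whole-genome synthetic dataset generator: multi-chromosome panels stitched
# from ARG-simulated chunks, a random reference with real codon structure,
# gene annotation, QTL table, planted sweeps and planted screen variants,
# plus the truth tables needed to validate every downstream stage.

#' Genome layout configuration for the synthetic-data generator
#'
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param n_wild,n_cult haploid accession counts (wild / cultivated).
#' @param chunk_bp length of the independently simulated ARG chunks that are
#'   stitched into chromosomes; linkage is exact within a chunk and absent
#'   across chunk boundaries.
#' @param gene_codons CDS length in codons of each synthetic gene (the last
#'   codon is a stop).
#' @param gene_utr5,gene_utr3 UTR lengths in bp.
#' @param gene_spacing distance between successive gene starts in bp.
#' @param fourfold_frac fraction of codons drawn from fourfold-degenerate
#'   families, so genes carry enough synonymous sites for the
#'   first-1000-synonymous-sites convention.
#' @param qtl_per_chrom number of random QTL intervals per chromosome.
#' @param qtl_over_sweep number of extra QTLs (highlighted domestication
#'   categories) planted with midpoints near each sweep center.
#' @param sweeps list of [sweep_spec()] with `chrom` set.
#' @param plant_causal plant fixed causal variants (replacement, frameshift,
#'   upstream) at each sweep center.
#' @param plant_controls plant negative-control variants (near-fixed,
#'   low-coverage, synonymous) near each sweep center.
#' @param missing_rate per-call missingness applied to simulated sites.
#' @return A `genome_config` list.
#' @export
genome_config <- function(chrom_lengths = c(chr1 = 10e6, chr2 = 10e6, chr3 = 10e6),
                          n_wild = 10, n_cult = 22, chunk_bp = 5e5,
                          gene_codons = 1200, gene_utr5 = 150, gene_utr3 = 100,
                          gene_spacing = 10000, fourfold_frac = 0.9,
                          qtl_per_chrom = 30, qtl_over_sweep = 2,
                          sweeps = list(), plant_causal = TRUE,
                          plant_controls = TRUE, missing_rate = 0.03) {
  stopifnot(length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)))
  for (sw in sweeps) {
    stopifnot(inherits(sw, "sweep_spec"))
    if (!sw$chrom %in% names(chrom_lengths))
      stop("sweep chromosome not in genome: ", sw$chrom)
    if (sw$pos < 0 || sw$pos >= chrom_lengths[sw$chrom])
      stop("sweep position outside chromosome ", sw$chrom)
  }
  gene_len <- gene_utr5 + 3 * gene_codons + gene_utr3
  if (gene_spacing < gene_len) stop("gene_spacing smaller than gene length")
  structure(list(chrom_lengths = chrom_lengths, n_wild = n_wild,
                 n_cult = n_cult, chunk_bp = chunk_bp,
                 gene_codons = gene_codons, gene_utr5 = gene_utr5,
                 gene_utr3 = gene_utr3, gene_spacing = gene_spacing,
                 fourfold_frac = fourfold_frac,
                 qtl_per_chrom = qtl_per_chrom,
                 qtl_over_sweep = qtl_over_sweep, sweeps = sweeps,
                 plant_causal = plant_causal,
                 plant_controls = plant_controls,
                 missing_rate = missing_rate),
            class = "genome_config")
}

.FOURFOLD_PREFIX <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")
.OTHER_CODONS <- c("ATG", "AAA", "AAG", "GAT", "GAC", "GAA", "GAG", "TTT",
                   "TTC", "CAT", "CAC", "AAT", "AAC", "TGG", "ATT", "ATC")

# Build one synthetic chromosome sequence plus its gene table.
build_chromosome <- function(len, cfg, chrom) {
  bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  gene_len <- cfg$gene_utr5 + 3 * cfg$gene_codons + cfg$gene_utr3
  starts <- seq(2000, len - gene_len - 2000, by = cfg$gene_spacing)
  genes <- vector("list", length(starts))
  cds <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    strand <- if (i %% 2 == 0) "-" else "+"
    g0 <- starts[i]
    nc <- cfg$gene_codons
    use_ff <- runif(nc - 2) < cfg$fourfold_frac
    body <- ifelse(use_ff,
                   paste0(sample(.FOURFOLD_PREFIX, nc - 2, replace = TRUE),
                          sample(c("A", "C", "G", "T"), nc - 2, replace = TRUE)),
                   sample(.OTHER_CODONS, nc - 2, replace = TRUE))
    cds_seq <- paste(c("ATG", body, "TAA"), collapse = "")
    if (strand == "+") {
      cds_start <- g0 + cfg$gene_utr5
      insert <- cds_seq
    } else {
      cds_start <- g0 + cfg$gene_utr3
      insert <- paste(rev(unname(.COMPLEMENT[strsplit(cds_seq, "")[[1]]])),
                      collapse = "")
    }
    bases[(cds_start + 1):(cds_start + nchar(insert))] <-
      strsplit(insert, "")[[1]]
    gid <- sprintf("%s_g%04d", chrom, i)
    genes[[i]] <- data.frame(gene_id = gid, chrom = chrom, strand = strand,
                             start = g0, end = g0 + gene_len)
    cds[[i]] <- data.frame(gene_id = gid, start = cds_start,
                           end = cds_start + 3 * cfg$gene_codons, phase = 0L)
  }
  list(seq = paste(bases, collapse = ""),
       genes = do.call(rbind, genes), cds = do.call(rbind, cds))
}

# Simulate the panel of one chromosome by stitching ARG chunks.
simulate_chromosome_panel <- function(model, cfg, chrom, len, seed) {
  sweeps_here <- Filter(function(s) s$chrom == chrom, model$sweeps)
  chunk_starts <- seq(0, len - 1, by = cfg$chunk_bp)
  panels <- vector("list", length(chunk_starts))
  for (i in seq_along(chunk_starts)) {
    cs <- chunk_starts[i]
    cl <- min(cfg$chunk_bp, len - cs)
    sw <- NULL
    if (length(sweeps_here)) {
      d <- vapply(sweeps_here, function(s)
        max(0, max(cs - s$pos, s$pos - (cs + cl))), 0)
      j <- which.min(d)
      s <- sweeps_here[[j]]
      if (d[j] <= 10 * s$lambda)
        sw <- sweep_spec(chrom, s$pos - cs, s$lambda, s$t_fix)
    }
    p <- simulate_locus(model, cfg$n_wild, cfg$n_cult, cl, sweep = sw,
                        seed = seed + i, chrom = chrom)
    p$sites$pos <- p$sites$pos + as.integer(cs)
    panels[[i]] <- p
  }
  pan <- panel_concat(panels)
  pan$chrom_lengths <- setNames(len, chrom)
  pan
}

#' Synthesize a complete fake study dataset
#'
#' Generates a multi-chromosome panel of near-homozygous wild and cultivated
#' accessions under the two-population bottleneck model with planted
#' completed sweeps, a random reference genome with codon-structured genes,
#' a QTL table (some QTLs deliberately placed over planted sweeps), planted
#' screen variants, missing data with quality/depth annotations, and truth
#' tables for every planted feature.
#'
#' @param config a [genome_config()].
#' @param model a [demographic_model()]; its `sweeps` are taken from
#'   `config$sweeps`.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return A `sweepqtl_dataset` list: `panel`, `popmap`, `reference`
#'   (`DNAStringSet`), `annotation`, `qtl` (QTL table), `truth`, `model`,
#'   `config`.
#' @export
synthesize_genome <- function(config = genome_config(),
                              model = demographic_model(), seed = 1) {
  stopifnot(inherits(config, "genome_config"),
            inherits(model, "demographic_model"))
  if (any(config$chrom_lengths < config$chunk_bp))
    stop("chromosome lengths must be >= chunk_bp")
  model$sweeps <- config$sweeps
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  chroms <- names(config$chrom_lengths)
  built <- lapply(seq_along(chroms), function(i)
    build_chromosome(config$chrom_lengths[i], config, chroms[i]))
  reference <- Biostrings::DNAStringSet(
    setNames(vapply(built, `[[`, "", "seq"), chroms))
  annotation <- gene_annotation(do.call(rbind, lapply(built, `[[`, "genes")),
                                do.call(rbind, lapply(built, `[[`, "cds")))

  panels <- lapply(seq_along(chroms), function(i)
    simulate_chromosome_panel(model, config, chroms[i],
                              config$chrom_lengths[i],
                              seed = derive_seed(seed, paste0("chr", i))))
  panel <- panel_concat(panels)
  panel$chrom_lengths <- config$chrom_lengths
  popmap <- default_popmap(config$n_wild, config$n_cult)

  # reference/alternate alleles from the synthetic reference (the reference
  # sequence doubles as the ancestral state)
  bases <- c("A", "C", "G", "T")
  for (ch in chroms) {
    idx <- which(panel$sites$chrom == ch)
    if (!length(idx)) next
    rb <- ref_bases(reference, ch, panel$sites$pos[idx])
    panel$sites$ref[idx] <- rb
    shift <- sample(1:3, length(idx), replace = TRUE)
    panel$sites$alt[idx] <- bases[(match(rb, bases) - 1 + shift) %% 4 + 1]
  }

  panel <- degrade_panel(panel, missing_rate = config$missing_rate,
                         seed = derive_seed(seed, "degrade"))

  planted <- plant_screen_variants(panel, config, model, annotation,
                                   reference,
                                   seed = derive_seed(seed, "plant"))
  panel <- planted$panel
  panel <- assign_site_classes(panel, annotation, reference)

  qtl <- synth_qtl_table(config, seed = derive_seed(seed, "qtl"))

  sweeps_df <- if (length(config$sweeps)) {
    data.frame(
      label = sprintf("SW%02d", seq_along(config$sweeps)),
      chrom = vapply(config$sweeps, `[[`, "", "chrom"),
      pos = vapply(config$sweeps, `[[`, 0, "pos"),
      lambda = vapply(config$sweeps, `[[`, 0, "lambda"),
      t_fix = vapply(config$sweeps, function(s) s$t_fix %||% model$T1, 0)
    )
  } else {
    data.frame(label = character(), chrom = character(), pos = numeric(),
               lambda = numeric(), t_fix = numeric())
  }

  structure(list(
    panel = panel, popmap = popmap, reference = reference,
    annotation = annotation, qtl = qtl,
    truth = list(sweeps = sweeps_df, variants = planted$truth,
                 model = model, seed = seed),
    model = model, config = config
  ), class = "sweepqtl_dataset")
}

#' @export
print.sweepqtl_dataset <- function(x, ...) {
  cat("<sweepqtl_dataset>\n")
  cat(sprintf("  %d chromosomes (%.1f Mb), %d genes, %d QTLs\n",
              length(x$config$chrom_lengths),
              sum(x$config$chrom_lengths) / 1e6,
              nrow(x$annotation$genes), nrow(x$qtl)))
  cat(sprintf("  panel: %d wild + %d cultivated accessions, %d sites\n",
              x$config$n_wild, x$config$n_cult, n_sites(x$panel)))
  cat(sprintf("  planted: %d sweeps, %d screen variants\n",
              nrow(x$truth$sweeps), nrow(x$truth$variants)))
  invisible(x)
}

# Random QTL table with some QTLs purposely over sweeps.  1-based inclusive
# coordinates are produced at export time; internally 0-based half-open.
synth_qtl_table <- function(cfg, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cats <- c("shattering", "awn length", "seed dormancy", "grain quality",
            "plant height", "yield", "disease resistance", "root thickness")
  high <- c("shattering", "awn length", "seed dormancy", "grain quality")
  rows <- list()
  k <- 0
  for (ch in names(cfg$chrom_lengths)) {
    len <- cfg$chrom_lengths[ch]
    for (i in seq_len(cfg$qtl_per_chrom)) {
      span <- runif(1, 2e5, 7e6)  # some exceed the 5 Mb span filter
      mid <- runif(1, 0, len)
      s <- max(0, mid - span / 2); e <- min(len, mid + span / 2)
      cat_i <- sample(cats, 1)
      k <- k + 1
      rows[[k]] <- data.frame(id = sprintf("AQ%04d", k),
                              trait = paste(cat_i, "QTL"), category = cat_i,
                              chrom = ch, start = floor(s), end = floor(e))
    }
  }
  for (sw in cfg$sweeps) {
    len <- cfg$chrom_lengths[sw$chrom]
    for (i in seq_len(cfg$qtl_over_sweep)) {
      span <- runif(1, 5e5, 4e6)
      mid <- min(max(0, sw$pos + runif(1, -1e6, 1e6)), len)
      s <- max(0, mid - span / 2); e <- min(len, mid + span / 2)
      k <- k + 1
      rows[[k]] <- data.frame(id = sprintf("AQ%04d", k),
                              trait = paste(sample(high, 1), "QTL"),
                              category = sample(high, 1),
                              chrom = sw$chrom, start = floor(s),
                              end = floor(e))
    }
  }
  out <- do.call(rbind, rows)
  qtl_table(out)
}

# Inject screen-truth variants near each sweep center: three reportable
# classes fixed in the cultivated group, and negative controls that the
# screen must reject.
plant_screen_variants <- function(panel, cfg, model, annotation, reference,
                                  seed) {
  truth <- list()
  if (!length(cfg$sweeps) || !(cfg$plant_causal || cfg$plant_controls))
    return(list(panel = panel,
                truth = data.frame(chrom = character(), pos = integer(),
                                   ref = character(), alt = character(),
                                   class = character(),
                                   expected_report = logical(),
                                   note = character())))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  nw <- cfg$n_wild; ncu <- cfg$n_cult
  popmap <- default_popmap(nw, ncu)
  wild_idx <- seq_len(nw)
  cult_idx <- nw + seq_len(ncu)

  add <- list()
  for (si in seq_along(cfg$sweeps)) {
    sw <- cfg$sweeps[[si]]
    genes <- annotation$genes[annotation$genes$chrom == sw$chrom, ]
    gi <- which.min(abs((genes$start + genes$end) / 2 - sw$pos))
    g <- genes[gi, ]
    cd <- annotation$cds[annotation$cds$gene_id == g$gene_id, ]
    tpos <- cds_positions(annotation, g$gene_id)
    cds_seq <- cds_sequence(annotation, reference, g$gene_id)
    codon_at <- function(codon_i) substr(cds_seq, 3 * codon_i - 2, 3 * codon_i)

    # find a codon whose first-position change is nonsynonymous, and a
    # fourfold codon for the synonymous control
    find_repl <- function(exclude = integer()) {
      for (ci in setdiff(5:(cfg$gene_codons - 5), exclude)) {
        cod <- codon_at(ci)
        for (b in setdiff(c("A", "C", "G", "T"), substr(cod, 1, 1))) {
          alt_cod <- paste0(b, substr(cod, 2, 3))
          if (!translate_codon(alt_cod) %in% c(translate_codon(cod), "*"))
            return(list(ci = ci, alt = b, cod = cod))
        }
      }
      NULL
    }
    used <- integer()
    geno_full <- function(cult, wild) {
      v <- integer(nw + ncu)
      v[wild_idx] <- wild
      v[cult_idx] <- cult
      v
    }
    strand_alt <- function(b) if (g$strand == "+") b else unname(.COMPLEMENT[b])
    plant_one <- function(codon_i, codon_off, alt_cds_base, class, geno, note,
                          expected, indel_ref = NULL, indel_alt = NULL) {
      t_i <- 3 * (codon_i - 1) + codon_off  # transcript index, 1-based
      gpos <- tpos[t_i]
      rb <- ref_bases(reference, g$chrom, gpos)
      if (is.null(indel_ref)) {
        ref <- rb
        alt <- strand_alt(alt_cds_base)
        if (alt == ref) return(NULL)
      } else {
        ref <- indel_ref; alt <- indel_alt
      }
      list(chrom = g$chrom, pos = gpos, ref = ref, alt = alt, class = class,
           geno = geno, note = note, expected = expected)
    }

    if (cfg$plant_causal) {
      r <- find_repl(used); used <- c(used, r$ci)
      add[[length(add) + 1]] <- plant_one(r$ci, 1, r$alt, "replacement",
        geno_full(rep(1L, ncu), rep(0L, nw)), "causal_replacement", TRUE)
      # frameshift: 2-bp deletion anchored one base before two CDS bases
      fs_ci <- max(setdiff(5:(cfg$gene_codons - 5), used)[1], 5)
      used <- c(used, fs_ci)
      gpos <- sort(tpos[(3 * (fs_ci - 1) + 1):(3 * fs_ci)])[1]
      rb3 <- paste(ref_bases(reference, g$chrom, gpos + 0:2), collapse = "")
      add[[length(add) + 1]] <- list(chrom = g$chrom, pos = gpos,
        ref = rb3, alt = substr(rb3, 1, 1), class = "frameshift",
        geno = geno_full(rep(1L, ncu), rep(0L, nw)),
        note = "causal_frameshift", expected = TRUE)
      # upstream: 100 bp 5' of the TSS (strand-aware)
      up_pos <- if (g$strand == "+") g$tss - 100 else g$tss + 100
      rb <- ref_bases(reference, g$chrom, up_pos)
      add[[length(add) + 1]] <- list(chrom = g$chrom, pos = up_pos,
        ref = rb, alt = setdiff(c("A", "C", "G", "T"), rb)[1],
        class = "upstream", geno = geno_full(rep(1L, ncu), rep(0L, nw)),
        note = "causal_upstream", expected = TRUE)
    }
    if (cfg$plant_controls) {
      # near-fixed: one cultivated accession still carries the wild allele
      r <- find_repl(used); used <- c(used, r$ci)
      gn <- geno_full(c(0L, rep(1L, ncu - 1)), rep(0L, nw))
      add[[length(add) + 1]] <- plant_one(r$ci, 1, r$alt, "replacement",
        gn, "control_near_fixed", FALSE)
      # low coverage: cultivated called count below the screen minimum
      r <- find_repl(used); used <- c(used, r$ci)
      gn <- geno_full(c(rep(1L, 11), rep(NA_integer_, ncu - 11)), rep(0L, nw))
      add[[length(add) + 1]] <- plant_one(r$ci, 1, r$alt, "replacement",
        gn, "control_low_coverage", FALSE)
      # synonymous: fixed and divergent but silent
      ff <- fourfold_sites(annotation, reference, g$gene_id)
      if (length(ff)) {
        gpos <- ff[[min(20, length(ff))]]
        rb <- ref_bases(reference, g$chrom, gpos)
        add[[length(add) + 1]] <- list(chrom = g$chrom, pos = gpos,
          ref = rb, alt = setdiff(c("A", "C", "G", "T"), rb)[1],
          class = "synonymous",
          geno = geno_full(rep(1L, ncu), rep(0L, nw)),
          note = "control_synonymous", expected = FALSE)
      }
    }
  }
  add <- Filter(Negate(is.null), add)
  if (!length(add))
    return(list(panel = panel, truth = data.frame()))

  # remove simulated sites colliding with planted positions
  key <- paste(vapply(add, `[[`, "", "chrom"), vapply(add, `[[`, 0, "pos"))
  clash <- paste(panel$sites$chrom, panel$sites$pos) %in% key
  if (any(clash)) panel <- panel_subset_sites(panel, which(!clash))

  planted_panel <- genotype_panel(
    geno = do.call(cbind, lapply(add, `[[`, "geno")),
    chrom = vapply(add, `[[`, "", "chrom"),
    pos = vapply(add, `[[`, 0, "pos"),
    ref = vapply(add, `[[`, "", "ref"),
    alt = vapply(add, `[[`, "", "alt"),
    qual = rep(250, length(add)), depth = rep(30, length(add)),
    samples = panel$samples, chrom_lengths = panel$chrom_lengths
  )
  truth <- data.frame(
    chrom = vapply(add, `[[`, "", "chrom"),
    pos = vapply(add, `[[`, 0, "pos"),
    ref = vapply(add, `[[`, "", "ref"),
    alt = vapply(add, `[[`, "", "alt"),
    class = vapply(add, `[[`, "", "class"),
    expected_report = vapply(add, `[[`, TRUE, "expected"),
    note = vapply(add, `[[`, "", "note")
  )
  list(panel = panel_concat(list(panel, planted_panel)), truth = truth)
}
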