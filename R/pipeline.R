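# End-to-end orchestration: simulate -> filter -> tracks -> demography ->
# null -> scan -> F_ST scans -> QTL map -> screen -> reports, with cached
# intermediates and a run manifest.

#' Default pipeline configuration
#'
#' Returns the nested configuration list understood by [run_pipeline()].
#' Components may be overridden by passing a (partial) list or a YAML file;
#' unknown keys are rejected.  Desk-scale defaults keep an end-to-end run on
#' a laptop-sized synthetic genome in the minutes range; `null$R` can be
#' raised to the full-scale 1e5.
#'
#' @param ... named overrides of top-level sections (merged shallowly into
#'   each section).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    genome = list(chrom_lengths = c(chr1 = 4e6, chr2 = 4e6),
                  sweeps = list(list(chrom = "chr1", pos = 2e6, lambda = 2e5)),
                  qtl_per_chrom = 30),
    model = list(),           # demographic_model() overrides
    filters = list(min_qual = 100, min_depth = 3, max_depth_exclusive = 100),
    windows = list(size = 5e5, step = 2e4),
    demography = list(enabled = FALSE, R = 500, max_loci = 150),
    null = list(R = 10000),
    scan = list(K = 15),
    fst = list(pairs = list(c("indica", "japonica"),
                            c("japonica_temperate", "japonica_tropical")),
               K = 1),
    qtl = list(span_limit = 5e6, pad = 2e6),
    screen = list(fst_threshold = 0.7, min_wild = 6, min_cult = 12)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "))
  # shallow per-section merge: a supplied key replaces the default wholly
  # (modifyList would recurse into unnamed lists such as `sweeps`)
  for (nm in names(over))
    for (k in names(over[[nm]])) cfg[[nm]][[k]] <- over[[nm]][[k]]
  if (cfg$windows$step > cfg$windows$size)
    stop("config error: window step larger than window size")
  structure(cfg, class = "pipeline_config")
}

load_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (inherits(config, "pipeline_config")) return(config)
  do.call(pipeline_config, config)
}

#' Run the full sweep-detection pipeline on a synthetic genome
#'
#' Executes every stage in order, writes intermediates and reports under
#' `out_dir`, and returns the results with a manifest (derived per-stage
#' seeds, parameter values, counts, and md5 hashes of the outputs).
#' Deterministic given `seed`.
#'
#' @param config a [pipeline_config()], a partial list of overrides, or the
#'   path to a YAML file of overrides.
#' @param seed integer master seed; per-stage seeds are derived from it.
#' @param out_dir output directory.
#' @return Invisibly, a list with `dataset`, `filtered`, `track`, `fit`
#'   (or `NULL`), `null`, `scored`, `regions`, `fst_tracks`, `fst_regions`,
#'   `qtl_map`, `variants`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1,
                         out_dir = tempfile("sweepqtl_run_")) {
  cfg <- load_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, config = unclass(cfg), stages = list())
  t_all <- Sys.time()
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- c(list(seed = derive_seed(seed, stage)), list(...))
  }

  # 1. simulate
  sweeps <- lapply(cfg$genome$sweeps, function(s)
    sweep_spec(s$chrom, s$pos, s$lambda, s$t_fix %||% NULL))
  gcfg_args <- cfg$genome
  gcfg_args$sweeps <- sweeps
  gcfg_args$chrom_lengths <- unlist(gcfg_args$chrom_lengths)
  gcfg <- do.call(genome_config, gcfg_args)
  model <- do.call(demographic_model, cfg$model)
  dataset <- synthesize_genome(gcfg, model, seed = derive_seed(seed, "simulate"))
  data_paths <- export_dataset(dataset, file.path(out_dir, "data"))
  note("simulate", n_sites = n_sites(dataset$panel),
       n_sweeps = nrow(dataset$truth$sweeps))

  # 2. filter
  filt <- apply_snp_filters(dataset$panel, cfg$filters$min_qual,
                            cfg$filters$min_depth,
                            cfg$filters$max_depth_exclusive)
  panel <- filt$panel
  note("filter", removed = sum(filt$report$removed), kept = n_sites(panel))

  # 3. diversity tracks (gene-region callable mask)
  genes <- dataset$annotation$genes
  callable <- data.frame(chrom = genes$chrom, start = genes$start,
                         end = genes$end)
  track <- diversity_ratio_track(panel, dataset$popmap,
                                 num = "sativa", den = "rufipogon",
                                 size = cfg$windows$size,
                                 step = cfg$windows$step,
                                 callable_regions = callable)
  note("tracks", n_windows = nrow(track))

  # 4. demography (optional at desk scale: the generator model is the
  # fallback null model when disabled)
  fit <- NULL
  null_model <- demographic_model(model$N0, model$N1, model$T1, model$mu,
                                  model$rec, model$s_wild, model$s_cult)
  if (isTRUE(cfg$demography$enabled)) {
    loci <- locus_summaries(panel, dataset$annotation, dataset$reference,
                            dataset$popmap,
                            max_loci = cfg$demography$max_loci)
    fit <- fit_bottleneck(loci, n_wild = gcfg$n_wild, n_cult = gcfg$n_cult,
                          mu = model$mu, R = cfg$demography$R,
                          seed = derive_seed(seed, "demography"))
    co <- coef(fit)
    null_model <- demographic_model(co["N0"], co["N1"], co["T1"], model$mu,
                                    model$rec, model$s_wild, model$s_cult)
    note("demography", N0 = co[["N0"]], N1 = co[["N1"]], T1 = co[["T1"]])
  }

  # 5. null distribution
  null <- build_null_distribution(null_model, gcfg$n_wild, gcfg$n_cult,
                                  window_bp = cfg$windows$size,
                                  R = cfg$null$R,
                                  seed = derive_seed(seed, "null"))
  note("null", R = null$R, n_redrawn = null$n_redrawn)

  # 6. scan
  scored <- score_windows(track, null)
  regions <- call_sweep_regions(scored, K = cfg$scan$K)
  write.table(scored, file.path(out_dir, "scored_track.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  note("scan", n_regions = nrow(regions))

  # 7. F_ST scans
  fst_tracks <- list()
  fst_regions <- list()
  for (pair in cfg$fst$pairs) {
    key <- paste(pair, collapse = "_vs_")
    tr <- fst_scan(panel, dataset$popmap, pair, size = cfg$windows$size,
                   step = cfg$windows$step)
    fst_tracks[[key]] <- tr
    fst_regions[[key]] <- top_fst_regions(tr, K = cfg$fst$K)
    write.table(tr, file.path(out_dir, paste0("fst_", key, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  note("fst", pairs = length(cfg$fst$pairs))

  # 8. QTL co-localization
  qtl_map <- map_qtls_to_regions(dataset$qtl, regions,
                                 span_limit = cfg$qtl$span_limit,
                                 pad = cfg$qtl$pad)
  note("qtl_map", n_kept = qtl_map$n_qtl_kept, n_mapped = nrow(qtl_map$mapped))

  # 9. fixed-variant screen
  variants <- screen_fixed_variants(panel, dataset$popmap, regions,
                                    dataset$annotation, dataset$reference,
                                    fst_threshold = cfg$screen$fst_threshold,
                                    min_wild = cfg$screen$min_wild,
                                    min_cult = cfg$screen$min_cult)
  note("screen", n_reported = nrow(variants))

  # 10. reports + manifest
  report_paths <- write_reports(file.path(out_dir, "reports"), regions,
                                qtl_map, variants, dataset$annotation)
  outputs <- c(data_paths, report_paths,
               scored = file.path(out_dir, "scored_track.tsv"))
  manifest$outputs <- lapply(as.list(outputs), function(p)
    list(path = p, md5 = unname(tools::md5sum(p))))
  manifest$elapsed_sec <- as.numeric(Sys.time() - t_all, units = "secs")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(list(dataset = dataset, filtered = filt, track = track,
                 fit = fit, null = null, scored = scored, regions = regions,
                 fst_tracks = fst_tracks, fst_regions = fst_regions,
                 qtl_map = qtl_map, variants = variants,
                 manifest = manifest, out_dir = out_dir))
}
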