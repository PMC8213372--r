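# One-config orchestration of the full analysis: universe -> counts/QC ->
# differential -> modules -> enrichment -> super-enhancers, with a run
# manifest for reproducibility.

.default_config <- function() {
  list(
    fdr_threshold = 0.05,      # FDR cutoff for differential ChARs
    k_clusters = 4,            # accessibility modules
    dispersion_floor = 1e-8,
    prior_df = 10,             # dispersion moderation weight
    kmeans_restarts = 10,
    random_seed = 1,
    max_fragment_length = 1000,
    apply_shift = FALSE,       # fragment files are pre-shifted by default
    tss_window = 1000,
    tss_flank = 100,
    tss_smooth = 51,
    basal_up = 5000,           # GREAT regulatory-domain defaults
    basal_down = 1000,
    extension_max = 1e6,
    enrichment_background = "universe",
    se_comparison = c("baseline", "art_1yr"))
}

#' Validate a pipeline configuration
#'
#' Applies defaults, rejects unknown keys, and checks ranges.
#'
#' @param config A named list of overrides, a YAML file path, or `NULL`
#'   for all defaults.
#' @return Complete configuration list of class `pipeline_config`.
#' @export
validate_config <- function(config = NULL) {
  defaults <- .default_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (!(cfg$fdr_threshold > 0 && cfg$fdr_threshold < 1))
    stop("fdr_threshold must be in (0, 1)")
  if (cfg$k_clusters < 2) stop("k_clusters must be >= 2")
  pos <- c("dispersion_floor", "prior_df", "kmeans_restarts",
           "max_fragment_length", "tss_window", "tss_flank", "tss_smooth",
           "basal_up", "basal_down", "extension_max")
  for (key in pos)
    if (cfg[[key]] <= 0) stop(key, " must be positive")
  if (!cfg$enrichment_background %in% c("universe", "differential"))
    stop("enrichment_background must be 'universe' or 'differential'")
  if (length(cfg$se_comparison) != 2) stop("se_comparison must name 2 conditions")
  structure(cfg, class = c("pipeline_config", "list"))
}

.stage_msg <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(..., collapse = "")))
}

#' Run the full analysis pipeline
#'
#' Consumes a directory of inputs (the layout written by
#' [simulate_dataset()]): per-condition `peaks_<condition>.narrowPeak`,
#' `samples.tsv`, a count matrix `counts.tsv` with its region universe
#' `universe_truth.bed` (or counts are produced from per-sample
#' `fragments_<sample>.bed` on the peak-derived universe), optional
#' `tss.tsv`, `genes.tsv` and `annotation.tsv`. Writes all stage outputs
#' plus `manifest.json` to `out_dir`. Rerunning on identical inputs and
#' config reproduces identical stage outputs.
#'
#' @param input_dir Input directory.
#' @param out_dir Output directory (created).
#' @param config Overrides for [validate_config()].
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(input_dir, out_dir, config = NULL) {
  cfg <- validate_config(config)
  t0 <- Sys.time()
  inp <- function(f) file.path(input_dir, f)
  peak_files <- list.files(input_dir, "^peaks_.*\\.narrowPeak$",
                           full.names = TRUE)
  frag_files <- list.files(input_dir, "^fragments_.*\\.bed$",
                           full.names = TRUE)
  # validate inputs before any computation
  if (length(peak_files) == 0) stop("no peaks_<condition>.narrowPeak inputs found")
  if (!file.exists(inp("samples.tsv"))) stop("missing input: samples.tsv")
  has_counts <- file.exists(inp("counts.tsv"))
  if (has_counts && !file.exists(inp("universe_truth.bed")))
    stop("counts.tsv given without its region universe (universe_truth.bed)")
  if (!has_counts && length(frag_files) == 0)
    stop("neither counts.tsv nor fragment files present; nothing to count")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()

  samples <- read.table(inp("samples.tsv"), header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)

  .stage_msg("universe", "merging ", length(peak_files), " peak sets")
  t <- Sys.time()
  peaksets <- lapply(peak_files, read_bed, dialect = "narrowPeak")
  universe <- build_universe(peaksets)
  write_bed(universe, file.path(out_dir, "universe.bed"))
  timings$universe <- as.numeric(Sys.time() - t, units = "secs")

  qc <- NULL
  if (length(frag_files) > 0) {
    .stage_msg("count_qc", "counting ", length(frag_files), " fragment files")
    t <- Sys.time()
    ids <- sub("^fragments_(.*)\\.bed$", "\\1", basename(frag_files))
    sources <- stats::setNames(as.list(frag_files), ids)
    qc_samples <- samples[samples$sample_id %in% ids, , drop = FALSE]
    fq <- count_matrix(sources, universe, qc_samples,
                       apply_shift = cfg$apply_shift,
                       max_fragment_length = cfg$max_fragment_length)
    write.table(data.frame(region_id = rownames(fq), fq, check.names = FALSE),
                file.path(out_dir, "counts_fragments.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    tss <- if (file.exists(inp("tss.tsv")))
      read.table(inp("tss.tsv"), header = TRUE, sep = "\t",
                 stringsAsFactors = FALSE) else NULL
    qc <- qc_report(sources, universe, qc_samples, tss = tss,
                    window = cfg$tss_window, flank = cfg$tss_flank,
                    smooth = cfg$tss_smooth)
    write.table(qc, file.path(out_dir, "qc.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    timings$count_qc <- as.numeric(Sys.time() - t, units = "secs")
  }

  .stage_msg("differential", "loading counts")
  t <- Sys.time()
  if (has_counts) {
    cdf <- read.table(inp("counts.tsv"), header = TRUE, sep = "\t",
                      check.names = FALSE, stringsAsFactors = FALSE)
    counts <- as.matrix(cdf[, -1, drop = FALSE])
    rownames(counts) <- cdf$region_id
    count_universe <- peak_universe(read_bed(inp("universe_truth.bed"))$intervals)
  } else {
    counts <- fq
    count_universe <- universe
  }
  counts <- counts[, samples$sample_id, drop = FALSE]
  sf <- estimate_size_factors(counts)
  disp <- estimate_dispersion(counts, sf, samples,
                              floor = cfg$dispersion_floor)
  res <- all_pairwise(counts, sf, disp, samples, prior_df = cfg$prior_df)
  for (nm in names(res))
    write.table(res[[nm]], file.path(out_dir, sprintf("differential_%s.tsv", nm)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  diff_ids <- select_differential_union(res, cfg$fdr_threshold)
  if (length(diff_ids) == 0)
    stop("no differential regions at FDR < ", cfg$fdr_threshold,
         "; module clustering is undefined")
  diff_regions <- count_universe$regions[
    match(diff_ids, count_universe$region_ids), , drop = FALSE]
  write_bed(peak_universe(diff_regions), file.path(out_dir, "differential_union.bed"))
  timings$differential <- as.numeric(Sys.time() - t, units = "secs")

  .stage_msg("modules", "clustering ", length(diff_ids), " regions, k = ",
             cfg$k_clusters)
  t <- Sys.time()
  cm <- condition_mean_rows(counts, sf, samples, regions = diff_ids)
  rn <- row_normalize(cm)
  modules <- kmeans_modules(rn, k = cfg$k_clusters, seed = cfg$random_seed,
                            restarts = cfg$kmeans_restarts)
  write.table(data.frame(region_id = names(modules$labels),
                         module = modules$labels),
              file.path(out_dir, "modules.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(region_id = rownames(rn), rn, check.names = FALSE),
              file.path(out_dir, "row_normalized.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  timings$modules <- as.numeric(Sys.time() - t, units = "secs")

  enr <- NULL
  if (file.exists(inp("annotation.tsv"))) {
    .stage_msg("enrichment", "scoring modules against categories")
    t <- Sys.time()
    ann <- load_category_annotation(inp("annotation.tsv"), count_universe)
    bg <- if (cfg$enrichment_background == "universe") "universe" else diff_ids
    enr <- enrichment_table(modules, ann, background = bg)
    write.table(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    timings$enrichment <- as.numeric(Sys.time() - t, units = "secs")
  }

  se_up <- se_down <- NULL
  if (file.exists(inp("genes.tsv"))) {
    .stage_msg("superenhancer", "elbow calling")
    t <- Sys.time()
    genes <- read_genes(inp("genes.tsv"))
    pr <- cfg$se_comparison
    nm <- paste(pr[2], "vs", pr[1], sep = "_")
    if (!nm %in% names(res)) {
      nm <- paste(pr[1], "vs", pr[2], sep = "_")
      pr <- rev(pr)
    }
    if (nm %in% names(res)) {
      for (direction in c("up", "down")) {
        er <- tryCatch(
          se_genes_for_direction(res[[nm]], count_universe, genes,
                                 direction = direction,
                                 fdr_threshold = cfg$fdr_threshold,
                                 basal_up = cfg$basal_up,
                                 basal_down = cfg$basal_down,
                                 extension_max = cfg$extension_max),
          error = function(e) NULL)
        if (is.null(er)) next
        tag <- if (direction == "up") pr[2] else pr[1]
        out <- er$curve
        out$is_SE <- out$gene_id %in% er$se_genes
        write.table(out, file.path(out_dir, sprintf("se_genes_%s_up.tsv", tag)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        if (direction == "up") se_up <- er else se_down <- er
      }
    }
    timings$superenhancer <- as.numeric(Sys.time() - t, units = "secs")
  }

  inputs <- Filter(function(f) !dir.exists(f),
                   list.files(input_dir, full.names = TRUE))
  manifest <- list(
    package_version = as.character(utils::packageVersion("charmod")),
    config = unclass(cfg),
    seed = cfg$random_seed,
    input_checksums = as.list(tools::md5sum(inputs)),
    n_universe = length(universe),
    n_differential = length(diff_ids),
    timings_sec = timings,
    total_sec = as.numeric(Sys.time() - t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(universe = universe, qc = qc, results = res,
                 differential = diff_ids, modules = modules,
                 enrichment = enr, se_up = se_up, se_down = se_down,
                 config = cfg))
}
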