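# End-to-end pipeline: configuration, file I/O in a single TSV dialect,
# stage execution and a deterministic run manifest.

#' Pipeline configuration
#'
#' All thresholds default to the values used throughout the analysis:
#' minimum MAS5 signal 50, minimum fold change 1.5, expression t-test alpha
#' 0.001, differential-methylation p 0.01 with minimum |delta| 0.2, ANOVA
#' alpha 0.001, Cy3 saturation ceiling 15,000, TSS window -800..+100 nt,
#' loess span 0.3.  The simulation block controls the synthetic study size
#' (default: 1,600 promoters plus 400 intergenic CpG islands, 80 arrays).
#'
#' @param seed master seed for the synthetic study.
#' @param min_signal,min_fc,de_alpha expression cascade thresholds.
#' @param dm_p,dm_delta differential-methylation thresholds.
#' @param anova_alpha split-plot ANOVA significance threshold.
#' @param saturation Cy3 saturation ceiling.
#' @param window TSS aggregation window, `c(upstream, downstream)` nt.
#' @param loess_span,loess_iterations per-array loess parameters.
#' @param n_regions,n_intergenic,n_dm,n_de,n_switch synthetic study size.
#' @param top_n rows per direction in the gene integration table.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, min_signal = 50, min_fc = 1.5,
                            de_alpha = 0.001, dm_p = 0.01, dm_delta = 0.2,
                            anova_alpha = 0.001, saturation = 15000,
                            window = c(-800, 100), loess_span = 0.3,
                            loess_iterations = 4L, n_regions = 1600L,
                            n_intergenic = 400L, n_dm = 100L, n_de = 100L,
                            n_switch = 1L, top_n = 30L) {
  cfg <- as.list(environment())
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Write / read a pipeline configuration as YAML
#'
#' The configuration round-trips through serialization unchanged, and a copy
#' is written into every output directory.
#'
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  vals <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, list())
  cfg[names(vals)] <- vals
  cfg$window <- as.numeric(unlist(cfg$window))
  cfg$seed <- as.integer(cfg$seed)
  for (nm in c("n_regions", "n_intergenic", "n_dm", "n_de", "n_switch",
               "top_n", "loess_iterations")) {
    cfg[[nm]] <- as.integer(cfg[[nm]])
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

## ---- simulation I/O -------------------------------------------------------

#' Write a synthetic study to a directory
#'
#' Writes the annotation (BED plus region-metadata TSV and probe table), the
#' truth table, per-array intensity TSVs with array metadata, the expression
#' matrix, and the validation-assay tables, all in the package's single TSV
#' dialect.
#'
#' @param sim list with elements `design`, `annotation`, `truth`, `arrays`,
#'   `expression`, `assays` (as produced by the generators).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- sim$design
  yaml::write_yaml(list(
    n_donors_per_group = d$n_donors_per_group, organs = d$organs,
    treatments = d$treatments, tech_reps_per_sample = d$tech_reps_per_sample,
    seed = d$seed,
    noise = unclass(sim$arrays$noise)[c(
      "sigma_tech", "sigma_donor", "sigma_probe", "dye_bias_coefficients",
      "dye_bias_center", "dye_bias_scale", "saturation_ceiling",
      "cy3_meanlog", "cy3_sdlog",
      "sigma_expr", "sigma_expr_donor", "coupling_expr", "coupling_meth",
      "sigma_ct", "sigma_pyro")]
  ), file.path(dir, "design.yaml"))
  rg <- sim$annotation$regions
  bed <- data.frame(chrom = rg$chrom, start = rg$start, end = rg$end,
                    name = rg$region_id, score = 0L, strand = rg$strand)
  write_tsv(bed, file.path(dir, "regions.bed"))
  write_tsv(rg, file.path(dir, "regions.tsv"))
  write_tsv(sim$annotation$probes, file.path(dir, "probes.tsv"))
  write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  adir <- file.path(dir, "arrays")
  dir.create(adir, showWarnings = FALSE)
  write_tsv(sim$arrays$arrays, file.path(adir, "metadata.tsv"))
  for (j in seq_len(ncol(sim$arrays$cy3))) {
    write_tsv(data.frame(probe_id = sim$arrays$probes$probe_id,
                         cy5 = sim$arrays$cy5[, j],
                         cy3 = sim$arrays$cy3[, j]),
              file.path(adir, paste0(colnames(sim$arrays$cy3)[j], ".tsv")))
  }
  ex <- sim$expression
  write_tsv(data.frame(probe_set_id = rownames(ex$signal), ex$signal,
                       check.names = FALSE),
            file.path(dir, "expression.tsv"))
  write_tsv(ex$samples, file.path(dir, "expression_samples.tsv"))
  write_tsv(ex$probe_map, file.path(dir, "probe_map.tsv"))
  as_ <- sim$assays
  write_tsv(as_$expression_ct, file.path(dir, "expression_ct.tsv"))
  write_tsv(as_$medip_ct, file.path(dir, "medip_ct.tsv"))
  write_tsv(as_$chip_ct, file.path(dir, "chip_ct.tsv"))
  for (g in names(as_$clones)) {
    write_tsv(data.frame(clone_id = rownames(as_$clones[[g]]),
                         as_$clones[[g]], check.names = FALSE),
              file.path(dir, paste0("clones_", g, ".tsv")))
  }
  write_tsv(as_$pyro, file.path(dir, "pyro.tsv"))
  invisible(dir)
}

#' Read a synthetic study back from a directory
#'
#' Inverse of [write_simulation()]; reconstructs the design, annotation,
#' truth, array set, expression set and assay tables.
#'
#' @param dir directory written by [write_simulation()].
#' @return list with the same elements as the `sim` argument of
#'   [write_simulation()].
#' @export
read_simulation <- function(dir) {
  dy_path <- file.path(dir, "design.yaml")
  if (!file.exists(dy_path)) stopf("input file not found: %s", dy_path)
  dy <- yaml::read_yaml(dy_path)
  design <- study_design(dy$n_donors_per_group, unlist(dy$organs),
                         unlist(dy$treatments), dy$tech_reps_per_sample,
                         dy$seed)
  noise <- do.call(noise_model,
                   lapply(dy$noise, function(x) unlist(x)))
  regions <- read_tsv(file.path(dir, "regions.tsv"))
  probes <- read_tsv(file.path(dir, "probes.tsv"))
  regions$tss <- as.character(regions$tss)
  annotation <- structure(list(regions = regions, probes = probes),
                          class = "region_annotation")
  truth <- read_tsv(file.path(dir, "truth.tsv"))
  class(truth) <- c("truth_table", "data.frame")
  meta <- read_tsv(file.path(dir, "arrays", "metadata.tsv"))
  cy5 <- cy3 <- matrix(NA_real_, nrow(probes), nrow(meta),
                       dimnames = list(probes$probe_id, meta$array_id))
  for (j in seq_len(nrow(meta))) {
    a <- read_tsv(file.path(dir, "arrays", paste0(meta$array_id[j], ".tsv")))
    cy5[, j] <- a$cy5; cy3[, j] <- a$cy3
  }
  arrays <- structure(list(cy5 = cy5, cy3 = cy3, probes = probes,
                           arrays = meta, design = design, noise = noise),
                      class = "medip_arrays")
  exdf <- read_tsv(file.path(dir, "expression.tsv"))
  signal <- as.matrix(exdf[, -1, drop = FALSE])
  rownames(signal) <- exdf$probe_set_id
  expression <- structure(list(
    signal = signal,
    samples = read_tsv(file.path(dir, "expression_samples.tsv")),
    probe_map = read_tsv(file.path(dir, "probe_map.tsv"))
  ), class = "expression_set")
  clones <- list()
  for (g in design$treatments) {
    cl <- read_tsv(file.path(dir, paste0("clones_", g, ".tsv")))
    m <- as.matrix(cl[, -1, drop = FALSE])
    rownames(m) <- cl$clone_id
    clones[[g]] <- m
  }
  assays <- structure(list(
    expression_ct = read_tsv(file.path(dir, "expression_ct.tsv")),
    medip_ct = read_tsv(file.path(dir, "medip_ct.tsv")),
    chip_ct = read_tsv(file.path(dir, "chip_ct.tsv")),
    clones = clones, pyro = read_tsv(file.path(dir, "pyro.tsv"))
  ), class = "assay_data")
  list(design = design, annotation = annotation, truth = truth,
       arrays = arrays, expression = expression, assays = assays)
}

## ---- stages ---------------------------------------------------------------

simulate_study <- function(config) {
  design <- study_design(seed = config$seed)
  noise <- noise_model(saturation_ceiling = config$saturation)
  annotation <- generate_annotation(config$n_regions, config$n_intergenic,
                                    seed = sub_seed(config$seed, 11L))
  truth <- generate_truth(annotation, design, n_dm = config$n_dm,
                          n_de = config$n_de, n_switch = config$n_switch)
  arrays <- simulate_two_color_arrays(design, annotation, truth, noise)
  expression <- simulate_expression(design, truth, noise)
  assays <- simulate_assay_data(design, truth, noise)
  list(design = design, annotation = annotation, truth = truth,
       arrays = arrays, expression = expression, assays = assays)
}

stage_methylome <- function(sim, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  proc <- process_medip(sim$arrays, sim$annotation,
                        saturation = config$saturation,
                        window = config$window, span = config$loess_span,
                        iterations = config$loess_iterations)
  target <- sim$design$organs[1]
  dm <- differential_methylation(proc$donor$values, proc$donor$samples,
                                 organ = target, p_threshold = config$dm_p,
                                 delta_threshold = config$dm_delta,
                                 control = sim$design$treatments[1])
  anova <- split_plot_anova(aggregate_stage_values(proc), sim$arrays$arrays,
                            alpha = config$anova_alpha)
  write_tsv(data.frame(region_id = rownames(proc$donor$values),
                       proc$donor$values, check.names = FALSE),
            file.path(dir, "donor_m.tsv"))
  write_tsv(proc$donor$samples, file.path(dir, "donor_samples.tsv"))
  write_tsv(dm, file.path(dir, paste0("dm_", target, ".tsv")))
  write_tsv(anova, file.path(dir, "anova.tsv"))
  volcano <- data.frame(region_id = dm$region_id, delta = dm$delta,
                        neg_log10_p = -log10(dm$p), class = dm$class)
  write_tsv(volcano, file.path(dir, "volcano.tsv"))
  list(proc = proc, dm = dm, anova = anova)
}

# array-level normalized region matrix (ANOVA runs before donor averaging)
aggregate_stage_values <- function(proc) proc$region_m

stage_transcriptome <- function(sim, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  de <- expression_cascade(sim$expression$signal, sim$expression$samples,
                           min_signal = config$min_signal,
                           min_fc = config$min_fc, alpha = config$de_alpha,
                           control = sim$design$treatments[1])
  de$symbol <- sim$expression$probe_map$symbol[
    match(de$probe_set_id, sim$expression$probe_map$probe_set_id)]
  write_tsv(de, file.path(dir, "de_results.tsv"))
  clust <- NULL
  if (sum(de$pass_final) >= 2) {
    clust <- cluster_significant(
      sim$expression$signal[de$pass_final, , drop = FALSE])
    write_tsv(data.frame(
      sample_id = colnames(sim$expression$signal)[clust$sample_order],
      position = seq_along(clust$sample_order)),
      file.path(dir, "cluster_samples.tsv"))
    write_tsv(data.frame(
      probe_set_id = rownames(clust$z)[clust$probe_order],
      position = seq_along(clust$probe_order)),
      file.path(dir, "cluster_probes.tsv"))
  }
  list(de = de, clust = clust)
}

stage_integrate <- function(sim, meth, trans, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pairs <- map_by_symbol(sim$expression$probe_map, sim$annotation$regions)
  corr <- integrate_methylation_expression(sim$expression, meth$proc$donor,
                                           pairs, sim$design$organs[1])
  up <- build_gene_table(trans$de, meth$dm, corr, pairs,
                         sim$annotation$regions, top_n = config$top_n,
                         direction = "up", min_signal = config$min_signal)
  down <- build_gene_table(trans$de, meth$dm, corr, pairs,
                           sim$annotation$regions, top_n = config$top_n,
                           direction = "down",
                           min_signal = config$min_signal)
  write_tsv(pairs, file.path(dir, "pairs.tsv"))
  write_tsv(corr, file.path(dir, "correlations.tsv"))
  write_tsv(up, file.path(dir, "gene_table_up.tsv"))
  write_tsv(down, file.path(dir, "gene_table_down.tsv"))
  list(pairs = pairs, corr = corr, up = up, down = down)
}

stage_validate <- function(sim, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ddct <- ddct_fold_change(sim$assays$expression_ct, target = "target",
                           reference = "reference",
                           control_group = sim$design$treatments[1])
  medip <- qpcr_enrichment(sim$assays$medip_ct)
  pm <- lapply(sim$assays$clones, percent_methylation)
  bis <- data.frame(group = names(pm),
                    percent = vapply(pm, `[[`, numeric(1), "percent"),
                    n_clones = vapply(pm, `[[`, numeric(1), "n_clones"))
  pyro_target <- sim$assays$pyro[
    sim$assays$pyro$organ == sim$design$organs[1], , drop = FALSE]
  pyro <- pyro_group_compare(pyro_target,
                             control = sim$design$treatments[1])
  chip <- chip_enrichment(sim$assays$chip_ct)
  write_tsv(ddct$per_sample, file.path(dir, "ddct_per_sample.tsv"))
  write_tsv(ddct$per_group, file.path(dir, "ddct_per_group.tsv"))
  write_tsv(medip, file.path(dir, "medip_enrichment.tsv"))
  write_tsv(bis, file.path(dir, "bisulfite_percent.tsv"))
  write_tsv(pyro, file.path(dir, "pyro_compare.tsv"))
  write_tsv(chip$records, file.path(dir, "chip_records.tsv"))
  write_tsv(chip$switch_summary, file.path(dir, "chip_switch_summary.tsv"))
  list(ddct = ddct, medip = medip, bisulfite = bis, pyro = pyro,
       chip = chip)
}

## ---- run ------------------------------------------------------------------

#' Run the full pipeline end to end
#'
#' Executes the stages in order — simulate, methylome, transcriptome,
#' integrate, validate — writing every stage's tables plus a serialized copy
#' of the configuration and a deterministic run manifest (stage list, file
#' checksums, seed, software version) into `out_dir`.  Re-running with the
#' same configuration reproduces byte-identical outputs and manifest.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory.
#' @param simulate generate inputs (`TRUE`, default) or read them from
#'   `input_dir`.
#' @param input_dir directory holding a study written by
#'   [write_simulation()] (required when `simulate = FALSE`).
#' @param quiet suppress per-stage messages.
#' @return invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         simulate = TRUE, input_dir = NULL, quiet = FALSE) {
  run <- function(expr) if (quiet) suppressMessages(expr) else expr
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- if (simulate) {
    run(simulate_study(config))
  } else {
    if (is.null(input_dir)) stopf("input_dir required when simulate = FALSE")
    run(read_simulation(input_dir))
  }
  run(write_simulation(sim, file.path(out_dir, "sim")))
  meth <- run(stage_methylome(sim, config, file.path(out_dir, "methylome")))
  trans <- run(stage_transcriptome(sim, config,
                                   file.path(out_dir, "transcriptome")))
  integ <- run(stage_integrate(sim, meth, trans, config,
                               file.path(out_dir, "integration")))
  valid <- run(stage_validate(sim, config, file.path(out_dir, "validation")))
  write_config(config, file.path(out_dir, "config.yaml"))
  manifest <- build_manifest(config, out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(sprintf("completed at %s", format(Sys.time(), tz = "UTC")),
             file.path(out_dir, "run.log"))
  invisible(list(sim = sim, methylome = meth, transcriptome = trans,
                 integration = integ, validation = valid,
                 manifest = manifest))
}

# Deterministic manifest: stages, sorted relative paths with md5 checksums,
# seed and package version.  Wall-clock time is logged separately (run.log)
# so that identical runs yield identical manifests.
build_manifest <- function(config, out_dir) {
  files <- sort(list.files(out_dir, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, c("manifest.json", "run.log"))
  sums <- as.vector(tools::md5sum(file.path(out_dir, files)))
  list(
    package = "episwitch",
    version = as.character(utils::packageVersion("episwitch")),
    seed = config$seed,
    stages = c("simulate", "methylome", "transcriptome", "integrate",
               "validate"),
    config = unclass(config),
    files = as.list(stats::setNames(sums, files))
  )
}
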