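# End-to-end pipeline: simulate -> centrality -> GLM -> spatial association
# -> enrichment -> cell-type profiling, with a single config object and JSON
# provenance sidecars for every written output.

#' Pipeline configuration with the analysis' standard thresholds
#'
#' Defaults are the canonical analysis settings: GM mask at 0.20, degree cut
#' r > 0.25, display threshold p < 0.001 with cluster extent k = 20, light
#' association-input threshold p < 0.01, 5-mm sampling window, PCA variance
#' target 95%, 1000 bootstraps, filter (chance likelihood < 0.001,
#' autocorrelation >= 0.2, adjusted R^2 >= 0.15), enrichment alpha 0.05.
#'
#' @param gm_threshold,r_threshold,display_p,display_k,assoc_p,window_mm
#'   imaging-side thresholds (see description).
#' @param parcel_edge_vox parcel edge (voxels) for donor alignment.
#' @param pca_variance,n_boot,cl_max,ac_min,r2_min association-side settings.
#' @param enrichment_alpha Bonferroni-corrected significance level.
#' @param seed integer master seed.
#' @param sim a [sim_config()] describing the synthetic study (used when the
#'   pipeline simulates its own inputs); its seed is kept in sync with `seed`.
#' @return object of class `imgtx_config`.
#' @export
pipeline_config <- function(gm_threshold = 0.20, r_threshold = 0.25,
                            display_p = 0.001, display_k = 20L,
                            assoc_p = 0.01, window_mm = 5,
                            parcel_edge_vox = 2L, pca_variance = 0.95,
                            n_boot = 1000L, cl_max = 0.001, ac_min = 0.2,
                            r2_min = 0.15, enrichment_alpha = 0.05,
                            seed = 1L, sim = NULL) {
  chk01 <- function(x, nm, lo = 0, hi = 1) {
    if (!is.numeric(x) || length(x) != 1L || x <= lo || x >= hi) {
      stop(nm, " must lie strictly inside (", lo, ", ", hi, ")", call. = FALSE)
    }
  }
  chk01(gm_threshold, "gm_threshold")
  chk01(display_p, "display_p")
  chk01(assoc_p, "assoc_p")
  chk01(pca_variance, "pca_variance")
  chk01(cl_max, "cl_max")
  chk01(enrichment_alpha, "enrichment_alpha")
  if (r_threshold <= -1 || r_threshold >= 1) stop("r_threshold must be in (-1, 1)", call. = FALSE)
  if (display_k < 1L) stop("display_k must be >= 1", call. = FALSE)
  if (window_mm <= 0) stop("window_mm must be positive", call. = FALSE)
  if (n_boot < 1L) stop("n_boot must be >= 1", call. = FALSE)
  if (is.null(sim)) sim <- sim_config(seed = as.integer(seed))
  sim$seed <- as.integer(seed)
  structure(list(gm_threshold = gm_threshold, r_threshold = r_threshold,
                 display_p = display_p, display_k = as.integer(display_k),
                 assoc_p = assoc_p, window_mm = window_mm,
                 parcel_edge_vox = as.integer(parcel_edge_vox),
                 pca_variance = pca_variance, n_boot = as.integer(n_boot),
                 cl_max = cl_max, ac_min = ac_min, r2_min = r2_min,
                 enrichment_alpha = enrichment_alpha,
                 seed = as.integer(seed), sim = sim),
            class = "imgtx_config")
}

config_as_list <- function(config) {
  cfg <- unclass(config)
  cfg$sim <- unclass(cfg$sim)
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config an `imgtx_config`.
#' @param path YAML file path.
#' @return `path` / the restored `imgtx_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "imgtx_config"))
  yaml::write_yaml(config_as_list(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim
  sim_args$n_per_group <- unlist(sim_args$n_per_group)
  sim_args$shared_signal_gain <- unlist(sim_args$shared_signal_gain)
  sim_args$grid_shape <- unlist(sim_args$grid_shape)
  sim_args$hub_voxels <- unlist(sim_args$hub_voxels)
  sim <- do.call(sim_config, sim_args)
  raw$sim <- NULL
  do.call(pipeline_config, c(raw, list(sim = sim)))
}

# JSON provenance sidecar: the verbatim config, seed, stage, input hashes
# and the package version suffice to re-run the producing stage.
write_sidecar <- function(data_path, stage, config, inputs = character(0)) {
  side <- list(
    stage = stage,
    output = basename(data_path),
    seed = config$seed,
    config = config_as_list(config),
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    package_version = as.character(utils::packageVersion("imgtx"))
  )
  jsonlite::write_json(side, paste0(data_path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(data_path)
}

#' Run the full imaging-transcriptomics pipeline on synthetic inputs
#'
#' Executes simulate -> centrality -> GLM (patients vs controls, one-sided
#' "greater") -> display and light thresholding -> donor atlas coupled to
#' the light-thresholded map -> donor preprocessing -> image sampling ->
#' unit alignment -> per-gene association -> filter -> gene-set enrichment
#' -> cell-type profiling of passing genes. When `out_dir` is given, every
#' tabular output is written as TSV with a JSON provenance sidecar;
#' re-running with the same config yields byte-identical TSVs.
#'
#' @param config an [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list with cohort, maps, contrast maps, atlas truth, association
#'   table, passing genes, enrichment table, cell-type profiles, and summary
#'   recovery metrics.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "imgtx_config"))
  simc <- config$sim

  cohort <- generate_cohort(simc)
  maps <- cohort_centrality(cohort, gm_threshold = config$gm_threshold,
                            r_threshold = config$r_threshold)
  design <- group_design(cohort$covariates)
  contrast <- group_contrast(design, "patient", "control")
  cm <- fit_voxelwise_glm(maps, design, contrast, label = "patient_gt_control",
                          direction = "greater",
                          voxel_mm = cohort$voxel_mm,
                          origin_mm = cohort$origin_mm)
  display_map <- threshold_map(cm, p_voxel = config$display_p,
                               k = config$display_k)
  light_map <- threshold_map(cm, p_voxel = config$assoc_p, k = 1L)

  # expression couples to the association-input map at the same window
  # scale the image is sampled at
  atlas <- generate_donor_atlas(simc, coupling_map = light_map,
                                window_mm = config$window_mm)
  prep <- prepare_donors(atlas$bundles)
  image_samples <- lapply(prep$bundles, function(b) {
    sample_image_at_coords(light_map, b$samples, window_mm = config$window_mm)
  })
  aligned <- align_units(prep$bundles, image_samples,
                         parcel_edge_vox = config$parcel_edge_vox,
                         voxel_mm = cohort$voxel_mm,
                         origin_mm = cohort$origin_mm,
                         mode = if (simc$shared_donor_coords) "sample" else "parcel")
  assoc <- gene_association(aligned, n_boot = config$n_boot,
                            seed = config$seed, var_target = config$pca_variance,
                            cl_max = config$cl_max, ac_min = config$ac_min,
                            r2_min = config$r2_min)
  passing <- filter_genes(assoc, config$cl_max, config$ac_min, config$r2_min)

  gene_sets <- generate_gene_sets(atlas$truth$genes, seed = config$seed + 101L)
  enr <- if (length(passing)) {
    hypergeometric_enrichment(passing, gene_sets$sets, gene_sets$background,
                              alpha = config$enrichment_alpha)
  } else NULL

  ct_mat <- generate_celltype_matrix(
    atlas$truth$genes$gene_symbol,
    cell_types = c("neuron", "astrocyte", "microglia", "oligodendrocyte",
                   "endothelial"),
    seed = config$seed + 202L
  )
  ct_norm <- quantile_normalize(ct_mat)
  profiles <- if (length(passing)) {
    do.call(rbind, lapply(passing, function(g) {
      pr <- celltype_profile(ct_norm, g)
      pr$gene <- g
      pr[, c("gene", setdiff(names(pr), "gene"))]
    }))
  } else NULL

  truth <- atlas$truth$genes
  coupled <- truth$gene_symbol[truth$coupled]
  nullg <- truth$gene_symbol[!truth$coupled]
  metrics <- list(
    n_passing = length(passing),
    coupled_recovery = if (length(coupled)) mean(coupled %in% passing) else NA_real_,
    null_pass_rate = if (length(nullg)) mean(nullg %in% passing) else NA_real_
  )

  result <- list(cohort = cohort, centrality_maps = maps, contrast_map = cm,
                 display_map = display_map, light_map = light_map,
                 atlas_truth = atlas$truth, aligned = aligned,
                 association = assoc, passing_genes = passing,
                 gene_sets = gene_sets, enrichment = enr,
                 celltype_matrix = ct_norm, celltype_profiles = profiles,
                 metrics = metrics, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name, stage) {
      p <- file.path(out_dir, name)
      write_tsv_canonical(df, p)
      write_sidecar(p, stage, config)
      p
    }
    wr(cohort$covariates, "covariates.tsv", "simulate")
    wr(assoc, "association.tsv", "associate")
    wr(data.frame(gene = passing, stringsAsFactors = FALSE),
       "passing_genes.tsv", "associate")
    if (!is.null(enr)) wr(enr, "enrichment.tsv", "enrich")
    if (!is.null(profiles)) wr(profiles, "celltype_profiles.tsv", "celltype")
    wr(truth, "gene_truth.tsv", "simulate")
    write_gmt(gene_sets$sets, file.path(out_dir, "gene_sets.gmt"))
    write_sidecar(file.path(out_dir, "gene_sets.gmt"), "simulate", config)
    write_config(config, file.path(out_dir, "config.yaml"))
  }
  result
}
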