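# Synthetic study generator: two-group resting-state cohorts with planted
# connectivity hubs, multi-donor expression atlases spatially coupled to a
# contrast map, annotation sets and cell-type matrices -- all with ground
# truth attached so recovery rates are computable downstream.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic study: the voxel grid, cohort sizes,
#' the planted hub region and per-group connectivity gains, and the donor
#' atlas (number of donors, samples, genes, expression-to-map coupling,
#' probe multiplicity and induced skew). Defaults are the package's standard
#' study conditions; see the methods vignette for the rationale behind each.
#'
#' @param grid_shape integer triple, voxels per axis.
#' @param n_timepoints number of time points per subject (>= 3).
#' @param n_per_group named integer pair `c(control=, patient=)`.
#' @param hub_voxels integer vector of linear voxel indices carrying the
#'   shared latent signal; default is the central 3x3x3 block.
#' @param shared_signal_gain named numeric pair, latent-signal gain per group;
#'   a larger gain raises pairwise correlation among hub voxels and hence
#'   their degree centrality.
#' @param noise_sd standard deviation of the i.i.d. Gaussian background noise.
#' @param n_donors,n_samples_per_donor atlas dimensions.
#' @param n_genes,n_coupled_genes total genes and how many are spatially
#'   coupled to the map.
#' @param coupling_beta effect size: coupled expression = beta * map z-value
#'   at the sample's voxel + noise.
#' @param expression_noise_sd SD of expression noise.
#' @param n_probes_per_gene probes measured per gene (>= 1); exactly one is
#'   the untransformed representative signal.
#' @param skew_severity s >= 0; non-representative probes are passed through
#'   the monotone map (exp(s*x) - 1)/s, which induces positive skew and
#'   reduces to the identity at s = 0.
#' @param voxel_mm isotropic voxel size in mm.
#' @param gm_mask_floor gray-matter probability assigned inside the brain
#'   (must be >= any mask threshold in use for the whole grid to be masked in).
#' @param confounded_covariates if TRUE, age is shifted upward in patients so
#'   covariate adjustment has something to remove; default independent.
#' @param shared_donor_coords if TRUE all donors share one set of sample
#'   coordinates (enables exact sample-level alignment); default donor-specific.
#' @param seed integer master seed; all generator randomness derives from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(grid_shape = c(12L, 12L, 12L),
                       n_timepoints = 100L,
                       n_per_group = c(control = 20L, patient = 20L),
                       hub_voxels = NULL,
                       shared_signal_gain = c(control = 0.2, patient = 1.0),
                       noise_sd = 1,
                       n_donors = 6L,
                       n_samples_per_donor = 900L,
                       n_genes = 60L,
                       n_coupled_genes = 20L,
                       coupling_beta = 2.5,
                       expression_noise_sd = 1,
                       n_probes_per_gene = 3L,
                       skew_severity = 1,
                       voxel_mm = 2,
                       gm_mask_floor = 0.9,
                       confounded_covariates = FALSE,
                       shared_donor_coords = FALSE,
                       seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L)) {
    stop("grid_shape must be three positive integers", call. = FALSE)
  }
  if (n_timepoints < 3L) stop("n_timepoints must be >= 3", call. = FALSE)
  n_per_group <- as.integer(n_per_group)
  if (length(n_per_group) != 2L || any(n_per_group < 2L)) {
    stop("n_per_group must be two integers >= 2", call. = FALSE)
  }
  names(n_per_group) <- c("control", "patient")
  if (is.null(hub_voxels)) hub_voxels <- default_hub(grid_shape)
  hub_voxels <- sort(unique(as.integer(hub_voxels)))
  nvox <- prod(grid_shape)
  if (length(hub_voxels) == 0L || any(hub_voxels < 1L) || any(hub_voxels > nvox)) {
    stop("hub_voxels must be non-empty linear indices inside the grid", call. = FALSE)
  }
  if (length(shared_signal_gain) != 2L || any(shared_signal_gain < 0)) {
    stop("shared_signal_gain must be two non-negative gains", call. = FALSE)
  }
  names(shared_signal_gain) <- c("control", "patient")
  if (noise_sd <= 0 || expression_noise_sd <= 0) {
    stop("noise SDs must be positive", call. = FALSE)
  }
  if (n_coupled_genes > n_genes) stop("n_coupled_genes must be <= n_genes", call. = FALSE)
  if (n_probes_per_gene < 1L) stop("n_probes_per_gene must be >= 1", call. = FALSE)
  if (skew_severity < 0) stop("skew_severity must be >= 0", call. = FALSE)
  if (n_donors < 2L) stop("need at least 2 donors", call. = FALSE)
  cfg <- list(
    grid_shape = grid_shape, n_timepoints = as.integer(n_timepoints),
    n_per_group = n_per_group, hub_voxels = hub_voxels,
    shared_signal_gain = shared_signal_gain, noise_sd = noise_sd,
    n_donors = as.integer(n_donors),
    n_samples_per_donor = as.integer(n_samples_per_donor),
    n_genes = as.integer(n_genes), n_coupled_genes = as.integer(n_coupled_genes),
    coupling_beta = coupling_beta, expression_noise_sd = expression_noise_sd,
    n_probes_per_gene = as.integer(n_probes_per_gene),
    skew_severity = skew_severity, voxel_mm = voxel_mm,
    gm_mask_floor = gm_mask_floor,
    confounded_covariates = isTRUE(confounded_covariates),
    shared_donor_coords = isTRUE(shared_donor_coords),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Linear voxel indices of a cubic block
#'
#' @param grid_shape integer triple.
#' @param lo lower corner (1-based voxel indices).
#' @param edge block edge in voxels.
#' @return integer vector of linear indices.
#' @export
block_voxels <- function(grid_shape, lo, edge = 3L) {
  lo <- pmax(1L, as.integer(lo))
  hi <- pmin(grid_shape, lo + as.integer(edge) - 1L)
  idx <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
  as.integer(idx$x + (idx$y - 1L) * grid_shape[1] +
               (idx$z - 1L) * grid_shape[1] * grid_shape[2])
}

# Linear indices of the central edge^3 block of the grid.
central_block <- function(grid_shape, edge = 3L) {
  block_voxels(grid_shape, floor((grid_shape - edge) / 2) + 1L, edge)
}

# Default planted phenotype: three hub nodes (two left-hemisphere, one
# right), emulating a spatially distributed network rather than one focal
# cluster; node edge scales with the grid.
default_hub <- function(grid_shape) {
  edge <- max(2L, min(4L, floor(min(grid_shape) / 3)))
  lo_l <- pmax(1L, floor(grid_shape / 6))
  hi <- pmax(1L, floor(2 * grid_shape / 3))
  sort(unique(c(
    block_voxels(grid_shape, c(lo_l[1], lo_l[2], lo_l[3]), edge),
    block_voxels(grid_shape, c(lo_l[1], hi[2], hi[3]), edge),
    block_voxels(grid_shape, c(hi[1], floor(grid_shape[2] / 2), floor(grid_shape[3] / 2)), edge)
  )))
}

#' Generate a two-group resting-state cohort with a planted hub region
#'
#' Each subject's 4-D time series is i.i.d. Gaussian noise; voxels in the
#' configured hub set additionally receive one subject-specific latent time
#' series scaled by the subject's group gain, so hub voxels correlate with
#' one another and their degree centrality rises monotonically with the gain.
#' Covariates (age, sex, scanner) are drawn independently of group unless
#' `confounded_covariates` is set.
#'
#' @param config a [sim_config()].
#' @return an object of class `imgtx_cohort`: list with `subjects` (named list
#'   of 4-D arrays), `gm_probability` (3-D), `covariates` (data.frame with
#'   subject_id, group, age, sex, scanner), grid geometry, and `truth`
#'   (hub voxel indices and the config).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed, {
    dims <- config$grid_shape
    nvox <- prod(dims)
    tp <- config$n_timepoints
    groups <- rep(c("control", "patient"), config$n_per_group)
    n <- length(groups)
    ids <- sprintf("sub-%03d", seq_len(n))
    subjects <- vector("list", n)
    names(subjects) <- ids
    for (i in seq_len(n)) {
      flat <- matrix(stats::rnorm(nvox * tp, sd = config$noise_sd), nvox, tp)
      gain <- config$shared_signal_gain[[groups[i]]]
      if (gain > 0) {
        latent <- stats::rnorm(tp)
        flat[config$hub_voxels, ] <- flat[config$hub_voxels, , drop = FALSE] +
          gain * matrix(latent, length(config$hub_voxels), tp, byrow = TRUE)
      }
      subjects[[i]] <- array(flat, dim = c(dims, tp))
    }
    age <- round(pmin(80, pmax(18, stats::rnorm(n, 45, 12))), 1)
    if (config$confounded_covariates) age <- age + 8 * (groups == "patient")
    covars <- data.frame(
      subject_id = ids,
      group = groups,
      age = age,
      sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.6, 0.4)),
      scanner = sample(c("scannerA", "scannerB"), n, replace = TRUE,
                       prob = c(0.55, 0.45)),
      stringsAsFactors = FALSE
    )
    gm <- array(config$gm_mask_floor, dim = dims)
    structure(list(
      subjects = subjects,
      gm_probability = gm,
      covariates = covars,
      voxel_mm = rep(config$voxel_mm, 3),
      origin_mm = default_origin(dims, config$voxel_mm),
      truth = list(hub_voxels = config$hub_voxels, config = config)
    ), class = "imgtx_cohort")
  })
}

# Monotone skew transform for non-representative probes; identity at s = 0.
skew_transform <- function(x, s) {
  if (s == 0) x else (exp(s * x) - 1) / s
}

#' Generate a multi-donor expression atlas coupled to a contrast map
#'
#' Each donor receives sample coordinates drawn uniformly over the grid
#' (donor-specific unless `shared_donor_coords`), spanning both hemispheres.
#' The map value at a coordinate is the mean of the map's defined voxels in
#' the cubic window of edge `window_mm` centered there (the scale at which
#' the association stage reads the image), z-scored across the donor's
#' samples; a coupled gene's expression at a sample is `coupling_beta` times
#' that value plus Gaussian noise, a null gene pure noise. Every gene carries
#' `n_probes_per_gene` probes: one untransformed representative and
#' monotonically skew-transformed copies of it.
#'
#' @param config a [sim_config()].
#' @param coupling_map a `contrast_map` on the atlas grid (its t-volume drives
#'   the coupling). Required when `coupling_beta != 0` and
#'   `n_coupled_genes > 0`.
#' @param window_mm edge of the averaging window used to evaluate the map at
#'   sample coordinates, default 5.
#' @return list with `bundles` (list of `donor_bundle`) and `truth`
#'   (data.frames `genes` with gene_symbol/coupled and `probes` with
#'   probe_id/gene_symbol/representative).
#' @export
generate_donor_atlas <- function(config, coupling_map = NULL, window_mm = 5) {
  stopifnot(inherits(config, "sim_config"))
  dims <- config$grid_shape
  wants_coupling <- config$coupling_beta != 0 && config$n_coupled_genes > 0L
  if (wants_coupling) {
    if (is.null(coupling_map)) {
      stop("coupling_beta is nonzero but no coupling_map was supplied", call. = FALSE)
    }
    stopifnot(inherits(coupling_map, "contrast_map"))
    if (!identical(dim(coupling_map$t), dims)) {
      stop("coupling_map grid does not match config$grid_shape", call. = FALSE)
    }
    if (!any(!is.na(coupling_map$t))) {
      stop("coupling_map has no defined voxels", call. = FALSE)
    }
  }
  voxel_mm <- rep(config$voxel_mm, 3)
  origin <- default_origin(dims, config$voxel_mm)
  half <- dims * config$voxel_mm / 2 # grid is centered on 0 on every axis

  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  local_seed(config$seed + 1L, {
    coupled <- rep(FALSE, config$n_genes)
    coupled[sample.int(config$n_genes, config$n_coupled_genes)] <- TRUE
    rep_slot <- sample.int(config$n_probes_per_gene, config$n_genes, replace = TRUE)
    probe_tab <- data.frame(
      probe_id = sprintf("%s_p%02d", rep(genes, each = config$n_probes_per_gene),
                         rep(seq_len(config$n_probes_per_gene), config$n_genes)),
      gene_symbol = rep(genes, each = config$n_probes_per_gene),
      representative = as.vector(vapply(seq_len(config$n_genes), function(g) {
        seq_len(config$n_probes_per_gene) == rep_slot[g]
      }, logical(config$n_probes_per_gene))),
      stringsAsFactors = FALSE
    )
    draw_xyz <- function(ns) {
      vapply(1:3, function(a) stats::runif(ns, -half[a], half[a]),
             numeric(ns))
    }
    shared_xyz <- if (config$shared_donor_coords) {
      draw_xyz(config$n_samples_per_donor)
    } else NULL
    bundles <- lapply(seq_len(config$n_donors), function(d) {
      ns <- config$n_samples_per_donor
      xyz <- if (!is.null(shared_xyz)) shared_xyz else draw_xyz(ns)
      # window-averaged map value at each sample, z-scored across samples
      mv <- if (wants_coupling) {
        coords <- data.frame(sample_id = seq_len(ns),
                             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
        raw <- sample_image_at_coords(coupling_map, coords, window_mm)$raw
        raw[is.na(raw)] <- 0
        s <- stats::sd(raw)
        if (s > 0) (raw - mean(raw)) / s else raw * 0
      } else {
        numeric(ns)
      }
      signal <- matrix(0, config$n_genes, ns)
      if (any(coupled)) {
        signal[coupled, ] <- config$coupling_beta *
          matrix(mv, sum(coupled), ns, byrow = TRUE)
      }
      expr_gene <- signal + matrix(stats::rnorm(config$n_genes * ns,
                                                sd = config$expression_noise_sd),
                                   config$n_genes, ns)
      # expand to probes: representative = signal, others skewed copies
      expr <- matrix(NA_real_, nrow(probe_tab), ns,
                     dimnames = list(probe_tab$probe_id,
                                     sprintf("D%02d_s%04d", d, seq_len(ns))))
      for (g in seq_len(config$n_genes)) {
        rows <- which(probe_tab$gene_symbol == genes[g])
        for (j in seq_along(rows)) {
          expr[rows[j], ] <- if (probe_tab$representative[rows[j]]) {
            expr_gene[g, ]
          } else {
            skew_transform(expr_gene[g, ], config$skew_severity)
          }
        }
      }
      samples <- data.frame(
        sample_id = colnames(expr),
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        stringsAsFactors = FALSE
      )
      donor_bundle(sprintf("donor%02d", d), expr,
                   probe_tab[, c("probe_id", "gene_symbol")], samples)
    })
    list(
      bundles = bundles,
      truth = list(
        genes = data.frame(gene_symbol = genes, coupled = coupled,
                           stringsAsFactors = FALSE),
        probes = probe_tab
      )
    )
  })
}

#' Generate annotation gene sets with one planted enriched set
#'
#' The first ("planted") set is filled with coupled genes at the requested
#' fraction; all remaining sets are drawn uniformly from the background, so
#' under `enriched_fraction` equal to the background coupled proportion the
#' planted set carries no signal.
#'
#' @param truth_genes data.frame with columns gene_symbol and coupled (the
#'   `truth$genes` of [generate_donor_atlas()]).
#' @param n_sets number of sets.
#' @param enriched_fraction fraction of the planted set drawn from coupled
#'   genes, in \[0, 1\].
#' @param set_size genes per set.
#' @param seed integer seed.
#' @return list with `sets` (named list of gene vectors), `enriched_set`
#'   (label of the planted set) and `background` (all gene symbols).
#' @export
generate_gene_sets <- function(truth_genes, n_sets = 10L, enriched_fraction = 1,
                               set_size = 10L, seed = 1L) {
  if (enriched_fraction < 0 || enriched_fraction > 1) {
    stop("enriched_fraction must be in [0, 1]", call. = FALSE)
  }
  background <- truth_genes$gene_symbol
  if (length(background) == 0L) stop("empty background", call. = FALSE)
  coupled <- background[truth_genes$coupled]
  nullg <- background[!truth_genes$coupled]
  local_seed(seed, {
    n_c <- min(length(coupled), round(enriched_fraction * set_size))
    planted <- c(sample(coupled, n_c),
                 sample(nullg, min(length(nullg), set_size - n_c)))
    sets <- c(list(planted),
              lapply(seq_len(max(0L, n_sets - 1L)), function(i) {
                sample(background, min(set_size, length(background)))
              }))
    names(sets) <- c("SET_PLANTED", sprintf("SET_%03d", seq_len(n_sets))[-1][seq_len(max(0L, n_sets - 1L))])
    list(sets = sets, enriched_set = "SET_PLANTED", background = background)
  })
}

#' Generate a cell-type expression matrix with designated marker genes
#'
#' Baseline expression is nonnegative (gamma-distributed) across
#' `n_replicates` replicate columns per cell type; each marker gene's
#' expression is amplified in its assigned cell type.
#'
#' @param genes character vector of gene symbols (rows).
#' @param cell_types character vector of >= 2 cell-type labels.
#' @param n_replicates replicate columns per cell type.
#' @param markers optional named character vector gene -> cell type.
#' @param marker_fold fold elevation of a marker in its own type.
#' @param seed integer seed.
#' @return a numeric genes x (type x replicate) matrix with attribute
#'   `cell_types` (character vector, one per column).
#' @export
generate_celltype_matrix <- function(genes, cell_types, n_replicates = 4L,
                                     markers = NULL, marker_fold = 8,
                                     seed = 1L) {
  if (length(cell_types) < 2L) stop("need at least 2 cell types", call. = FALSE)
  local_seed(seed, {
    ncol_total <- length(cell_types) * n_replicates
    col_types <- rep(cell_types, each = n_replicates)
    m <- matrix(stats::rgamma(length(genes) * ncol_total, shape = 2, rate = 1),
                length(genes), ncol_total,
                dimnames = list(genes,
                                paste0(col_types, "_r",
                                       rep(seq_len(n_replicates), length(cell_types)))))
    if (!is.null(markers)) {
      bad <- setdiff(names(markers), genes)
      if (length(bad)) stop("marker genes absent from `genes`: ",
                            paste(bad, collapse = ", "), call. = FALSE)
      for (g in names(markers)) {
        m[g, col_types == markers[[g]]] <- m[g, col_types == markers[[g]]] * marker_fold
      }
    }
    attr(m, "cell_types") <- col_types
    m
  })
}
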