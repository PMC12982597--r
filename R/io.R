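# File interfaces: NIfTI volumes, donor-bundle TSV triplets, GMT gene sets,
# canonical TSV writing for reproducible pipeline outputs.

#' Write a 3-D or 4-D volume as NIfTI
#'
#' @param vol numeric array (NA allowed).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_mm voxel size per spatial axis in mm.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(vol, path, voxel_mm = c(1, 1, 1)) {
  img <- RNifti::asNifti(vol)
  pd <- rep(1, length(dim(vol)))
  pd[1:3] <- voxel_mm
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file.
#' @return numeric array with attribute `voxel_mm`.
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "voxel_mm") <- RNifti::pixdim(img)[seq_len(min(3L, length(dim(img))))]
  out
}

# Deterministic TSV writer: fixed column order, no quoting surprises,
# 15 significant digits.
write_tsv_canonical <- function(df, path) {
  old <- options(scipen = 0, digits = 15)
  on.exit(options(old))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

#' Write a donor bundle as its three-TSV representation
#'
#' Creates `<dir>/<donor_id>/{expression,probes,samples}.tsv`: expression is
#' probe x sample (first column probe_id), probes maps probe_id to
#' gene_symbol, samples holds sample_id and x/y/z in mm.
#'
#' @param bundle a `donor_bundle`.
#' @param dir output directory.
#' @return the donor directory, invisibly.
#' @export
write_donor_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "donor_bundle"))
  ddir <- file.path(dir, bundle$donor_id)
  dir.create(ddir, recursive = TRUE, showWarnings = FALSE)
  expr_df <- data.frame(probe_id = rownames(bundle$expression),
                        bundle$expression, check.names = FALSE,
                        stringsAsFactors = FALSE)
  write_tsv_canonical(expr_df, file.path(ddir, "expression.tsv"))
  write_tsv_canonical(bundle$probes, file.path(ddir, "probes.tsv"))
  write_tsv_canonical(bundle$samples[, c("sample_id", "x", "y", "z")],
                      file.path(ddir, "samples.tsv"))
  invisible(ddir)
}

#' Read a donor bundle from its three-TSV representation
#'
#' @param ddir donor directory containing expression.tsv, probes.tsv,
#'   samples.tsv.
#' @param donor_id donor label; defaults to the directory name.
#' @return a `donor_bundle`.
#' @export
read_donor_bundle <- function(ddir, donor_id = basename(ddir)) {
  expr_df <- utils::read.delim(file.path(ddir, "expression.tsv"),
                               check.names = FALSE, stringsAsFactors = FALSE)
  expr <- as.matrix(expr_df[, -1, drop = FALSE])
  rownames(expr) <- expr_df[[1]]
  probes <- utils::read.delim(file.path(ddir, "probes.tsv"),
                              stringsAsFactors = FALSE)
  samples <- utils::read.delim(file.path(ddir, "samples.tsv"),
                               stringsAsFactors = FALSE)
  donor_bundle(donor_id, expr, probes, samples)
}

#' Write gene sets in GMT format
#'
#' One line per set: label, description ("na"), then member genes,
#' tab-separated.
#'
#' @param sets named list of gene vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (label, description, members per line).
#' @return named list of gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1L)
  sets
}

#' Write a cohort to disk (NIfTI volumes + covariate TSV)
#'
#' @param cohort an `imgtx_cohort`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "imgtx_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$subjects)) {
    write_volume_nifti(cohort$subjects[[id]],
                       file.path(dir, paste0(id, "_bold.nii.gz")),
                       cohort$voxel_mm)
  }
  write_volume_nifti(cohort$gm_probability, file.path(dir, "gm_prob.nii.gz"),
                     cohort$voxel_mm)
  write_tsv_canonical(cohort$covariates, file.path(dir, "covariates.tsv"))
  invisible(dir)
}
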