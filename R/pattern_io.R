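#' Save and load a covariance-pattern bundle
#'
#' A pattern bundle is a directory holding `weights.nii.gz`, `gmp.nii.gz`,
#' and `mask.nii.gz` plus a `pattern.json` sidecar with the scalar
#' provenance (component indices, logistic coefficients, variance
#' fractions, normalization, derivation summary).  A reloaded bundle scores
#' new scans identically to the in-memory pattern.
#'
#' @param pattern a `covariance_pattern`.
#' @param dir bundle directory (created if absent).
#' @return `write_pattern` returns `dir` invisibly; `read_pattern` returns
#'   the `covariance_pattern`.
#' @export
write_pattern <- function(pattern, dir) {
  stopifnot(inherits(pattern, "covariance_pattern"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  export_weight_map(pattern$weights, pattern$mask, pattern$affine,
                    file.path(dir, "weights.nii.gz"))
  export_weight_map(pattern$gmp, pattern$mask, pattern$affine,
                    file.path(dir, "gmp.nii.gz"))
  write_nifti_volume(array(as.numeric(pattern$mask), pattern$grid_shape),
                     pattern$affine, file.path(dir, "mask.nii.gz"))
  summ <- pattern$derivation_summary
  summ$aic_trace <- NULL  # tabular; serialized separately below
  meta <- list(
    component_indices = pattern$component_indices,
    coefficients = pattern$coefficients,
    intercept = pattern$intercept,
    variance_fractions = pattern$variance_fractions,
    normalization = pattern$normalization,
    grid_shape = pattern$grid_shape,
    derivation_summary = summ,
    aic_trace = pattern$derivation_summary$aic_trace
  )
  jsonlite::write_json(meta, file.path(dir, "pattern.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' @rdname write_pattern
#' @export
read_pattern <- function(dir) {
  meta_path <- file.path(dir, "pattern.json")
  if (!file.exists(meta_path)) {
    stop_ssm("config", "not a pattern bundle (missing pattern.json): %s", dir)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  mask_img <- RNifti::readNifti(file.path(dir, "mask.nii.gz"))
  mask <- array(as.vector(mask_img) > 0.5, dim = dim(mask_img))
  w_img <- RNifti::readNifti(file.path(dir, "weights.nii.gz"))
  g_img <- RNifti::readNifti(file.path(dir, "gmp.nii.gz"))
  structure(
    list(weights = as.vector(w_img)[as.vector(mask)],
         mask = mask, grid_shape = as.integer(dim(mask)),
         affine = unclass(RNifti::xform(mask_img)),
         component_indices = as.integer(meta$component_indices),
         coefficients = as.numeric(meta$coefficients),
         intercept = meta$intercept %||% NA_real_,
         variance_fractions = as.numeric(meta$variance_fractions),
         gmp = as.vector(g_img)[as.vector(mask)],
         normalization = meta$normalization,
         derivation_summary = meta$derivation_summary),
    class = "covariance_pattern"
  )
}

#' Write bootstrap stability maps
#'
#' Emits `stable_mask.nii.gz`, `lower.nii.gz`, `upper.nii.gz` for a
#' [bootstrap_stability()] result, next to the pattern they describe.
#'
#' @param result a `bootstrap_result`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_bootstrap_maps <- function(result, dir) {
  stopifnot(inherits(result, "bootstrap_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- result$pattern
  export_weight_map(as.numeric(result$stable_mask), p$mask, p$affine,
                    file.path(dir, "stable_mask.nii.gz"))
  export_weight_map(result$lower_bound, p$mask, p$affine,
                    file.path(dir, "lower.nii.gz"))
  export_weight_map(result$upper_bound, p$mask, p$affine,
                    file.path(dir, "upper.nii.gz"))
  jsonlite::write_json(
    list(n_replicates = result$n_replicates, ci_level = result$ci_level,
         replicate_failures = result$replicate_failures,
         n_stable = sum(result$stable_mask),
         n_voxels = length(result$stable_mask)),
    file.path(dir, "bootstrap.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
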