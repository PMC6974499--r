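#' Specification of a synthetic multicenter cohort
#'
#' Defines the generative model for synthetic metabolic scans.  Scans are
#' log-multiplicative, matching the SSM's assumptions: for subject `i` on
#' camera `c`,
#' `intensity_v = exp(baseline_v + camera_field_cv + offset_i + s_i * pattern_v + noise_iv)`,
#' with expression score `s_i ~ N(0, score_sd^2)` for controls and
#' `N(effect_size, score_sd^2)` for patients, global offsets
#' `offset_i ~ N(0, subject_offset_sd^2)`, iid voxel noise
#' `noise_iv ~ N(0, voxel_noise_sd^2)`, and an optional smooth per-camera
#' log-gain field (off by default; enable for center-effect studies).  The
#' ground-truth pattern is a unit-norm sum of signed Gaussian blobs,
#' emulating the subcortical-hypermetabolism / cortical-hypometabolism
#' topography of disease-related metabolic patterns.
#'
#' @param grid_shape integer triple (default 20x24x20, giving a brain-like
#'   mask of roughly 6000 voxels).
#' @param n_controls,n_patients subjects per camera.
#' @param cameras character vector of camera names.
#' @param effect_size patient-minus-control mean true expression.
#' @param score_sd sd of the true expression scores within group.
#' @param subject_offset_sd sd of per-subject global log-offsets.
#' @param voxel_noise_sd sd of iid log-unit voxel noise.
#' @param camera_gain_sd sd of the smooth per-camera log-gain field (0
#'   disables it).
#' @param camera_global_gain optional named numeric vector of constant
#'   log-gains per camera (a pure global scanner gain).
#' @param pattern_spec data frame of Gaussian blobs (columns `cx`, `cy`,
#'   `cz`, `sigma`, `amplitude`); `NULL` uses a default six-blob topography
#'   scaled to the grid.
#' @param baseline_level mean log-uptake inside the brain.
#' @param baseline_bump amplitude of a smooth central elevation of the
#'   baseline field.
#' @param seed integer seed making the cohort fully deterministic.
#' @return A list of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(grid_shape = c(20L, 24L, 20L),
                                  n_controls = 20L, n_patients = 20L,
                                  cameras = "cam1",
                                  effect_size = 2.0, score_sd = 1.0,
                                  subject_offset_sd = 0.2,
                                  voxel_noise_sd = 0.05,
                                  camera_gain_sd = 0,
                                  camera_global_gain = NULL,
                                  pattern_spec = NULL,
                                  baseline_level = log(50),
                                  baseline_bump = 0.3,
                                  seed = 1L) {
  if (any(c(score_sd, subject_offset_sd, voxel_noise_sd, camera_gain_sd) < 0)) {
    stop_ssm("value", "all standard deviations must be >= 0")
  }
  if (n_controls < 0 || n_patients < 0) {
    stop_ssm("value", "group sizes must be >= 0")
  }
  grid_shape <- as.integer(grid_shape)
  if (is.null(pattern_spec)) pattern_spec <- default_pattern_spec(grid_shape)
  structure(
    list(grid_shape = grid_shape, n_controls = as.integer(n_controls),
         n_patients = as.integer(n_patients), cameras = cameras,
         effect_size = effect_size, score_sd = score_sd,
         subject_offset_sd = subject_offset_sd,
         voxel_noise_sd = voxel_noise_sd, camera_gain_sd = camera_gain_sd,
         camera_global_gain = camera_global_gain,
         pattern_spec = pattern_spec, baseline_level = baseline_level,
         baseline_bump = baseline_bump, seed = as.integer(seed)),
    class = "synthetic_cohort_spec"
  )
}

## Default ground-truth topography: central/posterior-inferior/superior
## positive blobs (subcortical and motor hypermetabolism analogues) co-varying
## with posterior and bilateral-lateral negative blobs (cortical
## hypometabolism analogues).  Coordinates scale with the grid.
default_pattern_spec <- function(grid_shape) {
  g <- (grid_shape - 1) / 2  # grid center
  u <- min(grid_shape) / 20  # size unit
  data.frame(
    cx = c(g[1], g[1], g[1], g[1], g[1] - 4.5 * u, g[1] + 4.5 * u),
    cy = c(g[2], g[2] - 4.5 * u, g[2] + 4.5 * u, g[2] - 7.5 * u,
           g[2] + 5.5 * u, g[2] + 5.5 * u),
    cz = c(g[3], g[3] - 3.5 * u, g[3] + 4.5 * u, g[3] + 3.5 * u,
           g[3], g[3]),
    sigma = c(2, 2, 2, 2.5, 2, 2) * u,
    amplitude = c(1.0, 0.8, 0.7, -0.9, -0.6, -0.6)
  )
}

## Brain-shaped analysis region: a superellipsoid (exponent 4) spanning most
## of the grid, reproducing the in-mask voxel count of a tightly cropped
## normalized brain volume.
synthetic_brain_mask <- function(grid_shape, exponent = 4, frac = 0.97) {
  half <- (grid_shape - 1) / 2
  ax <- frac * half
  x <- slice.index(array(0, grid_shape), 1) - 1
  y <- slice.index(array(0, grid_shape), 2) - 1
  z <- slice.index(array(0, grid_shape), 3) - 1
  v <- abs((x - half[1]) / ax[1])^exponent +
    abs((y - half[2]) / ax[2])^exponent +
    abs((z - half[3]) / ax[3])^exponent
  v <= 1
}

#' Build a ground-truth pattern from a blob specification
#'
#' Sums signed Gaussian blobs over the grid, restricts to the mask, and
#' normalizes to unit Euclidean norm.
#'
#' @param pattern_spec data frame with columns `cx`, `cy`, `cz`, `sigma`,
#'   `amplitude` (voxel units, 0-based centers).
#' @param grid_shape integer triple.
#' @param mask logical 3D array.
#' @return Numeric vector of unit-norm weights, one per `TRUE` mask voxel.
#' @export
make_ground_truth_pattern <- function(pattern_spec, grid_shape, mask) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(identical(dim(mask), grid_shape))
  field <- gaussian_blob_field(pattern_spec, grid_shape)
  w <- field[mask]
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) stop_ssm("value", "pattern field is zero everywhere in the mask")
  w / nrm
}

gaussian_blob_field <- function(pattern_spec, grid_shape) {
  x <- slice.index(array(0, grid_shape), 1) - 1
  y <- slice.index(array(0, grid_shape), 2) - 1
  z <- slice.index(array(0, grid_shape), 3) - 1
  field <- array(0, grid_shape)
  for (i in seq_len(nrow(pattern_spec))) {
    b <- pattern_spec[i, ]
    field <- field + b$amplitude *
      exp(-((x - b$cx)^2 + (y - b$cy)^2 + (z - b$cz)^2) / (2 * b$sigma^2))
  }
  field
}

## Smooth zero-mean random field: white noise convolved with a separable
## Gaussian kernel, then standardized to unit in-mask sd.
smooth_random_field <- function(grid_shape, mask, fwhm_vox = 4) {
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  half <- ceiling(3 * sigma)
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  f <- array(rnorm(prod(grid_shape)), grid_shape)
  convolve_axis <- function(a, axis) {
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    ap <- aperm(a, perm)
    d <- dim(ap)
    m <- matrix(ap, nrow = d[1])
    padded <- rbind(m[rep(1, half), , drop = FALSE], m,
                    m[rep(nrow(m), half), , drop = FALSE])
    sm <- apply(padded, 2, function(col) {
      stats::filter(col, k, sides = 2)[(half + 1):(half + d[1])]
    })
    aperm(array(sm, d), order(perm))
  }
  for (ax in 1:3) f <- convolve_axis(f, ax)
  f <- f - mean(f[mask])
  f / sd(f[mask])
}

#' Generate a synthetic multicenter cohort with known ground truth
#'
#' Draws a cohort from the generative model of [synthetic_cohort_spec()].
#' Deterministic for a fixed spec seed.  The returned volume set is
#' unmasked (full grid, all-true mask), exactly like freshly loaded scans;
#' the truth object records the analysis-region mask under which the true
#' pattern is defined.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @return A list with `volumes` (a [volume_set()]) and `truth` (class
#'   `synthetic_truth`: `true_pattern` over the brain mask, `brain_mask`,
#'   `true_scores`, `true_offsets`, `true_camera_fields`, and the spec).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  gs <- spec$grid_shape
  mask <- synthetic_brain_mask(gs)
  pattern <- make_ground_truth_pattern(spec$pattern_spec, gs, mask)
  pat_vol <- unmask_to_volume(pattern, mask)
  baseline <- array(0, gs)  # log(1) background outside the brain
  bump <- gaussian_blob_field(
    data.frame(cx = (gs[1] - 1) / 2, cy = (gs[2] - 1) / 2,
               cz = (gs[3] - 1) / 2, sigma = min(gs) * 0.3,
               amplitude = spec$baseline_bump), gs)
  baseline[mask] <- spec$baseline_level + bump[mask]
  V <- prod(gs)
  n_cam <- spec$n_controls + spec$n_patients
  n <- n_cam * length(spec$cameras)

  out <- with_seed(spec$seed, {
    cam_fields <- lapply(spec$cameras, function(cm) {
      f <- if (spec$camera_gain_sd > 0) {
        spec$camera_gain_sd * smooth_random_field(gs, mask)[mask]
      } else {
        numeric(sum(mask))
      }
      if (!is.null(spec$camera_global_gain)) {
        f <- f + (spec$camera_global_gain[[cm]] %||% 0)
      }
      f
    })
    names(cam_fields) <- spec$cameras
    groups <- rep(rep(c("control", "patient"),
                      c(spec$n_controls, spec$n_patients)),
                  length(spec$cameras))
    cameras <- rep(spec$cameras, each = n_cam)
    s <- rnorm(n, mean = ifelse(groups == "patient", spec$effect_size, 0),
               sd = spec$score_sd)
    offsets <- rnorm(n, 0, spec$subject_offset_sd)
    data <- matrix(0, n, V)
    for (i in seq_len(n)) {
      logv <- baseline
      logv[mask] <- logv[mask] + cam_fields[[cameras[i]]]
      logv <- logv + offsets[i] + s[i] * pat_vol
      if (spec$voxel_noise_sd > 0) {
        logv <- logv + rnorm(V, 0, spec$voxel_noise_sd)
      }
      data[i, ] <- exp(as.vector(logv))
    }
    list(data = data, groups = groups, cameras = cameras, s = s,
         offsets = offsets, cam_fields = cam_fields)
  })

  ids <- sprintf("s%03d_%s_%s", seq_len(n), out$cameras,
                 ifelse(out$groups == "patient", "pd", "hc"))
  vs <- volume_set(out$data, mask = NULL, grid_shape = gs,
                   subject_ids = ids, group_labels = out$groups,
                   camera_labels = out$cameras)
  truth <- structure(
    list(true_pattern = pattern, brain_mask = mask,
         true_scores = setNames(out$s, ids),
         true_offsets = setNames(out$offsets, ids),
         true_camera_fields = out$cam_fields, spec = spec),
    class = "synthetic_truth"
  )
  list(volumes = vs, truth = truth)
}

#' Write a synthetic cohort to disk
#'
#' Emits one NIfTI volume per subject, a `manifest.tsv`, and (optionally) a
#' `truth.json` with generator parameters and ground-truth scores.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if absent).
#' @param write_truth also write `truth.json`.
#' @return The manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_truth = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- cohort$volumes
  paths <- file.path(dir, paste0(vs$subject_ids, ".nii.gz"))
  for (i in seq_along(paths)) {
    write_nifti_volume(array(vs$data[i, ], vs$grid_shape), vs$affine,
                       paths[i])
  }
  manifest <- data.frame(path = paths, subject_id = vs$subject_ids,
                         group = vs$group_labels, camera = vs$camera_labels,
                         stringsAsFactors = FALSE)
  write_manifest(manifest, file.path(dir, "manifest.tsv"))
  if (write_truth) {
    tr <- cohort$truth
    jsonlite::write_json(
      list(spec = tr$spec[setdiff(names(tr$spec), "pattern_spec")],
           pattern_spec = tr$spec$pattern_spec,
           true_scores = as.list(tr$true_scores),
           true_offsets = as.list(tr$true_offsets)),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    write_nifti_volume(unmask_to_volume(tr$true_pattern, tr$brain_mask),
                       vs$affine, file.path(dir, "true_pattern.nii.gz"))
  }
  invisible(manifest)
}

#' Ground-truth recovery experiment
#'
#' For each seed: generates a derivation cohort and an independent
#' validation cohort from the same spec, derives a pattern, and reports (i)
#' the Pearson correlation between derived weights and the ground-truth
#' pattern, (ii) the correlation between estimated and true expression
#' scores in the validation cohort, (iii) the validation ROC AUC of the
#' z-scores, and optionally (iv) bootstrap stable-voxel sensitivity on the
#' truth support (voxels with |true weight| at least `support_fraction` of
#' the maximum).  Medians across seeds are aggregated.
#'
#' @param spec a [synthetic_cohort_spec()]; its seed field is overridden
#'   per run.
#' @param seeds integer vector of cohort seeds.
#' @param config a [derive_config()].
#' @param mode `"stepwise"` ([derive_pattern()]) or `"pc1"`
#'   ([derive_pattern_pc1()]).
#' @param include_bootstrap also run [bootstrap_stability()] per seed.
#' @param n_boot_replicates bootstrap repetitions when enabled.
#' @param support_fraction truth-support cut as a fraction of the maximum
#'   absolute true weight.
#' @return A list of class `recovery_report` with `per_seed` (data frame)
#'   and `medians`.
#' @export
reference_recovery_experiment <- function(spec = synthetic_cohort_spec(),
                                          seeds = 1:10,
                                          config = derive_config(),
                                          mode = c("stepwise", "pc1"),
                                          include_bootstrap = FALSE,
                                          n_boot_replicates = 200,
                                          support_fraction = 0.1) {
  mode <- match.arg(mode)
  rows <- lapply(seeds, function(sd) {
    spec_d <- spec; spec_d$seed <- as.integer(sd)
    spec_v <- spec; spec_v$seed <- as.integer(sd + 1000003)
    deriv <- generate_cohort(spec_d)
    valid <- generate_cohort(spec_v)
    fit <- if (mode == "stepwise") derive_pattern(deriv$volumes, config)
    else derive_pattern_pc1(deriv$volumes, config)
    truth_w <- truth_on_pattern_mask(deriv$truth, fit$pattern)
    weight_r <- cor(fit$pattern$weights, truth_w)
    sc <- score_cohort(valid$volumes, fit$pattern)
    score_r <- cor(sc$table$z, valid$truth$true_scores[sc$table$subject_id])
    auc <- roc_auc(sc$table$z, sc$table$group)
    sens <- NA_real_
    if (include_bootstrap) {
      bt <- bootstrap_stability(deriv$volumes, config,
                                n_replicates = n_boot_replicates,
                                seed = as.integer(sd))
      support <- abs(truth_w) >= support_fraction * max(abs(truth_w))
      sens <- mean(bt$stable_mask[support])
    }
    data.frame(seed = sd, weight_r = weight_r, abs_weight_r = abs(weight_r),
               score_r = score_r, abs_score_r = abs(score_r),
               validation_auc = auc, stable_sensitivity = sens,
               n_components = length(fit$pattern$component_indices))
  })
  per_seed <- do.call(rbind, rows)
  medians <- list(
    abs_weight_r = median(per_seed$abs_weight_r),
    abs_score_r = median(per_seed$abs_score_r),
    validation_auc = median(per_seed$validation_auc),
    stable_sensitivity = if (include_bootstrap) {
      median(per_seed$stable_sensitivity)
    } else NA_real_
  )
  structure(list(per_seed = per_seed, medians = medians, mode = mode),
            class = "recovery_report")
}

## True pattern restricted to (and re-normalized on) the derived pattern's
## mask, which the derivation estimated from the data.
truth_on_pattern_mask <- function(truth, pattern) {
  tv <- unmask_to_volume(truth$true_pattern, truth$brain_mask)
  w <- tv[pattern$mask]
  w / sqrt(sum(w^2))
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery_report (%s mode, %d seeds):\n",
              x$mode, nrow(x$per_seed)))
  cat(sprintf("  median |weight r| = %.3f, median |score r| = %.3f, median AUC = %.3f\n",
              x$medians$abs_weight_r, x$medians$abs_score_r,
              x$medians$validation_auc))
  if (!is.na(x$medians$stable_sensitivity)) {
    cat(sprintf("  median stable-voxel sensitivity = %.3f\n",
                x$medians$stable_sensitivity))
  }
  invisible(x)
}
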