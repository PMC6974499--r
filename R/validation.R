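#' Area under the ROC curve
#'
#' AUC computed through the Mann-Whitney identity: the probability that a
#' randomly chosen patient outscores a randomly chosen control, with ties
#' counted one half.  Equivalent to integrating the empirical ROC curve.
#'
#' @param scores numeric vector of (z-)scores.
#' @param labels per-element group labels; `"patient"` is the positive
#'   class, `"control"` the negative; other labels are dropped.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  keep <- labels %in% c("control", "patient")
  scores <- scores[keep]
  labels <- labels[keep]
  n_pat <- sum(labels == "patient")
  n_ctl <- sum(labels == "control")
  if (n_pat == 0L || n_ctl == 0L) {
    stop_ssm("value", "both classes must be present to compute an AUC")
  }
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[labels == "patient"]) - n_pat * (n_pat + 1) / 2) / (n_pat * n_ctl)
}

#' Two-sample comparison of pattern expression scores
#'
#' Student's t test (classical pooled-variance form by default; Welch
#' available via `var_equal = FALSE`), patient minus control, two-sided.
#'
#' @param scores numeric vector of z-scores.
#' @param labels `"control"` / `"patient"` labels (others dropped).
#' @param var_equal pooled-variance Student form when `TRUE` (default).
#' @param alpha significance threshold used only for the report flag.
#' @return A list with `t_statistic`, `p_value`, `significant`, group
#'   means/sds and counts (a discrimination-report fragment).
#' @export
group_compare <- function(scores, labels, var_equal = TRUE, alpha = 0.05) {
  keep <- labels %in% c("control", "patient")
  scores <- scores[keep]
  labels <- labels[keep]
  pat <- scores[labels == "patient"]
  ctl <- scores[labels == "control"]
  if (length(pat) < 2L || length(ctl) < 2L) {
    stop_ssm("value", "need at least 2 subjects per group")
  }
  tt <- tryCatch(t.test(pat, ctl, var.equal = var_equal),
                 error = function(e) {
                   stop_ssm("degenerate", "degenerate comparison: %s",
                            conditionMessage(e))
                 })
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       significant = tt$p.value < alpha,
       mean_patient = mean(pat), mean_control = mean(ctl),
       sd_patient = sd(pat), sd_control = sd(ctl),
       n_patients = length(pat), n_controls = length(ctl))
}

#' Pearson correlation with t-distribution p value
#'
#' @param x,y equal-length numeric vectors (length at least 3, nonzero
#'   variance in both).
#' @return A list with `r` and `p_value`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop_ssm("dimension", "x and y lengths differ")
  if (length(x) < 3L) stop_ssm("value", "need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) {
    stop_ssm("degenerate", "zero variance in one of the inputs")
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Discrimination report for a scored dataset
#'
#' Bundles the AUC and the two-sample t test computed from the same
#' z-scores, the within-cohort validity check applied to every pattern in
#' every dataset.
#'
#' @param scores a [score_cohort()] result or a numeric z-score vector.
#' @param labels group labels (unneeded when `scores` is a
#'   `cohort_scores`).
#' @param var_equal pooled-variance t test when `TRUE`.
#' @return A list of class `discrimination_report` with `auc`, the t-test
#'   fields of [group_compare()], and group sizes.
#' @export
discrimination_report <- function(scores, labels = NULL, var_equal = TRUE) {
  if (inherits(scores, "cohort_scores")) {
    labels <- scores$table$group
    scores <- scores$table$z
  }
  gc <- group_compare(scores, labels, var_equal = var_equal)
  structure(c(list(auc = roc_auc(scores, labels)), gc),
            class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat(sprintf(
    "discrimination_report: AUC = %.3f (HC n=%d, PD n=%d); t = %.2f, p = %.3g\n",
    x$auc, x$n_controls, x$n_patients, x$t_statistic, x$p_value))
  invisible(x)
}

#' Volume-of-interest atlas
#'
#' @param labels integer 3D array of region labels (0 = background).
#' @param names named character vector mapping label (as name) to region
#'   name; every named label must occur in the grid.
#' @return An object of class `voi_atlas`.
#' @export
voi_atlas <- function(labels, names) {
  labels <- array(as.integer(labels), dim = dim(labels))
  if (length(dim(labels)) != 3L) stop_ssm("dimension", "atlas must be 3D")
  present <- unique(as.vector(labels))
  wanted <- as.integer(base::names(names))
  if (anyNA(wanted)) stop_ssm("key", "atlas `names` must be keyed by integer labels")
  missing <- setdiff(wanted, present)
  if (length(missing)) {
    stop_ssm("key", "atlas label(s) absent from the grid: %s",
             paste(missing, collapse = ", "))
  }
  structure(list(labels = labels, names = names), class = "voi_atlas")
}

#' Mean pattern weight per atlas region
#'
#' The region weight of each named VOI is the unweighted mean of the
#' pattern weights over the in-mask voxels carrying that region's label.
#' Regions with no in-mask voxel are reported as missing (`NA`), not zero.
#'
#' @param pattern a `covariance_pattern`.
#' @param atlas a [voi_atlas()] on the same grid.
#' @return Data frame with columns `label`, `region`, `n_voxels`, `weight`.
#' @export
voi_region_weights <- function(pattern, atlas) {
  stopifnot(inherits(pattern, "covariance_pattern"),
            inherits(atlas, "voi_atlas"))
  if (!identical(dim(atlas$labels), pattern$grid_shape)) {
    stop_ssm("dimension", "atlas grid does not match the pattern grid")
  }
  wvol <- unmask_to_volume(pattern$weights, pattern$mask, fill = NA_real_)
  labs <- as.integer(names(atlas$names))
  out <- data.frame(label = labs, region = unname(atlas$names),
                    n_voxels = NA_integer_, weight = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(labs)) {
    sel <- atlas$labels == labs[i] & pattern$mask
    out$n_voxels[i] <- sum(sel)
    out$weight[i] <- if (any(sel)) mean(wvol[sel]) else NA_real_
  }
  if (all(is.na(out$weight))) {
    stop_ssm("value", "no atlas region overlaps the pattern mask")
  }
  out
}

#' Compare two covariance patterns
#'
#' Similarity is assessed two ways, as in cross-cohort pattern validation:
#' the Pearson correlation of VOI region weights over the regions common to
#' both patterns, and (when a scored dataset is supplied) the Pearson
#' correlation of the two patterns' subject z-scores on that dataset
#' (per-camera control referencing).  Symmetric in its two pattern
#' arguments.
#'
#' @param pattern_a,pattern_b `covariance_pattern`s on the same grid.
#' @param atlas a [voi_atlas()].
#' @param scored_dataset optional [volume_set()] on which both patterns are
#'   scored.
#' @param ... passed to [score_cohort()] (e.g. `other_reference_camera`).
#' @return A list of class `similarity_report` with
#'   `region_weight_correlation`, `region_weight_p`, `n_regions`, and (if a
#'   dataset was given) `score_correlation`, `score_p`.
#' @export
compare_patterns <- function(pattern_a, pattern_b, atlas,
                             scored_dataset = NULL, ...) {
  if (!identical(pattern_a$grid_shape, pattern_b$grid_shape)) {
    stop_ssm("dimension", "patterns live on different grids")
  }
  wa <- voi_region_weights(pattern_a, atlas)
  wb <- voi_region_weights(pattern_b, atlas)
  common <- !is.na(wa$weight) & !is.na(wb$weight)
  if (sum(common) < 3L) {
    stop_ssm("value", "fewer than 3 atlas regions common to both patterns")
  }
  rw <- correlate(wa$weight[common], wb$weight[common])
  out <- list(region_weight_correlation = rw$r, region_weight_p = rw$p_value,
              n_regions = sum(common))
  if (!is.null(scored_dataset)) {
    za <- score_cohort(scored_dataset, pattern_a, pattern_id = "A", ...)
    zb <- score_cohort(scored_dataset, pattern_b, pattern_id = "B", ...)
    sc <- correlate(za$table$z, zb$table$z)
    out$score_correlation <- sc$r
    out$score_p <- sc$p_value
  }
  structure(out, class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("similarity_report: region-weight r = %.3f (n = %d regions)\n",
              x$region_weight_correlation, x$n_regions))
  if (!is.null(x$score_correlation)) {
    cat(sprintf("  subject-score r = %.3f\n", x$score_correlation))
  }
  invisible(x)
}

#' Synthetic demonstration VOI atlas of labeled ellipsoids
#'
#' Generates an atlas of `n_regions` ellipsoidal VOIs placed at random
#' centers inside a mask -- a synthetic stand-in with the same role as a
#' standardized anatomical VOI set, for demonstrations and tests.  Any
#' labeled NIfTI atlas can be used instead for real data.
#'
#' @param grid_shape integer triple.
#' @param mask logical 3D array inside which regions are placed.
#' @param n_regions number of VOIs (default 30).
#' @param radius_range voxel semi-axis range of the ellipsoids.
#' @param seed integer seed.
#' @return A [voi_atlas()].
#' @export
demo_voi_atlas <- function(grid_shape, mask, n_regions = 30,
                           radius_range = c(1.5, 3), seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(identical(dim(mask), grid_shape))
  coords <- which(mask, arr.ind = TRUE)
  labels <- array(0L, dim = grid_shape)
  gx <- slice.index(labels, 1); gy <- slice.index(labels, 2)
  gz <- slice.index(labels, 3)
  with_seed(seed, {
    centers <- coords[sample(nrow(coords), n_regions), , drop = FALSE]
    for (i in seq_len(n_regions)) {
      ax <- runif(3, radius_range[1], radius_range[2])
      inside <- ((gx - centers[i, 1]) / ax[1])^2 +
        ((gy - centers[i, 2]) / ax[2])^2 +
        ((gz - centers[i, 3]) / ax[3])^2 <= 1
      labels[inside & mask & labels == 0L] <- i
    }
  })
  present <- sort(setdiff(unique(as.vector(labels)), 0L))
  voi_atlas(labels, setNames(sprintf("region_%02d", present), present))
}
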