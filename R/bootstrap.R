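#' Bootstrap stability of pattern voxel weights
#'
#' Resamples the derivation cohort with replacement, stratified within
#' group so group sizes are preserved, reruns the full derivation pipeline
#' (PCA, variance selection, stepwise regression, combination) on each
#' replicate, aligns each replicate pattern's sign to the original (flipped
#' when its correlation with the original weights is negative), and
#' summarizes the per-voxel weight distribution by percentile bounds.  A
#' voxel is *stable* when its one-sided confidence interval at `ci_level`
#' does not straddle zero: lower bound above zero (reliably positive
#' weight) or upper bound below zero (reliably negative).
#'
#' Replicates whose stepwise search selects no component are counted as
#' degenerate and skipped, as are replicates whose derivation fails
#' outright.
#'
#' @param vs the derivation [volume_set()].
#' @param config a [derive_config()].
#' @param n_replicates number of bootstrap repetitions (1000 in routine
#'   use; smaller values keep tests fast).
#' @param ci_level one-sided confidence level in (0,1), default 0.90.
#' @param seed integer seed; replicate `r` draws from a deterministic child
#'   stream of it.
#' @param freeze_components if `TRUE`, replicates skip the stepwise search
#'   and reuse the original pattern's component set (refitting only the
#'   logistic coefficients).
#' @param max_failure_fraction replicate failure fraction above which the
#'   run errors instead of warning.
#' @param keep_replicates store the aligned replicate-by-voxel weight
#'   matrix in the result (needed by [stability_at()]).
#' @param .resample internal test hook; `FALSE` disables resampling so every
#'   replicate is the original cohort.
#' @return An object of class `bootstrap_result` with `lower_bound`,
#'   `upper_bound`, `stable_mask` (per-voxel), `n_replicates`, `ci_level`,
#'   `replicate_failures`, the original `pattern`, and (optionally)
#'   `replicate_weights`.
#' @export
bootstrap_stability <- function(vs, config = derive_config(),
                                n_replicates = 1000, ci_level = 0.90,
                                seed = 1L, freeze_components = FALSE,
                                max_failure_fraction = 0.2,
                                keep_replicates = FALSE,
                                .resample = TRUE) {
  if (n_replicates < 1L) stop_ssm("config", "n_replicates must be >= 1")
  if (!(ci_level > 0 && ci_level < 1)) {
    stop_ssm("config", "ci_level must lie in (0,1)")
  }
  orig <- derive_pattern(vs, config)
  w0 <- orig$pattern$weights
  ## Mask once so replicates share the original voxel space.
  if (all(vs$mask)) {
    vs <- apply_mask(vs, orig$pattern$mask)
  }
  groups <- split(seq_len(n_subjects(vs)), vs$group_labels)
  frozen <- orig$pattern$component_indices

  reps <- vector("list", n_replicates)
  failures <- 0L
  for (r in seq_len(n_replicates)) {
    idx <- if (.resample) {
      with_seed(child_seed(seed, r),
                unlist(lapply(groups, function(g) {
                  sample(g, length(g), replace = TRUE)
                }), use.names = FALSE))
    } else seq_len(n_subjects(vs))
    bs <- volume_set(vs$data[idx, , drop = FALSE], mask = vs$mask,
                     grid_shape = vs$grid_shape, affine = vs$affine,
                     subject_ids = make.unique(vs$subject_ids[idx]),
                     group_labels = vs$group_labels[idx],
                     camera_labels = vs$camera_labels[idx])
    w <- tryCatch(
      bootstrap_replicate_weights(bs, config, freeze_components, frozen),
      ssmpca_error = function(e) NULL)
    if (is.null(w)) {
      failures <- failures + 1L
    } else {
      if (cor(w, w0) < 0) w <- -w
      reps[[r]] <- w
    }
  }
  frac_failed <- failures / n_replicates
  if (frac_failed > max_failure_fraction) {
    stop_ssm("degenerate",
             "%.0f%% of bootstrap replicates were degenerate (limit %.0f%%)",
             100 * frac_failed, 100 * max_failure_fraction)
  }
  if (failures > 0) {
    warning(sprintf("%d of %d bootstrap replicates degenerate and skipped",
                    failures, n_replicates))
  }
  W <- do.call(rbind, reps[!vapply(reps, is.null, TRUE)])
  alpha <- 1 - ci_level
  lower <- apply(W, 2, quantile, probs = alpha, names = FALSE)
  upper <- apply(W, 2, quantile, probs = ci_level, names = FALSE)
  structure(
    list(n_replicates = n_replicates, ci_level = ci_level,
         lower_bound = lower, upper_bound = upper,
         stable_mask = lower > 0 | upper < 0,
         replicate_failures = failures,
         pattern = orig$pattern,
         replicate_weights = if (keep_replicates) W else NULL),
    class = "bootstrap_result"
  )
}

## One replicate: rerun derivation; an empty stepwise selection counts as a
## degenerate replicate here (no PC1 fallback inside the bootstrap).
bootstrap_replicate_weights <- function(bs, config, freeze_components,
                                        frozen) {
  st <- derive_stages(bs, config)
  if (freeze_components) {
    selected <- frozen
    fit <- stepwise_logistic_aic(
      st$pca$subject_scores[, selected, drop = FALSE], bs$group_labels)
    coefficients <- if (length(fit$selected) == length(selected)) {
      fit$coefficients
    } else {
      ## coefficients from the full frozen model regardless of what a
      ## stepwise search would keep
      full <- ridge_logistic(st$pca$subject_scores[, selected, drop = FALSE],
                             as.integer(bs$group_labels == "patient"))
      full$coefficients
    }
  } else {
    cand <- select_top_variance_components(st$pca$variance_fractions,
                                           config$cum_var_threshold)
    sw <- stepwise_logistic_aic(
      st$pca$subject_scores[, cand, drop = FALSE], bs$group_labels)
    if (!length(sw$selected)) {
      stop_ssm("degenerate", "stepwise selected no component")
    }
    selected <- cand[sw$selected]
    coefficients <- sw$coefficients
  }
  pat <- combine_pattern(st$pca, selected, coefficients, gmp = st$rp$gmp,
                         mask = st$vs$mask, grid_shape = st$vs$grid_shape,
                         affine = st$vs$affine)
  pat$weights
}

#' Recompute bootstrap stability at a different confidence level
#'
#' Requires a [bootstrap_stability()] result created with
#' `keep_replicates = TRUE`; reuses the stored aligned replicate weights.
#'
#' @param result a `bootstrap_result`.
#' @param ci_level new one-sided confidence level.
#' @return A `bootstrap_result` at the new level.
#' @export
stability_at <- function(result, ci_level) {
  stopifnot(inherits(result, "bootstrap_result"))
  if (is.null(result$replicate_weights)) {
    stop_ssm("config",
             "result lacks replicate weights; rerun with keep_replicates = TRUE")
  }
  if (!(ci_level > 0 && ci_level < 1)) {
    stop_ssm("config", "ci_level must lie in (0,1)")
  }
  W <- result$replicate_weights
  alpha <- 1 - ci_level
  lower <- apply(W, 2, quantile, probs = alpha, names = FALSE)
  upper <- apply(W, 2, quantile, probs = ci_level, names = FALSE)
  out <- result
  out$ci_level <- ci_level
  out$lower_bound <- lower
  out$upper_bound <- upper
  out$stable_mask <- lower > 0 | upper < 0
  out
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "bootstrap_result: %d replicates (%d degenerate), one-sided %.0f%% CI\n",
    x$n_replicates, x$replicate_failures, 100 * x$ci_level))
  cat(sprintf("  stable voxels: %d of %d (%.1f%%)\n",
              sum(x$stable_mask), length(x$stable_mask),
              100 * mean(x$stable_mask)))
  invisible(x)
}
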