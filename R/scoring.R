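#' Topographic profile rating: project scans onto a pattern
#'
#' Computes the raw expression score of each subject on a fixed covariance
#' pattern.  Each scan is log-transformed, its subject mean (over the
#' pattern's mask voxels) and the pattern's stored derivation group mean
#' profile are removed, and the resulting residual profile is projected
#' onto the pattern weights by inner product.  Scoring is a pure function
#' of the stored pattern: it never alters the pattern, its GMP, or any
#' reference statistics, and multiplying a scan by a positive constant
#' leaves its score unchanged.
#'
#' @param vs a [volume_set()].  If unmasked, the pattern's mask is applied;
#'   if masked, its mask must equal the pattern's.
#' @param pattern a [combine_pattern()] result (or loaded pattern bundle).
#' @return Named numeric vector of raw scores, one per subject.
#' @export
score_subjects <- function(vs, pattern) {
  stopifnot(inherits(vs, "volume_set"), inherits(pattern, "covariance_pattern"))
  vs <- conform_to_pattern(vs, pattern)
  rp <- ssm_transform(vs, reference_gmp = pattern$gmp)
  setNames(drop(rp$srp %*% pattern$weights), vs$subject_ids)
}

conform_to_pattern <- function(vs, pattern) {
  if (!identical(vs$grid_shape, pattern$grid_shape)) {
    stop_ssm("dimension", "scan grid (%s) does not match pattern grid (%s)",
             paste(vs$grid_shape, collapse = "x"),
             paste(pattern$grid_shape, collapse = "x"))
  }
  if (all(vs$mask) && !all(pattern$mask)) {
    return(apply_mask(vs, pattern$mask))
  }
  if (!identical(which(vs$mask), which(pattern$mask))) {
    stop_ssm("dimension", "scan mask does not match the pattern mask")
  }
  vs
}

#' z-transform raw scores against a reference control group
#'
#' Standardizes raw subject scores to the mean and (sample, n-1) standard
#' deviation of a designated reference group, the convention used to make
#' pattern expression comparable across acquisition settings: reference
#' controls end up with mean 0 and sd 1 by construction.
#'
#' @param raw named numeric vector of raw scores to transform.
#' @param reference_raw raw scores of the designated reference controls
#'   (at least 2, with nonzero spread).
#' @param reference_group identifier recorded for provenance.
#' @return An object of class `subject_scores` with fields `raw`, `z`,
#'   `reference_mean`, `reference_sd`, `reference_group`.
#' @export
z_transform <- function(raw, reference_raw, reference_group = "control") {
  if (length(reference_raw) < 2L) {
    stop_ssm("value", "z-transform needs at least 2 reference subjects")
  }
  m <- mean(reference_raw)
  s <- sd(reference_raw)
  if (s == 0) stop_ssm("degenerate", "reference scores have zero spread")
  structure(
    list(raw = raw, z = (raw - m) / s,
         reference_mean = m, reference_sd = s,
         reference_group = reference_group),
    class = "subject_scores"
  )
}

#' Score a cohort with per-camera control referencing
#'
#' Computes raw pattern-expression scores for every subject and
#' z-transforms them within acquisition batches: each camera's subjects are
#' referenced to the healthy controls scanned on that same camera, so
#' camera-dependent score shifts are absorbed and batches are never mixed.
#' A batch that contains patients but fewer than 2 same-camera controls is
#' a configuration error.  Batches containing only `"other"`-group subjects
#' (e.g. a third diagnostic group scored against another cohort's controls)
#' may be referenced to a designated control camera via
#' `other_reference_camera`.
#'
#' @param vs a [volume_set()].
#' @param pattern a `covariance_pattern`.
#' @param reference_group group label defining the reference subjects
#'   (default `"control"`).
#' @param per_camera if `FALSE`, all subjects are referenced to the pooled
#'   reference group regardless of camera.
#' @param other_reference_camera camera whose controls reference batches
#'   that have no controls of their own and no patients.
#' @param pattern_id identifier recorded with the scores.
#' @return An object of class `cohort_scores`: a data frame-like list with
#'   `table` (subject_id, group, camera, raw, z) plus per-camera reference
#'   statistics.
#' @export
score_cohort <- function(vs, pattern, reference_group = "control",
                         per_camera = TRUE, other_reference_camera = NULL,
                         pattern_id = "pattern") {
  raw <- score_subjects(vs, pattern)
  cameras <- vs$camera_labels
  groups <- vs$group_labels
  z <- rep(NA_real_, length(raw))
  refstats <- list()
  batches <- if (per_camera) unique(cameras) else "all"
  for (b in batches) {
    in_b <- if (per_camera) cameras == b else rep(TRUE, length(raw))
    ref <- in_b & groups == reference_group
    if (sum(ref) < 2L) {
      if (per_camera && !any(in_b & groups == "patient") &&
          !is.null(other_reference_camera)) {
        ref <- cameras == other_reference_camera & groups == reference_group
      }
      if (sum(ref) < 2L) {
        stop_ssm("config",
                 "camera batch '%s' has no usable reference '%s' subjects",
                 b, reference_group)
      }
    }
    zt <- z_transform(raw[in_b], raw[ref], reference_group)
    z[in_b] <- zt$z
    refstats[[as.character(b)]] <- list(mean = zt$reference_mean,
                                        sd = zt$reference_sd,
                                        n = sum(ref))
  }
  structure(
    list(table = data.frame(subject_id = vs$subject_ids, group = groups,
                            camera = cameras, raw = unname(raw), z = z,
                            stringsAsFactors = FALSE),
         reference_group = reference_group, per_camera = per_camera,
         reference_stats = refstats, pattern_id = pattern_id),
    class = "cohort_scores"
  )
}

#' @export
print.cohort_scores <- function(x, ...) {
  cat(sprintf("cohort_scores: %d subjects on '%s' (reference: %s%s)\n",
              nrow(x$table), x$pattern_id, x$reference_group,
              if (x$per_camera) ", per camera" else ", pooled"))
  print(utils::head(x$table, 6))
  if (nrow(x$table) > 6) cat("  ...\n")
  invisible(x)
}
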