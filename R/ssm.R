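#' Scaled Subprofile Model transform
#'
#' Log-transforms the masked scans and removes, per subject, the subject
#' mean (global scaling) and a group mean profile (GMP), leaving the subject
#' residual profiles (SRP) that carry between-subject covariance:
#' `srp[i, ] = log(data[i, ]) - mean(log(data[i, ])) - gmp`.
#'
#' When `reference_gmp` is `NULL` the GMP is the voxelwise mean of the
#' row-centered log data of this set (a derivation-set transform; the SRP is
#' then doubly centered).  When scoring new scans against a stored pattern,
#' pass the pattern's own GMP so the residuals live in the pattern's space.
#'
#' @param vs a masked [volume_set()]; all intensities must be strictly
#'   positive.
#' @param reference_gmp optional per-voxel group mean profile (log units) of
#'   length `ncol(vs$data)`.
#' @param gmp_group which subjects define a self-derived GMP: `"all"`
#'   (default, pooled controls and patients, the cited SSM convention) or
#'   `"control"`.
#' @return An object of class `residual_profiles` with fields `srp`
#'   (subject-by-voxel matrix), `gmp`, `subject_offsets`, and the carried
#'   subject metadata.
#' @export
ssm_transform <- function(vs, reference_gmp = NULL,
                          gmp_group = c("all", "control")) {
  stopifnot(inherits(vs, "volume_set"))
  gmp_group <- match.arg(gmp_group)
  if (any(vs$data <= 0)) {
    stop_ssm("value",
             "%d in-mask intensities are <= 0; the log transform requires strictly positive values",
             sum(vs$data <= 0))
  }
  logd <- log(vs$data)
  offsets <- rowMeans(logd)
  centered <- logd - offsets
  if (is.null(reference_gmp)) {
    rows <- if (gmp_group == "all") seq_len(nrow(centered)) else
      which(vs$group_labels == "control")
    if (!length(rows)) stop_ssm("degenerate", "no subjects available for the GMP")
    gmp <- colMeans(centered[rows, , drop = FALSE])
    self_gmp <- TRUE
  } else {
    if (length(reference_gmp) != ncol(vs$data)) {
      stop_ssm("dimension", "reference_gmp has length %d but data has %d voxels",
               length(reference_gmp), ncol(vs$data))
    }
    gmp <- as.numeric(reference_gmp)
    self_gmp <- FALSE
  }
  srp <- sweep(centered, 2, gmp)
  structure(
    list(srp = srp, gmp = gmp, subject_offsets = offsets,
         self_gmp = self_gmp, gmp_group = if (self_gmp) gmp_group else NA,
         mask = vs$mask, grid_shape = vs$grid_shape, affine = vs$affine,
         subject_ids = vs$subject_ids, group_labels = vs$group_labels,
         camera_labels = vs$camera_labels),
    class = "residual_profiles"
  )
}

#' @export
print.residual_profiles <- function(x, ...) {
  cat(sprintf("residual_profiles: %d subjects x %d voxels (GMP: %s)\n",
              nrow(x$srp), ncol(x$srp),
              if (x$self_gmp) sprintf("self-derived, %s", x$gmp_group)
              else "external reference"))
  invisible(x)
}

#' Principal component analysis of residual profiles
#'
#' Eigendecomposition of the between-subject covariance of the SRP matrix in
#' its dual (subject-by-subject) form, mapped back to unit-norm voxel
#' loadings -- numerically identical to a dense voxel-space decomposition but
#' feasible when voxels far outnumber subjects.  Components are oriented so
#' that the mean patient score minus the mean control score is nonnegative
#' (ties broken by making the largest-magnitude loading positive), which
#' removes the sign ambiguity before regression and bootstrap alignment.
#'
#' @param rp a `residual_profiles` object from [ssm_transform()] with a
#'   self-derived GMP.
#' @param tol relative eigenvalue tolerance below which components are
#'   treated as null space and dropped.
#' @return An object of class `ssm_pca` with fields `components`
#'   (component-by-voxel loading matrix, orthonormal rows), `eigenvalues`
#'   (descending, variance units), `variance_fractions`, and
#'   `subject_scores` (subject-by-component; `subject_scores %*% components`
#'   reconstructs the SRP).
#' @export
fit_pca <- function(rp, tol = 1e-9) {
  stopifnot(inherits(rp, "residual_profiles"))
  n <- nrow(rp$srp)
  if (n < 2L) stop_ssm("degenerate", "PCA needs at least 2 subjects")
  gram <- tcrossprod(rp$srp)
  total <- sum(diag(gram))
  if (total <= 0 || max(abs(rp$srp)) == 0) {
    stop_ssm("degenerate", "residual profiles carry no signal (all zero)")
  }
  e <- eigen(gram, symmetric = TRUE)
  keep <- which(e$values > tol * e$values[1])
  ev_gram <- e$values[keep]
  u <- e$vectors[, keep, drop = FALSE]
  ## voxel loadings: columns of t(S) u / sqrt(ev) are orthonormal
  comp <- crossprod(rp$srp, u)
  comp <- sweep(comp, 2, sqrt(ev_gram), "/")
  scores <- sweep(u, 2, sqrt(ev_gram), "*")
  ## orientation: patient-minus-control mean score >= 0 per component
  is_pat <- rp$group_labels == "patient"
  is_ctl <- rp$group_labels == "control"
  for (k in seq_along(keep)) {
    flip <- FALSE
    if (any(is_pat) && any(is_ctl)) {
      d <- mean(scores[is_pat, k]) - mean(scores[is_ctl, k])
      if (d < 0) flip <- TRUE
      else if (d == 0) flip <- comp[which.max(abs(comp[, k])), k] < 0
    } else {
      flip <- comp[which.max(abs(comp[, k])), k] < 0
    }
    if (flip) {
      comp[, k] <- -comp[, k]
      scores[, k] <- -scores[, k]
    }
  }
  eigenvalues <- ev_gram / (n - 1)
  structure(
    list(components = t(comp), eigenvalues = eigenvalues,
         variance_fractions = eigenvalues / sum(eigenvalues),
         subject_scores = scores,
         subject_ids = rp$subject_ids, group_labels = rp$group_labels,
         camera_labels = rp$camera_labels),
    class = "ssm_pca"
  )
}

#' @export
print.ssm_pca <- function(x, ...) {
  k <- length(x$eigenvalues)
  cat(sprintf("ssm_pca: %d components over %d subjects\n",
              k, nrow(x$subject_scores)))
  vf <- round(100 * x$variance_fractions[seq_len(min(6, k))], 1)
  cat("  variance explained (%):", paste(vf, collapse = ", "),
      if (k > 6) "...", "\n")
  invisible(x)
}

#' Select the components explaining the top share of total variance
#'
#' Returns the smallest prefix of (descending-variance) components whose
#' cumulative variance fraction reaches `cumulative_threshold`; always at
#' least one component, and never more than the number supplied.
#'
#' @param variance_fractions numeric vector sorted descending, summing to at
#'   most 1 (within tolerance).
#' @param cumulative_threshold cumulative variance target in (0,1].
#' @return Integer vector of component indices `1:k`.
#' @export
select_top_variance_components <- function(variance_fractions,
                                           cumulative_threshold = 0.5) {
  if (!length(variance_fractions)) {
    stop_ssm("value", "variance_fractions is empty")
  }
  if (is.unsorted(rev(variance_fractions))) {
    stop_ssm("value", "variance_fractions must be sorted descending")
  }
  if (sum(variance_fractions) > 1 + 1e-8) {
    stop_ssm("value", "variance_fractions sum to more than 1")
  }
  if (!(cumulative_threshold > 0 && cumulative_threshold <= 1)) {
    stop_ssm("config", "cumulative_threshold must lie in (0,1]")
  }
  cum <- cumsum(variance_fractions)
  k <- which(cum >= cumulative_threshold - 1e-12)[1]
  if (is.na(k)) k <- length(variance_fractions)
  seq_len(max(1L, k))
}
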