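#' Cohort of vectorized brain volumes
#'
#' A `volume_set` holds a cohort of scans as a subject-by-voxel matrix
#' together with the boolean analysis mask, the 3D grid geometry, and
#' per-subject metadata (subject id, group, acquisition camera).  Voxels
#' are linearized in the native array order of the grid (first index
#' fastest), which is also the NIfTI on-disk order, so masks and weight
#' maps written by this package are portable across runs and platforms.
#'
#' @param data numeric subject-by-voxel matrix of nonnegative tracer-uptake
#'   intensities.  Column count must equal the number of `TRUE` mask voxels.
#' @param mask logical 3D array marking in-analysis voxels, or `NULL` for an
#'   all-true mask over `grid_shape`.
#' @param grid_shape integer triple, the 3D grid dimensions.
#' @param affine 4x4 voxel-to-world transform.
#' @param subject_ids character vector of unique subject identifiers.
#' @param group_labels per-subject label in `"control"`, `"patient"`,
#'   `"other"`.
#' @param camera_labels per-subject acquisition-batch (camera) label.
#' @return An object of class `volume_set`.
#' @export
volume_set <- function(data, mask = NULL, grid_shape, affine = diag(4),
                       subject_ids, group_labels, camera_labels) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L) {
    stop_ssm("dimension", "grid_shape must be an integer triple")
  }
  if (is.null(mask)) mask <- array(TRUE, dim = grid_shape)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!identical(dim(mask), grid_shape)) {
    stop_ssm("dimension", "mask shape (%s) does not match grid_shape (%s)",
             paste(dim(mask), collapse = "x"),
             paste(grid_shape, collapse = "x"))
  }
  data <- as.matrix(data)
  n <- nrow(data)
  if (ncol(data) != sum(mask)) {
    stop_ssm("dimension",
             "data has %d columns but mask selects %d voxels",
             ncol(data), sum(mask))
  }
  if (length(subject_ids) != n || length(group_labels) != n ||
      length(camera_labels) != n) {
    stop_ssm("dimension",
             "subject_ids, group_labels, camera_labels must each have one entry per data row")
  }
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) {
    stop_ssm("value", "subject_ids must be unique")
  }
  group_labels <- as.character(group_labels)
  bad <- setdiff(unique(group_labels), c("control", "patient", "other"))
  if (length(bad)) {
    stop_ssm("value", "unknown group label(s): %s", paste(bad, collapse = ", "))
  }
  if (!all(is.finite(data))) {
    stop_ssm("value", "volume data contain non-finite values")
  }
  if (any(data < 0)) {
    stop_ssm("value", "volume data contain negative intensities")
  }
  affine <- matrix(as.numeric(affine), 4, 4)
  structure(
    list(data = data, mask = mask, grid_shape = grid_shape, affine = affine,
         subject_ids = subject_ids, group_labels = group_labels,
         camera_labels = as.character(camera_labels)),
    class = "volume_set"
  )
}

#' @export
print.volume_set <- function(x, ...) {
  cat(sprintf("volume_set: %d subjects x %d voxels (grid %s, mask %d/%d)\n",
              nrow(x$data), ncol(x$data),
              paste(x$grid_shape, collapse = "x"),
              sum(x$mask), prod(x$grid_shape)))
  tab <- table(x$group_labels)
  cat("  groups: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  cameras:", paste(unique(x$camera_labels), collapse = ", "), "\n")
  invisible(x)
}

n_subjects <- function(vs) nrow(vs$data)

#' Load a cohort of NIfTI volumes into a volume set
#'
#' Reads one volume per subject, checks that all volumes share the same grid
#' and (within tolerance) the same voxel-to-world transform, and attaches
#' subject metadata.  The returned set carries an all-true mask; apply
#' [compute_brain_mask()] and [apply_mask()] before analysis.
#'
#' @param paths character vector of NIfTI file paths (.nii or .nii.gz).
#' @param metadata data frame with columns `subject_id`, `group`, `camera`,
#'   and optionally `path`.  When a `path` column is present rows are matched
#'   to `paths` by it; otherwise row order must match `paths`.
#' @param affine_tol elementwise absolute tolerance for declaring two
#'   transforms equal (inputs are assumed already spatially normalized).
#' @return A [volume_set()] with data rows ordered as in `metadata`.
#' @export
load_volume_set <- function(paths, metadata, affine_tol = 1e-4) {
  stopifnot(is.data.frame(metadata))
  need <- c("subject_id", "group", "camera")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) {
    stop_ssm("key", "metadata lacks column(s): %s", paste(miss, collapse = ", "))
  }
  if (!is.null(metadata$path)) {
    if (nrow(metadata) != length(paths)) {
      stop_ssm("key", "metadata has %d rows for %d volume paths",
               nrow(metadata), length(paths))
    }
    idx <- match(normalizePath(metadata$path, mustWork = FALSE),
                 normalizePath(paths, mustWork = FALSE))
    if (anyNA(idx)) {
      stop_ssm("key", "metadata row(s) reference path(s) not in `paths`: %s",
               paste(metadata$subject_id[is.na(idx)], collapse = ", "))
    }
    paths <- paths[idx]
  }
  if (nrow(metadata) != length(paths)) {
    stop_ssm("key", "metadata has %d rows for %d volume paths",
             nrow(metadata), length(paths))
  }
  vols <- lapply(paths, RNifti::readNifti)
  dims <- lapply(vols, dim)
  if (any(vapply(dims, length, 1L) != 3L)) {
    stop_ssm("dimension", "all volumes must be 3D")
  }
  ref_dim <- dims[[1]]
  same <- vapply(dims, function(d) identical(d, ref_dim), TRUE)
  if (!all(same)) {
    stop_ssm("dimension", "volume grid shapes differ (e.g. %s vs %s)",
             paste(ref_dim, collapse = "x"),
             paste(dims[[which(!same)[1]]], collapse = "x"))
  }
  affines <- lapply(vols, function(v) unclass(RNifti::xform(v)))
  ref_aff <- affines[[1]]
  for (a in affines) {
    if (max(abs(a - ref_aff)) > affine_tol) {
      stop_ssm("dimension",
               "volume affines differ by more than %g; not in a common space",
               affine_tol)
    }
  }
  data <- do.call(rbind, lapply(vols, function(v) as.vector(v)))
  if (!all(is.finite(data))) {
    stop_ssm("value", "input volumes contain non-finite voxels")
  }
  volume_set(data, mask = NULL, grid_shape = ref_dim, affine = ref_aff,
             subject_ids = metadata$subject_id,
             group_labels = metadata$group,
             camera_labels = metadata$camera)
}

#' Construct the analysis mask from a cohort
#'
#' A voxel enters the mask iff, for every subject, its intensity exceeds
#' `threshold_fraction` times that subject's maximum intensity; the returned
#' mask is the intersection of the per-subject supra-threshold sets.  This
#' relative-threshold rule is the established SSM convention for removing
#' out-of-brain voxels; the fraction is configurable.
#'
#' @param vs a [volume_set()] with an all-true (not yet applied) mask.
#' @param threshold_fraction fraction of the per-subject maximum, in (0,1).
#' @return Logical 3D array of the same shape as the grid.
#' @export
compute_brain_mask <- function(vs, threshold_fraction = 0.35) {
  stopifnot(inherits(vs, "volume_set"))
  if (!(threshold_fraction > 0 && threshold_fraction < 1)) {
    stop_ssm("config", "threshold_fraction must lie in (0,1)")
  }
  if (!all(vs$mask)) {
    stop_ssm("value", "compute_brain_mask expects an unmasked volume_set")
  }
  keep <- rep(TRUE, ncol(vs$data))
  for (i in seq_len(nrow(vs$data))) {
    keep <- keep & (vs$data[i, ] > threshold_fraction * max(vs$data[i, ]))
  }
  if (!any(keep)) {
    stop_ssm("degenerate", "brain mask is empty at threshold %g",
             threshold_fraction)
  }
  array(keep, dim = vs$grid_shape)
}

#' Restrict a volume set to a mask
#'
#' Keeps only the data columns whose voxels lie inside `mask`.  The new mask
#' must be a subset of the set's current mask.
#'
#' @param vs a [volume_set()].
#' @param mask logical 3D array of the grid shape.
#' @return A masked [volume_set()].
#' @export
apply_mask <- function(vs, mask) {
  stopifnot(inherits(vs, "volume_set"))
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!identical(dim(mask), vs$grid_shape)) {
    stop_ssm("dimension", "mask shape does not match the volume grid")
  }
  if (!any(mask)) {
    stop_ssm("degenerate", "mask selects zero voxels")
  }
  if (any(mask & !vs$mask)) {
    stop_ssm("value", "new mask includes voxels outside the current mask")
  }
  keep <- mask[vs$mask]
  volume_set(vs$data[, keep, drop = FALSE], mask = mask,
             grid_shape = vs$grid_shape, affine = vs$affine,
             subject_ids = vs$subject_ids, group_labels = vs$group_labels,
             camera_labels = vs$camera_labels)
}

#' Restore a masked voxel vector to a full 3D volume
#'
#' @param values numeric vector with one entry per `TRUE` mask voxel.
#' @param mask logical 3D array.
#' @param fill value outside the mask (default 0).
#' @return Numeric 3D array.
#' @export
unmask_to_volume <- function(values, mask, fill = 0) {
  if (length(values) != sum(mask)) {
    stop_ssm("dimension", "got %d values for %d mask voxels",
             length(values), sum(mask))
  }
  vol <- array(fill, dim = dim(mask))
  vol[mask] <- values
  vol
}

#' Write a per-voxel weight map as a NIfTI volume
#'
#' Weights are placed at mask positions, zero outside, and written in double
#' precision so a reload reproduces them to floating tolerance.
#'
#' @param weights numeric vector, one value per `TRUE` mask voxel.
#' @param mask logical 3D array.
#' @param affine 4x4 voxel-to-world transform.
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
export_weight_map <- function(weights, mask, affine, path) {
  vol <- unmask_to_volume(weights, mask)
  write_nifti_volume(vol, affine, path)
  invisible(path)
}

## Shared NIfTI writer: double precision, explicit affine.
write_nifti_volume <- function(vol, affine, path) {
  img <- RNifti::asNifti(vol)
  img <- RNifti::`sform<-`(img, structure(matrix(as.numeric(affine), 4, 4),
                                          code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read and write cohort manifest tables
#'
#' A manifest is a tab-separated table with columns `path`, `subject_id`,
#' `group`, `camera` describing one scan per row.
#'
#' @param path file path of the manifest.
#' @return `read_manifest` returns a data frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop_ssm("config", "manifest file not found: %s", path)
  }
  m <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("path", "subject_id", "group", "camera")
  miss <- setdiff(need, names(m))
  if (length(miss)) {
    stop_ssm("key", "manifest lacks column(s): %s", paste(miss, collapse = ", "))
  }
  m
}

#' @rdname read_manifest
#' @param manifest data frame to write.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
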