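# Shared fixtures, built in code at test time.

# Small, fast synthetic cohort: 10x12x10 grid (~800 in-mask voxels), 8+8
# subjects.  Defaults inherit the package generator's study conditions.
small_spec <- function(...) {
  args <- list(...)
  defaults <- list(grid_shape = c(10L, 12L, 10L),
                   n_controls = 8L, n_patients = 8L)
  do.call(synthetic_cohort_spec,
          c(args, defaults[setdiff(names(defaults), names(args))]))
}

# Tiny hand-made volume_set: n subjects over an arbitrary positive matrix.
toy_volume_set <- function(data, grid_shape, mask = NULL,
                           groups = NULL, cameras = NULL) {
  n <- nrow(data)
  volume_set(data, mask = mask, grid_shape = grid_shape,
             subject_ids = sprintf("s%02d", seq_len(n)),
             group_labels = groups %||% rep(c("control", "patient"),
                                            length.out = n),
             camera_labels = cameras %||% rep("cam1", n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a 3D array as NIfTI into a tempdir and return the path.
write_tmp_nifti <- function(vol, affine = diag(4), dir = tempdir()) {
  path <- tempfile(fileext = ".nii.gz", tmpdir = dir)
  img <- RNifti::asNifti(vol)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  path
}

# Random orthonormal n x k score-like matrix columns (mimics PCA scores).
random_orthogonal_scores <- function(n, k) {
  qr.Q(qr(matrix(rnorm(n * k), n, k)))
}
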