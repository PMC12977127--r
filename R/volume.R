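#' Volumes on a regular grid
#'
#' A `foliakit_volume` couples a 3-D array with an invertible 4x4 affine that
#' maps 0-based voxel indices of voxel *centers* to world coordinates in mm
#' (the NIfTI convention). [label_volume()] additionally requires integer
#' storage and is used for segmentations and atlases; [intensity_volume()]
#' holds continuous images such as MRIs.
#'
#' @param array 3-D array.
#' @param affine 4x4 numeric matrix, last row `c(0, 0, 0, 1)`, invertible.
#' @return An object of class `label_volume` or `intensity_volume` (both
#'   inherit from `foliakit_volume`) with fields `array` and `affine`.
#' @examples
#' v <- label_volume(array(0L, c(4, 4, 4)), diag(4))
#' voxel_size(v)
#' @export
label_volume <- function(array, affine = diag(4)) {
  vol <- new_volume(array, affine)
  storage.mode(vol$array) <- "integer"
  class(vol) <- c("label_volume", "foliakit_volume")
  vol
}

#' @rdname label_volume
#' @export
intensity_volume <- function(array, affine = diag(4)) {
  vol <- new_volume(array, affine)
  storage.mode(vol$array) <- "double"
  class(vol) <- c("intensity_volume", "foliakit_volume")
  vol
}

new_volume <- function(array, affine) {
  if (length(dim(array)) != 3L)
    fk_stop("fk_dimensionality_error",
            "volume must be 3-D, got %d dimensions", length(dim(array)))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    fk_stop("fk_affine_error", "affine must be a 4x4 matrix")
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    fk_stop("fk_affine_error", "affine is singular (|det| < 1e-12)")
  list(array = array, affine = affine)
}

#' @rdname label_volume
#' @param volume a `foliakit_volume`.
#' @export
voxel_size <- function(volume) {
  sqrt(colSums(volume$affine[1:3, 1:3]^2))
}

#' Convert between voxel indices and world coordinates
#'
#' Voxel indices are 0-based and address voxel centers; `affine %*% (i,j,k,1)`
#' gives the center's world position in mm.
#'
#' @param affine 4x4 voxel-center-to-world matrix.
#' @param ijk n x 3 matrix of (possibly fractional) 0-based voxel indices.
#' @param xyz n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix.
#' @export
voxel_to_world <- function(affine, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  t(affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(affine, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  t(solve(affine) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

#' @export
print.foliakit_volume <- function(x, ...) {
  d <- dim(x$array)
  cat(sprintf("<%s> %d x %d x %d, voxel size %s mm\n", class(x)[1],
              d[1], d[2], d[3],
              paste(signif(voxel_size(x), 4), collapse = " x ")))
  if (inherits(x, "label_volume")) {
    labs <- sort(unique(as.vector(x$array)))
    cat("  labels:", paste(head(labs, 12), collapse = ", "),
        if (length(labs) > 12) "..." else "", "\n")
  }
  invisible(x)
}

# world coordinates of every voxel center, in array (column-major) order
grid_world_coords <- function(dim, affine) {
  ijk <- cbind(
    rep.int(seq_len(dim[1]) - 1L, dim[2] * dim[3]),
    rep.int(rep(seq_len(dim[2]) - 1L, each = dim[1]), dim[3]),
    rep(seq_len(dim[3]) - 1L, each = dim[1] * dim[2])
  )
  voxel_to_world(affine, ijk)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$array), dim(b$array)) &&
    max(abs(a$affine - b$affine)) < tol
}
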