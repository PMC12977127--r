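#' Dense displacement fields
#'
#' A displacement field stores one world-mm displacement vector per voxel of
#' its own grid (X x Y x Z x 3) plus the grid's voxel-center-to-world affine.
#' As a point map it sends world position `x` to `x + d(x)`, with `d`
#' interpolated trilinearly. Fields produced by [register()] satisfy the
#' diffeomorphism contract: the Jacobian determinant of `id + d` is positive
#' at all interior grid points (see [jacobian_determinant_range()]).
#'
#' @param vectors 4-D array X x Y x Z x 3, displacements in mm.
#' @param affine 4x4 voxel-center-to-world matrix of the field grid.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(vectors, affine = diag(4)) {
  vectors <- as.array(vectors)
  if (length(dim(vectors)) != 4L || dim(vectors)[4] != 3L)
    fk_stop("fk_dimensionality_error", "vectors must be X x Y x Z x 3")
  if (!all(is.finite(vectors)))
    fk_stop("fk_field_error", "displacement field contains non-finite values")
  affine <- as.matrix(affine)
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    fk_stop("fk_affine_error", "field affine is singular")
  structure(list(vectors = vectors, affine = affine),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  d <- dim(x$vectors)
  cat(sprintf("<displacement_field> %d x %d x %d grid, |d| max %.3g mm\n",
              d[1], d[2], d[3], max(sqrt(apply(x$vectors^2, c(1, 2, 3),
                                               sum)))))
  invisible(x)
}

identity_field <- function(dim, affine = diag(4)) {
  displacement_field(array(0, c(dim, 3L)), affine)
}

#' Evaluate a displacement field at world points
#'
#' Trilinear interpolation of the vector components at arbitrary world
#' positions; positions outside the grid are clamped to the nearest edge.
#'
#' @param field a [displacement_field()].
#' @param points n x 3 world coordinates (mm).
#' @return n x 3 matrix of displacement vectors (mm).
#' @export
field_at_points <- function(field, points) {
  points <- matrix(as.numeric(points), ncol = 3L)
  vox <- world_to_voxel(field$affine, points)
  d <- dim(field$vectors)[1:3]
  out <- matrix(0, nrow(points), 3L)
  for (c in 1:3)
    out[, c] <- cpp_sample_volume(as.vector(field$vectors[, , , c]),
                                  as.integer(d), vox, 1L)
  out
}

# fraction of points falling outside the field grid (before clamping)
fraction_outside_grid <- function(field, points) {
  vox <- world_to_voxel(field$affine, points)
  d <- dim(field$vectors)[1:3]
  outside <- vox[, 1] < 0 | vox[, 2] < 0 | vox[, 3] < 0 |
    vox[, 1] > d[1] - 1 | vox[, 2] > d[2] - 1 | vox[, 3] > d[3] - 1
  mean(outside)
}

#' Compose two displacement fields
#'
#' Returns a single field equivalent to applying `first` and then `second` as
#' point maps: `composed(x) = first(x) + second(x + first(x))`, evaluated on
#' the grid of `first`.
#'
#' @param first,second [displacement_field()] objects with overlapping world
#'   domains.
#' @return a [displacement_field()] on the grid of `first`.
#' @export
compose_fields <- function(first, second) {
  d <- dim(first$vectors)[1:3]
  grid <- grid_world_coords(d, first$affine)
  v1 <- matrix(first$vectors, ncol = 3L)
  v2 <- field_at_points(second, grid + v1)
  displacement_field(array(v1 + v2, c(d, 3L)), first$affine)
}

#' Numerically invert a displacement field
#'
#' Fixed-point iteration `inv(x) <- -d(x + inv(x))`, which converges for
#' diffeomorphic fields (displacement gradients below 1). Used to turn the
#' pull-back fields produced by image registration into forward point maps
#' for warping surface vertices.
#'
#' @param field a [displacement_field()].
#' @param max_iterations iteration cap.
#' @param tol convergence tolerance on the update, mm.
#' @return a [displacement_field()] on the same grid.
#' @export
invert_field <- function(field, max_iterations = 50L, tol = 1e-3) {
  d <- dim(field$vectors)[1:3]
  grid <- grid_world_coords(d, field$affine)
  inv <- matrix(0, nrow(grid), 3L)
  for (i in seq_len(max_iterations)) {
    upd <- -field_at_points(field, grid + inv)
    delta <- max(abs(upd - inv))
    inv <- upd
    if (delta < tol) break
  }
  displacement_field(array(inv, c(d, 3L)), field$affine)
}

#' Resample a volume through a displacement field
#'
#' Pull-back warping: the output volume lives on the field's grid and
#' `out(y) = vol(y + d(y))`. Use `method = "nearest"` for label volumes and
#' `"trilinear"` for intensity volumes.
#'
#' @param volume a [label_volume()] or [intensity_volume()].
#' @param field a [displacement_field()]; its grid defines the output grid.
#' @param method `"nearest"` or `"trilinear"`.
#' @return a volume of the same class as `volume` on the field's grid.
#' @export
warp_volume <- function(volume, field, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  d <- dim(field$vectors)[1:3]
  grid <- grid_world_coords(d, field$affine)
  src <- grid + matrix(field$vectors, ncol = 3L)
  vox <- world_to_voxel(volume$affine, src)
  vals <- cpp_sample_volume(as.numeric(volume$array),
                            as.integer(dim(volume$array)), vox,
                            if (method == "nearest") 0L else 1L)
  arr <- array(vals, d)
  if (inherits(volume, "label_volume")) label_volume(arr, field$affine)
  else intensity_volume(arr, field$affine)
}

#' Warp a surface through a chain of displacement fields
#'
#' Applies each field in order as a point map: `v <- v + d_i(v)`. Faces,
#' labels and spherical coordinates are untouched. Vertices outside a field's
#' grid use nearest-edge extrapolation with a warning; if more than 1% of
#' vertices fall outside, a domain error is raised.
#'
#' @param surface a [labeled_surface()].
#' @param field_chain a [displacement_field()] or list of them, applied in
#'   list order.
#' @return the warped [labeled_surface()].
#' @export
warp_surface <- function(surface, field_chain) {
  if (inherits(field_chain, "displacement_field"))
    field_chain <- list(field_chain)
  v <- surface$vertices
  for (field in field_chain) {
    fo <- fraction_outside_grid(field, v)
    if (fo > 0.01)
      fk_stop("fk_domain_error",
              "%.1f%% of vertices outside the field domain", 100 * fo)
    if (fo > 0)
      fk_warn("fk_domain_warning",
              "%.2f%% of vertices outside the field domain; using %s",
              100 * fo, "nearest-edge extrapolation")
    v <- v + field_at_points(field, v)
  }
  out <- surface
  out$vertices <- v
  out
}

#' Jacobian determinant range of a warp
#'
#' Finite-difference Jacobian determinant of the map `id + d` at all interior
#' grid points. Positive values everywhere mean the sampled warp is
#' orientation-preserving (locally diffeomorphic).
#'
#' @param field a [displacement_field()].
#' @return named numeric vector with elements `min` and `max`.
#' @export
jacobian_determinant_range <- function(field) {
  v <- field$vectors
  d <- dim(v)[1:3]
  if (any(d < 3L))
    fk_stop("fk_field_error", "grid too small for interior differences")
  a <- field$affine[1:3, 1:3]
  i <- 2:(d[1] - 1); j <- 2:(d[2] - 1); k <- 2:(d[3] - 1)
  # central differences of each displacement component along each voxel axis
  g <- array(0, c(length(i), length(j), length(k), 3L, 3L))
  for (c in 1:3) {
    g[, , , c, 1] <- (v[i + 1, j, k, c] - v[i - 1, j, k, c]) / 2
    g[, , , c, 2] <- (v[i, j + 1, k, c] - v[i, j - 1, k, c]) / 2
    g[, , , c, 3] <- (v[i, j, k + 1, c] - v[i, j, k - 1, c]) / 2
  }
  # d(phi)/d(ijk) = A + d(d)/d(ijk); det in world units = det / det(A)
  j11 <- a[1, 1] + g[, , , 1, 1]; j12 <- a[1, 2] + g[, , , 1, 2]
  j13 <- a[1, 3] + g[, , , 1, 3]
  j21 <- a[2, 1] + g[, , , 2, 1]; j22 <- a[2, 2] + g[, , , 2, 2]
  j23 <- a[2, 3] + g[, , , 2, 3]
  j31 <- a[3, 1] + g[, , , 3, 1]; j32 <- a[3, 2] + g[, , , 3, 2]
  j33 <- a[3, 3] + g[, , , 3, 3]
  det3 <- j11 * (j22 * j33 - j23 * j32) - j12 * (j21 * j33 - j23 * j31) +
    j13 * (j21 * j32 - j22 * j31)
  det3 <- det3 / det(a)
  c(min = min(det3), max = max(det3))
}
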