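#' Subdivided icosahedron (icosphere)
#'
#' Deterministic genus-0 triangulation of the unit sphere: a regular
#' icosahedron whose faces are recursively 4-split with midpoint vertices
#' projected back to the sphere. Faces are consistently outward-oriented.
#'
#' @param subdivisions number of 4-splits (0 = icosahedron, 12 vertices;
#'   each level quadruples the face count; level 5 has 10,242 vertices).
#' @return a [labeled_surface()] with unit-norm vertices (no labels).
#' @export
icosphere <- function(subdivisions = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    edges <- unique(rbind(
      cbind(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2])),
      cbind(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3])),
      cbind(pmin(f[, 1], f[, 3]), pmax(f[, 1], f[, 3]))))
    mid <- (v[edges[, 1], ] + v[edges[, 2], ]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    key <- edges[, 1] * (nv + 1) + edges[, 2]
    lookup <- function(a, b) {
      k <- pmin(a, b) * (nv + 1) + pmax(a, b)
      nv + match(k, key)
    }
    m12 <- lookup(f[, 1], f[, 2])
    m23 <- lookup(f[, 2], f[, 3])
    m13 <- lookup(f[, 1], f[, 3])
    f <- rbind(cbind(f[, 1], m12, m13), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m13, m23), cbind(m12, m23, m13))
    v <- rbind(v, mid)
  }
  labeled_surface(v, f)
}

#' Synthetic folded cortical phantom
#'
#' A closed genus-0 surface with sinusoidal radial folds standing in for the
#' folial geometry of a real cortex: the radial map
#' `r(theta, phi) = R (1 + a sin(k theta) sin(k phi))` is applied to a
#' subdivided icosphere. Because `a < 0.5` keeps the radius positive and the
#' map radial (star-shaped), the surface cannot self-intersect. Labels are
#' `n_regions` contiguous latitude bands with balanced vertex counts, ids
#' 1..`n_regions`; the pre-deformation unit icosphere provides the spherical
#' coordinates. The defaults (R = 25 mm, k = 6, a = 0.2, subdivision 5,
#' about 10k vertices) are large enough to exercise folding while keeping
#' whole-pipeline runs at desk scale.
#'
#' @param base_radius sphere radius R in mm.
#' @param fold_count angular fold frequency k (>= 0).
#' @param fold_amplitude fold amplitude a as a fraction of R (0 <= a < 0.5).
#' @param mesh_subdivisions icosphere subdivision level.
#' @param n_regions number of latitude-band regions (>= 1).
#' @param rng_seed recorded for provenance; the construction is deterministic.
#' @param add_vermis also label a midline strip (id `n_regions + 1`) cutting
#'   across the bands, to exercise midline groups in evaluation.
#' @param check_self_intersection verify via winding tests at offset face
#'   centroids that the surface bounds a proper interior.
#' @return a [labeled_surface()] with labels, spherical coordinates and a
#'   default [label_table()] (white matter id `n_regions + 2`, tract id
#'   `n_regions + 3` reserved, unused by the phantom itself).
#' @export
make_folded_phantom <- function(base_radius = 25, fold_count = 6L,
                                fold_amplitude = 0.2, mesh_subdivisions = 5L,
                                n_regions = 8L, rng_seed = 1L,
                                add_vermis = FALSE,
                                check_self_intersection = FALSE) {
  if (fold_amplitude < 0 || fold_amplitude >= 0.5)
    fk_stop("fk_spec_error", "fold_amplitude must be in [0, 0.5)")
  if (fold_count < 0 || n_regions < 1)
    fk_stop("fk_spec_error", "fold_count >= 0 and n_regions >= 1 required")
  ico <- icosphere(mesh_subdivisions)
  sph <- ico$vertices
  theta <- acos(pmin(pmax(sph[, 3], -1), 1))
  phi <- atan2(sph[, 2], sph[, 1])
  r <- base_radius * (1 + fold_amplitude * sin(fold_count * theta) *
                        sin(fold_count * phi))
  vertices <- sph * r
  # contiguous latitude bands with balanced vertex counts
  qs <- quantile(theta, probs = seq(0, 1, length.out = n_regions + 1),
                 type = 8)
  labels <- as.integer(cut(theta, breaks = qs, include.lowest = TRUE))
  if (add_vermis) labels[abs(sph[, 1]) < 0.12] <- n_regions + 1L
  n_named <- n_regions + if (add_vermis) 1L else 0L
  table <- label_table(
    ids = c(seq_len(n_named), n_regions + 2L, n_regions + 3L),
    names = c(paste0("band_", seq_len(n_regions)),
              if (add_vermis) "vermis_strip",
              "white_matter", "wm_tract"),
    wm_id = n_regions + 2L, tract_id = n_regions + 3L)
  out <- labeled_surface(vertices, ico$faces, labels = labels,
                         spherical = sph, label_table = table)
  if (check_self_intersection) {
    idx <- seq(1, nrow(out$faces), length.out = min(200, nrow(out$faces)))
    fc <- (out$vertices[out$faces[idx, 1], ] +
             out$vertices[out$faces[idx, 2], ] +
             out$vertices[out$faces[idx, 3], ]) / 3
    eps <- 0.05 * mean_edge_length(out)
    nrm <- fc / sqrt(rowSums(fc^2))  # radial surface: outward ~ radial
    w_out <- winding_number(out, fc + eps * nrm)
    w_in <- winding_number(out, fc - eps * nrm)
    if (any(w_out > 0.5) || any(w_in < 0.5))
      fk_stop("fk_spec_error",
              "phantom self-intersects (winding test at face centroids)")
  }
  attr(out, "rng_seed") <- rng_seed
  out
}

#' Smooth random deformation with positive Jacobian
#'
#' A band-limited mixture of random 3-D sinusoids, one mixture per
#' displacement component, rescaled so the maximum displacement equals
#' `amplitude_mm` and then, if necessary, rescaled again so the maximum
#' finite-difference displacement gradient stays below 0.9 — which guarantees
#' a positive Jacobian determinant of `id + d` everywhere. Serves as the
#' known ground-truth diffeomorphism for registration-recovery experiments.
#'
#' @param grid_shape length-3 integer grid dimensions.
#' @param affine 4x4 voxel-center-to-world matrix of the grid.
#' @param amplitude_mm peak displacement magnitude in mm.
#' @param wavelength_mm spatial wavelength of the sinusoid mixture in mm.
#' @param rng_seed integer seed; fields are reproducible bit for bit.
#' @param n_waves sinusoids per component.
#' @return a [displacement_field()].
#' @export
make_smooth_deformation <- function(grid_shape, affine = diag(4),
                                    amplitude_mm = 2, wavelength_mm = 20,
                                    rng_seed = 1L, n_waves = 4L) {
  grid_shape <- as.integer(grid_shape)
  set.seed(rng_seed)
  xyz <- grid_world_coords(grid_shape, affine)
  vec <- matrix(0, nrow(xyz), 3L)
  for (c in 1:3) {
    for (w in seq_len(n_waves)) {
      dir <- rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      phase <- runif(1, 0, 2 * pi)
      amp <- runif(1, 0.5, 1)
      vec[, c] <- vec[, c] +
        amp * sin(2 * pi * (xyz %*% dir) / wavelength_mm + phase)
    }
  }
  if (amplitude_mm == 0) vec[] <- 0
  else {
    mag <- sqrt(rowSums(vec^2))
    if (max(mag) > 0) vec <- vec * (amplitude_mm / max(mag))
  }
  field <- displacement_field(array(vec, c(grid_shape, 3L)), affine)
  g <- max_displacement_gradient(field)
  if (g >= 0.9) {
    scale <- 0.85 / g
    field$vectors <- field$vectors * scale
    message(sprintf(
      "deformation rescaled by %.3f to keep displacement gradients < 0.9",
      scale))
  }
  field
}

# max absolute finite-difference gradient entry of the displacement, in
# world units (an upper-bound proxy for ||grad d||)
max_displacement_gradient <- function(field) {
  v <- field$vectors
  d <- dim(v)[1:3]
  vs <- voxel_size_from_affine(field$affine)
  g <- 0
  for (c in 1:3) {
    a <- v[, , , c]
    if (d[1] > 1)
      g <- max(g, max(abs(a[2:d[1], , ] - a[1:(d[1] - 1), , ])) / vs[1])
    if (d[2] > 1)
      g <- max(g, max(abs(a[, 2:d[2], ] - a[, 1:(d[2] - 1), ])) / vs[2])
    if (d[3] > 1)
      g <- max(g, max(abs(a[, , 2:d[3]] - a[, , 1:(d[3] - 1)])) / vs[3])
  }
  g
}

#' Synthesize a subject from an atlas and a known deformation
#'
#' Warps the atlas segmentation (nearest neighbor) and the atlas virtual MRI
#' (trilinear, plus additive Gaussian noise) through a known displacement
#' field, emulating the standard-resolution inputs of an atlas-to-subject
#' reconstruction while retaining the ground truth.
#'
#' @param atlas_label_volume a [label_volume()].
#' @param atlas_virtual_mri an [intensity_volume()] on the same grid.
#' @param field the ground-truth [displacement_field()] (pull-back: subject
#'   voxel y samples atlas at `y + d(y)`).
#' @param noise_sd additive Gaussian noise SD on the MRI intensities.
#' @param rng_seed integer seed for the noise.
#' @return list with `subject_mri`, `subject_segmentation` and
#'   `ground_truth_field` (the input field; invert it to map atlas points
#'   into subject space).
#' @export
make_subject <- function(atlas_label_volume, atlas_virtual_mri, field,
                         noise_sd = 0, rng_seed = 1L) {
  seg <- warp_volume(atlas_label_volume, field, "nearest")
  mri <- warp_volume(atlas_virtual_mri, field, "trilinear")
  if (noise_sd > 0) {
    set.seed(rng_seed)
    mri$array <- mri$array + array(rnorm(length(mri$array), sd = noise_sd),
                                   dim(mri$array))
  }
  list(subject_mri = mri, subject_segmentation = seg,
       ground_truth_field = field)
}
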