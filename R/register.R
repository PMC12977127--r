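#' Virtual MRI synthesis from a label volume
#'
#' Renders an intensity image from a segmentation by mapping each label to a
#' constant intensity and blurring with an isotropic Gaussian. Because the
#' blur kernel is normalized, the output never leaves the intensity range of
#' the map. The default intensities (cortex 110, white matter 250,
#' background 0, in arbitrary units) give strong cortex/core contrast for
#' intensity-based registration.
#'
#' @param label_volume a [label_volume()].
#' @param intensity_map named numeric vector mapping every label id present in
#'   the volume (names) to an intensity.
#' @param blur_sigma_mm Gaussian sigma in mm (0 disables blurring).
#' @return an [intensity_volume()] on the same grid.
#' @export
make_virtual_mri <- function(label_volume, intensity_map,
                             blur_sigma_mm = 0.5) {
  ids <- sort(unique(as.vector(label_volume$array)))
  unmapped <- setdiff(ids, as.integer(names(intensity_map)))
  if (length(unmapped))
    fk_stop("fk_mapping_error", "labels without intensities: %s",
            paste(unmapped, collapse = ", "))
  vals <- unname(intensity_map[as.character(label_volume$array)])
  arr <- array(vals, dim(label_volume$array))
  if (blur_sigma_mm > 0) {
    sig <- blur_sigma_mm / voxel_size(label_volume)
    arr <- cpp_gaussian_blur3d(arr, as.integer(dim(arr)), sig)
  }
  intensity_volume(arr, label_volume$affine)
}

#' @rdname make_virtual_mri
#' @param cortex_ids,wm_id,background label groups for the default map.
#' @export
default_intensity_map <- function(cortex_ids, wm_id, background = 0L) {
  setNames(c(0, rep(110, length(cortex_ids)), 250),
           c(background, cortex_ids, wm_id))
}

#' Registration backend configuration
#'
#' The builtin backend is a multi-resolution diffeomorphic demons algorithm:
#' per iteration the demons force is computed from the (optionally locally
#' normalized) fixed and warped moving images, smoothed ("fluid"
#' regularization), exponentiated by scaling-and-squaring so the update is a
#' small diffeomorphism, composed with the running field, and smoothed again
#' ("diffusion" regularization). With `metric = "lncc"` both images are
#' locally normalized (window mean removed, divided by window SD) before the
#' force computation, which makes the SSD force insensitive to intensity
#' scaling, approximating a local normalized cross-correlation drive. The
#' external adapter delegates to a user-supplied function or command (e.g. a
#' symmetric-normalization implementation) and only reads back the
#' displacement field.
#'
#' @param backend `"builtin-demons"` or `"external-adapter"`.
#' @param metric `"lncc"` (local normalized cross-correlation drive,
#'   window `lncc_window` voxels) or `"ssd"`.
#' @param pyramid_levels number of resolution levels (>= 1; level 1 = full
#'   resolution, each coarser level downsamples by 2).
#' @param smoothing_sigma_mm length-2 vector `c(fluid, diffusion)` Gaussian
#'   sigmas in mm.
#' @param step_size maximum update magnitude per iteration, in voxels.
#' @param max_iterations iterations per level, coarsest first (recycled).
#' @param refine_iterations extra full-resolution iterations run after the
#'   pyramid with `refine_sigma_mm` smoothing. Because the per-iteration
#'   diffusion smoothing of the total field slightly attenuates the
#'   recovered displacement, a short low-diffusion refinement pass sharpens
#'   the converged field without destabilizing it. 0 disables the pass.
#' @param refine_sigma_mm length-2 `c(fluid, diffusion)` sigmas of the
#'   refinement pass.
#' @param lncc_window local-normalization window in voxels (odd).
#' @param external_fn for the external adapter: `function(fixed_path,
#'   moving_path, mask_path, out_field_path)` that writes a displacement-field
#'   NIfTI; alternatively a character command template with placeholders
#'   `{fixed}`, `{moving}`, `{mask}`, `{out}`.
#' @return a list of class `registration_config`.
#' @export
registration_config <- function(backend = c("builtin-demons",
                                            "external-adapter"),
                                metric = c("lncc", "ssd"),
                                pyramid_levels = 3L,
                                smoothing_sigma_mm = c(2, 2),
                                step_size = 1,
                                max_iterations = c(100L, 60L, 30L),
                                refine_iterations = 25L,
                                refine_sigma_mm = c(2, 0.5),
                                lncc_window = 5L,
                                external_fn = NULL) {
  backend <- match.arg(backend)
  metric <- match.arg(metric)
  if (pyramid_levels < 1L)
    fk_stop("fk_config_error", "pyramid_levels must be >= 1")
  if (smoothing_sigma_mm[1] <= 0 || smoothing_sigma_mm[2] < 0)
    fk_stop("fk_config_error",
            "fluid sigma must be > 0 and diffusion sigma >= 0")
  structure(list(backend = backend, metric = metric,
                 pyramid_levels = as.integer(pyramid_levels),
                 smoothing_sigma_mm = smoothing_sigma_mm,
                 step_size = step_size,
                 max_iterations = as.integer(max_iterations),
                 refine_iterations = as.integer(refine_iterations),
                 refine_sigma_mm = refine_sigma_mm,
                 lncc_window = as.integer(lncc_window),
                 external_fn = external_fn),
            class = "registration_config")
}

## ---- internal demons machinery ---------------------------------------------
## Images are plain 3-D arrays on a common grid; displacement vectors are kept
## in voxel units internally and converted to world mm only at the end
## (grids here are axis-aligned with isotropic-ish voxels, so per-axis voxel
## units are well defined).

blur3 <- function(arr, sigma_vox) {
  if (all(sigma_vox <= 0)) return(arr)
  cpp_gaussian_blur3d(arr, as.integer(dim(arr)), pmax(sigma_vox, 0))
}

downsample2 <- function(arr) {
  arr <- blur3(arr, c(1, 1, 1))
  d <- dim(arr)
  arr[seq(1, d[1], 2), seq(1, d[2], 2), seq(1, d[3], 2), drop = FALSE]
}

# local normalization: subtract window mean, divide by window SD
local_normalize <- function(arr, window) {
  sig <- rep(window / 4, 3)  # Gaussian window matched to the box size
  mu <- blur3(arr, sig)
  v <- blur3(arr^2, sig) - mu^2
  (arr - mu) / sqrt(pmax(v, 0) + 1e-6 * max(abs(arr))^2 + 1e-12)
}

# central-difference gradient of a 3-D array, voxel units
gradient3 <- function(arr) {
  d <- dim(arr)
  g <- array(0, c(d, 3L))
  g[2:(d[1] - 1), , , 1] <- (arr[3:d[1], , ] - arr[1:(d[1] - 2), , ]) / 2
  g[, 2:(d[2] - 1), , 2] <- (arr[, 3:d[2], ] - arr[, 1:(d[2] - 2), ]) / 2
  g[, , 2:(d[3] - 1), 3] <- (arr[, , 3:d[3]] - arr[, , 1:(d[3] - 2)]) / 2
  g
}

# sample 3-D array at voxel positions grid + disp (both voxel units)
warp_arr <- function(arr, disp, grid_vox) {
  d <- dim(arr)
  v <- cpp_sample_volume(as.numeric(arr), as.integer(d),
                         grid_vox + matrix(disp, ncol = 3L), 1L)
  array(v, d)
}

blur_field <- function(disp, sigma_vox) {
  d <- dim(disp)
  for (c in 1:3) disp[, , , c] <- blur3(disp[, , , c], sigma_vox)
  disp
}

# compose voxel-unit displacement fields on a shared grid:
# out(x) = a(x) + b(x + a(x))
compose_vox <- function(a, b, grid_vox) {
  d <- dim(a)
  pos <- grid_vox + matrix(a, ncol = 3L)
  out <- a
  for (c in 1:3)
    out[, , , c] <- out[, , , c] +
      array(cpp_sample_volume(as.numeric(b[, , , c]), as.integer(d[1:3]), pos,
                              1L), d[1:3])
  out
}

# scaling-and-squaring exponential of a voxel-unit velocity field
exp_field <- function(vel, grid_vox) {
  mx <- max(abs(vel))
  n <- if (mx <= 0) 0L else max(0L, ceiling(log2(mx / 0.25)))
  u <- vel / 2^n
  for (i in seq_len(n)) u <- compose_vox(u, u, grid_vox)
  u
}

grid_vox_coords <- function(d) {
  cbind(rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
        rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
        rep(seq_len(d[3]) - 1L, each = d[1] * d[2]))
}

demons_level <- function(fixed_ch, moving_ch, disp, iters, fluid_vox,
                         diff_vox, step_vox) {
  d <- dim(fixed_ch[[1]])
  grid_vox <- grid_vox_coords(d)
  grads <- lapply(fixed_ch, gradient3)
  scale2 <- mean(vapply(fixed_ch, function(f) mean(f^2), 0)) + 1e-12
  for (it in seq_len(iters)) {
    num <- array(0, c(d, 3L))
    den <- array(0, d)
    for (c in seq_along(fixed_ch)) {
      mw <- warp_arr(moving_ch[[c]], disp, grid_vox)
      diffim <- fixed_ch[[c]] - mw
      # symmetric force: average of fixed and warped-moving gradients
      g <- (grads[[c]] + gradient3(mw)) / 2
      g2 <- g[, , , 1]^2 + g[, , , 2]^2 + g[, , , 3]^2
      for (a in 1:3) num[, , , a] <- num[, , , a] + diffim * g[, , , a]
      den <- den + g2 + diffim^2 / scale2
    }
    den <- den + 1e-12
    u <- num
    for (a in 1:3) u[, , , a] <- u[, , , a] / den
    # cap the update at step_vox voxels
    mag <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
    cap <- pmin(1, step_vox / pmax(mag, 1e-12))
    for (a in 1:3) u[, , , a] <- u[, , , a] * cap
    u <- blur_field(u, fluid_vox)
    u <- exp_field(u, grid_vox)
    disp <- compose_vox(u, disp, grid_vox)
    disp <- blur_field(disp, diff_vox)
  }
  disp
}

# upsample a voxel-unit field from a coarse grid (factor 2) to a fine grid
upsample_field <- function(disp, fine_dim) {
  d <- dim(disp)[1:3]
  pts <- grid_vox_coords(fine_dim) / 2  # fine voxel -> coarse voxel coords
  out <- array(0, c(fine_dim, 3L))
  for (c in 1:3)
    out[, , , c] <- array(cpp_sample_volume(as.numeric(disp[, , , c]),
                                            as.integer(d), pts, 1L),
                          fine_dim) * 2  # voxel units double in size
  out
}

#' Diffeomorphic registration of two intensity volumes
#'
#' Estimates a dense displacement field such that resampling `moving` through
#' the field approximates `fixed`: `moving(x + d(x)) ~ fixed(x)`. The field
#' lives on the grid of `fixed` and is a pull-back for image resampling (see
#' [warp_volume()]); to move points from fixed space into moving space, apply
#' it directly, and use [invert_field()] for the opposite direction.
#'
#' Both volumes (or lists of volumes for multi-channel registration, all on a
#' shared grid) must live on the same grid. See [registration_config()] for
#' the algorithm.
#'
#' @param fixed,moving [intensity_volume()] objects or lists of them
#'   (channels).
#' @param config a [registration_config()].
#' @return a [displacement_field()] (mm) on the fixed grid, with a positive
#'   Jacobian determinant at interior grid points.
#' @export
register <- function(fixed, moving, config = registration_config()) {
  if (inherits(fixed, "foliakit_volume")) fixed <- list(fixed)
  if (inherits(moving, "foliakit_volume")) moving <- list(moving)
  if (length(fixed) != length(moving))
    fk_stop("fk_config_error", "fixed and moving channel counts differ")
  for (i in seq_along(fixed))
    if (!same_grid(fixed[[i]], moving[[i]]) ||
        !same_grid(fixed[[1]], fixed[[i]]))
      fk_stop("fk_grid_error",
              "all channels must share one grid (dimensions and affine)")
  if (config$backend == "external-adapter")
    return(register_external(fixed, moving, config))

  vs <- voxel_size(fixed[[1]])
  fixed_arr <- lapply(fixed, function(v) v$array)
  moving_arr <- lapply(moving, function(v) v$array)
  if (config$metric == "lncc") {
    flat <- vapply(c(fixed_arr, moving_arr), function(a) sd(a) < 1e-12, TRUE)
    if (any(flat))
      fk_stop("fk_metric_error",
              "constant image: normalized correlation undefined; use metric = 'ssd'")
  } else {
    # bring intensities to unit scale so the demons force (and the step cap)
    # behave identically for images in [0, 1] and in scanner units
    sc <- max(1e-12, max(abs(unlist(lapply(fixed_arr, range))),
                         abs(unlist(lapply(moving_arr, range)))))
    fixed_arr <- lapply(fixed_arr, function(a) a / sc)
    moving_arr <- lapply(moving_arr, function(a) a / sc)
  }

  levels <- config$pyramid_levels
  iters <- rep_len(config$max_iterations, levels)
  disp <- NULL  # voxel units at the current level
  for (lev in levels:1) {
    f_ch <- fixed_arr
    m_ch <- moving_arr
    for (s in seq_len(lev - 1L)) {
      f_ch <- lapply(f_ch, downsample2)
      m_ch <- lapply(m_ch, downsample2)
    }
    if (config$metric == "lncc") {
      f_ch <- lapply(f_ch, local_normalize, window = config$lncc_window)
      m_ch <- lapply(m_ch, local_normalize, window = config$lncc_window)
    }
    d <- dim(f_ch[[1]])
    disp <- if (is.null(disp)) array(0, c(d, 3L))
            else upsample_field(disp, d)
    vs_lev <- vs * 2^(lev - 1L)
    disp <- demons_level(f_ch, m_ch, disp, iters[levels - lev + 1L],
                         fluid_vox = config$smoothing_sigma_mm[1] / vs_lev,
                         diff_vox = config$smoothing_sigma_mm[2] / vs_lev,
                         step_vox = config$step_size)
    if (lev == 1L && config$refine_iterations > 0L)
      disp <- demons_level(f_ch, m_ch, disp, config$refine_iterations,
                           fluid_vox = config$refine_sigma_mm[1] / vs_lev,
                           diff_vox = config$refine_sigma_mm[2] / vs_lev,
                           step_vox = config$step_size)
  }
  # voxel units -> world mm on the fixed grid (axis-aligned scaling)
  vec <- disp
  for (c in 1:3) vec[, , , c] <- disp[, , , c] * vs[c]
  # axis directions of the affine
  a <- fixed[[1]]$affine[1:3, 1:3]
  dirs <- sweep(a, 2, sqrt(colSums(a^2)), "/")
  flat_vec <- matrix(vec, ncol = 3L) %*% t(dirs)
  displacement_field(array(flat_vec, c(dim(fixed[[1]]$array), 3L)),
                     fixed[[1]]$affine)
}

register_external <- function(fixed, moving, config) {
  if (length(fixed) != 1L)
    fk_stop("fk_config_error", "external adapter takes single-channel input")
  td <- tempfile("fkreg")
  dir.create(td)
  fp <- file.path(td, "fixed.nii.gz")
  mp <- file.path(td, "moving.nii.gz")
  op <- file.path(td, "field.nii.gz")
  write_volume(fixed[[1]], fp)
  write_volume(moving[[1]], mp)
  fn <- config$external_fn
  if (is.function(fn)) {
    fn(fp, mp, NA_character_, op)
  } else if (is.character(fn)) {
    cmd <- gsub("{fixed}", fp, fn, fixed = TRUE)
    cmd <- gsub("{moving}", mp, cmd, fixed = TRUE)
    cmd <- gsub("{mask}", "", cmd, fixed = TRUE)
    cmd <- gsub("{out}", op, cmd, fixed = TRUE)
    status <- system(cmd)
    if (status != 0)
      fk_stop("fk_backend_error", "external command failed (status %d)",
              status)
  } else {
    fk_stop("fk_config_error", "external adapter needs external_fn")
  }
  read_field(op)
}
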