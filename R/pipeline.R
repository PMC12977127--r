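#' Configuration for the volumetric atlas pipeline
#'
#' The default iteration counts encode the atlas-construction recipe this
#' module implements: cortical regions are
#' expanded into the filled interior for 7 iterations, the labeled volume is
#' mode-smoothed for 3 iterations, white matter is expanded back for 4
#' iterations so cortical labels do not penetrate the corpus medullare, and
#' all non-white-matter labels are expanded once more at the end.
#'
#' @param cortical_expand_iters iterations of cortical expansion into the
#'   interior (default 7).
#' @param mode_smooth_iters volumetric mode-smoothing iterations (default 3).
#' @param wm_expand_iters white-matter expansion iterations (default 4).
#' @param final_cortical_expand_iters final expansion of non-white-matter
#'   labels into white matter (default 1).
#' @param expand_connectivity voxel connectivity for expansions (6, 18 or 26;
#'   default 6, face-adjacent, which keeps expansion isotropic in voxel
#'   steps).
#' @param mode_connectivity connectivity for mode smoothing (default 26).
#' @param voxel_size voxel edge length in mm for the voxelization step.
#' @param padding_voxels grid margin in voxels.
#' @param wm_id label id to assign to white matter / corpus medullare;
#'   defaults to `max(surface labels) + 2`.
#' @param surface_smooth_radius,surface_smooth_iters parameters of the
#'   surface mode filter applied after labels are pulled back to vertices.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(cortical_expand_iters = 7L,
                            mode_smooth_iters = 3L,
                            wm_expand_iters = 4L,
                            final_cortical_expand_iters = 1L,
                            expand_connectivity = 6L,
                            mode_connectivity = 26L,
                            voxel_size = 1,
                            padding_voxels = 2L,
                            wm_id = NULL,
                            surface_smooth_radius = 3L,
                            surface_smooth_iters = 3L) {
  iters <- c(cortical_expand_iters, mode_smooth_iters, wm_expand_iters,
             final_cortical_expand_iters)
  if (any(iters < 0L))
    fk_stop("fk_config_error", "iteration counts must be >= 0")
  if (!expand_connectivity %in% c(6L, 18L, 26L) ||
      !mode_connectivity %in% c(6L, 18L, 26L))
    fk_stop("fk_config_error", "connectivity must be 6, 18 or 26")
  structure(list(cortical_expand_iters = as.integer(cortical_expand_iters),
                 mode_smooth_iters = as.integer(mode_smooth_iters),
                 wm_expand_iters = as.integer(wm_expand_iters),
                 final_cortical_expand_iters =
                   as.integer(final_cortical_expand_iters),
                 expand_connectivity = as.integer(expand_connectivity),
                 mode_connectivity = as.integer(mode_connectivity),
                 voxel_size = voxel_size,
                 padding_voxels = as.integer(padding_voxels),
                 wm_id = wm_id,
                 surface_smooth_radius = as.integer(surface_smooth_radius),
                 surface_smooth_iters = as.integer(surface_smooth_iters)),
            class = "pipeline_config")
}

#' Competitive label expansion on a voxel grid
#'
#' One synchronized sweep per iteration: every voxel whose label is in
#' `target_labels` that is adjacent (per `connectivity`) to at least one voxel
#' whose label is in `source_labels` adopts the smallest such neighboring
#' label. Voxels outside `target_labels` (or under `protect`) never change,
#' so expanding labels compete for the target class but never overwrite each
#' other.
#'
#' @param volume a [label_volume()].
#' @param iterations number of sweeps (>= 0).
#' @param source_labels integer ids allowed to expand.
#' @param target_labels integer ids that may be consumed.
#' @param connectivity 6, 18 or 26.
#' @param protect optional logical array of voxels that must not change.
#' @return the expanded [label_volume()].
#' @export
expand_labels <- function(volume, iterations, source_labels, target_labels,
                          connectivity = 6L, protect = NULL) {
  if (iterations == 0L) return(volume)
  prot <- if (is.null(protect)) logical(0) else as.logical(protect)
  arr <- cpp_expand_labels(as.integer(volume$array),
                           as.integer(dim(volume$array)),
                           as.integer(iterations),
                           as.integer(source_labels),
                           as.integer(target_labels),
                           as.integer(connectivity), prot)
  dim(arr) <- dim(volume$array)
  out <- volume
  out$array <- arr
  out
}

#' Volumetric mode filter
#'
#' Each non-frozen voxel is assigned the modal label over its neighborhood
#' (center included), with synchronized updates per iteration. If the current
#' label ties for the mode it is kept, otherwise the smallest tied id wins.
#'
#' @param volume a [label_volume()].
#' @param iterations number of sweeps (>= 1).
#' @param connectivity 6, 18 or 26 (default 26 for stable modes).
#' @param frozen_labels optional logical array of voxels to leave untouched
#'   (e.g. shell voxels that carry the surface annotation).
#' @param ignore_background when TRUE, background (0) voxels neither vote nor
#'   change: the filter smooths the segmentation strictly within its own
#'   support, so labels can neither leak outward nor be eroded to background.
#'   This is the mode the atlas pipeline uses.
#' @return the smoothed [label_volume()].
#' @export
mode_filter_volume <- function(volume, iterations, connectivity = 26L,
                               frozen_labels = NULL,
                               ignore_background = FALSE) {
  stopifnot(iterations >= 1L)
  froz <- if (is.null(frozen_labels)) logical(0) else as.logical(frozen_labels)
  arr <- cpp_mode_filter_volume(as.integer(volume$array),
                                as.integer(dim(volume$array)),
                                as.integer(iterations),
                                as.integer(connectivity), froz,
                                isTRUE(ignore_background))
  dim(arr) <- dim(volume$array)
  out <- volume
  out$array <- arr
  out
}

# 0-based voxel index of each vertex on the volume grid
vertex_voxel_ijk <- function(surface, volume) {
  round(world_to_voxel(volume$affine, surface$vertices))
}

vertex_voxel_key <- function(surface, volume) {
  d <- dim(volume$array)
  ijk <- vertex_voxel_ijk(surface, volume)
  if (any(ijk < 0) || any(sweep(ijk, 2, d - 1L) > 0))
    fk_stop("fk_domain_error", "vertices outside the volume grid")
  as.integer(ijk[, 1] + d[1] * (ijk[, 2] + d[2] * ijk[, 3]))
}

#' Surface-volume label consistency pass
#'
#' First re-labels every vertex-containing voxel with the mode of its
#' contained vertices' labels, then assigns each vertex the label of its
#' containing voxel. After the pass every vertex label equals its voxel's
#' label, and running the pass twice changes nothing.
#'
#' @param volume a [label_volume()] covering the surface.
#' @param surface a labeled [labeled_surface()].
#' @return list with the updated `volume` and `surface`.
#' @export
consistency_pass <- function(volume, surface) {
  key <- vertex_voxel_key(surface, volume)
  m <- mode_by_group(key, surface$labels)
  volume$array[m$key + 1L] <- m$mode
  surface$labels <- as.integer(volume$array[key + 1L])
  list(volume = volume, surface = surface)
}

#' Build a consistent volumetric atlas from a labeled surface
#'
#' Executes the full volumetric pipeline: voxelization with interior fill,
#' competitive expansion of the cortical labels into the interior, white
#' matter assignment of the remaining core, volumetric mode smoothing (with
#' vertex-containing shell voxels frozen to protect the surface annotation),
#' white-matter re-expansion into cortical labels (never into shell voxels),
#' re-assignment of shell voxels from the surface, a final one-iteration
#' expansion of all non-white-matter labels into white matter, label
#' pull-back to the vertices, surface mode smoothing, and a final
#' [consistency_pass()]. The returned surface and volume agree exactly: every
#' vertex label equals its containing voxel's label.
#'
#' @param surface a closed labeled [labeled_surface()].
#' @param config a [pipeline_config()].
#' @return list of class `atlas_volume_result` with elements `volume`
#'   (a [label_volume()] with attribute `wm_id`), `surface` (relabeled), and
#'   `inside` (logical array of the winding interior plus shell).
#' @export
run_atlas_volume_pipeline <- function(surface, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cortical_ids <- sort(unique(surface$labels))
  if (any(cortical_ids == 0L))
    fk_stop("fk_label_error", "surface labels must be nonzero")
  wm_id <- if (is.null(config$wm_id)) max(cortical_ids) + 2L
           else as.integer(config$wm_id)
  if (wm_id %in% cortical_ids)
    fk_stop("fk_label_error", "wm_id %d collides with a surface label", wm_id)

  vol <- voxelize_labeled_surface(surface, voxel_size = config$voxel_size,
                                  padding_voxels = config$padding_voxels,
                                  interior_id = max(cortical_ids, wm_id) + 1L)
  interior_id <- attr(vol, "interior_id")
  inside <- attr(vol, "inside")
  vkey <- vertex_voxel_key(surface, vol)
  shell_mask <- array(FALSE, dim(vol$array))
  shell_mask[vkey + 1L] <- TRUE

  # 1. cortical labels claim the interior
  vol <- expand_labels(vol, config$cortical_expand_iters,
                       source_labels = cortical_ids,
                       target_labels = interior_id,
                       connectivity = config$expand_connectivity)
  # 2. what remains of the core is white matter
  vol$array[vol$array == interior_id] <- wm_id
  # 3. volumetric mode smoothing, shell voxels frozen
  if (config$mode_smooth_iters > 0L)
    vol <- mode_filter_volume(vol, config$mode_smooth_iters,
                              connectivity = config$mode_connectivity,
                              frozen_labels = shell_mask,
                              ignore_background = TRUE)
  # 4. white matter pushes back into cortical labels (never into the shell)
  vol <- expand_labels(vol, config$wm_expand_iters,
                       source_labels = wm_id, target_labels = cortical_ids,
                       connectivity = config$expand_connectivity,
                       protect = shell_mask)
  # 5. shell voxels re-assigned from the surface annotation
  m <- mode_by_group(vkey, surface$labels)
  vol$array[m$key + 1L] <- m$mode
  # 6. non-white-matter labels take one step back into white matter
  vol <- expand_labels(vol, config$final_cortical_expand_iters,
                       source_labels = cortical_ids, target_labels = wm_id,
                       connectivity = config$expand_connectivity)
  # 7. vertices take their containing voxel's label, then surface smoothing
  out_surface <- surface
  out_surface$labels <- as.integer(vol$array[vkey + 1L])
  adjacency <- build_adjacency(out_surface)
  out_surface$labels <- mode_filter_surface(out_surface$labels, adjacency,
                                            config$surface_smooth_radius,
                                            config$surface_smooth_iters)
  # 8. final consistency pass
  cp <- consistency_pass(vol, out_surface)
  vol <- cp$volume
  out_surface <- cp$surface

  unlabeled <- sum(inside & vol$array == 0L)
  if (unlabeled > 0L)
    fk_stop("fk_pipeline_error",
            "%d background voxels remain inside the winding interior",
            unlabeled)
  attr(vol, "wm_id") <- wm_id
  structure(list(volume = vol, surface = out_surface, inside = inside),
            class = "atlas_volume_result")
}
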