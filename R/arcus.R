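#' Atlas-to-subject cortical sheet reconstruction
#'
#' Two-stage diffeomorphic reconstruction of a high-resolution atlas surface
#' in individual subject space. Stage 1 registers the volumetric atlas to the
#' subject's lobular segmentation (each label rendered as a blurred one-hot
#' channel, registered with a summed multi-channel metric) to fix the overall
#' lobule correspondence. The stage-1 transform is applied to a virtual MRI of
#' the atlas, and stage 2 registers that image to the masked subject MRI to
#' fine-tune the fit against local image contrast. Both resampling fields are
#' composed, numerically inverted into a forward point map, and applied to the
#' atlas surface vertices, yielding the atlas-derived cortical sheet in
#' subject space with faces and labels unchanged.
#'
#' @param atlas_label_volume atlas segmentation, a [label_volume()].
#' @param atlas_surface the atlas [labeled_surface()] (world mm coordinates in
#'   the atlas volume's space).
#' @param atlas_virtual_mri atlas intensity rendering from
#'   [make_virtual_mri()].
#' @param subject_segmentation subject lobular segmentation
#'   (a [label_volume()]); its labels must be a subset of the atlas labels.
#' @param subject_mri subject intensity image ([intensity_volume()]).
#' @param subject_mask binary cerebellum mask (array or [label_volume()]);
#'   the subject MRI is multiplied by it before stage 2.
#' @param config a [registration_config()] for both stages (stage 1 always
#'   uses the SSD drive on the one-hot channels).
#' @param onehot_blur_mm Gaussian blur applied to the one-hot label channels.
#' @return list of class `arcus_reconstruction`: `surface` (warped
#'   [labeled_surface()]), `stage1_field`, `stage2_field` (pull-back
#'   [displacement_field()]s on the subject grid) and `forward_field`
#'   (the inverted composition actually applied to the vertices).
#' @export
arcus_reconstruct <- function(atlas_label_volume, atlas_surface,
                              atlas_virtual_mri, subject_segmentation,
                              subject_mri, subject_mask,
                              config = registration_config(),
                              onehot_blur_mm = 1) {
  atlas_ids <- setdiff(sort(unique(as.vector(atlas_label_volume$array))), 0L)
  subj_ids <- setdiff(sort(unique(as.vector(subject_segmentation$array))), 0L)
  extra <- setdiff(subj_ids, atlas_ids)
  if (length(extra))
    fk_stop("fk_mapping_error",
            "subject labels absent from the atlas: %s",
            paste(extra, collapse = ", "))

  common <- intersect(atlas_ids, subj_ids)
  atlas_ch <- onehot_channels(atlas_label_volume, common, onehot_blur_mm)
  subj_ch <- onehot_channels(subject_segmentation, common, onehot_blur_mm)

  cfg1 <- config
  cfg1$metric <- "ssd"  # one-hot channels are already on a common scale
  stage1 <- register(fixed = subj_ch, moving = atlas_ch, config = cfg1)

  vmri_in_subj <- warp_volume(atlas_virtual_mri, stage1, "trilinear")

  mask_arr <- if (inherits(subject_mask, "foliakit_volume"))
    subject_mask$array else subject_mask
  masked <- subject_mri
  masked$array <- masked$array * (mask_arr != 0)
  stage2 <- register(fixed = masked, moving = vmri_in_subj, config = config)

  # both pull-backs composed (stage 2 first, then stage 1) map subject points
  # to atlas points; the inverse is the forward map for the vertices
  pullback <- compose_fields(stage2, stage1)
  forward <- invert_field(pullback)
  out_surface <- warp_surface(atlas_surface, forward)

  structure(list(surface = out_surface, stage1_field = stage1,
                 stage2_field = stage2, forward_field = forward),
            class = "arcus_reconstruction")
}

# blurred one-hot intensity channels for a set of label ids
onehot_channels <- function(volume, ids, blur_mm) {
  sig <- blur_mm / voxel_size(volume)
  lapply(ids, function(id) {
    arr <- (volume$array == id) * 1.0
    if (blur_mm > 0) arr <- cpp_gaussian_blur3d(arr, as.integer(dim(arr)), sig)
    intensity_volume(arr, volume$affine)
  })
}

#' @export
print.arcus_reconstruction <- function(x, ...) {
  cat("<arcus_reconstruction>\n  ")
  print(x$surface)
  invisible(x)
}
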