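#' DICE overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` between two voxel masks on the same grid.
#' Two empty masks agree on absence and score 1; empty versus non-empty
#' scores 0.
#'
#' @param mask_a,mask_b logical arrays of identical shape.
#' @return value in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    fk_stop("fk_grid_error", "mask shapes differ: %s vs %s",
            paste(dim(mask_a), collapse = "x"),
            paste(dim(mask_b), collapse = "x"))
  na <- sum(mask_a); nb <- sum(mask_b)
  if (na + nb == 0) return(1.0)
  2 * sum(mask_a & mask_b) / (na + nb)
}

#' Structural hierarchies for grouped evaluation
#'
#' A hierarchy names disjoint groups of fine label ids (e.g. coarse:
#' whole-cortex / white matter / vermis; lobe: anterior, superior posterior,
#' inferior posterior, flocculonodular per side; lobule: every division).
#' Group definitions are plain named lists so they can be shipped and edited
#' as text (see [read_hierarchy_json()]).
#'
#' @param name hierarchy name.
#' @param groups named list; each element an integer vector of fine label ids.
#' @return object of class `hierarchy`.
#' @export
hierarchy <- function(name, groups) {
  all_ids <- unlist(groups)
  if (anyDuplicated(all_ids))
    fk_stop("fk_label_error",
            "hierarchy '%s': groups must be disjoint (duplicated ids: %s)",
            name, paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  structure(list(name = name, groups = lapply(groups, as.integer)),
            class = "hierarchy")
}

#' @rdname hierarchy
#' @param path JSON file: object mapping group names to id arrays, plus a
#'   `"name"` string member.
#' @export
read_hierarchy_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  hierarchy(obj$name, obj$groups)
}

#' @rdname hierarchy
#' @param h a `hierarchy`.
#' @export
write_hierarchy_json <- function(h, path) {
  jsonlite::write_json(list(name = h$name, groups = h$groups), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Per-group DICE across a hierarchy
#'
#' For each group, the member fine labels are merged into one mask per
#' segmentation and the DICE coefficient of the merged masks is computed.
#' Groups whose member labels occur in neither volume are reported as missing
#' (`NA`), not as 0.
#'
#' @param seg_a,seg_b [label_volume()] objects on the same grid, sharing the
#'   fine label table.
#' @param hierarchy a [hierarchy()].
#' @return data.frame with columns `group`, `dice`, `missing`.
#' @export
dice_hierarchy <- function(seg_a, seg_b, hierarchy) {
  if (!identical(dim(seg_a$array), dim(seg_b$array)))
    fk_stop("fk_grid_error", "segmentation grids differ")
  res <- lapply(names(hierarchy$groups), function(g) {
    ids <- hierarchy$groups[[g]]
    ma <- array(seg_a$array %in% ids, dim(seg_a$array))
    mb <- array(seg_b$array %in% ids, dim(seg_b$array))
    if (!any(ma) && !any(mb))
      data.frame(group = g, dice = NA_real_, missing = TRUE)
    else data.frame(group = g, dice = dice(ma, mb), missing = FALSE)
  })
  do.call(rbind, res)
}

#' Two-stage score summaries
#'
#' Collapses a per-subject, per-group score table the way multi-subject
#' evaluations are usually reported: first the median across subjects within
#' each group, then the unweighted median and mean over those group medians.
#' Quantile-based spread statistics (IQR, range) use the median-unbiased
#' quantile definition (type 8).
#'
#' @param scores data.frame with columns `subject`, `group`, `value`
#'   (NA values are dropped).
#' @return list with `group_medians` (data.frame), `median_of_medians`,
#'   `mean_of_medians`, `min_group`, `max_group`, and `pooled`
#'   (median/mean/sd/IQR/range over all subject-group values).
#' @export
summarize_scores <- function(scores) {
  stopifnot(all(c("subject", "group", "value") %in% names(scores)))
  scores <- scores[!is.na(scores$value), , drop = FALSE]
  if (!nrow(scores))
    fk_stop("fk_label_error", "no scores to summarize")
  med <- stats::aggregate(value ~ group, data = scores, FUN = median)
  names(med)[2] <- "median"
  q <- function(x, p) as.numeric(quantile(x, p, type = 8, names = FALSE))
  pooled <- scores$value
  list(
    group_medians = med,
    median_of_medians = median(med$median),
    mean_of_medians = mean(med$median),
    min_group = med$group[which.min(med$median)],
    max_group = med$group[which.max(med$median)],
    pooled = c(median = median(pooled), mean = mean(pooled),
               sd = if (length(pooled) > 1) sd(pooled) else 0,
               iqr_low = q(pooled, 0.25), iqr_high = q(pooled, 0.75),
               min = min(pooled), max = max(pooled))
  )
}

#' Hausdorff distance between a surface and a labeled volume
#'
#' Voxelizes the surface vertices of a label group onto the volume's grid
#' (set A = centers of voxels containing group-labeled vertices), takes the
#' group's voxel centers in the label volume (set B), and returns the classic
#' symmetric Hausdorff distance `max(max_a min_b d, max_b min_a d)` in mm.
#' Because one side is a filled volume and the other a voxelized sheet, the
#' value reflects a surface-volume discrepancy, not a boundary-to-boundary
#' distance.
#'
#' @param surface a labeled [labeled_surface()].
#' @param label_volume a [label_volume()] whose grid covers the surface.
#' @param group_labels integer ids defining the structure.
#' @return distance in mm.
#' @export
hausdorff_surface_volume <- function(surface, label_volume, group_labels) {
  key <- vertex_voxel_key(surface, label_volume)
  akeys <- unique(key[surface$labels %in% group_labels])
  d <- dim(label_volume$array)
  bidx <- which(label_volume$array %in% group_labels) - 1L
  if (!length(akeys) || !length(bidx))
    fk_stop("fk_undefined_distance_error",
            "group {%s} empty on the %s side",
            paste(group_labels, collapse = ","),
            if (!length(akeys)) "surface" else "volume")
  key_to_world <- function(k) {
    ijk <- cbind(k %% d[1], (k %/% d[1]) %% d[2], k %/% (d[1] * d[2]))
    voxel_to_world(label_volume$affine, ijk)
  }
  cpp_hausdorff(key_to_world(akeys), key_to_world(bidx))
}
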