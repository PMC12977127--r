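#' Apportion patch counts across regions
#'
#' Splits a total patch budget across anatomical regions proportionally to
#' their area fractions (default budget 800, sized so patch areas land near
#' those of a fine cortical parcellation), using largest-remainder
#' rounding. Every region with nonzero area receives at least one patch and
#' the counts sum exactly to `total_patches`.
#'
#' @param area_fractions named numeric vector of region area fractions
#'   (names = region ids) or the data.frame from [region_area_fractions()]
#'   (excluded rows with `NA` fractions are dropped).
#' @param total_patches total number of patches (>= number of regions).
#' @return named integer vector of per-region patch counts.
#' @export
patches_per_region <- function(area_fractions, total_patches = 800L) {
  if (is.data.frame(area_fractions)) {
    keep <- !is.na(area_fractions$fraction)
    fr <- setNames(area_fractions$fraction[keep],
                   area_fractions$label_id[keep])
  } else fr <- area_fractions
  if (any(fr <= 0))
    fk_stop("fk_apportionment_error",
            "region(s) with zero area: %s",
            paste(names(fr)[fr <= 0], collapse = ", "))
  if (abs(sum(fr) - 1) > 1e-6)
    fk_stop("fk_apportionment_error", "fractions must sum to 1 (got %.6f)",
            sum(fr))
  if (total_patches < length(fr))
    fk_stop("fk_apportionment_error",
            "total_patches %d < number of regions %d", total_patches,
            length(fr))
  q <- total_patches * fr
  counts <- floor(q)
  rem <- total_patches - sum(counts)
  if (rem > 0) {
    give <- order(q - counts, decreasing = TRUE)[seq_len(rem)]
    counts[give] <- counts[give] + 1
  }
  # every region gets at least one patch
  while (any(counts == 0)) {
    z <- which(counts == 0)[1]
    donor <- which.max(counts)
    counts[donor] <- counts[donor] - 1
    counts[z] <- counts[z] + 1
  }
  setNames(as.integer(counts), names(fr))
}

# chord distance on the unit sphere between one point and a matrix of points
chord_dist <- function(p, m) {
  sqrt(pmax(0, rowSums(sweep(m, 2, p)^2)))
}

#' Spread patch seeds over the surface
#'
#' Seeds ("pointers") are drawn uniformly without replacement within each
#' region, then repelled from one another for `iterations` sweeps: each
#' pointer in turn moves to the same-region neighboring vertex that maximizes
#' its minimum distance to the other pointers of that region (staying put when
#' no neighbor strictly improves it). Distance is the Euclidean chord length
#' in the spherical surface representation, a monotone proxy for geodesic
#' distance. Updates are sequential in ascending patch id.
#'
#' @param surface a [labeled_surface()] with spherical coordinates.
#' @param region_labels length-N integer region ids (defaults to
#'   `surface$labels`).
#' @param counts named integer vector from [patches_per_region()].
#' @param iterations repulsion sweeps (the atlas recipe uses 100).
#' @param rng_seed integer seed for the initial draw.
#' @param track_min_distance record the per-region minimum pairwise seed
#'   distance after every sweep (attribute `min_distance_per_sweep`, an
#'   iterations x regions matrix) — the quantity whose monotone growth shows
#'   the repulsion is working.
#' @return data.frame with columns `patch_id`, `region`, `vertex` (1-based),
#'   ordered by `patch_id`.
#' @export
spread_seeds <- function(surface, region_labels = surface$labels, counts,
                         iterations = 100L, rng_seed = 1L,
                         track_min_distance = FALSE) {
  if (is.null(surface$spherical))
    fk_stop("fk_geometry_error", "spherical coordinates required for seeding")
  sph <- surface$spherical
  adjacency <- build_adjacency(surface)
  regions <- as.integer(names(counts))
  seeds <- vector("list", length(regions))
  set.seed(rng_seed)
  for (r in seq_along(regions)) {
    verts <- which(region_labels == regions[r])
    if (counts[r] > length(verts))
      fk_stop("fk_seeding_error",
              "region %d has %d vertices but needs %d seeds", regions[r],
              length(verts), counts[r])
    seeds[[r]] <- sample(verts, counts[r])
  }
  seed_vertex <- unlist(seeds)
  seed_region <- rep(regions, times = vapply(seeds, length, 1L))
  n_seeds <- length(seed_vertex)
  region_members <- split(seq_len(n_seeds), seed_region)
  track <- if (track_min_distance)
    matrix(NA_real_, iterations, length(region_members),
           dimnames = list(NULL, names(region_members))) else NULL
  for (it in seq_len(iterations)) {
    for (i in seq_len(n_seeds)) {
      others <- setdiff(region_members[[as.character(seed_region[i])]], i)
      if (!length(others)) next
      othpos <- sph[seed_vertex[others], , drop = FALSE]
      cur <- seed_vertex[i]
      best_score <- min(chord_dist(sph[cur, ], othpos))
      cand <- adj_neighbors(adjacency, cur)
      cand <- cand[region_labels[cand] == seed_region[i]]
      for (v in cand) {
        s <- min(chord_dist(sph[v, ], othpos))
        if (s > best_score) { best_score <- s; cur <- v }
      }
      seed_vertex[i] <- cur
    }
    if (track_min_distance) {
      for (r in names(region_members)) {
        m <- region_members[[r]]
        track[it, r] <- if (length(m) > 1)
          min(dist(sph[seed_vertex[m], , drop = FALSE])) else NA_real_
      }
    }
  }
  out <- data.frame(patch_id = seq_len(n_seeds), region = seed_region,
                    vertex = seed_vertex)
  if (track_min_distance) attr(out, "min_distance_per_sweep") <- track
  out
}

#' Grow patches from seeds
#'
#' Multi-source breadth-first growth confined to anatomical regions: a single
#' FIFO frontier is seeded in ascending patch id, and every vertex joins the
#' first patch whose frontier reaches it. Vertices in region components that
#' contain no seed are assigned to the nearest same-region patch by spherical
#' chord distance, with a warning.
#'
#' @param surface a [labeled_surface()].
#' @param region_labels length-N integer region ids.
#' @param seeds data.frame from [spread_seeds()].
#' @return length-N integer vector of patch ids (>= 1).
#' @export
grow_patches <- function(surface, region_labels = surface$labels, seeds) {
  adjacency <- build_adjacency(surface)
  o <- order(seeds$patch_id)
  if (any(region_labels[seeds$vertex] != seeds$region))
    fk_stop("fk_seeding_error", "seed vertex outside its region")
  patch <- cpp_grow_patches(adjacency$offsets, adjacency$neighbors,
                            as.integer(region_labels),
                            as.integer(seeds$vertex[o]) - 1L,
                            as.integer(seeds$patch_id[o]))
  un <- which(patch == 0L)
  if (length(un)) {
    fk_warn("fk_seeding_warning",
            "%d vertices unreachable from any seed; assigning by %s",
            length(un), "spherical distance")
    sph <- surface$spherical
    if (is.null(sph)) sph <- surface$vertices  # fall back to world coords
    for (v in un) {
      same <- which(patch != 0L & region_labels == region_labels[v])
      if (!length(same))
        fk_stop("fk_seeding_error", "region %d has no seeded patch",
                region_labels[v])
      patch[v] <- patch[same[which.min(chord_dist(sph[v, ],
                                                  sph[same, , drop = FALSE]))]]
    }
  }
  patch
}

# reassign fragments so every patch is a single connected component; the
# largest component keeps the id, fragments join the adjacent same-region
# patch with the longest shared border
reconnect_patches <- function(adjacency, edges, patch, region, areas_v) {
  for (pass in 1:20) {
    comp <- cpp_mesh_components(adjacency$offsets, adjacency$neighbors,
                                as.integer(patch))
    tab <- table(patch, comp)
    frag_comps <- integer(0)
    for (p in rownames(tab)) {
      comps <- which(tab[p, ] > 0)
      if (length(comps) <= 1L) next
      sizes <- vapply(comps, function(cc)
        sum(areas_v[comp == cc & patch == as.integer(p)]), 0)
      frag_comps <- c(frag_comps, comps[-which.max(sizes)])
    }
    if (!length(frag_comps)) return(patch)
    for (cc in frag_comps) {
      verts <- which(comp == cc)
      infrag <- logical(length(patch)); infrag[verts] <- TRUE
      e_out <- edges[xor(infrag[edges[, 1]], infrag[edges[, 2]]), ,
                     drop = FALSE]
      other <- ifelse(infrag[e_out[, 1]], e_out[, 2], e_out[, 1])
      ok <- region[other] == region[verts[1]] & patch[other] != patch[verts[1]]
      if (!any(ok)) next  # isolated fragment: keep id (it is its own patch)
      target <- as.integer(names(which.max(table(patch[other][ok]))))
      patch[verts] <- target
    }
  }
  patch
}

patch_areas <- function(patch, areas_v) {
  a <- rowsum(areas_v, group = patch)
  setNames(a[, 1], rownames(a))
}

# split one patch in two: seeds at the mutually farthest vertex pair by
# spherical chord distance, then two-source BFS confined to the patch
split_patch <- function(adjacency, patch, sph, p, new_id) {
  verts <- which(patch == p)
  if (length(verts) < 2L) {
    fk_warn("fk_balance_warning", "patch %d has < 2 vertices; split skipped",
            p)
    return(patch)
  }
  m <- sph[verts, , drop = FALSE]
  # farthest pair = minimum dot product on the unit sphere
  dp <- m %*% t(m)
  idx <- arrayInd(which.min(dp), dim(dp))
  s1 <- verts[idx[1]]; s2 <- verts[idx[2]]
  sub <- cpp_grow_patches(adjacency$offsets, adjacency$neighbors,
                          as.integer(patch),  # confine growth to this patch
                          c(s1, s2) - 1L, c(1L, 2L))
  patch[verts[sub[verts] == 2L]] <- new_id
  # any unreached members of a disconnected patch stay with the first half
  patch
}

#' Balance patch areas by splitting and merging
#'
#' Iteratively splits every patch larger than twice the current mean patch
#' area (two new seeds at the patch's mutually farthest vertex pair, then
#' two-way breadth-first growth inside the patch) and merges every patch
#' smaller than half the mean into the same-region neighbor sharing the most
#' boundary edges. Each patch undergoes at most `max_ops` operations; because
#' that cap can leave stragglers, a final forced pass splits all remaining
#' oversized patches once and then merges all remaining undersized ones. The
#' mean is recomputed after every operation batch.
#'
#' @param surface a [labeled_surface()] with spherical coordinates.
#' @param parcellation a `parcellation` object or an integer patch-id vector.
#' @param region_labels length-N region ids (defaults to `surface$labels`).
#' @param max_ops per-patch operation cap (the atlas recipe uses 5).
#' @param forced_final_pass run the concluding forced split+merge pass.
#' @return a `parcellation` object (see [parcellate()]).
#' @export
balance_patches <- function(surface, parcellation,
                            region_labels = surface$labels, max_ops = 5L,
                            forced_final_pass = TRUE) {
  patch <- if (inherits(parcellation, "parcellation"))
    parcellation$patch_ids else as.integer(parcellation)
  adjacency <- build_adjacency(surface)
  edges <- unique_edges(surface$faces)
  areas_v <- vertex_areas(surface)
  sph <- surface$spherical
  if (is.null(sph))
    fk_stop("fk_geometry_error", "spherical coordinates required")
  ops <- new.env(parent = emptyenv())
  op_count <- function(p) {
    v <- ops[[as.character(p)]]
    if (is.null(v)) 0L else v
  }
  bump <- function(p, v) assign(as.character(p), v, envir = ops)
  next_id <- max(patch) + 1L

  do_split <- function(p) {
    patch2 <- split_patch(adjacency, patch, sph, p, next_id)
    if (!identical(patch2, patch)) {
      bump(next_id, op_count(p) + 1L)
      bump(p, op_count(p) + 1L)
      next_id <<- next_id + 1L
    }
    patch <<- patch2
  }
  do_merge <- function(p) {
    verts <- which(patch == p)
    inp <- logical(length(patch)); inp[verts] <- TRUE
    e_out <- edges[xor(inp[edges[, 1]], inp[edges[, 2]]), , drop = FALSE]
    other <- ifelse(inp[e_out[, 1]], e_out[, 2], e_out[, 1])
    ok <- region_labels[other] == region_labels[verts[1]]
    if (!any(ok)) return(invisible(NULL))  # no same-region neighbor
    target <- as.integer(names(which.max(table(patch[other][ok]))))
    patch[verts] <<- target
    bump(target, max(op_count(target), op_count(p)) + 1L)
  }

  repeat {
    pa <- patch_areas(patch, areas_v)
    mean_a <- mean(pa)
    big <- as.integer(names(pa)[pa > 2 * mean_a])
    big <- big[vapply(big, op_count, 0L) < max_ops]
    small <- as.integer(names(pa)[pa < 0.5 * mean_a])
    small <- small[vapply(small, op_count, 0L) < max_ops]
    if (!length(big) && !length(small)) break
    for (p in big) do_split(p)
    pa <- patch_areas(patch, areas_v)
    mean_a <- mean(pa)
    small <- as.integer(names(pa)[pa < 0.5 * mean_a])
    small <- small[vapply(small, op_count, 0L) < max_ops]
    for (p in small) if (p %in% patch) do_merge(p)
  }

  if (forced_final_pass) {
    pa <- patch_areas(patch, areas_v)
    mean_a <- mean(pa)
    for (p in as.integer(names(pa)[pa > 2 * mean_a])) do_split(p)
    pa <- patch_areas(patch, areas_v)
    mean_a <- mean(pa)
    for (p in as.integer(names(pa)[pa < 0.5 * mean_a]))
      if (p %in% patch) do_merge(p)
  }

  new_parcellation(surface, patch, region_labels, areas_v)
}

new_parcellation <- function(surface, patch, region_labels, areas_v = NULL) {
  if (is.null(areas_v)) areas_v <- vertex_areas(surface)
  # contiguous ids 1..K in order of first appearance by region then id
  ids <- sort(unique(patch))
  patch <- match(patch, ids)
  pa <- patch_areas(patch, areas_v)
  p2r <- setNames(region_labels[match(seq_along(ids),
                                      patch)], seq_along(ids))
  stats <- list(
    n_patches = length(ids),
    areas_mm2 = as.numeric(pa),
    mean_area_mm2 = mean(pa),
    cv = stats::sd(pa) / mean(pa),
    range_ratio = max(pa) / min(pa)
  )
  structure(list(patch_ids = as.integer(patch),
                 patch_to_region = p2r, stats = stats),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf(
    "<parcellation> %d patches over %d regions; area CV %.1f%%, range ratio %.2f\n",
    x$stats$n_patches, length(unique(x$patch_to_region)),
    100 * x$stats$cv, x$stats$range_ratio))
  invisible(x)
}

#' Equal-area patch parcellation of a labeled surface
#'
#' End-to-end stochastic parcellation: apportion the patch budget across
#' regions by area ([patches_per_region()]), draw and repel seeds
#' ([spread_seeds()]), grow patches by multi-source BFS ([grow_patches()]),
#' round patch shapes with a region-confined surface mode filter (radius 3,
#' 3 iterations), reconnect any patch fragmented by the smoothing, and balance
#' areas by split/merge ([balance_patches()]).
#'
#' @param surface a labeled [labeled_surface()] with spherical coordinates.
#' @param region_labels length-N region ids (defaults to `surface$labels`).
#' @param total_patches initial patch budget (the atlas recipe uses 800).
#' @param rng_seed integer seed controlling all stochastic choices.
#' @param spread_iterations seed-repulsion sweeps (default 100).
#' @param max_ops per-patch split/merge cap (default 5).
#' @param exclude_labels region ids excluded from parcellation budgeting
#'   (e.g. a white-matter-tract patch); they receive one patch each.
#' @return an object of class `parcellation`: `patch_ids` (length-N,
#'   contiguous ids from 1), `patch_to_region`, and `stats` (patch areas,
#'   coefficient of variation, max/min range ratio). The RNG seed is recorded
#'   in attribute `rng_seed`.
#' @export
parcellate <- function(surface, region_labels = surface$labels,
                       total_patches = 800L, rng_seed = 1L,
                       spread_iterations = 100L, max_ops = 5L,
                       exclude_labels = integer(0)) {
  fr <- region_area_fractions(surface, exclude_labels = exclude_labels)
  counts <- patches_per_region(fr, total_patches)
  for (ex in intersect(exclude_labels, region_labels))
    counts[as.character(ex)] <- 1L
  seeds <- spread_seeds(surface, region_labels, counts,
                        iterations = spread_iterations, rng_seed = rng_seed)
  patch <- grow_patches(surface, region_labels, seeds)
  adjacency <- build_adjacency(surface)
  patch <- mode_filter_surface(patch, adjacency, radius_edges = 3L,
                               iterations = 3L, region_mask = region_labels)
  edges <- unique_edges(surface$faces)
  areas_v <- vertex_areas(surface)
  patch <- reconnect_patches(adjacency, edges, patch, region_labels, areas_v)
  out <- balance_patches(surface, patch, region_labels, max_ops = max_ops)
  attr(out, "rng_seed") <- rng_seed
  out
}
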