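#' Labeled triangular surface meshes
#'
#' The central surface container: world-mm vertex coordinates, triangular
#' faces (1-based vertex index triples), optional per-vertex integer labels
#' and optional unit-sphere coordinates aligned to the vertex order (used as
#' the geodesic-distance proxy during parcellation).
#'
#' @param vertices N x 3 numeric matrix, world coordinates in mm.
#' @param faces M x 3 integer matrix of 1-based vertex indices.
#' @param labels optional length-N integer label vector.
#' @param spherical optional N x 3 matrix of unit-sphere coordinates.
#' @param label_table optional [label_table()] describing the label ids.
#' @return An object of class `labeled_surface`.
#' @examples
#' s <- labeled_surface(
#'   vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'   faces = rbind(c(1, 2, 3), c(1, 4, 2), c(2, 4, 3), c(1, 3, 4))
#' )
#' mean_edge_length(s)
#' @export
labeled_surface <- function(vertices, faces, labels = NULL, spherical = NULL,
                            label_table = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    fk_stop("fk_geometry_error", "vertices and faces must have 3 columns")
  n <- nrow(vertices)
  if (nrow(faces) > 0L && (min(faces) < 1L || max(faces) > n))
    fk_stop("fk_geometry_error", "face indices outside [1, %d]", n)
  degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  if (any(degen))
    fk_stop("fk_geometry_error", "%d degenerate faces (repeated indices)",
            sum(degen))
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n)
      fk_stop("fk_geometry_error", "labels length %d != vertex count %d",
              length(labels), n)
  }
  if (!is.null(spherical)) {
    spherical <- as.matrix(spherical)
    storage.mode(spherical) <- "double"
    if (nrow(spherical) != n || ncol(spherical) != 3L)
      fk_stop("fk_geometry_error", "spherical must be N x 3")
    norms <- sqrt(rowSums(spherical^2))
    if (any(abs(norms - 1) > 1e-6))
      fk_stop("fk_geometry_error",
              "spherical coordinates not unit-norm (max dev %.2e)",
              max(abs(norms - 1)))
  }
  structure(list(vertices = vertices, faces = faces, labels = labels,
                 spherical = spherical, label_table = label_table),
            class = "labeled_surface")
}

#' @export
print.labeled_surface <- function(x, ...) {
  cat(sprintf("<labeled_surface> %d vertices, %d faces%s%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (!is.null(x$labels))
                sprintf(", %d labels", length(unique(x$labels))) else "",
              if (!is.null(x$spherical)) ", spherical coords" else ""))
  invisible(x)
}

#' Vertex adjacency graph of a triangular mesh
#'
#' Builds per-vertex sorted neighbor lists from the union of face edges,
#' stored in compressed sparse row form for the C++ graph kernels.
#'
#' @param surface a [labeled_surface()].
#' @return An object of class `mesh_adjacency` with fields `offsets`
#'   (length N+1, 0-based positions into `neighbors`), `neighbors`
#'   (0-based vertex indices) and `n`.
#' @export
build_adjacency <- function(surface) {
  n <- nrow(surface$vertices)
  e <- unique_edges(surface$faces)
  # both directions, then CSR
  from <- c(e[, 1], e[, 2])
  to <- c(e[, 2], e[, 1])
  o <- order(from, to)
  from <- from[o]; to <- to[o]
  counts <- tabulate(from, nbins = n)
  structure(list(offsets = c(0L, cumsum(counts)),
                 neighbors = to - 1L, n = n),
            class = "mesh_adjacency")
}

#' @export
print.mesh_adjacency <- function(x, ...) {
  cat(sprintf("<mesh_adjacency> %d vertices, %d edges\n", x$n,
              length(x$neighbors) / 2))
  invisible(x)
}

# neighbors of 1-based vertex v, 1-based
adj_neighbors <- function(adjacency, v) {
  adjacency$neighbors[(adjacency$offsets[v] + 1L):adjacency$offsets[v + 1L]] + 1L
}

# deduplicated undirected edge list (1-based, col1 < col2)
unique_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(e), , drop = FALSE]
}

#' Mean edge length of a mesh
#'
#' Arithmetic mean over the deduplicated undirected edge set, in mm. This is
#' the "mean inter-vertex spacing" usually quoted for surface reconstructions.
#'
#' @param surface a [labeled_surface()].
#' @return scalar, mm.
#' @export
mean_edge_length <- function(surface) {
  e <- unique_edges(surface$faces)
  if (nrow(e) == 0L)
    fk_stop("fk_geometry_error", "mesh has no edges")
  d <- surface$vertices[e[, 1], , drop = FALSE] -
    surface$vertices[e[, 2], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

# per-face areas via the cross product
face_areas <- function(surface) {
  a <- surface$vertices[surface$faces[, 1], , drop = FALSE]
  b <- surface$vertices[surface$faces[, 2], , drop = FALSE]
  c <- surface$vertices[surface$faces[, 3], , drop = FALSE]
  u <- b - a
  v <- c - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' Per-vertex surface areas
#'
#' Each face contributes one third of its area to each of its three corner
#' vertices.
#'
#' @param surface a [labeled_surface()].
#' @return length-N numeric vector, mm^2.
#' @export
vertex_areas <- function(surface) {
  fa <- face_areas(surface)
  va <- numeric(nrow(surface$vertices))
  for (c in 1:3) {
    acc <- rowsum(fa / 3, group = surface$faces[, c])
    va[as.integer(rownames(acc))] <- va[as.integer(rownames(acc))] + acc[, 1]
  }
  va
}

#' Surface-area fractions per labeled region
#'
#' Splits every face area equally among its three corner vertices and sums
#' vertex areas per label. Fractions are taken over the cortical total, i.e.
#' excluding the ids in `exclude_labels` (typically the white-matter-tract
#' patch covering the peduncle cuts, which is not cortex).
#'
#' @param surface a labeled [labeled_surface()].
#' @param exclude_labels integer ids excluded from the fraction denominator;
#'   their rows are kept with `fraction = NA`.
#' @return data.frame with columns `label_id`, `area_mm2`, `fraction`.
#'   Fractions over included labels sum to 1.
#' @export
region_area_fractions <- function(surface, exclude_labels = integer(0)) {
  if (is.null(surface$labels))
    fk_stop("fk_label_error", "surface has no labels")
  va <- vertex_areas(surface)
  area <- rowsum(va, group = surface$labels)
  out <- data.frame(label_id = as.integer(rownames(area)),
                    area_mm2 = area[, 1], row.names = NULL)
  incl <- !(out$label_id %in% exclude_labels)
  denom <- sum(out$area_mm2[incl])
  if (denom <= 0)
    fk_stop("fk_label_error",
            "no cortical area left after excluding labels %s",
            paste(exclude_labels, collapse = ", "))
  out$fraction <- ifelse(incl, out$area_mm2 / denom, NA_real_)
  out
}

#' Mode filtering of vertex labels
#'
#' Replaces each vertex label by the modal label within its BFS ball of
#' `radius_edges` graph edges (the center vertex is included in the count),
#' repeated `iterations` times with synchronized updates. If the current label
#' ties for the mode it is kept; otherwise the smallest tied id wins. With a
#' `region_mask`, the ball never crosses region boundaries, so labels cannot
#' leak between anatomical regions.
#'
#' @param labels length-N integer vector.
#' @param adjacency a [build_adjacency()] result.
#' @param radius_edges BFS ball radius (>= 1); the atlas pipeline uses 3.
#' @param iterations number of sequential passes; the atlas pipeline uses 3.
#' @param region_mask optional length-N integer vector of region ids that
#'   confine the filter.
#' @return filtered integer label vector.
#' @export
mode_filter_surface <- function(labels, adjacency, radius_edges = 3L,
                                iterations = 3L, region_mask = NULL) {
  stopifnot(radius_edges >= 1L, iterations >= 0L)
  if (iterations == 0L) return(as.integer(labels))
  region <- if (is.null(region_mask)) integer(0) else as.integer(region_mask)
  cpp_mode_filter_surface(as.integer(labels), adjacency$offsets,
                          adjacency$neighbors, as.integer(radius_edges),
                          as.integer(iterations), region)
}
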