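#' Summary statistics of a labeled surface atlas
#'
#' Recomputes the headline descriptive numbers of a surface atlas directly
#' from its files or objects: vertex and face counts, mean inter-vertex
#' spacing (mean unique-edge length, mm) and per-region surface-area
#' fractions of the cortical total.
#'
#' @param surface a labeled [labeled_surface()], or a path to a surface file
#'   readable by [read_surface()].
#' @param labels optional path to a label file ([read_vertex_labels()]) when
#'   `surface` is a path or carries no labels.
#' @param exclude_labels ids excluded from the cortical denominator
#'   (e.g. the white-matter-tract patch).
#' @return list with `n_vertices`, `n_faces`, `mean_edge_length_mm` and
#'   `area_fractions` (data.frame from [region_area_fractions()]).
#' @export
atlas_summaries <- function(surface, labels = NULL,
                            exclude_labels = integer(0)) {
  if (is.character(surface)) surface <- read_surface(surface)
  if (!is.null(labels)) {
    if (is.character(labels)) labels <- read_vertex_labels(labels)$labels
    surface$labels <- as.integer(labels)
  }
  list(n_vertices = nrow(surface$vertices),
       n_faces = nrow(surface$faces),
       mean_edge_length_mm = mean_edge_length(surface),
       area_fractions = if (!is.null(surface$labels))
         region_area_fractions(surface, exclude_labels) else NULL)
}
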