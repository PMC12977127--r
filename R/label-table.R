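#' Label tables
#'
#' A label table maps integer label ids to names and RGB colors (the color is
#' what FreeSurfer `.annot` files store on disk). Id 0 is always present and
#' reserved for background/unlabeled. Two further conventional roles can be
#' designated: the white matter / corpus medullare id and the
#' white-matter-tract id covering the peduncle-cut patch that closes the
#' surface.
#'
#' @param ids non-negative integer label ids (0 added automatically if
#'   missing).
#' @param names character names, unique, same length as `ids`.
#' @param colors optional n x 3 integer matrix of RGB values in 0..255. When
#'   omitted, deterministic distinct colors are derived from the ids.
#' @param wm_id optional id playing the white matter / corpus medullare role.
#' @param tract_id optional id of the white-matter-tract patch.
#' @return data.frame of class `label_table` with columns `id`, `name`, `R`,
#'   `G`, `B` and attributes `wm_id`, `tract_id`.
#' @examples
#' lt <- label_table(1:3, c("lobule_a", "lobule_b", "cm"), wm_id = 3)
#' @export
label_table <- function(ids, names, colors = NULL, wm_id = NULL,
                        tract_id = NULL) {
  ids <- as.integer(ids)
  names <- as.character(names)
  if (length(ids) != length(names))
    fk_stop("fk_label_error", "ids and names differ in length")
  if (!0L %in% ids) {
    ids <- c(0L, ids)
    names <- c("background", names)
    if (!is.null(colors)) colors <- rbind(c(0L, 0L, 0L), colors)
  }
  if (anyDuplicated(ids))
    fk_stop("fk_label_error", "label ids must be unique")
  if (anyDuplicated(names))
    fk_stop("fk_label_error", "label names must be unique")
  if (any(ids < 0L))
    fk_stop("fk_label_error", "label ids must be non-negative")
  if (is.null(colors)) colors <- default_label_colors(ids)
  colors <- matrix(as.integer(colors), ncol = 3L)
  if (nrow(colors) != length(ids))
    fk_stop("fk_label_error", "colors must have one row per id")
  if (anyDuplicated(colors))
    fk_stop("fk_label_error", "label colors must be unique (annot codes)")
  out <- data.frame(id = ids, name = names, R = colors[, 1], G = colors[, 2],
                    B = colors[, 3])
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("label_table", "data.frame"),
            wm_id = if (is.null(wm_id)) NA_integer_ else as.integer(wm_id),
            tract_id = if (is.null(tract_id)) NA_integer_
                       else as.integer(tract_id))
}

# deterministic, collision-free RGB triples from ids (id 0 stays black)
default_label_colors <- function(ids) {
  h <- (ids * 2654435761) %% 2^24  # Knuth multiplicative hash, 24-bit
  col <- cbind(h %% 256, (h %/% 256) %% 256, (h %/% 65536) %% 256)
  col[ids == 0L, ] <- 0L
  # resolve accidental collisions by probing
  code <- col[, 1] + col[, 2] * 256 + col[, 3] * 65536
  while (anyDuplicated(code)) {
    i <- which(duplicated(code))[1]
    code[i] <- (code[i] + 7919) %% 2^24
    col[i, ] <- c(code[i] %% 256, (code[i] %/% 256) %% 256,
                  (code[i] %/% 65536) %% 256)
  }
  storage.mode(col) <- "integer"
  col
}

annot_code <- function(table) {
  table$R + table$G * 256L + table$B * 65536L
}

#' Read and write FreeSurfer-style color lookup tables
#'
#' Plain-text LUT with columns `id name R G B A` (A is ignored on read and
#' written as 0).
#'
#' @param path file path.
#' @param table a [label_table()].
#' @return [read_color_lut()] returns a `label_table`.
#' @export
read_color_lut <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[ \t]+")
  bad <- which(vapply(parts, length, 1L) < 6L)
  if (length(bad))
    fk_stop("fk_format_error", "LUT line %d has fewer than 6 fields", bad[1])
  m <- do.call(rbind, parts)
  label_table(ids = as.integer(m[, 1]), names = m[, 2],
              colors = cbind(as.integer(m[, 3]), as.integer(m[, 4]),
                             as.integer(m[, 5])))
}

#' @rdname read_color_lut
#' @export
write_color_lut <- function(table, path) {
  writeLines(sprintf("%-4d %-30s %3d %3d %3d %3d", table$id, table$name,
                     table$R, table$G, table$B, 0L), path)
  invisible(path)
}
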