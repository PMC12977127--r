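#' Read and write per-vertex labels
#'
#' Supported formats: FreeSurfer `.annot` (binary, big-endian, version-2
#' color table; labels are stored as packed 24-bit RGB codes and mapped back
#' to stable integer ids through the color table), GIFTI label files
#' (`.label.gii`/`.gii` with an `NIFTI_INTENT_LABEL` array), and plain CSV
#' with columns `vertex_id` (1-based) and `label_id`.
#'
#' @param path file path.
#' @param format `"auto"` (extension-based), `"annot"`, `"gifti"` or `"csv"`.
#' @param labels length-N integer vector of label ids.
#' @param table a [label_table()] covering all ids in `labels`.
#' @return [read_vertex_labels()] returns a list with elements `labels`
#'   (integer vector in vertex order) and `table` (a [label_table()], or
#'   `NULL` for bare CSV).
#' @export
read_vertex_labels <- function(path, format = c("auto", "annot", "gifti",
                                                "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    low <- tolower(path)
    format <- if (grepl("\\.annot$", low)) "annot"
    else if (grepl("\\.gii$", low)) "gifti"
    else "csv"
  }
  switch(format,
         annot = read_annot(path),
         gifti = read_labels_gifti(path),
         csv = read_labels_csv(path))
}

#' @rdname read_vertex_labels
#' @export
write_vertex_labels <- function(labels, path, table = NULL,
                                format = c("auto", "annot", "gifti", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    low <- tolower(path)
    format <- if (grepl("\\.annot$", low)) "annot"
    else if (grepl("\\.gii$", low)) "gifti"
    else "csv"
  }
  if (format %in% c("annot", "gifti") && is.null(table))
    table <- label_table(setdiff(sort(unique(as.integer(labels))), 0L),
                         paste0("label_",
                                setdiff(sort(unique(as.integer(labels))), 0L)))
  switch(format,
         annot = write_annot(labels, path, table),
         gifti = write_labels_gifti(labels, path, table),
         csv = write_labels_csv(labels, path))
  invisible(path)
}

## ---- CSV -------------------------------------------------------------------

read_labels_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("vertex_id", "label_id") %in% names(df)))
    fk_stop("fk_format_error",
            "%s: CSV must have columns vertex_id,label_id", path)
  labels <- integer(max(df$vertex_id))
  labels[df$vertex_id] <- as.integer(df$label_id)
  list(labels = labels, table = NULL)
}

write_labels_csv <- function(labels, path) {
  write.csv(data.frame(vertex_id = seq_along(labels),
                       label_id = as.integer(labels)),
            path, row.names = FALSE)
}

## ---- FreeSurfer .annot -----------------------------------------------------
## Layout: int32 n; n x (vertex index, packed RGB code) int32 pairs;
## int32 tag (1 = color table present); version-2 color table. Big-endian.

read_annot <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rint <- function(n = 1L) readBin(con, "integer", n = n, size = 4L,
                                   endian = "big")
  n <- rint()
  if (is.na(n) || n <= 0L)
    fk_stop("fk_format_error", "%s: bad vertex count at byte 0", path)
  dat <- rint(2L * n)
  vtx <- dat[seq(1L, 2L * n, by = 2L)]
  code <- dat[seq(2L, 2L * n, by = 2L)]
  tag <- rint()
  if (!identical(tag, 1L))
    fk_stop("fk_format_error", "%s: missing color table (tag %s)", path,
            tag)
  version <- rint()
  if (is.na(version) || version >= 0L || version != -2L)
    fk_stop("fk_format_error",
            "%s: unsupported annot color-table version %s", path, version)
  rint()                                  # max structure id (unused)
  fn_len <- rint()
  readBin(con, "raw", n = fn_len)         # original filename (unused)
  n_entries <- rint()
  ids <- integer(n_entries); nms <- character(n_entries)
  cols <- matrix(0L, n_entries, 3L)
  for (i in seq_len(n_entries)) {
    ids[i] <- rint()
    len <- rint()
    nm_raw <- readBin(con, "raw", n = len)
    nms[i] <- rawToChar(nm_raw[nm_raw != as.raw(0L)])
    rgbt <- rint(4L)
    cols[i, ] <- rgbt[1:3]
  }
  table <- label_table(ids, nms, cols)
  tcode <- annot_code(table)
  idx <- match(code, tcode)
  if (anyNA(idx)) {
    missing_codes <- unique(code[is.na(idx)])
    fk_stop("fk_label_lookup_error",
            "%s: %d vertex color(s) absent from color table: %s", path,
            length(missing_codes),
            paste(sprintf("#%06X", missing_codes[seq_len(min(5,
              length(missing_codes)))]), collapse = ", "))
  }
  labels <- integer(n)
  labels[vtx + 1L] <- table$id[idx]
  list(labels = labels, table = table)
}

write_annot <- function(labels, path, table) {
  labels <- as.integer(labels)
  miss <- setdiff(unique(labels), table$id)
  if (length(miss))
    fk_stop("fk_label_lookup_error",
            "label ids absent from table: %s", paste(miss, collapse = ", "))
  code <- annot_code(table)[match(labels, table$id)]
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "big")
  n <- length(labels)
  wint(n)
  inter <- integer(2L * n)
  inter[seq(1L, 2L * n, by = 2L)] <- seq_len(n) - 1L
  inter[seq(2L, 2L * n, by = 2L)] <- code
  wint(inter)
  wint(1L)                    # tag: color table follows
  wint(-2L)                   # color table version 2
  wint(max(table$id) + 1L)    # max structure id + 1
  fn <- "foliakit.ctab"
  wint(nchar(fn)); writeBin(charToRaw(fn), con)
  wint(nrow(table))
  for (i in seq_len(nrow(table))) {
    wint(table$id[i])
    nm <- table$name[i]
    wint(nchar(nm)); writeBin(charToRaw(nm), con)
    wint(c(table$R[i], table$G[i], table$B[i], 0L))
  }
}

## ---- GIFTI label files -----------------------------------------------------

read_labels_gifti <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  il <- which(xml2::xml_attr(arrays, "Intent") == "NIFTI_INTENT_LABEL")[1]
  if (is.na(il))
    fk_stop("fk_format_error", "%s: no NIFTI_INTENT_LABEL array", path)
  labels <- as.integer(gifti_decode_data(arrays[[il]],
                                         gifti_array_dims(arrays[[il]])))
  lab_nodes <- xml2::xml_find_all(doc, ".//LabelTable/Label")
  table <- NULL
  if (length(lab_nodes)) {
    table <- label_table(
      ids = as.integer(xml2::xml_attr(lab_nodes, "Key")),
      names = xml2::xml_text(lab_nodes),
      colors = cbind(
        as.integer(round(as.numeric(xml2::xml_attr(lab_nodes, "Red")) * 255)),
        as.integer(round(as.numeric(xml2::xml_attr(lab_nodes, "Green")) * 255)),
        as.integer(round(as.numeric(xml2::xml_attr(lab_nodes, "Blue")) * 255))))
  }
  list(labels = labels, table = table)
}

write_labels_gifti <- function(labels, path, table) {
  node <- gifti_data_node(as.integer(labels), "NIFTI_TYPE_INT32",
                          "NIFTI_INTENT_LABEL", length(labels))
  gifti_write_doc(list(node), path, label_table = table)
}
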