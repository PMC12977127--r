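#' Read and write triangular surface meshes
#'
#' Supported formats: FreeSurfer binary surface (big-endian triangle file),
#' GIFTI (`.gii`, pointset + triangle data arrays) and ASCII PLY. Vertex order
#' is preserved exactly; faces are stored 1-based in R and converted to the
#' formats' 0-based convention on disk. Coordinates are world mm.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"freesurfer"`, `"gifti"`, `"ply"`. `"auto"`
#'   dispatches on the file extension (`.gii`, `.ply`, else FreeSurfer).
#' @param surface a [labeled_surface()]; only the geometry is written.
#' @return [read_surface()] returns a [labeled_surface()] (geometry only).
#' @export
read_surface <- function(path, format = c("auto", "freesurfer", "gifti",
                                          "ply")) {
  format <- match.arg(format)
  if (!file.exists(path))
    fk_stop("fk_format_error", "file not found: %s", path)
  format <- resolve_surface_format(path, format)
  switch(format,
         freesurfer = read_surface_fs(path),
         gifti = read_surface_gifti(path),
         ply = read_surface_ply(path))
}

#' @rdname read_surface
#' @export
write_surface <- function(surface, path, format = c("auto", "freesurfer",
                                                    "gifti", "ply")) {
  format <- match.arg(format)
  format <- resolve_surface_format(path, format)
  switch(format,
         freesurfer = write_surface_fs(surface, path),
         gifti = write_surface_gifti(surface, path),
         ply = write_surface_ply(surface, path))
  invisible(path)
}

resolve_surface_format <- function(path, format) {
  if (format != "auto") return(format)
  low <- tolower(path)
  if (grepl("\\.gii$", low)) "gifti"
  else if (grepl("\\.ply$", low)) "ply"
  else "freesurfer"
}

## ---- FreeSurfer binary triangle surface ----------------------------------
## magic 0xFFFFFE, comment terminated by "\n\n", int32 counts, float32
## vertices, int32 0-based faces; everything big-endian.

TRIANGLE_MAGIC <- -2L  # low 24 bits 0xFFFFFE

read_surface_fs <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 3L ||
      !identical(as.integer(raw[1:3]), c(255L, 255L, 254L)))
    fk_stop("fk_format_error",
            "%s: bad magic at byte 0 (not a FreeSurfer triangle surface)",
            path)
  # comment ends at the first "\n\n"
  nl <- which(raw == as.raw(10L))
  end <- nl[which(diff(nl) == 1L)[1] + 1L]
  if (is.na(end))
    fk_stop("fk_format_error",
            "%s: unterminated comment (no \\n\\n found) after byte 3", path)
  con <- rawConnection(raw[(end + 1L):length(raw)])
  on.exit(close(con))
  counts <- readBin(con, "integer", n = 2L, size = 4L, endian = "big")
  nv <- counts[1]; nf <- counts[2]
  if (nv <= 0L || nf < 0L)
    fk_stop("fk_format_error", "%s: implausible counts at byte %d (%d, %d)",
            path, end + 1L, nv, nf)
  v <- readBin(con, "numeric", n = 3L * nv, size = 4L, endian = "big")
  f <- readBin(con, "integer", n = 3L * nf, size = 4L, endian = "big")
  if (length(v) != 3L * nv || length(f) != 3L * nf)
    fk_stop("fk_format_error", "%s: truncated at byte %d", path,
            end + 9L + 4L * length(v) + 4L * length(f))
  labeled_surface(matrix(v, ncol = 3L, byrow = TRUE),
                  matrix(f, ncol = 3L, byrow = TRUE) + 1L)
}

write_surface_fs <- function(surface, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(255L, 255L, 254L)), con)
  writeBin(charToRaw("created by foliakit\n\n"), con)
  writeBin(c(nrow(surface$vertices), nrow(surface$faces)), con, size = 4L,
           endian = "big")
  writeBin(as.numeric(t(surface$vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(t(surface$faces) - 1L), con, size = 4L, endian = "big")
}

## ---- ASCII PLY ------------------------------------------------------------

read_surface_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || lines[1] != "ply")
    fk_stop("fk_format_error", "%s: missing 'ply' header at line 1", path)
  hdr_end <- match("end_header", lines)
  if (is.na(hdr_end))
    fk_stop("fk_format_error", "%s: no end_header element", path)
  hdr <- lines[2:(hdr_end - 1L)]
  if (!any(grepl("^format ascii", hdr)))
    fk_stop("fk_format_error", "%s: only ASCII PLY is supported", path)
  nv <- as.integer(sub("^element vertex ", "", grep("^element vertex ", hdr,
                                                    value = TRUE)[1]))
  nf <- as.integer(sub("^element face ", "", grep("^element face ", hdr,
                                                  value = TRUE)[1]))
  if (is.na(nv) || is.na(nf))
    fk_stop("fk_format_error", "%s: missing vertex/face elements", path)
  # vertex property order, to locate x/y/z among possible extras
  vi <- grep("^element vertex ", hdr)
  fi <- grep("^element face ", hdr)
  props <- sub("^property \\S+ ", "", hdr[seq(vi + 1L, fi - 1L)])
  props <- props[grepl("^property", hdr[seq(vi + 1L, fi - 1L)])]
  xyz <- match(c("x", "y", "z"), props)
  if (anyNA(xyz))
    fk_stop("fk_format_error", "%s: vertex element lacks x/y/z", path)
  body <- lines[(hdr_end + 1L):length(lines)]
  vparts <- strsplit(trimws(body[seq_len(nv)]), "[ \t]+")
  vm <- matrix(as.numeric(unlist(vparts)), nrow = nv, byrow = TRUE)
  fparts <- strsplit(trimws(body[nv + seq_len(nf)]), "[ \t]+")
  cnt <- vapply(fparts, function(p) as.integer(p[1]), 1L)
  if (any(cnt != 3L))
    fk_stop("fk_unsupported_geometry",
            "%s: non-triangular face (first at face element %d with %d vertices)",
            path, which(cnt != 3L)[1], cnt[cnt != 3L][1])
  fm <- t(vapply(fparts, function(p) as.integer(p[2:4]), integer(3)))
  labeled_surface(vm[, xyz, drop = FALSE], fm + 1L)
}

write_surface_ply <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0", "comment created by foliakit",
               sprintf("element vertex %d", nrow(surface$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(surface$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(surface$vertices, 1, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = " ")), con)
  writeLines(apply(surface$faces - 1L, 1, function(r)
    paste(c(3L, r), collapse = " ")), con)
}

## ---- GIFTI ----------------------------------------------------------------
## Minimal GIFTI-1 reader/writer: pointset + triangle arrays, Base64Binary or
## GZipBase64Binary encodings, little- or big-endian, row- or column-major.

gifti_decode_data <- function(node, dims) {
  enc <- xml2::xml_attr(node, "Encoding")
  dtype <- xml2::xml_attr(node, "DataType")
  endian <- xml2::xml_attr(node, "Endian")
  order <- xml2::xml_attr(node, "ArrayIndexingOrder")
  data_node <- xml2::xml_find_first(node, ".//Data")
  txt <- gsub("[[:space:]]", "", xml2::xml_text(data_node))
  raw <- jsonlite::base64_dec(txt)
  if (identical(enc, "GZipBase64Binary")) {
    raw <- memDecompress(raw, type = "gzip")
  } else if (!identical(enc, "Base64Binary")) {
    fk_stop("fk_format_error", "unsupported GIFTI encoding '%s'", enc)
  }
  e <- if (identical(endian, "BigEndian")) "big" else "little"
  n <- prod(dims)
  vals <- switch(dtype,
                 NIFTI_TYPE_FLOAT32 = readBin(raw, "numeric", n = n, size = 4L,
                                              endian = e),
                 NIFTI_TYPE_FLOAT64 = readBin(raw, "numeric", n = n, size = 8L,
                                              endian = e),
                 NIFTI_TYPE_INT32 = readBin(raw, "integer", n = n, size = 4L,
                                            endian = e),
                 fk_stop("fk_format_error", "unsupported GIFTI DataType '%s'",
                         dtype))
  if (length(vals) != n)
    fk_stop("fk_format_error", "GIFTI data array truncated (%d of %d values)",
            length(vals), n)
  if (length(dims) == 1L) return(vals)
  if (identical(order, "ColumnMajorOrder")) matrix(vals, nrow = dims[1])
  else matrix(vals, ncol = dims[2], byrow = TRUE)
}

gifti_array_dims <- function(node) {
  nd <- as.integer(xml2::xml_attr(node, "Dimensionality"))
  vapply(seq_len(nd) - 1L, function(i)
    as.integer(xml2::xml_attr(node, paste0("Dim", i))), 1L)
}

read_surface_gifti <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  intents <- xml2::xml_attr(arrays, "Intent")
  ip <- which(intents == "NIFTI_INTENT_POINTSET")[1]
  it <- which(intents == "NIFTI_INTENT_TRIANGLE")[1]
  if (is.na(ip) || is.na(it))
    fk_stop("fk_format_error",
            "%s: GIFTI lacks pointset and/or triangle arrays", path)
  v <- gifti_decode_data(arrays[[ip]], gifti_array_dims(arrays[[ip]]))
  f <- gifti_decode_data(arrays[[it]], gifti_array_dims(arrays[[it]]))
  labeled_surface(v, f + 1L)
}

gifti_data_node <- function(values, dtype, intent, dims) {
  raw <- if (dtype == "NIFTI_TYPE_FLOAT32")
    writeBin(as.numeric(values), raw(), size = 4L, endian = "little")
  else writeBin(as.integer(values), raw(), size = 4L, endian = "little")
  b64 <- jsonlite::base64_enc(memCompress(raw, type = "gzip"))
  attrs <- c(Intent = intent, DataType = dtype,
             ArrayIndexingOrder = "RowMajorOrder",
             Dimensionality = as.character(length(dims)),
             setNames(as.character(dims), paste0("Dim", seq_along(dims) - 1L)),
             Encoding = "GZipBase64Binary", Endian = "LittleEndian",
             ExternalFileName = "", ExternalFileOffset = "")
  list(attrs = attrs, b64 = b64)
}

gifti_write_doc <- function(nodes, path, label_table = NULL) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = as.character(length(nodes)))
  if (!is.null(label_table)) {
    lt <- xml2::xml_add_child(doc, "LabelTable")
    for (i in seq_len(nrow(label_table))) {
      xml2::xml_add_child(lt, "Label", label_table$name[i],
                          Key = as.character(label_table$id[i]),
                          Red = sprintf("%.6f", label_table$R[i] / 255),
                          Green = sprintf("%.6f", label_table$G[i] / 255),
                          Blue = sprintf("%.6f", label_table$B[i] / 255),
                          Alpha = "1.000000")
    }
  }
  for (nd in nodes) {
    da <- xml2::xml_add_child(doc, "DataArray")
    for (a in names(nd$attrs)) xml2::xml_set_attr(da, a, nd$attrs[[a]])
    xml2::xml_add_child(da, "Data", nd$b64)
  }
  xml2::write_xml(doc, path)
}

write_surface_gifti <- function(surface, path) {
  # row-major serialization of the N x 3 matrices
  pv <- gifti_data_node(as.numeric(t(surface$vertices)), "NIFTI_TYPE_FLOAT32",
                        "NIFTI_INTENT_POINTSET",
                        c(nrow(surface$vertices), 3L))
  tf <- gifti_data_node(as.integer(t(surface$faces - 1L)), "NIFTI_TYPE_INT32",
                        "NIFTI_INTENT_TRIANGLE", c(nrow(surface$faces), 3L))
  gifti_write_doc(list(pv, tf), path)
}
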