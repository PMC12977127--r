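#' Read and write 3-D volumes
#'
#' NIfTI-1 (`.nii` / `.nii.gz`) goes through the RNifti package; MGH / MGZ
#' (`.mgh` / `.mgz`) is read and written directly (big-endian, version 1
#' headers). Integer arrays are stored as 32-bit integers and stay integer on
#' round-trip; the voxel-center-to-world affine is preserved.
#'
#' @param path file path; format chosen by extension.
#' @param volume a [label_volume()] or [intensity_volume()].
#' @return [read_volume()] returns a [label_volume()] when the on-disk data
#'   type is integral, otherwise an [intensity_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    fk_stop("fk_format_error", "file not found: %s", path)
  if (grepl("\\.(mgh|mgz)$", tolower(path))) return(read_mgh(path))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1, drop = TRUE]
  if (length(dim(arr)) != 3L)
    fk_stop("fk_dimensionality_error", "%s: expected a 3-D volume, got %d-D",
            path, length(dim(arr)))
  affine <- structure(RNifti::xform(img), class = NULL)
  attributes(affine) <- list(dim = dim(affine))
  dt <- RNifti::niftiHeader(img)$datatype
  is_int <- dt %in% c(2L, 4L, 8L, 256L, 512L, 768L)
  if (is_int) label_volume(arr, affine) else intensity_volume(arr, affine)
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "foliakit_volume"))
  if (grepl("\\.(mgh|mgz)$", tolower(path))) return(write_mgh(volume, path))
  dt <- if (inherits(volume, "label_volume")) "int32" else "float64"
  img <- RNifti::asNifti(volume$array, datatype = dt)
  img <- RNifti::`sform<-`(img, structure(volume$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

## ---- MGH / MGZ -------------------------------------------------------------
## version 1 header: dims, type, dof, goodRASflag, spacing, direction cosines
## and the world position of the volume center; 284-byte header, big-endian.

MGH_TYPE_INT <- 1L
MGH_TYPE_FLOAT <- 3L

read_mgh <- function(path) {
  con <- if (grepl("\\.mgz$", tolower(path))) gzfile(path, "rb")
         else file(path, "rb")
  on.exit(close(con))
  rint <- function(n = 1L) readBin(con, "integer", n = n, size = 4L,
                                   endian = "big")
  rflt <- function(n = 1L) readBin(con, "numeric", n = n, size = 4L,
                                   endian = "big")
  version <- rint()
  if (!identical(version, 1L))
    fk_stop("fk_format_error", "%s: unsupported MGH version %s at byte 0",
            path, version)
  dims <- rint(4L)
  type <- rint()
  rint()  # dof
  good_ras <- readBin(con, "integer", n = 1L, size = 2L, endian = "big")
  if (dims[4] != 1L)
    fk_stop("fk_dimensionality_error", "%s: expected 3-D volume, nframes=%d",
            path, dims[4])
  affine <- diag(4)
  hdr_read <- 4L * 7L + 2L
  if (identical(good_ras, 1L)) {
    spacing <- rflt(3L)
    mdc <- matrix(rflt(9L), 3L, 3L)            # column j = axis j direction
    c_ras <- rflt(3L)
    m <- mdc %*% diag(spacing)
    origin <- c_ras - m %*% (dims[1:3] / 2)
    affine <- rbind(cbind(m, origin), c(0, 0, 0, 1))
    hdr_read <- hdr_read + 4L * 15L
  }
  readBin(con, "raw", n = 284L - hdr_read)     # pad to data start
  nvox <- prod(dims[1:3])
  arr <- switch(as.character(type),
                "1" = rint(nvox),
                "3" = rflt(nvox),
                fk_stop("fk_format_error", "%s: unsupported MGH type %d",
                        path, type))
  dim(arr) <- dims[1:3]
  if (type == MGH_TYPE_INT) label_volume(arr, affine)
  else intensity_volume(arr, affine)
}

write_mgh <- function(volume, path) {
  con <- if (grepl("\\.mgz$", tolower(path))) gzfile(path, "wb")
         else file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "big")
  wflt <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "big")
  dims <- dim(volume$array)
  type <- if (inherits(volume, "label_volume")) MGH_TYPE_INT else
    MGH_TYPE_FLOAT
  wint(1L)                     # version
  wint(c(dims, 1L))            # width height depth nframes
  wint(type)
  wint(0L)                     # dof
  writeBin(1L, con, size = 2L, endian = "big")   # goodRASflag
  m <- volume$affine[1:3, 1:3]
  spacing <- sqrt(colSums(m^2))
  mdc <- sweep(m, 2L, spacing, "/")
  c_ras <- volume$affine[1:3, 4] + m %*% (dims / 2)
  wflt(spacing)
  wflt(as.numeric(mdc))
  wflt(as.numeric(c_ras))
  writeBin(raw(284L - (4L * 7L + 2L + 4L * 15L)), con)
  if (type == MGH_TYPE_INT) wint(as.vector(volume$array))
  else wflt(as.vector(volume$array))
  invisible(path)
}

#' Read and write displacement fields
#'
#' Dense displacement fields are stored as 4-D NIfTI volumes (X x Y x Z x 3)
#' of world-mm displacement vectors, with the field's own grid affine.
#'
#' @param field a [displacement_field()].
#' @param path NIfTI path (`.nii` / `.nii.gz`).
#' @return [read_field()] returns a [displacement_field()].
#' @export
write_field <- function(field, path) {
  img <- RNifti::asNifti(field$vectors, datatype = "float64")
  img <- RNifti::`sform<-`(img, structure(field$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) == 5L) arr <- arr[, , , 1, ]  # NIfTI vector convention
  if (length(dim(arr)) != 4L || dim(arr)[4] != 3L)
    fk_stop("fk_dimensionality_error",
            "%s: displacement field must be X x Y x Z x 3", path)
  affine <- structure(RNifti::xform(img), class = NULL)
  attributes(affine) <- list(dim = dim(affine))
  displacement_field(arr, affine)
}
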