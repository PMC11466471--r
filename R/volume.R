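#' Construct a CT/CBCT volume
#'
#' A `cbct_volume` is a 3D scalar grid of Hounsfield units together with its
#' physical metadata: voxel spacing (mm), the physical position of the first
#' voxel (origin, mm) and the isocenter (mm), which defaults to the grid
#' center. The physical position of voxel `(i, j, k)` (1-based) is
#' `origin + (i-1, j-1, k-1) * spacing`. All geometric operations in the
#' package (couch rotation, setup errors, ray casting, registration) act in
#' this physical frame about the isocenter.
#'
#' Axis convention: for a head-first-supine subject, x runs left-right,
#' y anterior-posterior (room-vertical), z inferior-superior (couch axis).
#'
#' @param voxels 3D numeric array of HU values (finite).
#' @param spacing numeric length-3, voxel spacing in mm (> 0).
#' @param origin numeric length-3, physical position of voxel (1,1,1) in mm.
#'   Default centers the grid on (0,0,0).
#' @param isocenter numeric length-3 physical point in mm; default grid center.
#' @return A `cbct_volume` object.
#' @export
cbct_volume <- function(voxels, spacing = c(1, 1, 1), origin = NULL,
                        isocenter = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  if (!all(is.finite(voxels))) stop("`voxels` must be finite HU values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive lengths (mm)")
  d <- dim(voxels)
  if (any(d < 1L)) stop("grid dims must be >= 1")
  center <- (d - 1) / 2 * spacing
  if (is.null(origin)) origin <- -center
  origin <- as.numeric(origin)
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("`origin` must be 3 finite coordinates (mm)")
  if (is.null(isocenter)) isocenter <- origin + center
  isocenter <- as.numeric(isocenter)
  if (length(isocenter) != 3L || !all(is.finite(isocenter)))
    stop("`isocenter` must be 3 finite coordinates (mm)")
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 isocenter = isocenter),
            class = "cbct_volume")
}

#' @export
print.cbct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<cbct_volume> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f], origin (%.2f, %.2f, %.2f) mm\n",
              min(x$voxels), max(x$voxels),
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
dim.cbct_volume <- function(x) dim(x$voxels)

stopifnot_volume <- function(x, arg = deparse(substitute(x))) {
  if (!inherits(x, "cbct_volume"))
    stop(sprintf("`%s` must be a cbct_volume", arg))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-8))
}

#' Physical coordinates of every voxel
#'
#' @param vol a [cbct_volume()].
#' @param relative_to optional point (mm) subtracted from the coordinates,
#'   e.g. the isocenter.
#' @return matrix with one row per voxel (x fastest) and columns x, y, z (mm).
#' @keywords internal
voxel_coords <- function(vol, relative_to = c(0, 0, 0)) {
  d <- dim(vol$voxels)
  gx <- vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1] - relative_to[1]
  gy <- vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2] - relative_to[2]
  gz <- vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3] - relative_to[3]
  cbind(x = rep(gx, times = d[2] * d[3]),
        y = rep(rep(gy, each = d[1]), times = d[3]),
        z = rep(gz, each = d[1] * d[2]))
}

#' Read a volume from NIfTI or MetaImage
#'
#' NIfTI (`.nii`, `.nii.gz`) is read with RNifti; MetaImage (`.mha`) with the
#' package's own uncompressed reader. Spacing and origin are honored.
#'
#' @param path file path ending in `.nii`, `.nii.gz` or `.mha`.
#' @return A [cbct_volume()].
#' @export
read_volume <- function(path) {
  if (grepl("\\.mha$", path, ignore.case = TRUE)) return(read_mha(path))
  img <- RNifti::readNifti(path)
  vox <- array(as.numeric(img), dim = dim(img))
  sp <- RNifti::pixdim(img)
  cbct_volume(vox, spacing = sp[seq_len(3)], origin = nifti_origin(img))
}

nifti_origin <- function(img) {
  # physical position of voxel (1,1,1): xform %*% index 0
  xf <- RNifti::xform(img)
  as.numeric(xf[1:3, 4])
}

#' Write a volume to NIfTI or MetaImage
#'
#' @param vol a [cbct_volume()].
#' @param path output path (`.nii`, `.nii.gz` or `.mha`).
#' @param datatype `"float"` (default) or `"int16"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = c("float", "int16")) {
  stopifnot_volume(vol)
  datatype <- match.arg(datatype)
  if (grepl("\\.mha$", path, ignore.case = TRUE))
    return(write_mha(vol, path, datatype))
  vox <- if (datatype == "int16") {
    storage.mode(vol$voxels) <- "integer"
    vol$voxels
  } else vol$voxels
  img <- RNifti::asNifti(vox)
  RNifti::pixdim(img) <- vol$spacing
  xf <- diag(4)
  diag(xf)[1:3] <- vol$spacing
  xf[1:3, 4] <- vol$origin
  img <- RNifti::`qform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path, datatype = if (datatype == "int16") "short" else "float")
  invisible(path)
}

# Minimal uncompressed MetaImage (.mha) IO: text header + raw voxel block.
read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated MHA header")
    kv <- strsplit(line, " = ", fixed = TRUE)[[1]]
    if (length(kv) == 2L) hdr[[kv[1]]] <- kv[2]
    if (identical(kv[1], "ElementDataFile")) break
  }
  dims <- as.integer(strsplit(hdr$DimSize, " ")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing, " ")[[1]])
  origin <- as.numeric(strsplit(hdr$Offset, " ")[[1]])
  n <- prod(dims)
  vox <- switch(hdr$ElementType,
    MET_SHORT = as.numeric(readBin(con, "integer", n, size = 2L, signed = TRUE,
                                   endian = "little")),
    MET_FLOAT = readBin(con, "numeric", n, size = 4L, endian = "little"),
    MET_DOUBLE = readBin(con, "numeric", n, size = 8L, endian = "little"),
    stop("unsupported MHA ElementType: ", hdr$ElementType))
  cbct_volume(array(vox, dim = dims), spacing = spacing, origin = origin)
}

write_mha <- function(vol, path, datatype = "float") {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(vol$voxels)
  et <- if (datatype == "int16") "MET_SHORT" else "MET_FLOAT"
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           paste("Offset =", paste(format(vol$origin, digits = 10), collapse = " ")),
           paste("ElementSpacing =", paste(format(vol$spacing, digits = 10), collapse = " ")),
           paste("DimSize =", paste(d, collapse = " ")),
           paste("ElementType =", et),
           "ElementDataFile = LOCAL")
  writeLines(hdr, con)
  if (datatype == "int16")
    writeBin(as.integer(round(vol$voxels)), con, size = 2L, endian = "little")
  else
    writeBin(as.numeric(vol$voxels), con, size = 4L, endian = "little")
  invisible(path)
}

#' Block-average downsampling of a volume
#'
#' Used by the multi-resolution registration pyramid. Each output voxel is the
#' mean of a `factor`-cubed block; spacing is scaled accordingly.
#'
#' @param vol a [cbct_volume()].
#' @param factor integer block edge (dims are truncated to a multiple).
#' @return A [cbct_volume()] at coarser resolution with the same isocenter.
#' @export
downsample_volume <- function(vol, factor = 2L) {
  stopifnot_volume(vol)
  factor <- as.integer(factor)
  if (factor < 1L) stop("`factor` must be >= 1")
  if (factor == 1L) return(vol)
  d <- dim(vol$voxels)
  nd <- d %/% factor
  if (any(nd < 1L)) stop("volume too small for this downsampling factor")
  v <- vol$voxels[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                  seq_len(nd[3] * factor), drop = FALSE]
  a <- array(v, dim = c(factor, nd[1], factor, nd[2], factor, nd[3]))
  out <- apply(a, c(2, 4, 6), mean)
  # block center of the first block sits at origin + (factor-1)/2 * spacing
  cbct_volume(out, spacing = vol$spacing * factor,
              origin = vol$origin + (factor - 1) / 2 * vol$spacing,
              isocenter = vol$isocenter)
}

#' Resample a volume to a target grid size
#'
#' Trilinear resampling preserving the physical extent (spacing is rescaled),
#' used to bring stored volumes onto a network input grid.
#'
#' @param vol a [cbct_volume()].
#' @param dims integer length-3 target voxel counts.
#' @return A [cbct_volume()] with `dims` voxels.
#' @export
resize_volume <- function(vol, dims) {
  stopifnot_volume(vol)
  dims <- as.integer(dims)
  d <- dim(vol$voxels)
  if (identical(d, dims)) return(vol)
  M <- diag((d - 1) / pmax(dims - 1, 1))
  vox <- cpp_resample_idx(vol$voxels, d, dims, M, c(0, 0, 0), -1000)
  cbct_volume(vox, spacing = vol$spacing * (d - 1) / pmax(dims - 1, 1),
              origin = vol$origin, isocenter = vol$isocenter)
}

#' Normalize HU to the network intensity window
#'
#' Maps the fixed window \[-1000, 2000\] HU linearly onto \[-1, 1\] (clamped);
#' `denormalize_hu()` inverts the map. All network inputs and outputs live in
#' this normalized domain.
#'
#' @param hu numeric array of HU values.
#' @param x numeric array in normalized units.
#' @return Array of the same shape.
#' @export
normalize_hu <- function(hu) {
  out <- pmin(1, pmax(-1, (hu - 500) / 1500))
  dim(out) <- dim(hu)
  out
}

#' @rdname normalize_hu
#' @export
denormalize_hu <- function(x) x * 1500 + 500
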