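#' 3D volume image with isotropic spacing
#'
#' Container for a 3D scalar voxel grid. Axis convention: x runs
#' anterior to posterior, y medial to lateral, z proximal to distal.
#' Coordinates used throughout the package are 0-based, voxel-centered,
#' in voxel units; physical micrometres are obtained by multiplying by
#' `spacing`.
#'
#' @param voxels 3D numeric array.
#' @param spacing isotropic voxel edge length in micrometres (default 10.4).
#' @param origin physical position of voxel (0,0,0), micrometres.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(voxels, spacing = 10.4, origin = c(0, 0, 0)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0)
    stop("spacing must be a single positive number (isotropic)")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "volume_image")
}

#' Binary (bone/background) volume
#'
#' A [volume_image()] whose voxels are 0/1 with 1 = bone.
#'
#' @param voxels 3D array of 0/1 (integer or logical).
#' @inheritParams volume_image
#' @return An object of class `c("binary_volume", "volume_image")`.
#' @export
binary_volume <- function(voxels, spacing = 10.4, origin = c(0, 0, 0)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  storage.mode(voxels) <- "integer"
  if (!all(voxels %in% c(0L, 1L))) stop("binary volume must contain only 0/1")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = c("binary_volume", "volume_image"))
}

is_binary_volume <- function(x) inherits(x, "binary_volume")

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %.3g um, range [%.3g, %.3g]\n",
              class(x)[1], d[1], d[2], d[3], x$spacing,
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$voxels)

#' Gaussian blur of a volume
#'
#' Separable Gaussian smoothing with replicate padding.
#'
#' @param image a [volume_image()].
#' @param sigma standard deviation in voxels; 0 returns the input.
#' @return A `volume_image` of the same shape.
#' @export
blur_volume <- function(image, sigma) {
  v <- cpp_gauss_blur(as.double(image$voxels), dim(image$voxels), sigma)
  volume_image(array(v, dim(image$voxels)), image$spacing, image$origin)
}

#' Trilinear sampling of a volume at arbitrary points
#'
#' @param image a [volume_image()].
#' @param points n x 3 matrix of 0-based voxel coordinates.
#' @param clamp clamp out-of-bounds points to the edge (default) or fill.
#' @param fill fill value used when `clamp = FALSE`.
#' @return Numeric vector of n sampled values.
#' @export
sample_volume <- function(image, points, clamp = TRUE, fill = 0) {
  points <- as_points(points)
  cpp_trilinear(as.double(image$voxels), dim(image$voxels), points, clamp, fill)
}

as_points <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must be an n x 3 matrix")
  storage.mode(points) <- "double"
  points
}

# ---------------------------------------------------------------------- IO

#' Write a volume as MetaImage (MHD header + RAW data)
#'
#' @param image a [volume_image()].
#' @param path path of the `.mhd` header; the `.raw` file is written next
#'   to it.
#' @return `path`, invisibly.
#' @export
write_mhd <- function(image, path) {
  if (!grepl("\\.mhd$", path)) path <- paste0(path, ".mhd")
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  d <- dim(image$voxels)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %g %g %g", image$spacing, image$spacing, image$spacing),
    sprintf("Offset = %g %g %g", image$origin[1], image$origin[2], image$origin[3]),
    "ElementType = MET_DOUBLE",
    sprintf("ElementDataFile = %s", raw_name))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  writeBin(as.double(image$voxels), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a MetaImage volume written by [write_mhd()]
#'
#' Supports uncompressed MET_DOUBLE/MET_FLOAT/MET_UCHAR/MET_SHORT raw data.
#'
#' @param path path to the `.mhd` header.
#' @return A [volume_image()].
#' @export
read_mhd <- function(path) {
  hdr <- readLines(path)
  field <- function(key) {
    ln <- grep(paste0("^", key, " *="), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    trimws(sub("^[^=]*=", "", ln[1]))
  }
  d <- as.integer(strsplit(field("DimSize"), " +")[[1]])
  sp <- as.numeric(strsplit(field("ElementSpacing"), " +")[[1]])
  off <- field("Offset")
  origin <- if (is.null(off)) c(0, 0, 0) else as.numeric(strsplit(off, " +")[[1]])
  type <- field("ElementType")
  raw_path <- file.path(dirname(path), field("ElementDataFile"))
  n <- prod(d)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  v <- switch(type,
    MET_DOUBLE = readBin(con, "double", n, size = 8, endian = "little"),
    MET_FLOAT  = readBin(con, "double", n, size = 4, endian = "little"),
    MET_UCHAR  = as.double(readBin(con, "integer", n, size = 1, signed = FALSE)),
    MET_SHORT  = as.double(readBin(con, "integer", n, size = 2, endian = "little")),
    stop("unsupported ElementType: ", type))
  volume_image(array(v, d), sp[1], origin)
}

#' Write a volume as a multi-page TIFF stack
#'
#' One 32-bit float page per axial (z) slice; intensities are written as
#' stored (no rescaling), so round-trips are exact within float precision.
#'
#' @param image a [volume_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(image, path) {
  d <- dim(image$voxels)
  pages <- lapply(seq_len(d[3]), function(k) {
    # tiff expects row-major matrices; store x along columns
    t(image$voxels[, , k])
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF stack as a volume
#'
#' @param path input path.
#' @param spacing voxel size in micrometres to attach (default 10.4).
#' @return A [volume_image()].
#' @export
read_volume_tiff <- function(path, spacing = 10.4) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  nz <- length(pages)
  p1 <- pages[[1]]
  vox <- array(0, c(ncol(p1), nrow(p1), nz))
  for (k in seq_len(nz)) vox[, , k] <- t(pages[[k]])
  volume_image(vox, spacing)
}
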