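#' Read a labelmap from NIfTI or MetaImage
#'
#' Reads `.nii`/`.nii.gz` (via RNifti) or `.mhd`/`.mha` (MetaImage,
#' uncompressed) volumes of integer voxels. Spacing is taken from the file
#' header; voxel values must be whole numbers and every label must appear
#' in `legend`.
#'
#' @param path File path.
#' @param legend Label legend to attach; defaults to [default_legend()].
#' @return A [labelmap()].
#' @export
read_labelmap <- function(path, legend = default_legend()) {
  ext <- tolower(sub("^.*?(\\.[A-Za-z0-9.]+)$", "\\1", basename(path)))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    grid <- as.array(img)
    pd <- attr(img, "pixdim")
    if (is.null(pd)) pd <- RNifti::pixdim(img)
    spacing <- pd[seq_along(dim(grid))]
    if (any(!is.finite(spacing)) || any(spacing <= 0))
      stop("NIfTI header field 'pixdim' has no valid spacing in ", path)
  } else if (grepl("\\.mh[da]$", path, ignore.case = TRUE)) {
    meta <- read_metaimage(path)
    grid <- meta$grid
    spacing <- meta$spacing
  } else {
    stop("unsupported labelmap format: ", path,
         " (expected .nii, .nii.gz, .mhd or .mha)")
  }
  if (any(grid != round(grid)))
    stop("labelmap file holds non-integer voxel values: ", path)
  grid <- array(as.integer(grid), dim = dim(grid))  # drop reader attributes
  # squeeze singleton trailing dims (e.g. 3D file holding one slice stays 3D;
  # 4D time axis of size 1 is dropped)
  d <- dim(grid)
  if (length(d) > 3L && all(d[-(1:3)] == 1L)) {
    dim(grid) <- d[1:3]
    spacing <- spacing[1:3]
  }
  labelmap(grid, spacing = spacing, legend = legend)
}

#' Write a labelmap to NIfTI or MetaImage
#'
#' @param lm A [labelmap()].
#' @param path Destination ending in `.nii`, `.nii.gz`, `.mhd` or `.mha`.
#' @return Invisibly, `path`.
#' @export
write_labelmap <- function(lm, path) {
  stopifnot(inherits(lm, "labelmap"))
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(lm$grid)
    RNifti::pixdim(img) <- lm$spacing
    RNifti::writeNifti(img, path, datatype = "int16")
  } else if (grepl("\\.mh[da]$", path, ignore.case = TRUE)) {
    write_metaimage(lm, path)
  } else {
    stop("unsupported labelmap format: ", path)
  }
  invisible(path)
}

# --- MetaImage (.mhd/.mha): line-oriented "Key = Value" text header plus a
#     raw little-endian voxel blob; uncompressed files only. -----------------

mha_types <- c(MET_UCHAR = "uchar", MET_CHAR = "char", MET_SHORT = "short",
               MET_USHORT = "ushort", MET_INT = "int", MET_UINT = "uint")
mha_sizes <- c(MET_UCHAR = 1L, MET_CHAR = 1L, MET_SHORT = 2L,
               MET_USHORT = 2L, MET_INT = 4L, MET_UINT = 4L)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) break
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) next
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  for (req in c("NDims", "DimSize", "ElementType", "ElementDataFile"))
    if (is.null(hdr[[req]])) stop("MetaImage header missing ", req, " in ", path)
  if (is.null(hdr$ElementSpacing))
    stop("MetaImage header field 'ElementSpacing' missing in ", path)
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  et <- hdr$ElementType
  if (!et %in% names(mha_sizes))
    stop("MetaImage element type ", et, " is not an integer type")
  if (identical(tolower(hdr$CompressedData %||% "false"), "true"))
    stop("compressed MetaImage files are not supported")
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw <- readBin(con, "raw", n = n * mha_sizes[[et]])
  } else {
    rawpath <- file.path(dirname(path), hdr$ElementDataFile)
    raw <- readBin(rawpath, "raw", n = n * mha_sizes[[et]])
  }
  signed <- !et %in% c("MET_UCHAR", "MET_USHORT", "MET_UINT")
  vals <- readBin(raw, "integer", n = n, size = mha_sizes[[et]],
                  signed = if (mha_sizes[[et]] < 4) signed else TRUE,
                  endian = "little")
  grid <- array(vals, dim = dims)
  list(grid = grid, spacing = spacing)
}

write_metaimage <- function(lm, path) {
  dims <- dim(lm$grid)
  local_data <- grepl("\\.mha$", path, ignore.case = TRUE)
  datafile <- if (local_data) "LOCAL" else sub("\\.mhd$", ".raw", basename(path))
  hdr <- c(
    "ObjectType = Image",
    paste("NDims =", length(dims)),
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("DimSize =", paste(dims, collapse = " ")),
    paste("ElementSpacing =", paste(format(lm$spacing, digits = 10), collapse = " ")),
    paste("Offset =", paste(format(lm$origin, digits = 10), collapse = " ")),
    "ElementType = MET_SHORT",
    paste("ElementDataFile =", datafile)
  )
  vals <- as.integer(lm$grid)
  if (any(vals < -32768 | vals > 32767)) stop("labels exceed int16 range")
  if (local_data) {
    con <- file(path, "wb")
    writeLines(hdr, con)
    writeBin(vals, con, size = 2L, endian = "little")
    close(con)
  } else {
    writeLines(hdr, path)
    writeBin(vals, file.path(dirname(path), datafile), size = 2L,
             endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an ultrasound image as 8-bit PNG with a metadata sidecar
#'
#' Pixel values in \[0, 1\] are quantized as `round(255 * value)`; a JSON
#' sidecar `<path>.json` records pixel spacing, mode and (optionally) the
#' simulation seed.
#'
#' @param img An [ultrasound_image()].
#' @param path Destination `.png` path.
#' @param seed Optional integer recorded in the sidecar.
#' @return Invisibly, `path`.
#' @export
write_image <- function(img, path, seed = NULL) {
  stopifnot(inherits(img, "ultrasound_image"))
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  png::writePNG(round(255 * img$pixels) / 255, path)
  meta <- list(pixel_spacing = img$pixel_spacing, mode = img$mode,
               size = nrow(img$pixels))
  if (!is.null(seed)) meta$seed <- seed
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
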