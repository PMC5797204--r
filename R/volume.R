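#' Image volumes
#'
#' An `image_volume` is a 3D scalar grid together with the physical geometry
#' needed to place it in space: voxel spacing in mm per axis, the physical
#' coordinate of the first voxel (the origin), and a modality tag.
#'
#' Axis convention used throughout the package:
#' * axis 1 (`x`): patient right-to-left, increasing toward the patient's left;
#' * axis 2 (`y`): inferior-to-superior, increasing toward the head;
#' * axis 3 (`z`): chest-to-back (anterior-to-posterior), so constant-`z`
#'   planes are coronal slices.
#'
#' Voxel centers sit at `origin + (index - 1) * spacing` for 1-based array
#' indices (equivalently `origin + index * spacing` with 0-based indices).
#' All internal geometry (contours, shapes, models) is in physical mm, so a
#' model trained on a CT grid transfers to a SPECT grid with different
#' spacing; rasterization converts back per-volume. CT and SPECT inputs are
#' assumed to share one physical frame (co-registered by the hybrid scanner);
#' the package never resamples one grid onto the other.
#'
#' @param voxels 3D numeric array.
#' @param spacing numeric length-3, voxel spacing in mm; all components > 0.
#' @param origin numeric length-3, physical mm coordinate of voxel (1,1,1).
#' @param modality one of `"CT"`, `"SPECT-V"`, `"SPECT-P"`, `"SUM"`, `"MASK"`.
#'
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                         modality = c("CT", "SPECT-V", "SPECT-P", "SUM", "MASK")) {
  modality <- match.arg(modality)
  if (!is.array(voxels) || length(dim(voxels)) != 3L || length(voxels) == 0L)
    stop("`voxels` must be a non-empty 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite values (mm)")
  if (modality == "MASK" && !all(voxels %in% c(0, 1)))
    stop("MASK volumes may contain only 0 and 1")
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin, modality = modality),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image_volume> %s  %d x %d x %d voxels  spacing %.3g x %.3g x %.3g mm\n",
    x$modality, d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  cat(sprintf("  origin (%.4g, %.4g, %.4g) mm  range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$voxels)

is_binary_mask <- function(vol) all(vol$voxels %in% c(0, 1))

#' Convert between voxel indices and physical coordinates
#'
#' @param vol an `image_volume`.
#' @param idx matrix (n x 3) of 1-based voxel indices (may be fractional).
#' @param mm matrix (n x 3) of physical mm coordinates.
#' @return matrix (n x 3) of the converted coordinates.
#' @export
index_to_mm <- function(vol, idx) {
  idx <- rbind(idx)
  sweep(sweep(idx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' @rdname index_to_mm
#' @export
mm_to_index <- function(vol, mm) {
  mm <- rbind(mm)
  sweep(sweep(mm, 2, vol$origin, "-"), 2, vol$spacing, "/") + 1
}

#' Centers of the grid planes along one axis, in mm
#' @param vol an `image_volume`.
#' @param axis 1, 2 or 3.
#' @return numeric vector of plane-center coordinates.
#' @export
axis_mm <- function(vol, axis) {
  vol$origin[axis] + (seq_len(dim(vol$voxels)[axis]) - 1) * vol$spacing[axis]
}

#' Trilinear interpolation of a volume at physical points
#'
#' Points outside the grid are clamped to the nearest border voxel center
#' (points at the boundary therefore sample the edge value rather than NA),
#' matching how boundary-profile sampling treats out-of-field contour points.
#'
#' @param vol an `image_volume`.
#' @param pts_mm n x 3 matrix of physical coordinates (mm).
#' @return numeric vector of n interpolated values.
#' @export
sample_trilinear <- function(vol, pts_mm) {
  d <- dim(vol$voxels)
  idx <- mm_to_index(vol, pts_mm)
  # clamp to the valid cell range
  for (a in 1:3) idx[, a] <- pmin(pmax(idx[, a], 1), d[a])
  i0 <- pmin(floor(idx), rep(d, each = nrow(idx)) - 1)
  i0 <- pmax(i0, 1)
  f <- idx - i0
  v <- vol$voxels
  at <- function(dx, dy, dz) {
    v[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3]) * at(0, 0, 0) +
    f[, 1] * (1 - f[, 2]) * (1 - f[, 3]) * at(1, 0, 0) +
    (1 - f[, 1]) * f[, 2] * (1 - f[, 3]) * at(0, 1, 0) +
    (1 - f[, 1]) * (1 - f[, 2]) * f[, 3] * at(0, 0, 1) +
    f[, 1] * f[, 2] * (1 - f[, 3]) * at(1, 1, 0) +
    f[, 1] * (1 - f[, 2]) * f[, 3] * at(1, 0, 1) +
    (1 - f[, 1]) * f[, 2] * f[, 3] * at(0, 1, 1) +
    f[, 1] * f[, 2] * f[, 3] * at(1, 1, 1)
}

# ---------------------------------------------------------------------------
# File formats: NIfTI-1 (via RNifti) and MetaImage (.mhd/.mha, minimal
# uncompressed reader/writer -- no installed R package handles MetaImage).

#' Read a medical image volume
#'
#' Supports NIfTI-1 (`.nii`, `.nii.gz`) and uncompressed MetaImage
#' (`.mhd` + `.raw`, or single-file `.mha`). Spacing and origin are taken from
#' the header; a missing or non-positive spacing is an error, never guessed.
#'
#' @param path file path.
#' @param modality_hint modality tag to attach (the formats carry no such tag).
#' @return an `image_volume`.
#' @export
read_volume <- function(path, modality_hint = "CT") {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(sub("^.*?((\\.nii(\\.gz)?)|(\\.mhd)|(\\.mha))$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) == 4L && d[4] == 1L) {
      img <- img[, , , 1]
      d <- dim(img)
    }
    if (length(d) != 3L)
      stop("expected a 3D volume, got ", length(d), "D data in ", path)
    sp <- RNifti::pixdim(img)[1:3]
    if (any(!is.finite(sp)) || any(sp <= 0))
      stop("non-positive voxel spacing in NIfTI header field `pixdim`: ",
           paste(signif(sp, 4), collapse = " x "))
    xf <- RNifti::xform(img)
    org <- as.numeric(xf[1:3, 4])
    image_volume(array(as.numeric(img), d), spacing = as.numeric(sp),
                 origin = org, modality = modality_hint)
  } else if (ext %in% c(".mhd", ".mha")) {
    read_metaimage(path, modality_hint)
  } else {
    stop("unsupported volume format: ", path,
         " (expected .nii, .nii.gz, .mhd or .mha)")
  }
}

#' Write a volume to NIfTI or MetaImage
#'
#' The format is chosen from the file extension. Voxels are stored as
#' float64 and round-trip bit-exactly in both formats; MetaImage headers
#' also carry spacing and origin at full double precision, while the NIfTI-1
#' header stores them as single-precision floats (a format property), so
#' they round-trip to about 7 significant digits there.
#'
#' @param vol an `image_volume`.
#' @param path output path (`.nii`, `.nii.gz`, `.mhd` or `.mha`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  ext <- tolower(sub("^.*?((\\.nii(\\.gz)?)|(\\.mhd)|(\\.mha))$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::asNifti(vol$voxels)
    RNifti::pixdim(img) <- vol$spacing
    xf <- diag(c(vol$spacing, 1))
    xf[1:3, 4] <- vol$origin
    RNifti::`qform<-`(img, structure(xf, code = 2L)) -> img
    RNifti::writeNifti(img, path, datatype = "double")
  } else if (ext %in% c(".mhd", ".mha")) {
    write_metaimage(vol, path)
  } else {
    stop("unsupported volume format: ", path)
  }
  invisible(path)
}

#' Write a binary mask volume
#'
#' @param mask an `image_volume` whose voxels are all 0 or 1.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "image_volume"))
  if (!is_binary_mask(mask)) stop("mask values must all be 0 or 1")
  write_volume(mask, path)
}

# MetaImage: plain-text header; raw little-endian float64 block either in a
# companion .raw file (.mhd) or inline after the header (.mha, LOCAL).
write_metaimage <- function(vol, path) {
  d <- dim(vol$voxels)
  local_data <- grepl("\\.mha$", tolower(path))
  datafile <- if (local_data) "LOCAL" else paste0(basename(sub("\\.mhd$", "", path)), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %.17g %.17g %.17g",
            vol$spacing[1], vol$spacing[2], vol$spacing[3]),
    sprintf("Offset = %.17g %.17g %.17g",
            vol$origin[1], vol$origin[2], vol$origin[3]),
    "ElementType = MET_DOUBLE",
    paste0("ElementDataFile = ", datafile)
  )
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (local_data) {
    writeBin(as.numeric(vol$voxels), con, size = 8, endian = "little")
  } else {
    rawpath <- file.path(dirname(path), datafile)
    rcon <- file(rawpath, "wb")
    writeBin(as.numeric(vol$voxels), rcon, size = 8, endian = "little")
    close(rcon)
  }
  invisible(path)
}

read_metaimage <- function(path, modality_hint) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated MetaImage header in ", path)
    hdr <- c(hdr, line)
    if (grepl("^ElementDataFile", line)) break
  }
  field <- function(name) {
    hit <- grep(paste0("^", name, "\\s*="), hdr, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    trimws(sub("^[^=]*=", "", hit[1]))
  }
  ndims <- field("NDims")
  if (is.null(ndims) || as.integer(ndims) != 3L)
    stop("expected a 3D volume, header field NDims = ", ndims %||% "<missing>")
  d <- as.integer(strsplit(field("DimSize"), "\\s+")[[1]])
  sp_raw <- field("ElementSpacing")
  if (is.null(sp_raw))
    stop("missing voxel spacing: MetaImage header field `ElementSpacing` not found in ", path)
  sp <- as.numeric(strsplit(sp_raw, "\\s+")[[1]])
  if (length(sp) != 3L || any(!is.finite(sp)) || any(sp <= 0))
    stop("non-positive voxel spacing in MetaImage header field `ElementSpacing`: ",
         sp_raw)
  org <- field("Offset")
  org <- if (is.null(org)) c(0, 0, 0) else as.numeric(strsplit(org, "\\s+")[[1]])
  etype <- field("ElementType")
  size <- switch(etype,
                 MET_DOUBLE = 8L, MET_FLOAT = 4L,
                 MET_SHORT = 2L, MET_USHORT = 2L, MET_UCHAR = 1L, MET_CHAR = 1L,
                 stop("unsupported MetaImage ElementType: ", etype))
  what <- if (etype %in% c("MET_DOUBLE", "MET_FLOAT")) "double" else "integer"
  msb <- identical(field("BinaryDataByteOrderMSB"), "True") ||
    identical(field("ElementByteOrderMSB"), "True")
  n <- prod(d)
  datafile <- field("ElementDataFile")
  if (identical(datafile, "LOCAL")) {
    vox <- readBin(con, what, n = n, size = size,
                   endian = if (msb) "big" else "little",
                   signed = !etype %in% c("MET_UCHAR", "MET_USHORT"))
  } else {
    rcon <- file(file.path(dirname(path), datafile), "rb")
    on.exit(close(rcon), add = TRUE)
    vox <- readBin(rcon, what, n = n, size = size,
                   endian = if (msb) "big" else "little",
                   signed = !etype %in% c("MET_UCHAR", "MET_USHORT"))
  }
  if (length(vox) != n) stop("truncated MetaImage data block in ", path)
  image_volume(array(as.numeric(vox), d), spacing = sp, origin = org,
               modality = modality_hint)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
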