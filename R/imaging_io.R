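# CT input/output: DICOM series, NIfTI volumes, PNG slices, HU windowing.
# Voxel arrays are (rows, cols, slices); spacing is (row_mm, col_mm, slice_mm).

#' Construct a CT volume
#'
#' @param voxels 3-D numeric array (rows x cols x slices) of Hounsfield
#'   units, or a 2-D matrix (stored as a single-slice volume).
#' @param spacing numeric length-3 vector (row_mm, col_mm, slice_mm), all > 0.
#'   The default slice thickness of 6 mm matches routine non-contrast head CT.
#' @param patient,series opaque identifier strings.
#' @return Object of class `"ct_volume"`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 6), patient = "", series = "") {
  if (is.matrix(voxels)) voxels <- array(voxels, c(dim(voxels), 1L))
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 2-D or 3-D array", call. = FALSE)
  spacing <- as.double(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive numbers (row_mm, col_mm, slice_mm)",
         call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing,
                 patient = as.character(patient), series = as.character(series)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat("CT volume:", d[1], "x", d[2], "x", d[3], "voxels,",
      "spacing", paste(x$spacing, collapse = " x "), "mm\n")
  cat("HU range:", paste(signif(range(x$voxels), 5), collapse = " .. "), "\n")
  if (nzchar(x$patient)) cat("patient:", x$patient, "\n")
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

# ---- minimal DICOM reader ---------------------------------------------------
# Explicit-VR little-endian part-10 files only: enough for single-frame CT
# slices with the geometry, rescale and pixel-data tags the pipeline uses.

dcm_tag <- function(group, element) sprintf("%04X,%04X", group, element)

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  pos <- 133L
  u16 <- function(at) sum(as.integer(raw[at:(at + 1L)]) * c(1L, 256L))
  u32 <- function(at) sum(as.numeric(raw[at:(at + 3L)]) * c(1, 256, 65536, 16777216))
  elems <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= length(raw)) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("implicit-VR or corrupt DICOM element at byte ", pos, " in ", path,
           call. = FALSE)
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L); pos <- pos + 12L
    } else {
      len <- u16(pos + 6L); pos <- pos + 8L
    }
    if (len > 0 && pos + len - 1L > length(raw))
      stop("truncated DICOM element in ", path, call. = FALSE)
    value <- if (len > 0) raw[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    elems[[dcm_tag(group, element)]] <- list(vr = vr, value = value)
  }
  elems
}

dcm_string <- function(elems, tag, default = NULL) {
  e <- elems[[tag]]
  if (is.null(e)) return(default)
  trimws(rawToChar(e$value))
}

dcm_numeric <- function(elems, tag, default = NULL) {
  s <- dcm_string(elems, tag)
  if (is.null(s) || !nzchar(s)) return(default)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_uint16 <- function(elems, tag, default = NULL) {
  e <- elems[[tag]]
  if (is.null(e)) return(default)
  readBin(e$value, "integer", n = 1, size = 2, signed = FALSE,
          endian = "little")
}

dcm_pixels <- function(elems, rows, cols, signed) {
  e <- elems[["7FE0,0010"]]
  if (is.null(e)) stop("DICOM file has no pixel data", call. = FALSE)
  v <- readBin(e$value, "integer", n = rows * cols, size = 2,
               signed = signed, endian = "little")
  if (!signed) v <- as.integer(v)
  matrix(v, nrow = rows, ncol = cols, byrow = TRUE)  # DICOM is row-major
}

#' Read a DICOM series into a CT volume
#'
#' Reads every file in `directory` as an explicit-VR little-endian DICOM
#' slice, checks that all slices belong to one series with consistent
#' geometry, sorts them by position along the slice axis, applies the rescale
#' slope/intercept to produce Hounsfield units, and assembles a
#' [ct_volume()]. Missing rescale tags produce a warning and are treated as
#' identity.
#'
#' @param directory path to a directory holding exactly one series.
#' @return A [ct_volume()].
#' @export
read_dicom_series <- function(directory) {
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("no files in ", directory, call. = FALSE)
  parsed <- lapply(files, read_dicom_file)

  series <- vapply(parsed, dcm_string, "", tag = "0020,000E", default = "")
  if (length(unique(series)) > 1)
    stop("directory mixes multiple DICOM series", call. = FALSE)
  rows <- vapply(parsed, dcm_uint16, 0L, tag = "0028,0010")
  cols <- vapply(parsed, dcm_uint16, 0L, tag = "0028,0011")
  if (length(unique(rows)) > 1 || length(unique(cols)) > 1)
    stop("inconsistent slice dimensions within series", call. = FALSE)

  zpos <- vapply(parsed, function(e) {
    ipp <- dcm_numeric(e, "0020,0032")
    if (!is.null(ipp) && length(ipp) >= 3) ipp[3]
    else dcm_numeric(e, "0020,0013", default = NA_real_)[1]  # InstanceNumber
  }, 0)
  ord <- order(zpos)
  parsed <- parsed[ord]; zpos <- zpos[ord]

  slices <- lapply(parsed, function(e) {
    slope <- dcm_numeric(e, "0028,1053")
    intercept <- dcm_numeric(e, "0028,1052")
    if (is.null(slope) || is.null(intercept)) {
      warning("missing rescale slope/intercept; assuming identity",
              call. = FALSE)
      slope <- 1; intercept <- 0
    }
    signed <- isTRUE(dcm_uint16(e, "0028,0103", default = 0L) == 1L)
    px <- dcm_pixels(e, rows[1], cols[1], signed)
    slope * px + intercept
  })

  ps <- dcm_numeric(parsed[[1]], "0028,0030", default = c(1, 1))
  thick <- dcm_numeric(parsed[[1]], "0018,0050", default = 6)[1]
  if (length(slices) > 1) {
    dz <- diff(zpos)
    if (all(is.finite(dz)) && all(dz > 0)) thick <- stats::median(dz)
  }
  vox <- array(unlist(slices), c(rows[1], cols[1], length(slices)))
  ct_volume(vox, spacing = c(ps[1], ps[2], thick),
            patient = dcm_string(parsed[[1]], "0010,0020", default = ""),
            series = series[1])
}

# ---- NIfTI ------------------------------------------------------------------

#' Read a NIfTI volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return A [ct_volume()] carrying the voxel spacing from the header.
#' @export
read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  arr <- array(as.vector(arr), dim(arr))  # drop RNifti header attributes
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3) pd <- c(pd, rep(1, 3 - length(pd)))
  ct_volume(arr, spacing = pd[1:3])
}

#' Write a CT volume to NIfTI
#'
#' Lossless round trip of voxels and spacing; a 2-D matrix is stored as a
#' single-slice volume.
#'
#' @param volume a [ct_volume()], 3-D array or 2-D matrix.
#' @param path output `.nii` or `.nii.gz` file.
#' @param spacing used when `volume` is a bare array.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(volume, path, spacing = c(1, 1, 6)) {
  if (!inherits(volume, "ct_volume")) volume <- ct_volume(volume, spacing)
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- HU windowing -----------------------------------------------------------

#' CT display window
#'
#' @param level window center in HU.
#' @param width window span in HU (> 0).
#' @return Object of class `"window_spec"`.
#' @export
window_spec <- function(level, width) {
  if (width <= 0) stop("window width must be > 0", call. = FALSE)
  structure(list(level = level, width = width), class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat("CT window: level", x$level, "HU, width", x$width, "HU\n")
  invisible(x)
}

#' @rdname window_spec
#' @export
brain_window <- function() window_spec(40, 120)

#' @rdname window_spec
#' @export
skull_window <- function() window_spec(700, 120)

resolve_window <- function(window) {
  if (inherits(window, "window_spec")) return(window)
  if (is.character(window))
    return(switch(window,
                  brain = brain_window(),
                  skull = skull_window(),
                  stop("unknown window preset: ", window, call. = FALSE)))
  if (is.numeric(window) && length(window) == 2)
    return(window_spec(window[1], window[2]))
  stop("window must be a window_spec, preset name, or (level, width) pair",
       call. = FALSE)
}

#' Apply an HU display window
#'
#' Linearly maps the interval \[level - width/2, level + width/2\] to
#' \[0, 1\], clipping outside; monotone non-decreasing in HU.
#'
#' @param x HU values: matrix, array or [ct_volume()].
#' @param window a [window_spec()], a preset name (`"brain"` = 40/120,
#'   `"skull"` = 700/120), or a `c(level, width)` pair.
#' @return Same shape as the input, values in \[0, 1\].
#' @export
apply_window <- function(x, window = "brain") {
  w <- resolve_window(window)
  v <- if (inherits(x, "ct_volume")) x$voxels else x
  out <- (v - (w$level - w$width / 2)) / w$width
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Dual-window composite of a CT slice
#'
#' Stacks the brain-window and skull-window renderings of a slice as a
#' 2-channel image (channel 1 brain, channel 2 skull), the composite format
#' used for windowed hemorrhage CT; clustering consumes channel 1.
#'
#' @param slice_hu 2-D matrix of HU values.
#' @return rows x cols x 2 array in \[0, 1\].
#' @export
window_composite <- function(slice_hu) {
  stopifnot(is.matrix(slice_hu))
  out <- array(0, c(dim(slice_hu), 2L))
  out[, , 1] <- apply_window(slice_hu, "brain")
  out[, , 2] <- apply_window(slice_hu, "skull")
  out
}

# ---- PNG --------------------------------------------------------------------

#' Write a [0,1] image to 8-bit grayscale PNG
#'
#' @param grid numeric matrix with values in \[0, 1\].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
to_png <- function(grid, path) {
  stopifnot(is.matrix(grid))
  g <- pmin(pmax(grid, 0), 1)
  png::writePNG(g, path)
  invisible(path)
}

#' Read an 8-bit grayscale PNG as a [0,1] matrix
#'
#' Round trip through [to_png()] is exact to within the 8-bit quantization
#' step (1/510).
#'
#' @param path PNG file.
#' @return Numeric matrix in \[0, 1\].
#' @export
from_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}
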