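# Synthetic brain-CT phantom: skull ring enclosing CSF / gray / white matter
# with an optional hyperdense hemorrhage blob, in calibrated HU, with exact
# ground-truth labels. Supplies reproducible inputs for every other module.

#' Phantom tissue classes
#'
#' Integer truth codes, ordered by tissue HU so that `code + 1` equals the
#' cluster index a correct intensity clustering assigns (cluster 1 = darkest).
#'
#' @return Named integer vector: air 0, csf 1, white 2, gray 3, hemorrhage 4,
#'   bone 5.
#' @export
phantom_classes <- function() {
  c(air = 0L, csf = 1L, white = 2L, gray = 3L, hemorrhage = 4L, bone = 5L)
}

#' Specify a synthetic brain-CT phantom
#'
#' Tissue HU means default to standard radiology ranges and respect the
#' diagnostic ordering CSF < white < gray < hemorrhage < bone that makes
#' blood separable by intensity clustering.
#'
#' @param size image side in pixels (default 512).
#' @param hu named tissue means in HU (`air`, `csf`, `white`, `gray`,
#'   `hemorrhage`, `bone`).
#' @param lesion `NULL` for no hemorrhage, or a list with elements
#'   `area_px` (target area in pixels), `center` (row, col; default in the
#'   deep white matter), `shape` (`"ellipse"` or `"blob"`),
#'   `eccentricity` (axis ratio, default 1) and `blob_amp` (boundary
#'   perturbation amplitude for blobs, default 0.15).
#' @param gaussian_sd additive Gaussian noise, HU (default 0).
#' @param salt_pepper fraction of pixels replaced by extreme values
#'   (default 0; half salt at +1000 HU, half pepper at -1000 HU).
#' @param spacing voxel spacing (row_mm, col_mm, slice_mm), default
#'   `c(1, 1, 6)` -- 6 mm is a routine head-CT slice thickness.
#' @param seed integer seed controlling noise and blob shape.
#' @return Object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(size = 512,
                         hu = c(air = -1000, csf = 8, white = 28, gray = 38,
                                hemorrhage = 65, bone = 600),
                         lesion = NULL, gaussian_sd = 0, salt_pepper = 0,
                         spacing = c(1, 1, 6), seed = NULL) {
  need <- c("air", "csf", "white", "gray", "hemorrhage", "bone")
  if (!all(need %in% names(hu)))
    stop("hu must name all of: ", paste(need, collapse = ", "), call. = FALSE)
  ord <- hu[c("csf", "white", "gray", "hemorrhage", "bone")]
  if (is.unsorted(ord, strictly = TRUE))
    stop("tissue means must be strictly ordered csf < white < gray < ",
         "hemorrhage < bone", call. = FALSE)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  if (salt_pepper < 0 || salt_pepper > 1)
    stop("salt_pepper must be a fraction in [0, 1]", call. = FALSE)
  structure(list(size = as.integer(size), hu = hu, lesion = lesion,
                 gaussian_sd = gaussian_sd, salt_pepper = salt_pepper,
                 spacing = as.double(spacing), seed = seed),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Brain phantom spec:", x$size, "x", x$size, "px,",
      if (is.null(x$lesion)) "no lesion" else
        paste0("lesion ~", x$lesion$area_px, " px"),
      "\n  noise: gaussian", x$gaussian_sd, "HU, salt-pepper",
      x$salt_pepper, "\n")
  invisible(x)
}

# Radial fractions (of size/2) delimiting the concentric head regions.
# CSF is modeled as paramedian ventricle ellipses inside the white matter
# (the dominant CSF space on axial head CT) rather than a sub-voxel
# subarachnoid rim.
phantom_radii <- list(skull_outer = 0.92, skull_inner = 0.82,
                      gray_inner = 0.60)

# Normalized elliptical radius of every pixel from the head center.
head_rho <- function(size) {
  ctr <- (size + 1) / 2
  half <- size / 2
  r <- matrix(rep(seq_len(size), size), size)
  c_ <- matrix(rep(seq_len(size), each = size), size)
  sqrt(((r - ctr) / (0.94 * half))^2 + ((c_ - ctr) / half)^2)
}

# Rasterize a lesion boundary r(phi) at a center; returns logical mask.
lesion_mask_from_radius <- function(size, center, rfun) {
  r <- matrix(rep(seq_len(size), size), size) - center[1]
  c_ <- matrix(rep(seq_len(size), each = size), size) - center[2]
  rho <- sqrt(r^2 + c_^2)
  phi <- atan2(c_, r)
  rho <= rfun(phi)
}

#' Generate one phantom CT slice with ground truth
#'
#' Builds the label map -- a skull ring enclosing a gray-matter cortex and a
#' white-matter interior, with CSF as two paramedian ventricle ellipses and
#' the optional hemorrhage blob in the parenchyma -- assigns the tissue HU
#' means, and adds seeded noise to the HU image only; the truth labels stay
#' exact. Blob lesions perturb an ellipse boundary with a seeded
#' smooth harmonic series, emulating the unclear, incomplete hemorrhage edges
#' seen on real CT; the boundary radius is rescaled analytically so the
#' rasterized area stays within a couple of percent of the request.
#'
#' @param spec a [phantom_spec()].
#' @return List with `hu` (matrix, HU), `labels` (integer truth matrix, codes
#'   from [phantom_classes()]), and `spec`.
#' @export
generate_slice <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(spec$seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
  }
  size <- spec$size
  rho <- head_rho(size)
  cls <- phantom_classes()
  rad <- phantom_radii
  labels <- matrix(cls[["air"]], size, size)
  labels[rho <= rad$skull_outer] <- cls[["bone"]]
  labels[rho <= rad$skull_inner] <- cls[["gray"]]
  labels[rho <= rad$gray_inner] <- cls[["white"]]

  # lateral ventricles: two CSF ellipses above the head center
  ctr <- (size + 1) / 2
  rr <- matrix(rep(seq_len(size), size), size)
  cc <- matrix(rep(seq_len(size), each = size), size)
  for (s in c(-1, 1)) {
    vr <- ctr - 0.12 * size
    vc <- ctr + s * 0.16 * size
    vent <- ((rr - vr) / (0.045 * size))^2 + ((cc - vc) / (0.10 * size))^2 <= 1
    labels[vent & labels == cls[["white"]]] <- cls[["csf"]]
  }

  if (!is.null(spec$lesion)) {
    les <- spec$lesion
    if (is.null(les$area_px) || les$area_px <= 0)
      stop("lesion$area_px must be positive", call. = FALSE)
    ctr <- if (!is.null(les$center)) les$center
    else (size + 1) / 2 + c(0.14, 0.04) * size
    shape <- if (is.null(les$shape)) "ellipse" else les$shape
    ecc <- if (is.null(les$eccentricity)) 1 else les$eccentricity
    amp <- if (is.null(les$blob_amp)) 0.15 else les$blob_amp
    if (shape == "blob") {
      co <- rnorm(8, 0, 1) / (2:9)  # decaying harmonics, seeded
      gfun <- function(phi) {
        pert <- co[1] * cos(2 * phi) + co[2] * sin(2 * phi) +
          co[3] * cos(3 * phi) + co[4] * sin(3 * phi) +
          co[5] * cos(4 * phi) + co[6] * sin(4 * phi) +
          co[7] * cos(5 * phi) + co[8] * sin(5 * phi)
        pmax(1 + amp * pert, 0.2)
      }
    } else {
      gfun <- function(phi)
        1 / sqrt(cos(phi)^2 / ecc + sin(phi)^2 * ecc)
    }
    # area enclosed by r = r0 g(phi) is r0^2/2 * int g^2, solve for r0
    phi_grid <- seq(-pi, pi, length.out = 721)[-1]
    int_g2 <- sum(gfun(phi_grid)^2) * (2 * pi / 720)
    r0 <- sqrt(2 * les$area_px / int_g2)
    mask <- lesion_mask_from_radius(size, ctr, function(phi) r0 * gfun(phi))
    brain <- labels == cls[["white"]] | labels == cls[["gray"]]
    if (any(mask & !brain))
      stop("lesion extends outside the brain parenchyma", call. = FALSE)
    labels[mask] <- cls[["hemorrhage"]]
  }

  mean_of <- c(spec$hu[["air"]], spec$hu[["csf"]], spec$hu[["white"]],
               spec$hu[["gray"]], spec$hu[["hemorrhage"]], spec$hu[["bone"]])
  hu <- matrix(mean_of[labels + 1L], size, size)
  if (spec$gaussian_sd > 0)
    hu <- hu + rnorm(length(hu), 0, spec$gaussian_sd)
  if (spec$salt_pepper > 0) {
    n_noise <- round(spec$salt_pepper * length(hu))
    idx <- sample.int(length(hu), n_noise)
    half <- seq_len(n_noise) <= n_noise / 2
    hu[idx[half]] <- 1000
    hu[idx[!half]] <- -1000
  }
  list(hu = hu, labels = labels, spec = spec)
}

#' Generate a multi-slice phantom volume with a lesion of known volume
#'
#' The hemorrhage spans a contiguous range of slices with an ellipsoidal
#' through-slice area profile sized so the rasterized truth volume lands on
#' `target_ml`. The exact truth volume is recomputed from the truth masks and
#' the voxel spacing, so volume-recovery tests compare against rasterized
#' truth, not the nominal target.
#'
#' @param spec a [phantom_spec()] (its `lesion` field, if any, is replaced by
#'   the per-slice lesions derived from `target_ml`).
#' @param n_slices number of slices (default 10).
#' @param target_ml target hemorrhage volume in mL; 0 or `NULL` for none.
#' @param lesion_slices how many central slices the lesion spans (default
#'   `max(3, n_slices %/% 2)`).
#' @return List with `volume` (a [ct_volume()]), `truth` (integer label
#'   array), `truth_ml` (exact rasterized lesion volume), `target_ml`.
#' @export
generate_volume <- function(spec, n_slices = 10, target_ml = NULL,
                            lesion_slices = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_slices < 1) stop("n_slices must be >= 1", call. = FALSE)
  if (is.null(target_ml)) target_ml <- 0
  if (is.null(lesion_slices)) lesion_slices <- max(3L, n_slices %/% 2L)
  lesion_slices <- min(lesion_slices, n_slices)

  vox_mm3 <- prod(spec$spacing)
  target_vox <- target_ml * 1000 / vox_mm3
  # ellipsoid profile over k central slices: area_j proportional to 1 - z^2
  k <- lesion_slices
  z <- ((seq_len(k)) - (k + 1) / 2) / ((k + 1) / 2)
  prof <- 1 - z^2
  areas <- if (target_vox > 0) target_vox * prof / sum(prof) else rep(0, k)
  first <- (n_slices - k) %/% 2L + 1L
  slice_area <- rep(0, n_slices)
  slice_area[first:(first + k - 1L)] <- areas

  hu <- array(0, c(spec$size, spec$size, n_slices))
  truth <- array(0L, c(spec$size, spec$size, n_slices))
  base_seed <- if (is.null(spec$seed)) 0 else spec$seed
  for (j in seq_len(n_slices)) {
    les <- if (slice_area[j] >= 4) {
      l <- if (is.null(spec$lesion)) list() else spec$lesion
      l$area_px <- slice_area[j]
      l
    } else NULL
    sl <- generate_slice(phantom_spec(
      size = spec$size, hu = spec$hu, lesion = les,
      gaussian_sd = spec$gaussian_sd, salt_pepper = spec$salt_pepper,
      spacing = spec$spacing, seed = base_seed + j))
    hu[, , j] <- sl$hu
    truth[, , j] <- sl$labels
  }
  truth_ml <- sum(truth == phantom_classes()[["hemorrhage"]]) * vox_mm3 / 1000
  list(volume = ct_volume(hu, spec$spacing), truth = truth,
       truth_ml = truth_ml, target_ml = target_ml)
}
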