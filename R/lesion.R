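# Hemorrhage extraction from clustered label maps and volume quantification.

#' Select the hemorrhage cluster of a label map
#'
#' Acute blood is hyperdense relative to brain tissue but hypodense relative
#' to bone, so among the clusters whose pixels lie mostly inside the
#' intracranial mask the hemorrhage is the brightest one. Starting from the
#' brightest cluster (clusters are ordered by ascending center intensity),
#' the first cluster with at least half of its pixels inside the mask is
#' returned; the skull and background clusters fail that test. If no cluster
#' qualifies the result is 0 (no lesion), not an error.
#'
#' @param labels integer label matrix or array (1..f, ascending center
#'   order).
#' @param centers numeric vector of cluster centers, ascending.
#' @param intracranial logical mask (see [extract_intracranial()]); `NULL`
#'   treats the whole image as intracranial.
#' @return Cluster index, or 0 when no cluster qualifies.
#' @export
select_hemorrhage_cluster <- function(labels, centers, intracranial = NULL) {
  stopifnot(is.array(labels) || is.matrix(labels))
  if (is.unsorted(centers)) stop("centers must be ascending", call. = FALSE)
  if (is.null(intracranial))
    intracranial <- array(TRUE, dim(labels))
  check_same_shape(labels, intracranial)
  for (k in rev(seq_along(centers))) {
    npx <- sum(labels == k)
    if (npx == 0) next
    if (sum(labels == k & intracranial) / npx >= 0.5) return(k)
  }
  0L
}

#' Region-growing extraction of a labeled cluster
#'
#' Grows the seed cluster over connected pixels of the classified image:
#' connected components (8-connectivity by default) of the pixels carrying
#' `seed_cluster`'s label, discarding components smaller than `min_area_px`
#' (which removes the speckle "pseudo-spots" clustering leaves behind).
#'
#' @param labels integer label matrix.
#' @param seed_cluster cluster index to grow; 0 yields an empty mask.
#' @param connectivity 4 or 8 (default 8).
#' @param min_area_px minimum component area in pixels (default 10).
#' @return Object of class `"lesion_mask"`: logical `mask`, integer
#'   `components` (labelled), numeric `areas` (per retained component).
#' @export
region_grow <- function(labels, seed_cluster, connectivity = 8,
                        min_area_px = 10) {
  stopifnot(is.matrix(labels))
  sel <- labels == seed_cluster & seed_cluster > 0
  comp <- label_components(sel, connectivity)
  if (max(comp) > 0) {
    areas <- tabulate(comp[comp > 0])
    drop_ids <- which(areas < min_area_px)
    comp[comp %in% drop_ids] <- 0L
    keep_ids <- which(areas >= min_area_px)
    comp <- matrix(match(comp, keep_ids, nomatch = 0L), nrow(labels))
    areas <- areas[keep_ids]
  } else {
    areas <- numeric(0)
  }
  structure(list(mask = comp > 0, components = comp, areas = areas,
                 connectivity = connectivity, min_area_px = min_area_px),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat("Lesion mask:", sum(x$mask), "pixels in", length(x$areas),
      "component(s)\n")
  invisible(x)
}

#' Threshold a hemorrhage probability map
#'
#' A voxel is hemorrhagic when its predicted probability strictly exceeds
#' 0.5; exactly 0.5 is classified as normal. For fuzzy C-means outputs the
#' probability is the (column-stochastic) membership of the hemorrhage
#' cluster.
#'
#' @param probability numeric array/matrix with values in \[0, 1\].
#' @return Logical mask of the same shape.
#' @export
classify_voxels <- function(probability) {
  if (any(probability < 0 | probability > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  probability > 0.5
}

#' Hemorrhage volume from a mask stack
#'
#' Voxel count times voxel volume:
#' volume_ml = n_voxels * row_mm * col_mm * slice_mm / 1000. Additive over
#' disjoint masks and linear in the slice thickness.
#'
#' @param masks logical 3-D array, 2-D matrix (single slice), list of slice
#'   masks, or a `"lesion_mask"`.
#' @param spacing numeric (row_mm, col_mm, slice_mm), all > 0; required.
#' @return Volume in milliliters.
#' @export
compute_volume <- function(masks, spacing) {
  if (missing(spacing) || is.null(spacing))
    stop("voxel spacing is required to compute a volume", call. = FALSE)
  spacing <- as.double(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive numbers", call. = FALSE)
  n <- if (inherits(masks, "lesion_mask")) sum(masks$mask)
  else if (is.list(masks)) sum(vapply(masks, function(m) sum(m != 0), 0))
  else sum(masks != 0)
  n * prod(spacing) / 1000
}

#' Volume stratum of a hemorrhage
#'
#' Clinical reporting bins: `"<5 mL"`, `"5-25 mL"`, `">25 mL"`.
#'
#' @param volume_ml volume in milliliters.
#' @return Character stratum label.
#' @export
volume_stratum <- function(volume_ml) {
  ifelse(volume_ml < 5, "<5 mL", ifelse(volume_ml <= 25, "5-25 mL", ">25 mL"))
}
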