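# End-to-end pipeline functions: these are what the command-line wrapper in
# inst/scripts/fuzzyct calls, and what scripted analyses use directly.

fuzzyct_format_error <- function(msg) {
  stop(structure(class = c("fuzzyct_format_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# Load any supported input as a ct_volume. PNG slices carry no HU calibration
# and are flagged as pre-windowed.
load_ct_input <- function(input) {
  if (dir.exists(input))
    return(list(volume = read_dicom_series(input), windowed = FALSE))
  if (!file.exists(input))
    fuzzyct_format_error(paste0("input not found: ", input))
  if (grepl("\\.nii(\\.gz)?$", input))
    return(list(volume = read_nifti(input), windowed = FALSE))
  if (grepl("\\.(png|PNG)$", input)) {
    img <- from_png(input)
    return(list(volume = ct_volume(img, c(1, 1, 6)), windowed = TRUE))
  }
  fuzzyct_format_error(paste0("unsupported input format: ", input))
}

#' Segment a CT input into a tissue label map
#'
#' Runs the full slice pipeline: HU windowing, optional intracranial
#' extraction (skull stripping), fuzzy clustering (standard or improved FCM)
#' and defuzzification to a label map with clusters in ascending intensity
#' order. When `output` is given, the label map is written (NIfTI for
#' volumes, PNG for a single slice written to a `.png` path) together with a
#' JSON sidecar recording the configuration, the fitted centers, iteration
#' counts and cluster validity indices.
#'
#' @param input a DICOM series directory, a `.nii`/`.nii.gz` volume, or an
#'   8-bit grayscale `.png` slice (treated as already windowed).
#' @param output optional output path (`.nii`, `.nii.gz` or `.png`); the
#'   sidecar is written next to it with extension `.json`.
#' @param algorithm `"ifcm"` (default) or `"fcm"`.
#' @param clusters number of clusters (default 6: air, CSF, white, gray,
#'   hemorrhage, bone).
#' @param window HU window (see [apply_window()]); ignored for PNG input.
#' @param skull_strip mask each slice to the intracranial region before
#'   clustering (requires HU-calibrated input).
#' @param seed integer seed.
#' @param ... further arguments passed to [ifcm()] or [fcm()].
#' @return Invisibly, a list with `labels` (integer array), `fit` (the model
#'   object), `sidecar` (list), `volume` (the input [ct_volume()]), and
#'   `intracranial` (mask array or NULL).
#' @export
segment_file <- function(input, output = NULL, algorithm = c("ifcm", "fcm"),
                         clusters = 6, window = "brain", skull_strip = FALSE,
                         seed = 1, ...) {
  algorithm <- match.arg(algorithm)
  loaded <- load_ct_input(input)
  vol <- loaded$volume
  n_slices <- dim(vol$voxels)[3]
  gray <- if (loaded$windowed) vol$voxels else apply_window(vol$voxels, window)
  intracranial <- NULL
  if (skull_strip && !loaded$windowed) {
    intracranial <- array(FALSE, dim(vol$voxels))
    for (j in seq_len(n_slices))
      intracranial[, , j] <- extract_intracranial(vol$voxels[, , j])
    gray[!intracranial] <- 0
  }
  fit <- if (algorithm == "ifcm")
    ifcm(gray, clusters = clusters, seed = seed, ...)
  else
    fcm(gray, clusters = clusters, seed = seed, ...)
  labels <- array(as.integer(fitted(fit)), dim(vol$voxels))
  sidecar <- list(
    algorithm = algorithm, clusters = clusters,
    window = if (loaded$windowed) "pre-windowed" else window,
    skull_strip = skull_strip, seed = seed,
    centers = as.vector(coef(fit)),
    iterations = fit$iterations,
    converged = fit$converged,
    validity = list(
      vpc = partition_coefficient(fit$membership,
                                  if (inherits(fit, "ifcm")) fit$sample_weights),
      vpe = partition_entropy(fit$membership,
                              if (inherits(fit, "ifcm")) fit$sample_weights))
  )
  if (!is.null(output)) {
    if (grepl("\\.(png|PNG)$", output)) {
      if (n_slices != 1)
        stop("PNG output requires a single-slice input", call. = FALSE)
      to_png(labels[, , 1] / max(1, clusters), output)
    } else {
      write_nifti(ct_volume(labels, vol$spacing), output)
    }
    jsonlite::write_json(sidecar, sub("\\.[a-zA-Z.]+$", ".json", output),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(labels = labels, fit = fit, sidecar = sidecar,
                 volume = vol, intracranial = intracranial))
}

#' Extract the hemorrhage mask stack from a segmented volume
#'
#' Per slice: select the hemorrhage cluster ([select_hemorrhage_cluster()])
#' and grow it into a speckle-filtered mask ([region_grow()]).
#'
#' @param labels integer label array (rows x cols x slices) or matrix.
#' @param centers ascending cluster centers shared by the slices (a list of
#'   per-slice centers is also accepted).
#' @param intracranial optional logical mask array matching `labels`.
#' @param connectivity,min_area_px see [region_grow()].
#' @return Logical array of hemorrhage voxels.
#' @export
extract_lesion <- function(labels, centers, intracranial = NULL,
                           connectivity = 8, min_area_px = 10) {
  if (is.matrix(labels)) labels <- array(labels, c(dim(labels), 1L))
  if (!is.null(intracranial) && is.matrix(intracranial))
    intracranial <- array(intracranial, c(dim(intracranial), 1L))
  out <- array(FALSE, dim(labels))
  for (j in seq_len(dim(labels)[3])) {
    ctr <- if (is.list(centers)) centers[[j]] else centers
    msk <- if (is.null(intracranial)) NULL else intracranial[, , j]
    k <- select_hemorrhage_cluster(labels[, , j], ctr, msk)
    if (k > 0)
      out[, , j] <- region_grow(labels[, , j], k, connectivity,
                                min_area_px)$mask
  }
  out
}

#' Segment, extract and quantify a hemorrhage in one call
#'
#' The full volumetric pipeline: window each slice, strip the skull, cluster
#' (improved FCM by default), select and grow the hemorrhage cluster, and
#' convert the voxel count to milliliters with the volume's spacing.
#'
#' @param volume a [ct_volume()] in HU.
#' @param algorithm `"ifcm"` (default) or `"fcm"`.
#' @param clusters number of clusters; default 5 for skull-stripped volumes
#'   (background, CSF, white, gray, hemorrhage) and 6 otherwise (plus bone).
#' @param seed integer seed.
#' @param skull_strip mask slices to the intracranial region (default TRUE).
#' @param min_area_px speckle filter for [region_grow()] (default 10).
#' @param ... passed to the clustering fit.
#' @return List with `volume_ml`, `mask` (logical array), `labels`, `fit`
#'   (the pooled model object), `hemorrhage_cluster` (0 when none selected).
#' @export
quantify_hemorrhage <- function(volume, algorithm = c("ifcm", "fcm"),
                                clusters = NULL, seed = 1, skull_strip = TRUE,
                                min_area_px = 10, ...) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(volume, "ct_volume"))
  # a stripped volume has one intensity class fewer (no bone)
  if (is.null(clusters)) clusters <- if (skull_strip) 5 else 6
  n_slices <- dim(volume$voxels)[3]
  gray <- apply_window(volume$voxels, "brain")
  icm <- NULL
  if (skull_strip) {
    icm <- array(FALSE, dim(volume$voxels))
    for (j in seq_len(n_slices))
      icm[, , j] <- extract_intracranial(volume$voxels[, , j])
    gray[!icm] <- 0
  }
  # one pooled fit over the whole stack: a single consistent center set, so
  # the hemorrhage cluster exists volume-wide and is simply absent from
  # lesion-free slices
  fit <- if (algorithm == "ifcm")
    ifcm(gray, clusters = clusters, seed = seed, ...)
  else
    fcm(gray, clusters = clusters, seed = seed, ...)
  labels <- array(as.integer(fitted(fit)), dim(volume$voxels))
  k <- select_hemorrhage_cluster(labels, as.vector(coef(fit)), icm)
  mask <- array(FALSE, dim(volume$voxels))
  if (k > 0)
    for (j in seq_len(n_slices))
      mask[, , j] <- region_grow(labels[, , j], k, 8, min_area_px)$mask
  list(volume_ml = compute_volume(mask, volume$spacing), mask = mask,
       labels = labels, fit = fit, hemorrhage_cluster = k)
}

#' Per-case lesion volume report
#'
#' @param mask logical hemorrhage array.
#' @param spacing voxel spacing (row_mm, col_mm, slice_mm).
#' @param case case identifier.
#' @param output_csv optional path to append/write the CSV report.
#' @return One-row data frame: case, slices, voxels, volume_ml, stratum.
#' @export
lesion_report <- function(mask, spacing, case = "case", output_csv = NULL) {
  if (is.matrix(mask)) mask <- array(mask, c(dim(mask), 1L))
  vol <- compute_volume(mask, spacing)
  df <- data.frame(case = case,
                   slices = sum(apply(mask, 3, any)),
                   voxels = sum(mask),
                   volume_ml = vol,
                   stratum = volume_stratum(vol),
                   stringsAsFactors = FALSE)
  if (!is.null(output_csv))
    utils::write.table(df, output_csv, sep = ",", row.names = FALSE,
                       col.names = !file.exists(output_csv),
                       append = file.exists(output_csv))
  df
}

#' Evaluate predicted masks against ground truth
#'
#' Pairs prediction and truth by name (file name for directories of PNG
#' masks, list names for in-memory lists), computes Dice, RMSE, precision,
#' sensitivity and specificity per case, and appends aggregate mean and sd
#' rows. Unpaired cases are listed in a warning and skipped.
#'
#' @param pred,truth directories of PNG masks, or named lists of binary
#'   matrices.
#' @param output_csv optional CSV path.
#' @return Data frame of per-case and aggregate metric rows.
#' @export
evaluate_masks <- function(pred, truth, output_csv = NULL) {
  read_side <- function(x) {
    if (is.character(x) && length(x) == 1 && dir.exists(x)) {
      files <- list.files(x, pattern = "\\.png$", full.names = TRUE)
      masks <- lapply(files, function(f) from_png(f) > 0.5)
      names(masks) <- basename(files)
      masks
    } else if (is.list(x)) {
      if (is.null(names(x))) names(x) <- as.character(seq_along(x))
      x
    } else stop("pred/truth must be directories or named lists", call. = FALSE)
  }
  p <- read_side(pred); r <- read_side(truth)
  common <- intersect(names(p), names(r))
  extra <- setdiff(union(names(p), names(r)), common)
  if (length(extra) > 0)
    warning("unpaired cases skipped: ", paste(extra, collapse = ", "),
            call. = FALSE)
  if (length(common) == 0) stop("no paired cases to evaluate", call. = FALSE)
  rows <- lapply(common, function(nm) {
    pss <- precision_sensitivity_specificity(pred = p[[nm]], truth = r[[nm]])
    data.frame(case = nm, dice = dice(p[[nm]], r[[nm]]),
               rmse = rmse(p[[nm]], r[[nm]]),
               precision = pss[["precision"]],
               sensitivity = pss[["sensitivity"]],
               specificity = pss[["specificity"]],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  agg <- function(fun, label) data.frame(
    case = label, dice = fun(df$dice), rmse = fun(df$rmse),
    precision = fun(df$precision), sensitivity = fun(df$sensitivity),
    specificity = fun(df$specificity), stringsAsFactors = FALSE)
  df <- rbind(df, agg(function(v) mean(v, na.rm = TRUE), "mean"),
              agg(function(v) sd(v, na.rm = TRUE), "sd"))
  if (!is.null(output_csv))
    utils::write.csv(df, output_csv, row.names = FALSE)
  df
}

#' Generate a phantom cohort across the clinical volume strata
#'
#' One phantom volume per requested target, covering the small (<5 mL),
#' medium (5-25 mL) and large (>25 mL) hemorrhage strata.
#'
#' @param targets_ml target volumes, one phantom each
#'   (default `c(3, 15, 40)`).
#' @param size slice side in pixels (default 128).
#' @param n_slices slices per volume (default 10).
#' @param gaussian_sd,salt_pepper noise settings (defaults 3 HU, 0).
#' @param seed integer base seed.
#' @param dir optional directory: writes each phantom as NIfTI + truth mask
#'   NIfTI + a JSON manifest.
#' @return List of [generate_volume()] results, names by stratum.
#' @export
phantom_cohort <- function(targets_ml = c(3, 15, 40), size = 128,
                           n_slices = 10, gaussian_sd = 3, salt_pepper = 0,
                           seed = 1, dir = NULL) {
  out <- lapply(seq_along(targets_ml), function(i) {
    spec <- phantom_spec(size = size, gaussian_sd = gaussian_sd,
                         salt_pepper = salt_pepper,
                         seed = seed + 1000L * i)
    generate_volume(spec, n_slices = n_slices, target_ml = targets_ml[i])
  })
  names(out) <- volume_stratum(targets_ml)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(out)) {
      write_nifti(out[[i]]$volume, file.path(dir, sprintf("phantom%02d.nii", i)))
      write_nifti(ct_volume(out[[i]]$truth + 0,
                            out[[i]]$volume$spacing),
                  file.path(dir, sprintf("phantom%02d_truth.nii", i)))
    }
    jsonlite::write_json(
      list(targets_ml = targets_ml,
           truth_ml = vapply(out, function(x) x$truth_ml, 0),
           seed = seed, size = size, n_slices = n_slices),
      file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
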