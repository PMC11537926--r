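# Label-synchronized data augmentation: fuse image and label as channels,
# transform jointly (bilinear for the image, nearest-neighbor for the label),
# split back.

#' Fuse an image and its label map into a 2-channel array
#'
#' @param image numeric matrix in \[0, 1\].
#' @param label integer label matrix of the same shape.
#' @return rows x cols x 2 array: channel 1 image, channel 2 label.
#' @export
channel_fuse <- function(image, label) {
  check_same_shape(image, label)
  out <- array(0, c(dim(image), 2L))
  out[, , 1] <- image
  out[, , 2] <- label
  out
}

#' Split a fused 2-channel array back into image and label
#'
#' Inverse of [channel_fuse()]; the label channel is rounded back to
#' integers (exact after a nearest-neighbor pipeline).
#'
#' @param fused rows x cols x 2 array.
#' @return List with `image` and integer `label`.
#' @export
channel_split <- function(fused) {
  if (length(dim(fused)) != 3L || dim(fused)[3] != 2L)
    stop("fused input must have exactly 2 channels", call. = FALSE)
  lab <- round(fused[, , 2])
  storage.mode(lab) <- "integer"
  list(image = fused[, , 1], label = lab)
}

#' Augmentation transform specification
#'
#' Conservative default ranges that keep head anatomy plausible; all
#' configurable.
#'
#' @param rotation maximum absolute rotation, degrees (drawn uniformly in
#'   \[-rotation, rotation\]).
#' @param scale scaling-factor range.
#' @param contrast contrast-gain range (applied about the image mean).
#' @param noise_sd additive Gaussian noise sd on the \[0, 1\] image scale.
#' @param salt_pepper fraction of image pixels replaced by 0/1.
#' @param flip_h,flip_v probabilities of horizontal / vertical flips.
#' @return Object of class `"transform_spec"`.
#' @export
transform_spec <- function(rotation = 15, scale = c(0.9, 1.1),
                           contrast = c(0.8, 1.2), noise_sd = 0.02,
                           salt_pepper = 0, flip_h = 0.5, flip_v = 0.5) {
  structure(list(rotation = rotation, scale = scale, contrast = contrast,
                 noise_sd = noise_sd, salt_pepper = salt_pepper,
                 flip_h = flip_h, flip_v = flip_v),
            class = "transform_spec")
}

#' Identity transform specification
#'
#' @return A [transform_spec()] that leaves inputs unchanged.
#' @export
identity_spec <- function() {
  transform_spec(rotation = 0, scale = c(1, 1), contrast = c(1, 1),
                 noise_sd = 0, salt_pepper = 0, flip_h = 0, flip_v = 0)
}

# Rotation+scaling about the image center as an EBImage affine matrix.
affine_about_center <- function(dims, angle_deg, scale) {
  th <- angle_deg * pi / 180
  rs <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  ctr <- (dims + 1) / 2
  shift <- ctr - as.vector(rs %*% ctr)
  rbind(rs[1, ], rs[2, ], shift)  # 3 x 2: cbind(x, y, 1) %*% m
}

apply_geometric <- function(channel, m, filter) {
  out <- EBImage::affine(channel, m, filter = filter,
                         output.dim = dim(channel), bg.col = 0,
                         antialias = FALSE)
  as.matrix(out)
}

#' Randomly transform a fused image/label pair
#'
#' Draws one set of parameters from `spec` (seeded) and applies geometric
#' operations identically to both channels -- the image channel with bilinear
#' interpolation, the label channel with nearest-neighbor, so no interpolated
#' phantom classes appear -- and photometric operations (contrast gain about
#' the mean, Gaussian noise, salt-and-pepper) to the image channel only.
#' Out-of-frame pixels are filled with 0 (air / background label).
#'
#' @param fused 2-channel array from [channel_fuse()].
#' @param spec a [transform_spec()].
#' @param seed integer seed; the same seed reproduces the same transform.
#' @return Transformed fused array with a `"params"` attribute recording the
#'   drawn parameters.
#' @export
random_transform <- function(fused, spec = transform_spec(), seed = NULL) {
  if (length(dim(fused)) != 3L || dim(fused)[3] != 2L)
    stop("fused input must have exactly 2 channels", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  params <- list(
    angle = runif(1, -spec$rotation, spec$rotation),
    scale = runif(1, spec$scale[1], spec$scale[2]),
    flip_h = runif(1) < spec$flip_h,
    flip_v = runif(1) < spec$flip_v,
    gain = runif(1, spec$contrast[1], spec$contrast[2])
  )
  img <- fused[, , 1]
  lab <- fused[, , 2]

  if (params$flip_h) { img <- img[, ncol(img):1]; lab <- lab[, ncol(lab):1] }
  if (params$flip_v) { img <- img[nrow(img):1, ]; lab <- lab[nrow(lab):1, ] }
  if (params$angle != 0 || params$scale != 1) {
    m <- affine_about_center(dim(img), params$angle, params$scale)
    img <- apply_geometric(img, m, "bilinear")
    lab <- apply_geometric(lab, m, "none")
  }
  if (params$gain != 1)
    img <- mean(img) + params$gain * (img - mean(img))
  if (spec$noise_sd > 0)
    img <- img + rnorm(length(img), 0, spec$noise_sd)
  if (spec$salt_pepper > 0) {
    n_noise <- round(spec$salt_pepper * length(img))
    if (n_noise > 0) {
      idx <- sample.int(length(img), n_noise)
      img[idx] <- as.numeric(runif(n_noise) < 0.5)
    }
  }
  img <- pmin(pmax(img, 0), 1)
  out <- channel_fuse(img, round(lab))
  attr(out, "params") <- params
  out
}

#' Expand a paired dataset by label-synchronized augmentation
#'
#' Keeps the original pairs and appends `factor - 1` seeded transformed
#' copies of each, with a manifest recording the per-item seed and drawn
#' parameters; the same `seed` reproduces the same expansion exactly.
#'
#' @param pairs list of `list(image =, label =)` pairs.
#' @param factor expansion factor (>= 1); 1 returns the input unchanged.
#' @param spec a [transform_spec()].
#' @param seed integer base seed.
#' @return Expanded list of pairs with a `"manifest"` attribute
#'   (a data frame: item, source, seed, angle, scale, flips, gain).
#' @export
augment_dataset <- function(pairs, factor = 2, spec = transform_spec(),
                            seed = 1) {
  if (length(pairs) == 0) stop("empty input dataset", call. = FALSE)
  if (factor < 1) stop("factor must be >= 1", call. = FALSE)
  out <- pairs
  manifest <- data.frame(item = seq_along(pairs), source = seq_along(pairs),
                         seed = NA_integer_, angle = 0, scale = 1,
                         flip_h = FALSE, flip_v = FALSE, gain = 1)
  if (factor > 1) {
    for (rep_i in seq_len(factor - 1)) {
      for (i in seq_along(pairs)) {
        item_seed <- seed + 10000L * rep_i + i
        fused <- channel_fuse(pairs[[i]]$image, pairs[[i]]$label)
        tf <- random_transform(fused, spec, seed = item_seed)
        p <- attr(tf, "params")
        out[[length(out) + 1L]] <- channel_split(tf)
        manifest <- rbind(manifest, data.frame(
          item = length(out), source = i, seed = item_seed,
          angle = p$angle, scale = p$scale, flip_h = p$flip_h,
          flip_v = p$flip_v, gain = p$gain))
      }
    }
  }
  attr(out, "manifest") <- manifest
  out
}
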