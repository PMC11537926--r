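# Improved fuzzy C-means: intuitionistic fuzzification + Gaussian kernel
# distance + spatial neighborhood constraint + hesitation correction.

#' Normalize a grayscale image to [0, 1]
#'
#' Linear rescale of the observed gray range \eqn{[m_{min}, m_{max}]} onto
#' \eqn{[0, 1]}. A constant image has no gray range and is rejected.
#'
#' @param image numeric matrix (2-D grayscale image) or vector.
#' @return Object of the same shape with values in \[0, 1\].
#' @export
normalize_gray <- function(image) {
  rng <- range(image)
  if (!all(is.finite(rng))) stop("image must be finite", call. = FALSE)
  if (rng[2] <= rng[1])
    stop("constant image: gray range is degenerate", call. = FALSE)
  (image - rng[1]) / (rng[2] - rng[1])
}

#' Intuitionistic fuzzification of a normalized image
#'
#' Maps each normalized gray value b to the intuitionistic triple of
#' membership \eqn{\mu = b^2}, non-membership \eqn{\nu = (1-b)^2} and
#' hesitation \eqn{\pi = 2b(1-b)}. The triple partitions unity exactly:
#' \eqn{b^2 + (1-b)^2 + 2b(1-b) = 1}. The hesitation degree is largest at
#' mid-gray (b = 0.5), where the brightness class of a pixel is most
#' uncertain, and vanishes at pure black or white.
#'
#' @param normalized numeric matrix or vector with values in \[0, 1\]
#'   (see [normalize_gray()]).
#' @return A list of class `"intuitionistic_image"` with components `mu`,
#'   `nu`, `pi`, each the same shape as the input.
#' @export
intuitionistic_fuzzify <- function(normalized) {
  if (any(normalized < 0 | normalized > 1, na.rm = TRUE))
    stop("values must lie in [0, 1]; normalize first", call. = FALSE)
  b <- normalized
  structure(list(mu = b^2, nu = (1 - b)^2, pi = 2 * b * (1 - b)),
            class = "intuitionistic_image")
}

#' @export
print.intuitionistic_image <- function(x, ...) {
  cat("Intuitionistic image", paste(dim(as.matrix(x$mu)), collapse = " x "),
      "- mean hesitation", signif(mean(x$pi), 4), "\n")
  invisible(x)
}

# Mirror-pad a matrix by p pixels on every side.
pad_mirror <- function(m, p) {
  nr <- nrow(m); nc <- ncol(m)
  if (p >= nr || p >= nc) stop("padding exceeds image size", call. = FALSE)
  ri <- c(p:1, 1:nr, nr:(nr - p + 1))
  ci <- c(p:1, 1:nc, nc:(nc - p + 1))
  m[ri, ci]
}

#' Neighborhood context of an image
#'
#' Per-pixel mean (default) or median over the (2p+1) x (2p+1) window centered
#' on the pixel, with mirror padding at the borders. This is the local spatial
#' information \eqn{\bar m_y} that couples each pixel to its neighborhood in
#' the spatially-constrained updates; the median variant reproduces the
#' median-based spatial smoothing used by spatial-FCM comparisons.
#'
#' @param image numeric matrix.
#' @param radius neighborhood radius p >= 1 (default 2, i.e. a 5 x 5 window).
#' @param mode `"mean"` or `"median"`.
#' @return Matrix of the same shape.
#' @export
neighborhood_context <- function(image, radius = 2, mode = c("mean", "median")) {
  mode <- match.arg(mode)
  p <- as.integer(radius)
  if (p < 1) stop("radius must be >= 1", call. = FALSE)
  padded <- pad_mirror(image, p)
  nr <- nrow(image); nc <- ncol(image)
  w <- 2L * p + 1L
  if (mode == "mean") {
    k <- matrix(1 / w^2, w, w)
    out <- EBImage::filter2(padded, k, boundary = "replicate")
    out[(p + 1):(p + nr), (p + 1):(p + nc)]
  } else {
    # stack the w^2 shifted copies and take the row-wise median
    shifts <- expand.grid(dr = -p:p, dc = -p:p)
    stack <- vapply(seq_len(nrow(shifts)), function(i) {
      dr <- shifts$dr[i]; dc <- shifts$dc[i]
      as.vector(padded[(p + 1 + dr):(p + nr + dr), (p + 1 + dc):(p + nc + dc)])
    }, numeric(nr * nc))
    out <- apply(stack, 1L, median)
    matrix(out, nr, nc)
  }
}

#' Squared kernel-induced distance
#'
#' Distance between feature values after implicit mapping into the Gaussian
#' RBF kernel space: \eqn{\|\phi(x)-\phi(c)\|^2 = 2(1 - K(x,c))} with
#' \eqn{K(x,c) = \exp(-(x-c)^2/\sigma^2)}. Bounded in \[0, 2\], zero iff
#' x = c; saturates for far-apart values, which is what damps the influence
#' of outlying (noisy) intensities.
#'
#' @param x,center numeric (vectorized).
#' @param sigma kernel bandwidth > 0.
#' @return Squared distance(s) in \[0, 2\].
#' @export
kernel_distance_sq <- function(x, center, sigma) {
  if (any(sigma <= 0)) stop("sigma must be > 0", call. = FALSE)
  2 * (1 - exp(-(x - center)^2 / sigma^2))
}

#' Spatially-constrained center update
#'
#' Center update with the neighborhood term folded in:
#' \eqn{a_x = \sum_y b_{xy}^l (m_y + \theta \bar m_y) /
#' [(1+\theta) \sum_y b_{xy}^l]}. With theta = 0 this reduces to the plain
#' fuzzy C-means update; for a constant image the theta term cancels exactly.
#'
#' @param x numeric vector of samples (gray values).
#' @param context numeric vector of neighborhood context values, same length.
#' @param membership f x n membership matrix.
#' @param fuzzifier weighting exponent l > 1.
#' @param theta spatial constraint weight >= 0.
#' @param weights optional per-sample multiplicities (gray-level mode).
#' @return Numeric vector of f updated centers.
#' @export
update_centers_spatial <- function(x, context, membership, fuzzifier = 2,
                                   theta = 1, weights = NULL) {
  if (theta < 0) stop("theta must be >= 0", call. = FALSE)
  x <- as.double(x); context <- as.double(context)
  if (length(context) != length(x))
    stop("context and samples differ in length", call. = FALSE)
  check_membership(membership, n = length(x))
  bl <- membership^fuzzifier
  if (!is.null(weights)) bl <- sweep(bl, 2L, weights, "*")
  denom <- (1 + theta) * rowSums(bl)
  if (any(denom <= 0))
    stop("degenerate cluster: a membership row has zero total weight", call. = FALSE)
  drop(bl %*% (x + theta * context)) / denom
}

#' Kernel membership update with spatial constraint
#'
#' Memberships from the kernel-induced dissimilarities
#' \eqn{D_{xy} = \|\phi(m_y)-\phi(a_x)\|^2 + \theta\|\phi(\bar m_y)-\phi(a_x)\|^2}
#' normalized as \eqn{b_{xy} = [\sum_g (D_{xy}/D_{gy})^{1/(l-1)}]^{-1}}.
#' A sample whose D vanishes for some center (it coincides with the center
#' and so does its context) gets a crisp assignment split over the coinciding
#' centers.
#'
#' @inheritParams update_centers_spatial
#' @param centers numeric vector of f cluster centers.
#' @param sigma Gaussian kernel bandwidth > 0.
#' @return f x n column-stochastic membership matrix.
#' @export
update_membership_kernel <- function(x, context, centers, fuzzifier = 2,
                                     theta = 1, sigma = 0.2) {
  if (length(centers) < 2) stop("at least 2 centers are required", call. = FALSE)
  x <- as.double(x); context <- as.double(context)
  d_main <- outer(centers, x, function(a, m) kernel_distance_sq(m, a, sigma))
  d_ctx <- outer(centers, context, function(a, m) kernel_distance_sq(m, a, sigma))
  memberships_from_d2(d_main + theta * d_ctx, exponent = 1 / (fuzzifier - 1))
}

#' Hesitation-degree membership correction
#'
#' Sharpens each membership column using the pixel's hesitation degree
#' \eqn{\pi_y}: the winning membership \eqn{b_{ey} = \max_x b_{xy}} absorbs
#' the mass removed from the others, which are scaled by \eqn{\pi_y}:
#' losers \eqn{b_{xy} \leftarrow \pi_y b_{xy}}, winner
#' \eqn{b_{ey} \leftarrow 1 - \pi_y \sum_{x \ne e} b_{xy}}. Columns stay
#' stochastic and the winner never decreases; \eqn{\pi = 1} leaves the column
#' unchanged while \eqn{\pi = 0} makes it crisp.
#'
#' @param membership f x n column-stochastic membership matrix.
#' @param pi_y numeric vector of n hesitation degrees in \[0, 1\] (recycled if
#'   scalar).
#' @return Corrected f x n membership matrix.
#' @export
hesitation_correction <- function(membership, pi_y) {
  check_membership(membership)
  n <- ncol(membership)
  pi_y <- rep_len(as.double(pi_y), n)
  if (any(pi_y < 0 | pi_y > 1)) stop("pi must lie in [0, 1]", call. = FALSE)
  win <- max.col(t(membership), ties.method = "first")
  idx <- cbind(win, seq_len(n))
  loser_mass <- 1 - membership[idx]
  out <- sweep(membership, 2L, pi_y, "*")
  out[idx] <- 1 - pi_y * loser_mass
  out
}

#' Fit the improved (intuitionistic kernel spatial) fuzzy C-means model
#'
#' The improved algorithm (a) normalizes the gray scale, (b) re-expresses the
#' image as an intuitionistic fuzzy set (membership \eqn{b^2}, non-membership
#' \eqn{(1-b)^2}, hesitation \eqn{2b(1-b)}), then iterates (c) the
#' spatially-constrained center update, (d) the kernel-distance membership
#' update and (e) the hesitation correction, until the maximum absolute
#' membership change falls below `tol` or `max_iter` is reached. Finally the
#' membership matrix is substituted back into the image and each pixel takes
#' the class of maximum membership.
#'
#' Two clustering domains are available. `mode = "gray"` (default) extends
#' the membership matrix to the quantized gray levels: at most `levels`
#' samples, each weighted by its pixel count, the context of a level being
#' the mean context of its pixels. It is fast and exact on clean images.
#' `mode = "pixel"` clusters every pixel, so the spatial term sees each
#' pixel's own neighborhood -- this is the configuration that rescues
#' isolated impulse-noise pixels ("pseudo-spots") back to their local
#' tissue, at the cost of one sample per pixel.
#'
#' Initialization is deterministic: centers start at evenly spaced quantiles
#' of the distinct fuzzified gray values (the initial membership matrix is
#' derived from the fuzzified image, not drawn at random), so repeated fits
#' are bit-identical.
#'
#' @param image 2-D numeric matrix of gray values, or a 3-D slice stack
#'   (clustered jointly, with in-plane neighborhood context); any intensity
#'   range, normalized internally.
#' @param clusters number of clusters f (>= 2).
#' @param fuzzifier weighting exponent l > 1 (default 2).
#' @param theta spatial constraint weight (default 3.8, the weight
#'   established in the spatially-constrained FCM literature; 0 disables the
#'   spatial term).
#' @param sigma Gaussian kernel bandwidth; default `NULL` uses the sample
#'   standard deviation of the fuzzified intensities.
#' @param radius neighborhood radius p (default 2, a 5 x 5 window).
#' @param context_mode `"median"` (default; edge-preserving and robust to
#'   impulse noise) or `"mean"` neighborhood context.
#' @param mode `"gray"` (default) or `"pixel"` clustering domain.
#' @param levels number of gray levels for `mode = "gray"` (default 256).
#' @param hesitation apply the hesitation correction (default `TRUE`;
#'   `FALSE` is equivalent to forcing \eqn{\pi = 1}).
#' @param tol convergence tolerance on the membership change (default 1e-4).
#' @param max_iter maximum iterations (default 100).
#' @param seed accepted for interface symmetry with [fcm()]; the fit itself
#'   is deterministic.
#' @return An object of class `c("ifcm", "fcm")` with elements `centers`
#'   (ascending, in fuzzified-intensity space), `membership` (over samples:
#'   pixels or gray levels), `labels` (fitted label matrix), `pi` (hesitation
#'   field), `delta_trace` (membership change per iteration), `iterations`,
#'   `converged`, and the configuration.
#' @examples
#' img <- matrix(rep(c(0, 1), each = 32), 8, 8)
#' fit <- ifcm(img, clusters = 2, seed = 1)
#' table(fitted(fit))
#' @export
ifcm <- function(image, clusters, fuzzifier = 2, theta = 3.8, sigma = NULL,
                 radius = 2, context_mode = c("median", "mean"),
                 mode = c("gray", "pixel"), levels = 256, hesitation = TRUE,
                 tol = 1e-4, max_iter = 100, seed = NULL) {
  context_mode <- match.arg(context_mode)
  mode <- match.arg(mode)
  if (!is.array(image) || !(length(dim(image)) %in% c(2L, 3L)))
    stop("image must be a 2-D matrix or a 3-D slice stack", call. = FALSE)
  if (clusters < 2) stop("clusters must be >= 2", call. = FALSE)
  if (fuzzifier <= 1) stop("fuzzifier must be > 1", call. = FALSE)
  if (theta < 0) stop("theta must be >= 0", call. = FALSE)

  norm <- normalize_gray(image)
  iq <- intuitionistic_fuzzify(norm)
  feat_img <- iq$mu                     # cluster the fuzzified intensity
  ctx_img <- if (length(dim(image)) == 3L) {
    # neighborhoods are in-plane: context slice by slice
    out <- feat_img
    for (j in seq_len(dim(image)[3]))
      out[, , j] <- neighborhood_context(feat_img[, , j], radius = radius,
                                         mode = context_mode)
    out
  } else {
    neighborhood_context(feat_img, radius = radius, mode = context_mode)
  }
  if (is.null(sigma)) sigma <- max(sd(as.vector(feat_img)), 1e-6)

  if (mode == "gray") {
    lev <- round(as.vector(norm) * (levels - 1))
    present <- sort(unique(lev))
    b_lev <- present / (levels - 1)
    samples <- b_lev^2
    pi_s <- 2 * b_lev * (1 - b_lev)
    weights <- tabulate(match(lev, present), nbins = length(present))
    ctx <- vapply(split(as.vector(ctx_img), match(lev, present)), mean, 0)
    pixel_of <- match(lev, present)     # level index of each pixel
  } else {
    samples <- as.vector(feat_img)
    ctx <- as.vector(ctx_img)
    pi_s <- as.vector(iq$pi)
    weights <- NULL
    pixel_of <- seq_along(samples)
  }
  n <- length(samples)
  if (n < clusters)
    stop("fewer distinct samples than clusters", call. = FALSE)

  # Deterministic data-driven initialization: centers at evenly spaced
  # quantiles of the distinct fuzzified gray values. Random membership
  # initialization places every initial center at the global mean, a
  # symmetric fixed point that the saturating kernel updates escape too
  # slowly to beat the membership-change stopping rule.
  centers <- init_centers_quantile(samples, clusters)
  b <- update_membership_kernel(samples, ctx, centers, fuzzifier, theta, sigma)
  if (hesitation) b <- hesitation_correction(b, pi_s)
  delta_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    centers <- update_centers_spatial(samples, ctx, b, fuzzifier, theta,
                                      weights)
    b_new <- update_membership_kernel(samples, ctx, centers, fuzzifier,
                                      theta, sigma)
    if (hesitation) b_new <- hesitation_correction(b_new, pi_s)
    delta <- max(abs(b_new - b))
    delta_trace <- c(delta_trace, delta)
    b <- b_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  centers <- update_centers_spatial(samples, ctx, b, fuzzifier, theta, weights)

  ord <- order(centers)
  centers <- centers[ord]
  b <- b[ord, , drop = FALSE]
  labels <- array(defuzzify(b)[pixel_of], dim(image))

  structure(list(
    centers = matrix(centers, ncol = 1L),
    membership = b,
    labels = labels,
    pi = iq$pi,
    sample_pi = pi_s,
    sample_values = samples,
    sample_weights = weights,
    pixel_of = pixel_of,
    delta_trace = delta_trace,
    iterations = iter,
    converged = converged,
    fuzzifier = fuzzifier,
    theta = theta,
    sigma = sigma,
    radius = radius,
    context_mode = context_mode,
    mode = mode,
    hesitation = hesitation,
    tol = tol,
    dims = dim(image),
    n = n,
    call = match.call()
  ), class = c("ifcm", "fcm"))
}

#' Deblur a fitted improved-FCM model to a label map
#'
#' Substitutes the membership values of each sample (gray level or pixel)
#' back into the image and labels every pixel by maximum membership.
#' Clusters are reported in ascending-center order (cluster 1 = darkest).
#'
#' @param object a fitted [ifcm()] model.
#' @return Integer label matrix with the image's dimensions.
#' @export
deblur_to_labels <- function(object) {
  stopifnot(inherits(object, "ifcm"))
  object$labels
}

#' @export
fitted.ifcm <- function(object, ...) object$labels

#' @export
print.ifcm <- function(x, ...) {
  cat("Improved fuzzy C-means fit (intuitionistic, kernel, spatial)\n")
  cat("  image:", paste(x$dims, collapse = " x "), "-", x$mode, "domain,",
      x$n, "samples\n")
  cat("  clusters:", nrow(x$centers),
      " theta:", x$theta, " sigma:", signif(x$sigma, 4),
      " window:", paste0(2 * x$radius + 1, "x", 2 * x$radius + 1), "\n")
  cat("  centers (fuzzified scale):",
      paste(signif(x$centers[, 1L], 4), collapse = ", "), "\n")
  cat("  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  invisible(x)
}

#' @export
summary.ifcm <- function(object, ...) {
  out <- list(
    centers = drop(object$centers),
    sizes = tabulate(object$labels, nbins = nrow(object$centers)),
    vpc = partition_coefficient(object$membership, object$sample_weights),
    vpe = partition_entropy(object$membership, object$sample_weights),
    vxb = xie_beni(object$sample_values, object$membership,
                   drop(object$centers), object$fuzzifier,
                   weights = object$sample_weights),
    iterations = object$iterations,
    converged = object$converged
  )
  class(out) <- "summary.ifcm"
  out
}

#' @export
print.summary.ifcm <- function(x, ...) {
  cat("Improved fuzzy C-means summary\n")
  cat("  centers:", paste(signif(x$centers, 4), collapse = ", "), "\n")
  cat("  sizes:  ", paste(x$sizes, collapse = ", "), "\n")
  cat("  Vpc:", signif(x$vpc, 5), " Vpe:", signif(x$vpe, 5),
      " Vxb:", signif(x$vxb, 5), "\n")
  cat("  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(not converged)", "\n")
  invisible(x)
}

#' @export
plot.ifcm <- function(x, ...) {
  lab <- x$labels
  if (length(dim(lab)) == 3L) lab <- lab[, , ceiling(dim(lab)[3] / 2)]
  image(t(lab)[, nrow(lab):1], col = grDevices::hcl.colors(
    nrow(x$centers), "viridis"), axes = FALSE, asp = 1,
    main = "IFCM label map", ...)
  invisible(x)
}
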