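#' @importFrom stats sd median runif rnorm coef fitted predict
#' @importFrom graphics image plot
NULL

# ---- internal helpers -------------------------------------------------------

# Coerce samples to an n x h numeric matrix (h = feature dimension, 1 for gray).
as_sample_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    x
  } else {
    matrix(as.double(x), ncol = 1L)
  }
}

# f x n matrix of squared Euclidean distances from each center to each sample.
sq_distances <- function(x, centers) {
  x <- as_sample_matrix(x)
  centers <- as_sample_matrix(centers)
  if (ncol(x) != ncol(centers))
    stop("samples and centers have different feature dimensions", call. = FALSE)
  # ||m - a||^2 = ||m||^2 + ||a||^2 - 2 a.m
  d2 <- outer(rowSums(centers^2), rowSums(x^2), "+") - 2 * tcrossprod(centers, x)
  d2[d2 < 0] <- 0  # guard tiny negatives from cancellation
  d2
}

check_membership <- function(membership, n = NULL, f = NULL) {
  if (!is.matrix(membership) || !is.numeric(membership))
    stop("membership must be a numeric matrix (clusters x samples)", call. = FALSE)
  if (!is.null(n) && ncol(membership) != n)
    stop("membership has ", ncol(membership), " columns but there are ", n,
         " samples", call. = FALSE)
  if (!is.null(f) && nrow(membership) != f)
    stop("membership has ", nrow(membership), " rows but there are ", f,
         " centers", call. = FALSE)
  invisible(membership)
}

# Deterministic center initialization: evenly spaced quantiles of the
# distinct sample values (1-D only). Data-driven and seed-free.
init_centers_quantile <- function(x, f) {
  u <- sort(unique(as.double(x)))
  if (length(u) < f) stop("fewer distinct samples than clusters", call. = FALSE)
  u[round((seq_len(f) - 0.5) * length(u) / f + 0.5)]
}

# Seeded random column-stochastic matrix: uniform Dirichlet per column.
init_membership <- function(n, f, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  b <- matrix(-log(runif(f * n)), nrow = f, ncol = n)
  sweep(b, 2L, colSums(b), "/")
}

# ---- exported operations ----------------------------------------------------

#' Fuzzy C-means objective (cost) function
#'
#' Evaluates the weighted within-cluster scatter
#' \eqn{E = \sum_x \sum_y b_{xy}^l \, \|m_y - a_x\|^2}, the quantity that
#' fuzzy C-means minimizes by alternating membership and center updates.
#'
#' @param x samples: numeric vector (gray levels) or an n x h matrix of
#'   feature vectors.
#' @param membership f x n column-stochastic membership matrix.
#' @param centers numeric vector of f centers, or an f x h matrix.
#' @param fuzzifier the weighting exponent l > 1.
#' @return Non-negative scalar cost.
#' @examples
#' x <- c(0, 2)
#' fcm_cost(x, matrix(1, 1, 2), 1, fuzzifier = 2)  # 1 + 1 = 2
#' @export
fcm_cost <- function(x, membership, centers, fuzzifier = 2) {
  x <- as_sample_matrix(x)
  centers <- as_sample_matrix(centers)
  check_membership(membership, n = nrow(x), f = nrow(centers))
  sum(membership^fuzzifier * sq_distances(x, centers))
}

#' Fuzzy C-means center update
#'
#' Each center is the membership-weighted mean of the samples,
#' \eqn{a_x = \sum_y b_{xy}^l m_y / \sum_y b_{xy}^l}; every center therefore
#' lies in the convex hull of the samples.
#'
#' @inheritParams fcm_cost
#' @param weights optional non-negative per-sample multiplicities (used by the
#'   gray-level clustering mode, where one sample stands for all pixels at a
#'   gray level).
#' @return f x h matrix of updated centers.
#' @export
update_centers <- function(x, membership, fuzzifier = 2, weights = NULL) {
  x <- as_sample_matrix(x)
  check_membership(membership, n = nrow(x))
  bl <- membership^fuzzifier
  if (!is.null(weights)) bl <- sweep(bl, 2L, weights, "*")
  denom <- rowSums(bl)
  if (any(denom <= 0))
    stop("degenerate cluster: a membership row has zero total weight", call. = FALSE)
  (bl %*% x) / denom
}

#' Fuzzy C-means membership update
#'
#' Memberships follow the inverse-distance rule
#' \eqn{b_{xy} = [\sum_g (r_{xy}/r_{gy})^{2/(l-1)}]^{-1}} with
#' \eqn{r_{xy} = \|m_y - a_x\|}. A sample that coincides exactly with one or
#' more centers receives membership \eqn{1/|T_y|} on the coinciding centers and
#' 0 elsewhere, so exact zeros never enter a division.
#'
#' @inheritParams fcm_cost
#' @return f x n column-stochastic membership matrix.
#' @export
update_membership <- function(x, centers, fuzzifier = 2) {
  centers <- as_sample_matrix(centers)
  if (nrow(centers) < 2) stop("at least 2 centers are required", call. = FALSE)
  d2 <- sq_distances(x, centers)
  memberships_from_d2(d2, exponent = 1 / (fuzzifier - 1))
}

# Shared inverse-distance normalization with exact-coincidence handling.
# d2: f x n matrix of (squared) dissimilarities; membership ratio exponent
# applies to d2 directly, so pass 1/(l-1) for squared distances.
memberships_from_d2 <- function(d2, exponent) {
  f <- nrow(d2)
  zero <- d2 <= 0
  hit <- colSums(zero) > 0
  inv <- d2^(-exponent)
  b <- sweep(inv, 2L, colSums(inv), "/")
  if (any(hit)) {
    b[, hit] <- 0
    bz <- zero[, hit, drop = FALSE]
    b[, hit] <- sweep(bz * 1, 2L, colSums(bz), "/")
  }
  b
}

#' Defuzzify a membership matrix into hard labels
#'
#' Applies the maximum-membership principle: each sample is assigned to the
#' cluster with the largest membership; ties go to the lowest cluster index.
#'
#' @param membership f x n membership matrix.
#' @return Integer vector of n labels in 1..f.
#' @export
defuzzify <- function(membership) {
  check_membership(membership)
  max.col(t(membership), ties.method = "first")
}

#' Fit the standard fuzzy C-means model
#'
#' Alternates [update_centers()] and [update_membership()] from a seeded random
#' column-stochastic initial membership (centers are updated first). Iteration
#' stops when the maximum center shift falls below `tol` (the classical rule),
#' or, with `criterion = "membership"`, when the maximum absolute membership
#' change does, or after `max_iter` sweeps.
#'
#' For one-dimensional features the fitted centers are reported in ascending
#' order (cluster 1 = darkest), so label maps derived from the fit are ordered
#' by intensity.
#'
#' @param x numeric vector, matrix of samples (n x h), a 2-D image matrix or
#'   a 3-D slice stack (flattened internally; the fit then records the image
#'   dimensions so [fitted()] returns a label array).
#' @param clusters number of clusters f (>= 2).
#' @param fuzzifier weighting exponent l > 1 (default 2).
#' @param tol convergence tolerance alpha > 0 (default 1e-4).
#' @param max_iter maximum number of iterations I (default 100).
#' @param seed integer seed for the random initial membership.
#' @param criterion stopping rule: `"centers"` (default) stops on the maximum
#'   center shift, `"membership"` on the maximum membership change.
#' @param is_image how to read a matrix `x`: `TRUE` (default) treats it as a
#'   2-D image whose pixels are the samples, `FALSE` as an n x h table of
#'   feature vectors. Ignored for vector input.
#' @return An object of class `"fcm"`: a list with elements `centers`,
#'   `membership`, `cost_trace`, `iterations`, `converged`, plus bookkeeping
#'   fields used by the methods.
#' @seealso [ifcm()] for the spatially-constrained kernel variant.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(50, 0, 0.5), rnorm(50, 100, 0.5))
#' fit <- fcm(x, clusters = 2, seed = 1)
#' coef(fit)          # near 0 and 100
#' table(fitted(fit))
#' @export
fcm <- function(x, clusters, fuzzifier = 2, tol = 1e-4, max_iter = 100,
                seed = NULL, criterion = c("centers", "membership"),
                is_image = TRUE) {
  criterion <- match.arg(criterion)
  if (clusters < 2) stop("clusters must be >= 2", call. = FALSE)
  if (fuzzifier <= 1) stop("fuzzifier must be > 1", call. = FALSE)
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  if (max_iter < 1) stop("max_iter must be >= 1", call. = FALSE)

  dims <- NULL
  if (is.array(x) && length(dim(x)) %in% c(2L, 3L) && isTRUE(is_image)) {
    dims <- dim(x)
    x <- as.vector(x)
  }
  xm <- as_sample_matrix(x)
  if (anyNA(xm) || any(!is.finite(xm))) stop("samples must be finite", call. = FALSE)
  n <- nrow(xm)
  if (n < clusters) stop("need at least as many samples as clusters", call. = FALSE)

  b <- init_membership(n, clusters, seed)
  centers <- update_centers(xm, b, fuzzifier)
  cost_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    b_new <- update_membership(xm, centers, fuzzifier)
    centers_new <- update_centers(xm, b_new, fuzzifier)
    cost_trace <- c(cost_trace, fcm_cost(xm, b_new, centers_new, fuzzifier))
    shift <- if (criterion == "centers")
      max(sqrt(rowSums((centers_new - centers)^2)))
    else
      max(abs(b_new - b))
    b <- b_new
    centers <- centers_new
    if (shift < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }

  if (ncol(xm) == 1L) {
    ord <- order(centers[, 1L])
    centers <- centers[ord, , drop = FALSE]
    b <- b[ord, , drop = FALSE]
  }
  structure(list(
    centers = centers,
    membership = b,
    cost_trace = cost_trace,
    iterations = iter,
    converged = converged,
    fuzzifier = fuzzifier,
    tol = tol,
    criterion = criterion,
    dims = dims,
    n = n,
    call = match.call()
  ), class = "fcm")
}

#' @export
print.fcm <- function(x, ...) {
  cat("Fuzzy C-means fit:", nrow(x$centers), "clusters,", x$n, "samples\n")
  cat("Centers:", paste(signif(x$centers[, 1L], 5), collapse = ", "), "\n")
  cat("Iterations:", x$iterations,
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  cat("Final cost:", signif(utils::tail(x$cost_trace, 1), 6), "\n")
  invisible(x)
}

#' @export
coef.fcm <- function(object, ...) {
  if (ncol(object$centers) == 1L) drop(object$centers) else object$centers
}

#' @export
fitted.fcm <- function(object, ...) {
  lab <- defuzzify(object$membership)
  if (!is.null(object$dims)) dim(lab) <- object$dims
  lab
}

#' @export
predict.fcm <- function(object, newdata, type = c("class", "membership"), ...) {
  type <- match.arg(type)
  if (missing(newdata)) {
    b <- object$membership
  } else {
    shape <- if (is.matrix(newdata) && ncol(object$centers) == 1L) dim(newdata) else NULL
    xm <- if (!is.null(shape)) as.vector(newdata) else newdata
    b <- update_membership(xm, object$centers, object$fuzzifier)
    if (type == "class") {
      lab <- defuzzify(b)
      if (!is.null(shape)) dim(lab) <- shape
      return(lab)
    }
    return(b)
  }
  if (type == "class") fitted(object) else b
}

#' @export
summary.fcm <- function(object, ...) {
  lab <- defuzzify(object$membership)
  out <- list(
    centers = coef(object),
    sizes = tabulate(lab, nbins = nrow(object$centers)),
    vpc = partition_coefficient(object$membership),
    vpe = partition_entropy(object$membership),
    iterations = object$iterations,
    converged = object$converged,
    cost = utils::tail(object$cost_trace, 1)
  )
  class(out) <- "summary.fcm"
  out
}

#' @export
print.summary.fcm <- function(x, ...) {
  cat("Fuzzy C-means summary\n")
  cat("  centers:   ", paste(signif(x$centers, 5), collapse = ", "), "\n")
  cat("  sizes:     ", paste(x$sizes, collapse = ", "), "\n")
  cat("  Vpc:       ", signif(x$vpc, 5), "\n")
  cat("  Vpe:       ", signif(x$vpe, 5), "\n")
  cat("  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(not converged)", "\n")
  invisible(x)
}

#' @export
plot.fcm <- function(x, ...) {
  if (ncol(x$centers) != 1L)
    stop("plot method supports one-dimensional features only", call. = FALSE)
  plot(x$cost_trace, type = "b", xlab = "iteration", ylab = "cost",
       main = "FCM objective trace", ...)
  invisible(x)
}
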