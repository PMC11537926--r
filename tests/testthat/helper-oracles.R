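# Independent naive-loop reimplementations used as oracles. Deliberately
# written with explicit loops and no shared code with the package internals.

naive_cost <- function(x, b, a, l) {
  x <- as.matrix(x); a <- as.matrix(a)
  total <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(x)))
    total <- total + b[i, j]^l * sum((x[j, ] - a[i, ])^2)
  total
}

naive_centers <- function(x, b, l, w = NULL) {
  x <- as.matrix(x)
  if (is.null(w)) w <- rep(1, nrow(x))
  f <- nrow(b)
  out <- matrix(0, f, ncol(x))
  for (i in seq_len(f)) {
    num <- rep(0, ncol(x)); den <- 0
    for (j in seq_len(nrow(x))) {
      num <- num + w[j] * b[i, j]^l * x[j, ]
      den <- den + w[j] * b[i, j]^l
    }
    out[i, ] <- num / den
  }
  out
}

naive_membership <- function(x, a, l) {
  x <- as.matrix(x); a <- as.matrix(a)
  f <- nrow(a); n <- nrow(x)
  b <- matrix(0, f, n)
  for (j in seq_len(n)) {
    d <- sapply(seq_len(f), function(i) sqrt(sum((x[j, ] - a[i, ])^2)))
    hits <- which(d == 0)
    if (length(hits) > 0) {
      b[hits, j] <- 1 / length(hits)
    } else {
      for (i in seq_len(f))
        b[i, j] <- 1 / sum((d[i] / d)^(2 / (l - 1)))
    }
  }
  b
}

naive_centers_spatial <- function(x, ctx, b, l, theta, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  f <- nrow(b)
  out <- numeric(f)
  for (i in seq_len(f)) {
    num <- 0; den <- 0
    for (j in seq_along(x)) {
      num <- num + w[j] * b[i, j]^l * (x[j] + theta * ctx[j])
      den <- den + w[j] * (1 + theta) * b[i, j]^l
    }
    out[i] <- num / den
  }
  out
}

naive_kernel_membership <- function(x, ctx, a, l, theta, sigma) {
  kd <- function(u, v) 2 * (1 - exp(-(u - v)^2 / sigma^2))
  f <- length(a); n <- length(x)
  b <- matrix(0, f, n)
  for (j in seq_len(n)) {
    D <- sapply(seq_len(f), function(i) kd(x[j], a[i]) + theta * kd(ctx[j], a[i]))
    hits <- which(D == 0)
    if (length(hits) > 0) {
      b[hits, j] <- 1 / length(hits)
    } else {
      for (i in seq_len(f))
        b[i, j] <- 1 / sum((D[i] / D)^(1 / (l - 1)))
    }
  }
  b
}

naive_vpc <- function(b) {
  total <- 0
  for (i in seq_len(nrow(b))) for (j in seq_len(ncol(b)))
    total <- total + b[i, j]^2
  total / ncol(b)
}

naive_vpe <- function(b) {
  total <- 0
  for (i in seq_len(nrow(b))) for (j in seq_len(ncol(b)))
    if (b[i, j] > 0) total <- total - b[i, j] * log(b[i, j])
  total / ncol(b)
}

naive_xie_beni <- function(x, b, a, l) {
  x <- as.matrix(x); a <- as.matrix(a)
  num <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(x)))
    num <- num + b[i, j]^l * sum((x[j, ] - a[i, ])^2)
  sep <- Inf
  for (i in seq_len(nrow(a))) for (g in seq_len(nrow(a)))
    if (i != g) sep <- min(sep, sum((a[i, ] - a[g, ])^2))
  num / (nrow(x) * sep)
}

naive_context <- function(img, p, mode = "mean") {
  nr <- nrow(img); nc <- ncol(img)
  mirror <- function(i, n) {          # mirror index into 1..n
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    vals <- c()
    for (dr in -p:p) for (dc in -p:p)
      vals <- c(vals, img[mirror(r + dr, nr), mirror(c + dc, nc)])
    out[r, c] <- if (mode == "mean") mean(vals) else median(vals)
  }
  out
}

# Naive standard FCM reproducing the package's seeded initialization scheme
# (per-column unit-exponential draws normalized to sum 1, centers first).
naive_fcm <- function(x, f, l, tol, max_iter, seed) {
  x <- as.matrix(x)
  n <- nrow(x)
  set.seed(seed)
  b <- matrix(-log(runif(f * n)), f, n)
  for (j in seq_len(n)) b[, j] <- b[, j] / sum(b[, j])
  a <- naive_centers(x, b, l)
  for (it in seq_len(max_iter)) {
    b <- naive_membership(x, a, l)
    a_new <- naive_centers(x, b, l)
    shift <- max(sqrt(rowSums((a_new - a)^2)))
    a <- a_new
    if (shift < tol) break
  }
  ord <- order(a[, 1])
  list(centers = a[ord, , drop = FALSE], membership = b[ord, , drop = FALSE])
}

# Small standard phantom used across tests.
test_phantom <- function(size = 128, lesion_px = 400, seed = 7, ...) {
  lesion <- if (lesion_px > 0) list(area_px = lesion_px) else NULL
  generate_slice(phantom_spec(size = size, lesion = lesion,
                              seed = seed, ...))
}

mean_tissue_dice <- function(labels, truth) {
  mean(dice_per_class(labels, truth + 1L)[as.character(2:5)])
}
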