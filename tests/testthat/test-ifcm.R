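test_that("normalize_gray maps the observed range onto [0,1]", {
  img <- matrix(0:255, 16)
  n <- normalize_gray(img)
  expect_equal(range(n), c(0, 1))
  expect_equal(n[img == 128], 128 / 255)
  expect_equal(normalize_gray(matrix(c(40, 100, 160), 1))[2], 0.5)
  expect_error(normalize_gray(matrix(5, 3, 3)), "constant")
})

test_that("intuitionistic fuzzification partitions unity", {
  iq <- intuitionistic_fuzzify(matrix(0.5))
  expect_equal(c(iq$mu, iq$nu, iq$pi), c(0.25, 0.25, 0.5))
  iq0 <- intuitionistic_fuzzify(matrix(c(0, 1), 1))
  expect_equal(as.vector(iq0$mu), c(0, 1))
  expect_equal(as.vector(iq0$nu), c(1, 0))
  expect_equal(as.vector(iq0$pi), c(0, 0))
  set.seed(31)
  b <- matrix(runif(100), 10)
  iq <- intuitionistic_fuzzify(b)
  expect_equal(iq$mu + iq$nu + iq$pi, matrix(1, 10, 10))
  expect_true(all(iq$mu >= 0 & iq$mu <= 1))
  expect_true(all(iq$nu >= 0 & iq$nu <= 1))
  expect_true(all(iq$pi >= 0 & iq$pi <= 1))
  expect_error(intuitionistic_fuzzify(matrix(1.2)), "\\[0, 1\\]")
})

test_that("neighborhood context matches the naive sliding window", {
  const <- matrix(3, 6, 6)
  expect_equal(neighborhood_context(const, 1), const)
  expect_equal(neighborhood_context(const, 2, "median"), const)
  imp <- matrix(0, 7, 7); imp[4, 4] <- 1
  ctx <- neighborhood_context(imp, 1)
  expect_equal(ctx[3:5, 3:5], matrix(1 / 9, 3, 3))
  set.seed(32)
  img <- matrix(runif(64), 8)
  for (p in 1:2) {
    expect_equal(neighborhood_context(img, p, "mean"),
                 naive_context(img, p, "mean"), tolerance = 1e-12)
    expect_equal(neighborhood_context(img, p, "median"),
                 naive_context(img, p, "median"), tolerance = 1e-12)
  }
  expect_error(neighborhood_context(img, 0), "radius")
})

test_that("kernel distance has the Gaussian closed form", {
  expect_equal(kernel_distance_sq(0.3, 0.3, 0.1), 0)
  expect_equal(kernel_distance_sq(0, 100, 0.5), 2)
  expect_equal(kernel_distance_sq(1, 1 + 0.2, 0.2), 2 * (1 - exp(-1)))
  expect_error(kernel_distance_sq(0, 1, 0), "sigma")
})

test_that("spatial center update reduces to plain FCM and cancels on constants", {
  set.seed(33)
  x <- runif(20); ctx <- runif(20)
  b <- matrix(runif(3 * 20), 3); b <- sweep(b, 2, colSums(b), "/")
  expect_equal(update_centers_spatial(x, ctx, b, theta = 0),
               drop(update_centers(x, b)))
  # constant image: context equals the value, theta cancels
  xc <- rep(0.4, 20)
  expect_equal(update_centers_spatial(xc, xc, b, theta = 7),
               update_centers_spatial(xc, xc, b, theta = 0))
  for (rep in 1:20) {
    n <- sample(5:12, 1); f <- sample(2:4, 1)
    x <- runif(n); ctx <- runif(n)
    b <- matrix(runif(f * n), f); b <- sweep(b, 2, colSums(b), "/")
    l <- runif(1, 1.5, 3); th <- runif(1, 0, 4)
    expect_equal(update_centers_spatial(x, ctx, b, l, th),
                 naive_centers_spatial(x, ctx, b, l, th), tolerance = 1e-12)
  }
  expect_error(update_centers_spatial(runif(3), runif(2),
                                      matrix(0.5, 2, 3)), "length")
})

test_that("kernel membership update matches the naive loop and sums to 1", {
  # symmetric configuration
  b <- update_membership_kernel(0.5, 0.5, c(0.3, 0.7), theta = 1, sigma = 0.2)
  expect_equal(drop(b), c(0.5, 0.5))
  set.seed(34)
  for (rep in 1:20) {
    n <- sample(5:12, 1); f <- sample(2:4, 1)
    x <- runif(n); ctx <- runif(n); a <- runif(f)
    l <- runif(1, 1.3, 3); th <- runif(1, 0, 4); sg <- runif(1, 0.05, 1)
    b <- update_membership_kernel(x, ctx, a, l, th, sg)
    expect_equal(b, naive_kernel_membership(x, ctx, a, l, th, sg),
                 tolerance = 1e-12)
    expect_equal(colSums(b), rep(1, n), tolerance = 1e-9)
  }
})

test_that("kernel memberships approach Euclidean memberships for large sigma", {
  set.seed(35)
  x <- runif(30); a <- c(0.2, 0.5, 0.9)
  bk <- update_membership_kernel(x, x, a, fuzzifier = 2, theta = 0,
                                 sigma = 1e4)
  be <- update_membership(x, a, fuzzifier = 2)
  expect_lt(max(abs(bk - be)), 1e-3)
})

test_that("hesitation correction conserves mass and favors the winner", {
  b <- matrix(c(0.6, 0.3, 0.1), 3)
  expect_equal(drop(hesitation_correction(b, 1)), c(0.6, 0.3, 0.1))
  expect_equal(drop(hesitation_correction(b, 0)), c(1, 0, 0))
  expect_equal(drop(hesitation_correction(b, 0.5)), c(0.8, 0.15, 0.05))
  set.seed(36)
  for (rep in 1:20) {
    n <- sample(3:10, 1); f <- sample(2:4, 1)
    b <- matrix(runif(f * n), f); b <- sweep(b, 2, colSums(b), "/")
    p <- runif(n)
    bc <- hesitation_correction(b, p)
    expect_equal(colSums(bc), rep(1, n), tolerance = 1e-9)
    win <- max.col(t(b), ties.method = "first")
    idx <- cbind(win, seq_len(n))
    expect_true(all(bc[idx] >= b[idx] - 1e-12))
    expect_true(all(bc >= -1e-12 & bc <= 1 + 1e-12))
  }
  expect_error(hesitation_correction(b, 1.4), "pi")
})

test_that("ifcm exactly segments a clean two-class image", {
  img <- matrix(rep(c(10, 200), each = 128), 16, 16)
  fit <- ifcm(img, clusters = 2, seed = 1)
  truth <- matrix(rep(1:2, each = 128), 16, 16)
  expect_equal(unname(dice_per_class(fitted(fit), truth)), c(1, 1))
  # pixel mode agrees
  fitp <- ifcm(img, clusters = 2, seed = 1, mode = "pixel")
  expect_equal(fitted(fitp), fitted(fit))
})

test_that("ifcm with theta 0, huge sigma and no hesitation matches fcm labels", {
  sl <- test_phantom(size = 64, lesion_px = 120)
  g <- apply_window(sl$hu, "brain")
  fit_i <- ifcm(g, clusters = 6, seed = 1, theta = 0, sigma = 1e4,
                hesitation = FALSE, mode = "pixel")
  fit_f <- fcm(g, clusters = 6, seed = 1)
  expect_equal(as.vector(fitted(fit_i)), as.vector(fitted(fit_f)))
})

test_that("repeated ifcm fits are bit-identical", {
  sl <- test_phantom(size = 64, lesion_px = 120, gaussian_sd = 3)
  g <- apply_window(sl$hu, "brain")
  f1 <- ifcm(g, clusters = 6, seed = 9)
  f2 <- ifcm(g, clusters = 6, seed = 9)
  f1$call <- f2$call <- NULL
  expect_identical(f1, f2)
})

test_that("labels are invariant under monotone affine intensity rescaling", {
  sl <- test_phantom(size = 64, lesion_px = 120, gaussian_sd = 2)
  g <- apply_window(sl$hu, "brain")
  f1 <- ifcm(g, clusters = 6, seed = 1)
  f2 <- ifcm(3 * g + 17, clusters = 6, seed = 1)
  expect_identical(fitted(f1), fitted(f2))
})

test_that("deblurring labels every pixel with ascending-center clusters", {
  sl <- test_phantom(size = 64, lesion_px = 120)
  g <- apply_window(sl$hu, "brain")
  fit <- ifcm(g, clusters = 6, seed = 1)
  lab <- deblur_to_labels(fit)
  expect_true(all(lab %in% 1:6))
  expect_equal(dim(lab), dim(g))
  expect_false(is.unsorted(drop(fit$centers)))
  # brighter tissue never gets a lower label than a darker one, on average
  expect_lt(mean(g[lab == 1]), mean(g[lab == 6]))
})

test_that("ifcm rejects degenerate inputs", {
  expect_error(ifcm(matrix(1, 8, 8), clusters = 2), "constant")
  expect_error(ifcm(matrix(runif(64), 8), clusters = 1), "clusters")
  expect_error(ifcm(matrix(runif(64), 8), clusters = 2, theta = -1), "theta")
})

test_that("ifcm methods report the fit", {
  sl <- test_phantom(size = 64, lesion_px = 120)
  g <- apply_window(sl$hu, "brain")
  fit <- ifcm(g, clusters = 6, seed = 1)
  expect_output(print(fit), "Improved fuzzy C-means")
  s <- summary(fit)
  expect_output(print(s), "Vxb")
  expect_true(s$vpc >= 1 / 6 && s$vpc <= 1)
  expect_true(s$vpe >= 0)
  expect_gt(s$vxb, 0)
})
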