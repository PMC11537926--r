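test_that("fcm_cost matches hand values and the naive double loop", {
  # crisp assignment with centers on the samples: zero cost
  expect_equal(fcm_cost(c(0, 1), diag(2), c(0, 1)), 0)
  # all mass on one center at 1 for samples {0, 2}: 1 + 1
  expect_equal(fcm_cost(c(0, 2), matrix(1, 1, 2), 1), 2)
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:10, 1); f <- sample(2:4, 1)
    x <- matrix(rnorm(n * 2), n)
    b <- init_b <- matrix(runif(f * n), f); b <- sweep(b, 2, colSums(b), "/")
    a <- matrix(rnorm(f * 2), f)
    l <- runif(1, 1.3, 3)
    expect_equal(fcm_cost(x, b, a, l), naive_cost(x, b, a, l), tolerance = 1e-12)
  }
  expect_error(fcm_cost(c(0, 1, 2), diag(2), c(0, 1)), "columns")
})

test_that("update_centers is the membership-weighted mean", {
  # crisp split of {0,0,10,10}
  b <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(drop(update_centers(c(0, 0, 10, 10), b)), c(0, 10))
  # uniform membership: both centers at the sample mean
  x <- c(3, 1, 4, 1, 5)
  bu <- matrix(0.5, 2, 5)
  expect_equal(drop(update_centers(x, bu)), rep(mean(x), 2))
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(5:12, 1); f <- sample(2:4, 1)
    x <- rnorm(n)
    b <- matrix(runif(f * n), f); b <- sweep(b, 2, colSums(b), "/")
    l <- runif(1, 1.5, 3)
    expect_equal(drop(update_centers(x, b, l)),
                 drop(naive_centers(x, b, l)), tolerance = 1e-12)
  }
  expect_error(update_centers(c(0, 1), rbind(c(0, 0), c(1, 1))),
               "degenerate")
})

test_that("update_membership follows the inverse-distance rule", {
  # equidistant sample: symmetric membership
  expect_equal(drop(update_membership(1, c(0, 2))), c(0.5, 0.5))
  # sample on a center: crisp via the coincidence rule
  expect_equal(drop(update_membership(0, c(0, 3, 7))), c(1, 0, 0))
  # two coincident centers share the mass
  expect_equal(drop(update_membership(0, c(0, 0, 5))), c(0.5, 0.5, 0))
  # inverse squared distances: sample 1, centers {0, 3}, l = 2
  expect_equal(drop(update_membership(1, c(0, 3))), c(0.8, 0.2))
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(5:12, 1); f <- sample(2:4, 1)
    x <- rnorm(n); a <- rnorm(f)
    l <- runif(1, 1.3, 3)
    b <- update_membership(x, a, l)
    expect_equal(b, naive_membership(x, a, l), tolerance = 1e-12)
    expect_equal(colSums(b), rep(1, n), tolerance = 1e-9)
  }
})

test_that("fuzzifier near 1 approaches hard assignment", {
  x <- c(0, 0.1, 5, 5.1)
  b <- update_membership(x, c(0.05, 5.05), fuzzifier = 1.01)
  expect_true(all(apply(b, 2, max) > 0.99))
})

test_that("fcm recovers well-separated intensity groups", {
  set.seed(1)
  x <- c(rnorm(40, 0, 0.2), rnorm(40, 100, 0.2))
  fit <- fcm(x, clusters = 2, seed = 3)
  expect_true(fit$converged)
  expect_lt(abs(coef(fit)[1] - 0), 1)
  expect_lt(abs(coef(fit)[2] - 100), 1)
  expect_equal(unname(fitted(fit)), rep(1:2, each = 40))
})

test_that("fcm validates its configuration", {
  expect_error(fcm(1:10, clusters = 1), "clusters")
  expect_error(fcm(1:10, clusters = 2, fuzzifier = 1), "fuzzifier")
  expect_error(fcm(1:10, clusters = 2, tol = 0), "tol")
  expect_error(fcm(1:3, clusters = 4), "at least as many samples")
})

test_that("a huge tolerance stops after one sweep", {
  fit <- fcm(c(0, 1, 10, 11), clusters = 2, tol = 1e6, seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$iterations, 1L)
})

test_that("the objective trace is non-increasing", {
  for (s in 1:10) {
    set.seed(s)
    x <- rnorm(60, mean = sample(1:10, 1))
    fit <- fcm(x, clusters = 3, seed = s, max_iter = 50)
    expect_true(all(diff(fit$cost_trace) <= 1e-9))
  }
})

test_that("fcm agrees with an independent naive reimplementation", {
  for (s in 1:5) {
    set.seed(100 + s)
    n <- sample(10:20, 1)
    x <- rnorm(n)
    fit <- fcm(x, clusters = 3, fuzzifier = 2, tol = 1e-6, max_iter = 40,
               seed = s, is_image = FALSE)
    ref <- naive_fcm(matrix(x, ncol = 1), f = 3, l = 2, tol = 1e-6,
                     max_iter = 40, seed = s)
    expect_equal(drop(fit$centers), drop(ref$centers), tolerance = 1e-8)
    expect_equal(fit$membership, ref$membership, tolerance = 1e-8)
  }
})

test_that("permuting samples permutes membership columns identically", {
  set.seed(21)
  x <- rnorm(30)
  perm <- sample(30)
  f1 <- fcm(x, clusters = 3, seed = 5)
  # same fit on permuted data, initialized with the correspondingly
  # permuted membership: compare converged memberships directly instead
  b1 <- update_membership(x, coef(f1))
  b2 <- update_membership(x[perm], coef(f1))
  expect_equal(b1[, perm], b2)
})

test_that("defuzzify takes the maximum membership with low-index ties", {
  expect_equal(defuzzify(matrix(c(0.2, 0.7, 0.1), 3)), 2L)
  expect_equal(defuzzify(diag(3)), 1:3)
  expect_equal(defuzzify(matrix(c(0.5, 0.5), 2)), 1L)
})

test_that("fcm methods print, summarize and predict", {
  set.seed(2)
  x <- c(rnorm(30, 0, 0.3), rnorm(30, 10, 0.3))
  fit <- fcm(x, clusters = 2, seed = 1)
  expect_output(print(fit), "Fuzzy C-means fit")
  s <- summary(fit)
  expect_s3_class(s, "summary.fcm")
  expect_output(print(s), "Vpc")
  expect_equal(sum(s$sizes), 60)
  p <- predict(fit, newdata = c(-0.1, 10.2))
  expect_equal(unname(p), c(1L, 2L))
  pm <- predict(fit, newdata = c(-0.1, 10.2), type = "membership")
  expect_equal(colSums(pm), c(1, 1))
  # image input yields a label matrix
  img <- matrix(c(0, 0, 10, 10), 2)
  fi <- fcm(img, clusters = 2, seed = 1)
  expect_equal(dim(fitted(fi)), dim(img))
})
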