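# helper to build a model with a prescribed covariance
manual_model <- function(prototypes, covariance) {
  d <- ncol(prototypes)
  structure(list(prototypes = prototypes, covariance = covariance,
                 precision = solve(covariance), ridge = 0, ridge_used = 0,
                 counts = rep(2L, nrow(prototypes)), n_total = 2L * nrow(prototypes),
                 d = d, C = nrow(prototypes)),
            class = "gaussian_class_model")
}

test_that("prototypes are class means and zero scatter falls back to ridge", {
  f <- rbind(c(1, 2), c(1, 2), c(5, -1), c(5, -1))
  m <- fit_class_gaussians(f, c(1, 1, 2, 2), ridge = 1e-3)
  expect_equal(m$prototypes, rbind(c(1, 2), c(5, -1)))
  expect_equal(m$covariance, matrix(0, 2, 2))
  expect_equal(m$precision, diag(2) / 1e-3)
})

test_that("single-class 1D variance uses 1/N normalisation", {
  m <- fit_class_gaussians(matrix(c(0, 2), 2, 1), c(1, 1))
  expect_equal(m$prototypes[1, 1], 1)
  expect_equal(m$covariance[1, 1], 1)
})

test_that("tied covariance matches a brute-force double loop", {
  set.seed(31)
  N <- 500; d <- 8; C <- 3
  y <- sample(C, N, replace = TRUE)
  f <- matrix(rnorm(N * d), N, d) + 2 * y
  m <- fit_class_gaussians(f, y)
  S <- matrix(0, d, d)
  mu <- lapply(1:C, function(c) colMeans(f[y == c, , drop = FALSE]))
  for (i in seq_len(N)) {
    dl <- f[i, ] - mu[[y[i]]]
    S <- S + outer(dl, dl)
  }
  expect_equal(m$covariance, S / N, tolerance = 1e-10)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_class_gaussians(matrix(1:4, 4, 1), c(1, 1, 1, 2)),
               "insufficient data")
  expect_error(fit_class_gaussians(matrix(c(1, NA, 3, 4), 2, 2), c(1, 1)),
               "invalid input")
})

test_that("distance vanishes at the prototype and reduces to Euclidean", {
  m <- manual_model(rbind(c(0, 0), c(4, 0)), diag(2))
  expect_equal(mahalanobis_distance(c(0, 0), m, 1), 0)
  set.seed(2)
  z <- rnorm(2)
  expect_equal(mahalanobis_distance(z, m, 2), sqrt(sum((z - c(4, 0))^2)),
               tolerance = 1e-12)
  expect_error(mahalanobis_distance(c(1, 2, 3), m, 1), "invalid input")
  expect_error(mahalanobis_distance(c(1, 2), m, 5), "class index")
})

test_that("hand-computed anisotropic case gives sqrt(2)", {
  m <- manual_model(matrix(c(0, 0), 1), matrix(c(2, 0, 0, 2), 2))
  expect_equal(mahalanobis_distance(c(2, 0), m, 1), sqrt(2), tolerance = 1e-12)
})

test_that("distances agree with a solve-based computation", {
  set.seed(17)
  f <- matrix(rnorm(200 * 5), 200, 5)
  y <- rep(1:2, each = 100)
  m <- fit_class_gaussians(f, y, ridge = 1e-3)
  Sig <- m$covariance + diag(m$ridge_used, 5)
  for (i in 1:20) {
    z <- rnorm(5)
    c <- sample(2, 1)
    dl <- z - m$prototypes[c, ]
    oracle <- sqrt(drop(crossprod(dl, solve(Sig, dl))))
    expect_equal(mahalanobis_distance(z, m, c), oracle, tolerance = 1e-8)
  }
})

test_that("Mahalanobis distances are affine invariant", {
  set.seed(23)
  f <- matrix(rnorm(300 * 4), 300, 4)
  y <- rep(1:3, each = 100)
  m0 <- fit_class_gaussians(f, y, ridge = 0)
  A <- matrix(rnorm(16), 4, 4) + diag(4)
  b <- rnorm(4)
  ft <- sweep(f %*% t(A), 2, b, "+")
  m1 <- fit_class_gaussians(ft, y, ridge = 0)
  for (i in 1:10) {
    z <- rnorm(4)
    zt <- drop(A %*% z + b)
    for (c in 1:3)
      expect_equal(mahalanobis_distance(zt, m1, c),
                   mahalanobis_distance(z, m0, c), tolerance = 1e-6)
  }
})

test_that("confidence scores are non-positive with zero only at prototypes", {
  m <- manual_model(rbind(c(0, 0), c(4, 0)), diag(2))
  expect_equal(confidence_score(c(4, 0), m), 0)
  expect_equal(confidence_score(c(1, 0), m), -1)  # nearer class dominates
  set.seed(6)
  z <- matrix(rnorm(40), 20, 2)
  expect_true(all(confidence_score(z, m) <= 0))
  # moving radially away from every prototype never increases the score
  dir <- c(0, 1)
  s <- confidence_score(t(sapply(seq(0, 10, by = 0.5),
                                 function(t) c(2, 0) + t * dir)), m)
  expect_true(all(diff(s) <= 1e-12))
})

test_that("threshold calibration hits the requested acceptance rate", {
  expect_equal(calibrate_threshold(1:100, 0.95), 6)
  expect_equal(mean(1:100 >= calibrate_threshold(1:100, 0.95)), 0.95)
  expect_equal(calibrate_threshold(rep(3, 25)), 3)
  expect_equal(calibrate_threshold(1:50, 1.0), 1)
  expect_error(calibrate_threshold(1:10), "insufficient data")
})

test_that("detection accepts at the threshold and rejects far features", {
  m <- manual_model(rbind(c(0, 0), c(4, 0)), diag(2))
  expect_equal(detect(c(0, 0), m, -1)$label, "ID")
  expect_equal(detect(c(1, 0), m, -1)$label, "ID")   # score == lambda: tie
  expect_equal(detect(c(0, 50), m, -100)$label, "OOD")
})

test_that("well-separated synthetic Gaussians are detected near-perfectly", {
  set.seed(99)
  d <- 8
  mu <- rbind(rep(0, d), c(10, rep(0, d - 1)), c(0, 10, rep(0, d - 2)))
  f <- do.call(rbind, lapply(1:3, function(c)
    sweep(matrix(rnorm(300 * d), 300, d), 2, mu[c, ], "+")))
  y <- rep(1:3, each = 300)
  m <- fit_class_gaussians(f, y)
  id <- confidence_score(do.call(rbind, lapply(1:3, function(c)
    sweep(matrix(rnorm(100 * d), 100, d), 2, mu[c, ], "+"))), m)
  ood <- confidence_score(
    sweep(matrix(rnorm(100 * d), 100, d), 2, c(20, 20, rep(0, d - 2)), "+"), m)
  expect_gt(auroc(id, ood), 0.999)
})
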