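test_that("mean pairwise differences match the brute-force double loop", {
  expect_equal(mean_component_diff(c(0, 1)), 1)
  expect_equal(mean_component_diff(c(0, 1, 2)), 4 / 3)
  set.seed(41)
  for (rep in 1:5) {
    v <- rnorm(30)
    brute <- 0
    for (j in 1:29) for (k in (j + 1):30) brute <- brute + abs(v[j] - v[k])
    brute <- brute / choose(30, 2)
    expect_equal(mean_component_diff(v), brute, tolerance = 1e-12)
    expect_equal(mean_component_diff(sample(v)), mean_component_diff(v),
                 tolerance = 1e-12)
  }
  expect_error(mean_component_diff(1), class = "stseg_fit_error")
})

test_that("fitting sets half-mean bandwidths and count priors", {
  s <- cbind(c(0, 1, 2), c(0, 2, 4), c(1, 2, 3))
  n <- cbind(c(5, 6), c(5, 7), c(5, 8))
  m <- kde_fit(s, n)
  expect_equal(m$factor, 0.5)
  expect_equal(m$bandwidths$S[1], 0.5 * 4 / 3)   # {0,1,2} -> 2/3
  expect_equal(unname(m$priors), c(2, 3) / 5)
  m2 <- kde_fit(s, rbind(n, n[1, ]))
  expect_equal(unname(m2$priors["N"]), 0.5)
  # a degenerate component has no spread to set a bandwidth from
  bad <- cbind(c(1, 1, 1), c(0, 1, 2), c(0, 1, 2))
  expect_error(kde_fit(bad, n), "component 1")
  expect_error(kde_fit(s[1, , drop = FALSE], n), class = "stseg_fit_error")
})

test_that("each kernel integrates to one in three dimensions", {
  # radial quadrature of the normalizer ...
  for (kn in kde_kernels()) {
    ks <- kernel_spec(kn)
    upper <- if (is.finite(ks$support)) 1 else 12
    val <- stats::integrate(function(r) {
      4 * pi * r^2 * ks$constant * ks$profile(r)
    }, 0, upper, rel.tol = 1e-9)$value
    expect_equal(val, 1, tolerance = 1e-3)
  }
  # ... and grid quadrature of the full mixture likelihood
  set.seed(42)
  pts <- matrix(rnorm(9, sd = 0.2), 3, 3)
  other <- matrix(rnorm(6), 2, 3)
  for (kn in kde_kernels()) {
    m <- kde_fit(pts, other, kernel = kn, factor = 1)
    b <- m$bandwidths$S
    margin <- if (is.finite(kernel_spec(kn)$support)) b else 6 * b
    lo <- apply(pts, 2, min) - margin
    hi <- apply(pts, 2, max) + margin
    h <- (hi - lo) / 36
    grid <- as.matrix(expand.grid(lo[1] + h[1] * (0:35 + 0.5),
                                  lo[2] + h[2] * (0:35 + 0.5),
                                  lo[3] + h[3] * (0:35 + 0.5)))
    dens <- apply(grid, 1, function(y) kde_likelihood(m, y, "S"))
    expect_equal(sum(dens) * prod(h), 1, tolerance = 0.01)
  }
})

test_that("the likelihood has its closed form at a training point", {
  pts <- rbind(c(1, 2, 3), c(50, 50, 50))
  other <- rbind(c(0, 0, 0), c(1, 1, 1))
  m <- kde_fit(pts, other)
  b <- m$bandwidths$S
  # far point contributes ~exp(-large); the coincident one dominates
  expect_equal(kde_likelihood(m, c(1, 2, 3), "S"),
               0.5 * ((2 * pi)^(-3 / 2) / prod(b)) *
                 (1 + exp(-sum(((c(1, 2, 3) - c(50, 50, 50)) / b)^2) / 2)),
               tolerance = 1e-12)
  # compact support: zero when every point is beyond scaled distance 1
  mr <- kde_fit(pts, other, kernel = "rectangular")
  expect_identical(kde_likelihood(mr, c(1000, 1000, 1000), "S"), 0)
})

test_that("the stabilized Gaussian sum equals the naive formula", {
  set.seed(43)
  pts_s <- matrix(rnorm(30), 10, 3)
  pts_n <- matrix(rnorm(30, 2), 10, 3)
  m <- kde_fit(pts_s, pts_n)
  y <- c(0.3, -0.2, 0.5)
  for (cl in c("S", "N")) {
    pts <- if (cl == "S") pts_s else pts_n
    b <- m$bandwidths[[cl]]
    naive <- 0
    for (i in 1:10)
      naive <- naive + exp(-0.5 * sum(((y - pts[i, ]) / b)^2))
    naive <- naive * (2 * pi)^(-3 / 2) / prod(b) / 10
    expect_equal(kde_likelihood(m, y, cl), naive, tolerance = 1e-12)
  }
})

test_that("posteriors follow Bayes' rule and sum to one", {
  set.seed(44)
  pts_s <- matrix(rnorm(9), 3, 3)
  pts_n <- matrix(rnorm(9, 1), 3, 3)
  m <- kde_fit(pts_s, pts_n)
  for (rep in 1:20) {
    y <- rnorm(3)
    post <- kde_posterior(m, y)
    expect_equal(sum(post), 1, tolerance = 1e-12)
    # independent transcription of prior-weighted likelihood normalization
    ln <- kde_likelihood(m, y, "N") * nrow(pts_n) / 6
    ls <- kde_likelihood(m, y, "S") * nrow(pts_s) / 6
    expect_equal(unname(post["S"]), ls / (ln + ls), tolerance = 1e-12)
  }
  # mirror-image classes about y with equal counts: posterior = priors
  pts <- matrix(rnorm(9), 3, 3)
  m2 <- kde_fit(pts, -pts)
  expect_equal(unname(kde_posterior(m2, c(0, 0, 0))), c(0.5, 0.5),
               tolerance = 1e-12)
})

test_that("classification takes the posterior argmax with ties to N", {
  pts_s <- rbind(c(10, 10, 10), c(10.1, 10.2, 10.3))
  pts_n <- rbind(c(0, 0, 0), c(0.1, 0.2, 0.3))
  m <- kde_fit(pts_s, pts_n)
  expect_identical(kde_classify(m, c(10, 10, 10)), "S")
  expect_identical(kde_classify(m, c(0, 0, 0)), "N")
  # identical classes force an exact tie everywhere -> N
  m_tie <- kde_fit(pts_n, pts_n)
  expect_identical(kde_classify(m_tie, c(5, 5, 5)), "N")
  # compact kernel far from both classes: fall back to the (equal) priors
  mr <- kde_fit(pts_s, pts_n, kernel = "triweight")
  expect_identical(kde_classify(mr, c(500, 500, 500)), "N")
})

test_that("kernel constants cancel out of every decision", {
  set.seed(45)
  pts_s <- matrix(rnorm(60, 1), 20, 3)
  pts_n <- matrix(rnorm(60), 20, 3)
  probes <- matrix(rnorm(90, 0.5), 30, 3)
  for (kn in c("gaussian", "epanechnikov", "triangular")) {
    m <- kde_fit(pts_s, pts_n, kernel = kn)
    m_scaled <- m
    m_scaled$kernel$constant <- m$kernel$constant * 17.3
    expect_identical(kde_classify(m, probes), kde_classify(m_scaled, probes))
  }
})

test_that("bandwidths and decisions are equivariant to component rescaling", {
  set.seed(46)
  pts_s <- matrix(rnorm(60, 2), 20, 3)
  pts_n <- matrix(rnorm(60), 20, 3)
  probes <- matrix(rnorm(30, 1), 10, 3)
  m <- kde_fit(pts_s, pts_n)
  c_scale <- 250
  scale_mat <- function(x) { x[, 2] <- x[, 2] * c_scale; x }
  m2 <- kde_fit(scale_mat(pts_s), scale_mat(pts_n))
  expect_equal(m2$bandwidths$S[2], c_scale * m$bandwidths$S[2],
               tolerance = 1e-12)
  expect_identical(kde_classify(m, probes), kde_classify(m2, scale_mat(probes)))
})

test_that("well-separated Gaussian classes are recovered at adequate bandwidths", {
  set.seed(47)
  train_s <- matrix(rnorm(600, 4), 200, 3)
  train_n <- matrix(rnorm(600, 0), 200, 3)
  test_y <- rbind(matrix(rnorm(600, 4), 200, 3),
                  matrix(rnorm(600, 0), 200, 3))
  truth <- rep(c("S", "N"), each = 200)
  # the Gaussian kernel sees every training point at the half-mean factor
  m <- kde_fit(train_s, train_n, kernel = "gaussian", factor = 0.5)
  expect_gte(mean(kde_classify(m, test_y) == truth), 0.95)
  # compactly supported kernels need a wider factor before their support
  # covers fresh draws from the class cloud (cf. the bandwidth sweep,
  # which lands them at factors well above 1)
  for (kn in setdiff(kde_kernels(), "gaussian")) {
    m <- kde_fit(train_s, train_n, kernel = kn, factor = 1.5)
    acc <- mean(kde_classify(m, test_y) == truth)
    expect_gte(acc, 0.95)
  }
})

test_that("compact kernels at narrow bandwidths fall back to the prior", {
  set.seed(49)
  train_s <- matrix(rnorm(600, 4), 200, 3)
  train_n <- matrix(rnorm(600, 0), 200, 3)
  m <- kde_fit(train_s, train_n, kernel = "rectangular", factor = 0.5)
  fresh <- matrix(rnorm(300, 4), 100, 3)
  zero_both <- vapply(seq_len(100), function(i) {
    kde_likelihood(m, fresh[i, ], "S") == 0 &&
      kde_likelihood(m, fresh[i, ], "N") == 0
  }, logical(1))
  # a non-negligible share of fresh tail points sits outside every
  # support ellipsoid and inherits the prior-tie label N
  expect_gt(mean(zero_both), 0.02)
  expect_true(all(kde_classify(m, fresh[zero_both, , drop = FALSE]) == "N"))
})

test_that("episode calls require a strict ischemic majority", {
  expect_true(classify_episode(c("S", "S", "N")))
  expect_false(classify_episode(c("S", "N")))
  expect_false(classify_episode(c("N", "N", "N")))
  expect_error(classify_episode(character(0)), class = "stseg_input_error")
})

test_that("the factor sweep maximizes Se + Sp with ties to the smallest", {
  set.seed(48)
  mkdf <- function(n, mu, lab)
    data.frame(f1 = rnorm(n, mu), f2 = rnorm(n, mu), f3 = rnorm(n, mu),
               label = lab)
  train <- rbind(mkdf(30, 3, "S"), mkdf(30, 0, "N"))
  test <- rbind(mkdf(50, 3, "S"), mkdf(50, 0, "N"))
  sw <- kde_sweep_factor(train, test, factors = c(0.3, 0.5, 1))
  expect_equal(sw$best_factor,
               sw$metrics$factor[which.max(sw$metrics$sum)])
  expect_equal(nrow(sw$metrics), 3)
  # perfectly separated data ties every factor -> smallest wins
  expect_equal(sw$best_factor, 0.3)
})
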