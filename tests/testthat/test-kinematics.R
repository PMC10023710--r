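test_that("single-axis compositions match their defining rotations", {
  expect_equal(compose_orientation(c(0, 0, 0)), diag(3), tolerance = 1e-12)
  # pure abduction by 90 degrees carries +Y to +Z
  R <- compose_orientation(c(90, 0, 0))
  expect_equal(as.numeric(R %*% c(0, 1, 0)), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(det(R), 1, tolerance = 1e-12)
})

test_that("compose and decompose are mutual inverses away from gimbal lock", {
  expect_equal(as.numeric(decompose_orientation(diag(3))), c(0, 0, 0))
  a <- decompose_orientation(compose_orientation(c(10, 20, -30)))
  expect_equal(as.numeric(a), c(10, 20, -30), tolerance = 1e-9)

  set.seed(11)
  for (i in 1:1000) {
    ang <- c(runif(1, -170, 170), runif(1, -84, 84), runif(1, -170, 170))
    back <- decompose_orientation(compose_orientation(ang))
    expect_lt(max(abs(as.numeric(back) - ang)), 1e-9)
  }
})

test_that("gimbal lock at 90-degree flexion is refused", {
  R <- compose_orientation(c(25, 90, -40))
  expect_error(decompose_orientation(R), "gimbal lock")
  expect_error(cardan_xzy(0, 90, 0), "strictly inside")
})

test_that("long products of orientations stay orthonormal", {
  set.seed(21)
  R <- diag(3)
  for (i in 1:1e5) {
    R <- R %*% compose_orientation(runif(3, -5, 5))
    if (i %% 500 == 0) R <- orthonormalize(R)
  }
  R <- orthonormalize(R)
  expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
  expect_gt(det(R), 0)
})

test_that("R and compiled Cardan composition agree", {
  set.seed(31)
  for (i in 1:50) {
    ang <- runif(3, -80, 80)
    expect_equal(compose_orientation(ang),
                 glenosim:::cpp_compose_xzy(ang), tolerance = 1e-12)
  }
})

make_pivot_samples <- function(pivot_s, pivot_h, n = 30, noise = 0, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    R <- compose_orientation(runif(3, -40, 40))
    t <- pivot_s - R %*% pivot_h + rnorm(3, 0, noise)
    marker_frame(i * 0.1, R, t)
  })
}

test_that("pivot calibration recovers a known centre of rotation", {
  ps <- c(12, -8, 30); ph <- c(5, 40, -12)
  cor <- estimate_center_of_rotation(make_pivot_samples(ps, ph))
  expect_lt(max(abs(cor$pivot_scapular_mm - ps)), 1e-6)
  expect_lt(max(abs(cor$pivot_humeral_mm - ph)), 1e-6)
  expect_lt(cor$rms_mm, 1e-6)
})

test_that("pivot calibration tolerates marker noise", {
  ps <- c(3, -15, 22); ph <- c(-4, 28, 9)
  cor <- estimate_center_of_rotation(
    make_pivot_samples(ps, ph, n = 200, noise = 0.2, seed = 7))
  expect_lt(max(abs(cor$pivot_scapular_mm - ps)), 1)
})

test_that("pivot calibration matches a nonlinear least-squares oracle", {
  samples <- make_pivot_samples(c(5, 5, 5), c(-10, 20, 0), n = 40, seed = 3)
  fit <- estimate_center_of_rotation(samples)
  obj <- function(par) {
    ph <- par[1:3]; ps <- par[4:6]
    sum(vapply(samples, function(s)
      sum((s$R %*% ph + s$t - ps)^2), 0))
  }
  oracle <- optim(rep(1, 6), obj, method = "BFGS",
                  control = list(maxit = 2000, reltol = 1e-15))
  expect_lt(max(abs(c(fit$pivot_humeral_mm, fit$pivot_scapular_mm) -
                      oracle$par)), 1e-4)
  expect_lte(obj(c(fit$pivot_humeral_mm, fit$pivot_scapular_mm)),
             oracle$value + 1e-10)
})

test_that("pure translation cannot constrain the pivot", {
  samples <- lapply(1:20, function(i)
    marker_frame(i * 0.1, diag(3), c(i, 2 * i, 0)))
  expect_error(estimate_center_of_rotation(samples), "rank-deficient")
  expect_error(estimate_center_of_rotation(samples[1:5]), "at least 10")
})

test_that("relative pose composes marker frames correctly", {
  h <- marker_frame(1, diag(3), c(0, 0, 0))
  s <- marker_frame(1, diag(3), c(0, 0, 0))
  p <- relative_pose(h, s)
  expect_equal(p$orientation, diag(3))
  expect_equal(p$translation_mm, c(0, 0, 0))

  # known transform chain: oracle by explicit matrix products
  Rh <- compose_orientation(c(25, 10, -5)); th <- c(10, 20, 30)
  Rs <- compose_orientation(c(5, -8, 12));  ts <- c(-5, 4, 8)
  off <- list(humerus = c(1, 2, 3), scapula = c(-2, 0, 1))
  p <- relative_pose(marker_frame(2, Rh, th), marker_frame(2, Rs, ts), off)
  expect_equal(p$orientation, t(Rs) %*% Rh, tolerance = 1e-12)
  expect_equal(p$translation_mm,
               as.numeric(t(Rs) %*% (th + Rh %*% off$humerus - ts)) -
                 off$scapula, tolerance = 1e-12)

  expect_error(relative_pose(marker_frame(1, Rh, th),
                             marker_frame(2, Rs, ts)), "simultaneous")
})

test_that("marker recordings round-trip through CSV", {
  samples <- list(
    humerus = make_pivot_samples(c(1, 2, 3), c(0, 30, 0), n = 12, seed = 5),
    scapula = lapply(1:12, function(i) marker_frame(i * 0.1, diag(3), c(0, 0, 0))))
  path <- tempfile(fileext = ".csv")
  write_marker_csv(samples, path)
  back <- read_marker_csv(path)
  expect_setequal(names(back), c("humerus", "scapula"))
  expect_equal(back$humerus[[3]]$R, samples$humerus[[3]]$R, tolerance = 1e-9)
  expect_equal(back$humerus[[7]]$t, samples$humerus[[7]]$t, tolerance = 1e-9)
})
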