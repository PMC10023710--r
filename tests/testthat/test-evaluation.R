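test_that("resampling yields the inclusive integer-degree grid", {
  tr <- stub_trace("abduction")
  r <- resample_by_angle(tr)
  expect_equal(r$grid_deg, 20:60)            # 41 grid points
  expect_equal(nrow(r), 41)
  # grid values at exact samples coincide with those samples
  expect_equal(r$pv_abd, 20:60, tolerance = 1e-12)
  # negative-going ramp still yields a monotone grid
  re <- resample_by_angle(stub_trace("external_rotation"))
  expect_equal(re$grid_deg, 0:-45)
  expect_equal(re$pv_rot, 0:-45, tolerance = 1e-12)
})

test_that("a non-monotone scored setpoint is rejected", {
  tr <- stub_trace("abduction")
  i <- which(tr$phase == 2)
  tr$sp_abd[i] <- tr$sp_abd[i] + sin(seq_along(i)) * 5
  expect_error(resample_by_angle(tr), "monotone")
})

test_that("accuracy metrics have their closed forms", {
  tr <- stub_trace("abduction")
  r0 <- resample_by_angle(tr)
  expect_equal(accuracy_metrics(list(r0), "abd")$max_mean_dev_deg, 0)
  expect_equal(accuracy_metrics(list(r0), "abd")$rmse_deg, 0)

  rp <- r0; rp$pv_abd <- rp$pv_abd + 1
  a <- accuracy_metrics(list(rp), "abd")
  expect_equal(a$max_mean_dev_deg, 1)
  expect_equal(a$rmse_deg, 1)

  rm <- r0; rm$pv_abd <- rm$pv_abd - 1
  a <- accuracy_metrics(list(rp, rm), "abd")
  expect_equal(a$max_mean_dev_deg, 0)   # opposite offsets cancel in the mean
  expect_equal(a$rmse_deg, 1)           # but not in the RMSE
  expect_error(accuracy_metrics(list(), "abd"), "at least one")
})

test_that("repeatability SDs match hand computation", {
  r0 <- resample_by_angle(stub_trace("abduction"))
  expect_equal(repeatability_sd(list(r0, r0, r0), "abd")$max_sd_deg, 0)
  r1 <- r0; r1$pv_abd <- r1$pv_abd + 1
  r2 <- r0; r2$pv_abd <- r2$pv_abd + 2
  s <- repeatability_sd(list(r0, r1, r2), "abd")
  expect_equal(s$max_sd_deg, sd(c(0, 1, 2)))
  expect_equal(s$avg_sd_deg, sd(c(0, 1, 2)))
  expect_gte(s$max_sd_deg, s$avg_sd_deg)
  expect_error(repeatability_sd(list(r0), "abd"), "two repeats")
})

test_that("metrics are invariant under reordering of repeats", {
  set.seed(5)
  r0 <- resample_by_angle(stub_trace("abduction"))
  reps <- lapply(1:3, function(i) {
    r <- r0; r$pv_abd <- r$pv_abd + rnorm(nrow(r), 0, 0.5); r
  })
  perm <- reps[c(3, 1, 2)]
  expect_equal(accuracy_metrics(reps, "abd"), accuracy_metrics(perm, "abd"))
  expect_equal(repeatability_sd(reps, "abd"), repeatability_sd(perm, "abd"))
  m <- sapply(reps, `[[`, "pv_abd")
  expect_equal(icc_a1(m)$estimate, icc_a1(m[, c(2, 3, 1)])$estimate,
               tolerance = 1e-12)
})

test_that("RMSE dominates the RMS of the mean-deviation curve", {
  set.seed(6)
  r0 <- resample_by_angle(stub_trace("abduction"))
  for (trial in 1:20) {
    reps <- lapply(1:3, function(i) {
      r <- r0; r$pv_abd <- r$pv_abd + rnorm(nrow(r), 0.2, 0.7); r
    })
    a <- accuracy_metrics(reps, "abd")
    expect_gte(a$rmse_deg + 1e-12, sqrt(mean(a$mean_dev_deg^2)))
  }
})

icc_oracle <- function(m) {
  # independent route: mean squares from a two-way aov fit
  d <- data.frame(y = as.vector(m),
                  row = factor(rep(seq_len(nrow(m)), ncol(m))),
                  col = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  ms <- anova(aov(y ~ row + col, data = d))[["Mean Sq"]]
  n <- nrow(m); k <- ncol(m)
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}

test_that("ICC(A,1) equals the two-way ANOVA oracle on random matrices", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(5:20, 1); k <- sample(2:5, 1)
    m <- matrix(rnorm(n * k), n, k) + rnorm(n) + rep(rnorm(k, 0, 0.5), each = n)
    expect_equal(icc_a1(m)$estimate, icc_oracle(m), tolerance = 1e-8)
  }
})

test_that("ICC(A,1) matches an external reference implementation", {
  # 12 x 3 matrix with row effects and small column offsets; the reference
  # single-measurement absolute-agreement estimate is 0.642935 with a 95%
  # CI of (0.33, 0.87)
  m <- matrix(c(
    1.266578564737332, 2.143652425023245, 3.382093708740219,
    -1.300561382917099, -3.201106427334, -2.164912396921286,
    -2.21905525676747, -1.04695999252705, -3.403779299965465,
    -0.164893094666954, 0.22871594719365, 0.968961059887658,
    1.812564468398171, 2.406466113623911, -0.197197233037963,
    3.954663706675113, 0.186289023992785, 2.603736437773569,
    -1.74927381529122, -1.900016259345167, -2.275654752346401,
    -1.886409051169319, -0.434205278261671, -1.524453065788714,
    -0.1130746672992, -3.025249853778408, -1.798726794998908,
    -2.060532246636285, 0.007395389143365, -3.486536500499763,
    -0.819541105228933, 0.13432617220665, -2.160115339125804,
    0.721585487477659, 0.315083333737867, 0.543226675326555),
    nrow = 12, ncol = 3, byrow = TRUE)
  ic <- icc_a1(m)
  expect_equal(ic$estimate, 0.642935, tolerance = 1e-5)
  expect_lt(abs(ic$ci_lower - 0.33), 0.005)
  expect_lt(abs(ic$ci_upper - 0.87), 0.005)
})

test_that("identical columns give perfect agreement", {
  m <- matrix(rep(rnorm(10), 3), 10, 3)
  ic <- icc_a1(m)
  expect_equal(ic$estimate, 1)
  expect_false(ic$degenerate)
  # fully constant matrix is degenerate
  d <- icc_a1(matrix(2, 8, 3))
  expect_equal(d$estimate, 1)
  expect_true(d$degenerate)
  expect_error(icc_a1(matrix(1:6, 3, 2)), "at least 5")
  expect_error(icc_a1(matrix(c(NA, rnorm(17)), 6, 3)), "finite")
})

test_that("a column offset hurts absolute agreement but not consistency", {
  set.seed(8)
  m <- matrix(rep(rnorm(15, 0, 2), 3), 15, 3) + rnorm(45, 0, 0.2)
  m2 <- m
  m2[, 2] <- m2[, 2] + 1.5
  expect_lt(icc_a1(m2)$estimate, icc_a1(m)$estimate)
  icc_c1 <- function(x) {
    d <- data.frame(y = as.vector(x),
                    row = factor(rep(seq_len(nrow(x)), ncol(x))),
                    col = factor(rep(seq_len(ncol(x)), each = nrow(x))))
    ms <- anova(aov(y ~ row + col, data = d))[["Mean Sq"]]
    (ms[1] - ms[3]) / (ms[1] + (ncol(x) - 1) * ms[3])
  }
  expect_equal(icc_c1(m2), icc_c1(m), tolerance = 1e-10)
})

test_that("reliability bands follow the interpretation thresholds", {
  expect_equal(interpret_icc(0.95), "excellent")
  expect_equal(interpret_icc(0.90), "excellent")
  expect_equal(interpret_icc(0.60), "moderate")
  expect_equal(interpret_icc(0.75), "good")
  expect_equal(interpret_icc(0.49999), "poor")
  expect_error(interpret_icc(1.2), "-1, 1")
})

test_that("a perfect-tracking plant yields zero accuracy error and unit ICC", {
  traces <- list()
  k <- 0
  for (s in c("a", "b")) for (r in 1:3) {
    k <- k + 1
    traces[[k]] <- stub_trace("abduction", specimen = s, rep = r)
  }
  rep <- evaluate_campaign(traces)
  expect_true(all(rep$accuracy$max_mean_dev_deg == 0))
  expect_true(all(rep$accuracy$rmse_deg == 0))
  expect_true(all(rep$accuracy$max_sd_deg == 0))
  expect_true(all(rep$icc_force$icc == 1))
})
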