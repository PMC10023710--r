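test_that("kinetic constraints follow pCSA times specific strength", {
  mp <- muscle_params()
  expect_identical(unname(mp$mvc_n),
                   c(241, 118, 136, 308, 390, 132))
  expect_identical(unname(mp$couple_cap_adpd_n), 254)
  # rounding is half-up: 307.5 -> 308, 117.5 -> 118
  expect_identical(kinetic_constraint(12.30), 308)
  expect_identical(kinetic_constraint(4.70), 118)
})

test_that("muscle torque follows r x F with the cable line of action", {
  sp <- reference_specimen()
  # a cable whose line passes through the COR produces no torque
  sp$insertion_mm[, "MD"] <- c(0, 0, 50)
  sp$guide_mm[, "MD"] <- c(0, 0, 120)
  expect_equal(moment_arm_torque(sp, "MD", c(0, 0, 0), 80), c(0, 0, 0),
               tolerance = 1e-12)
  # hand cross-product: r = (0,0,0.05 m), u = (1,0,0) -> tau = (0, 0.05, 0)
  sp$guide_mm[, "MD"] <- c(200, 0, 50)
  expect_equal(moment_arm_torque(sp, "MD", c(0, 0, 0), 1), c(0, 0.05, 0),
               tolerance = 1e-12)
  # linearity in the applied force
  sp <- reference_specimen()
  t1 <- moment_arm_torque(sp, "AD", c(30, 10, -5), 60)
  t2 <- moment_arm_torque(sp, "AD", c(30, 10, -5), 120)
  expect_equal(t2, 2 * t1, tolerance = 1e-12)
  expect_error(moment_arm_torque(sp, "AD", c(0, 0, 0), -1), "push")
})

test_that("moment-arm signs match the muscles' anatomical actions", {
  sp <- reference_specimen()
  pose <- c(30, 0, 0)
  tq <- function(m) moment_arm_torque(sp, m, pose, 100)
  expect_gt(tq("MD")[1], 0)      # abductor
  expect_gt(tq("SSP")[1], 0)     # abductor
  expect_gt(tq("AD")[3], 0)      # flexor
  expect_lt(tq("PD")[3], 0)      # extensor
  expect_gt(tq("SSC")[2], 0)     # internal rotator
  expect_lt(tq("ISP_TM")[2], 0)  # external rotator
})

test_that("R-level torque agrees with the compiled plant torque", {
  sp <- reference_specimen()
  set.seed(41)
  for (i in 1:20) {
    ang <- c(runif(1, 0, 70), runif(1, -40, 40), runif(1, -45, 45))
    f <- runif(6, 10, 200)
    cppt <- glenosim:::cpp_muscle_torques(unclass(sp), ang, f)
    rt <- Reduce(`+`, lapply(seq_along(MUSCLES <- colnames(sp$insertion_mm)),
                             function(m) moment_arm_torque(sp, MUSCLES[m], ang, f[m])))
    expect_equal(as.numeric(cppt$total_nm), rt, tolerance = 1e-10)
  }
})

test_that("the plant settles near 10 degrees abduction under pretension", {
  sp <- reference_specimen()
  eq <- settle_passive(sp, rep(sp$pretension_n, 6), 20)
  expect_lt(abs(eq$state$angles_deg[1] - 10), 5)
  expect_lt(max(abs(eq$state$angles_deg[2:3])), 3)
  expect_lt(max(abs(eq$state$omega_deg_s)), 1e-3)
  # pretension centers the humeral head
  expect_lt(max(abs(eq$translation_mm)), 1)
})

test_that("with slack cables the plant falls to its passive equilibrium", {
  sp <- reference_specimen()
  eq <- settle_passive(sp, rep(0, 6), 25)
  expect_lt(max(abs(eq$state$omega_deg_s)), 1e-3)
  # adducted rest: gravity direction (10 deg inclination) vs capsule
  expect_gt(eq$state$angles_deg[1], 0)
  expect_lt(eq$state$angles_deg[1], 15)
})

test_that("mechanical energy never increases during passive motion", {
  sp <- reference_specimen()
  out <- settle_passive(sp, rep(0, 6), 6, record_energy = TRUE)
  expect_true(all(diff(out$energy_j) <= 1e-10))
})

test_that("halving the step size barely changes the trajectory endpoint", {
  sp <- reference_specimen()
  a <- settle_passive(sp, rep(12, 6), 80, dt_s = 0.005)
  b <- settle_passive(sp, rep(12, 6), 80, dt_s = 0.0025)
  expect_lt(max(abs(a$state$angles_deg - b$state$angles_deg)), 1e-3)
})

test_that("step_dynamics guards its preconditions", {
  sp <- reference_specimen()
  st <- list(angles_deg = c(10, 0, 0), omega_deg_s = c(0, 0, 0))
  expect_error(step_dynamics(sp, st, rep(10, 6), dt_s = 0.05), "dt_s")
  expect_error(step_dynamics(sp, st, c(-1, rep(10, 5))), "non-negative")
  expect_error(step_dynamics(sp, st, c(500, rep(10, 5))), "constraint")
  sp$dislocation_limit_mm <- 1e-4
  expect_error(step_dynamics(sp, st, rep(10, 6)), "dislocation")
})

test_that("specimen generation is deterministic and seed-sensitive", {
  a <- generate_specimen(7, 0.10)
  b <- generate_specimen(7, 0.10)
  expect_identical(a, b)
  d <- generate_specimen(8, 0.10)
  expect_false(isTRUE(all.equal(a$insertion_mm, d$insertion_mm)))
  expect_false(isTRUE(all.equal(a$mass_kg, d$mass_kg)))
  expect_false(isTRUE(all.equal(a$k_passive_nm_rad, d$k_passive_nm_rad)))
  # zero variability reproduces the reference bit-identically
  z <- generate_specimen(3, 0)
  r <- reference_specimen()
  expect_identical(z$insertion_mm, r$insertion_mm)
  expect_identical(z$mass_kg, r$mass_kg)
  expect_error(generate_specimen(1, 0.5), "variability")
})

test_that("generated specimens keep valid moment-arm signs in batch", {
  for (seed in 1:100) {
    sp <- generate_specimen(seed, 0.10)
    expect_gt(moment_arm_torque(sp, "MD", c(20, 0, 0), 100)[1], 0)
  }
})

test_that("sensor noise is observational, reproducible and calibrated", {
  sp <- reference_specimen()
  tr <- run_trial(sp, "abduction", record_dt_s = 0.1)
  sp0 <- sp
  sp0$noise_sd[] <- 0
  expect_identical(add_sensor_noise(tr, sp0, 1)$pv_abd, tr$pv_abd)
  n1 <- add_sensor_noise(tr, sp, 42)
  n2 <- add_sensor_noise(tr, sp, 42)
  expect_identical(n1$F_MD, n2$F_MD)

  big <- tr[rep(1, 10000), ]
  noisy <- add_sensor_noise(big, sp, 9)
  expect_gt(sd(noisy$pv_abd - big$pv_abd), 0.08)
  expect_lt(sd(noisy$pv_abd - big$pv_abd), 0.12)
})

test_that("specimen definitions round-trip through YAML", {
  sp <- generate_specimen(5, 0.10)
  path <- tempfile(fileext = ".yaml")
  write_specimen_yaml(sp, path)
  back <- read_specimen_yaml(path)
  expect_equal(back$insertion_mm, sp$insertion_mm, tolerance = 1e-9)
  expect_equal(back$mvc_n, sp$mvc_n)
  expect_equal(back$k_passive_nm_rad, sp$k_passive_nm_rad, tolerance = 1e-9)
  st <- run_trial(back, "abduction")
  expect_s3_class(st, "trial_trace")
})
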