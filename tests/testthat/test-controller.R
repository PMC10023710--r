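test_that("the PID follows the time-constant form with Ti in minutes", {
  g <- pid_gains(kc = 1.4, ti_min = 0.006, td_min = 0)
  st <- pid_state()
  # zero error forever -> zero output
  out <- pid_step(g, st, 10, 10, 0.01)
  expect_equal(out$u, 0)
  # constant error of 1 deg: after exactly 0.36 s (= Ti) the integral term
  # equals the proportional term, so u = 1.4 * (1 + 1) = 2.8
  st <- pid_state()
  for (i in 1:36) {
    out <- pid_step(g, st, 1, 0, 0.01)
    st <- out$state
  }
  expect_equal(out$u, 2.8, tolerance = 1e-9)
  # minutes-to-seconds conversion: Kc 1, Ti 1 min, e = 1 for 1 s
  g2 <- pid_gains(1, 1, 0)
  st <- pid_state()
  for (i in 1:100) {
    out <- pid_step(g2, st, 1, 0, 0.01)
    st <- out$state
  }
  expect_equal(out$u, 1 + 1 / 60, tolerance = 1e-9)
})

test_that("conditional integration freezes the accumulator at saturation", {
  g <- pid_gains(1, 0.01, 0)
  st <- pid_state()
  for (i in 1:500) {
    out <- pid_step(g, st, 5, 0, 0.01, lo = 0, hi = 2)
    st <- out$state
  }
  expect_equal(out$u, 2)
  expect_true(out$saturated)
  frozen <- st[["integ"]]
  out <- pid_step(g, st, 5, 0, 0.01, lo = 0, hi = 2)
  expect_equal(out$state[["integ"]], frozen)  # error still pushing: no windup
  # once the error reverses (and the output leaves the clamp), the
  # integrator moves again
  out <- pid_step(g, out$state, 0, 5, 0.01, lo = -10, hi = 2)
  expect_lt(out$state[["integ"]], frozen)
})

test_that("the SSP prior ratio interpolates its three knots", {
  expect_equal(ssp_ratio(30), 0.52)
  expect_equal(ssp_ratio(10), 0.99)
  expect_equal(ssp_ratio(60), 0.30)
  expect_equal(ssp_ratio(45), 0.41)   # midway between 0.52 and 0.30
  expect_equal(ssp_ratio(2), 0.99)    # clamped below
  expect_equal(ssp_ratio(75), 0.30)   # clamped above
  expect_equal(ssp_ratio(20), (0.99 + 0.52) / 2)
})

test_that("protocols select their operating sequence and gain rows", {
  m <- select_mode("abduction")
  expect_equal(m$algorithm, "cascade")
  expect_true(m$abd_profile)
  expect_false(m$fe_profile || m$ir_profile)

  m <- select_mode("flexion")
  expect_equal(m$algorithm, "parallel")
  expect_true(m$fe_profile)
  expect_false(m$abd_profile || m$ir_profile)

  m <- select_mode("extension_internal_rotation")
  expect_equal(m$algorithm, "parallel")
  expect_true(m$fe_profile && m$ir_profile)

  expect_error(select_mode("baseball_pitch"))
})

test_that("cascade ticks slave the couple totals to the MD force", {
  sp <- reference_specimen()
  g <- default_gains()
  st <- control_state()
  pv <- c(20, 0, 0)
  for (i in 1:400) {
    out <- cascade_step(sp, g, st, sp = c(25, 0, 0), pv = pv)
    st <- out$state
  }
  f <- out$forces_n
  expect_equal(out$tot_fe_raw / f[["MD"]], 0.60, tolerance = 1e-12)
  expect_equal(out$tot_ir_raw / f[["MD"]], 1.00, tolerance = 1e-12)
  # SSP slaved through the abduction-dependent ratio
  expect_equal(f[["SSP"]],
               min(132, max(10, f[["MD"]] * ssp_ratio(pv[1]))),
               tolerance = 1e-12)
  # conservation of the splits
  expect_equal(f[["AD"]] + f[["PD"]], min(out$tot_fe_raw, 254),
               tolerance = 1e-12)
  expect_equal(f[["SSC"]] + f[["ISP_TM"]], out$tot_ir_raw, tolerance = 1e-12)
  expect_error(cascade_step(sp, g, st, c(25, 0, 0), c(NaN, 0, 0)), "NaN")
})

test_that("MD saturates at its kinetic constraint with a flag", {
  sp <- reference_specimen()
  g <- default_gains()
  st <- control_state()
  for (i in 1:3000) {
    out <- cascade_step(sp, g, st, sp = c(170, 0, 0), pv = c(10, 0, 0))
    st <- out$state
  }
  expect_equal(out$forces_n[["MD"]], 241)
  expect_true(bitwAnd(as.integer(out$sat_flags), 1L) > 0)
})

test_that("the distribution share clamps to 5-95% and never unloads a cable", {
  sp <- reference_specimen()
  g <- default_gains()
  st <- control_state()
  # large persistent flexion error drives the share to its clamp
  for (i in 1:2000) {
    out <- parallel_step(sp, g, st, sp = c(50, 60, 0), pv = c(50, 0, 0))
    st <- out$state
  }
  expect_equal(out$share_fe, 0.95)
  f <- out$forces_n
  expect_gte(f[["PD"]], 10)   # antagonist never unloaded
  expect_lte(f[["AD"]], 118)
  # opposite error direction clamps at 0.05
  st <- control_state()
  for (i in 1:2000) {
    out <- parallel_step(sp, g, st, sp = c(50, -60, 0), pv = c(50, 0, 0),
                         fe_dir = -1)
    st <- out$state
  }
  expect_equal(out$share_fe, 0.05)
  expect_gte(out$forces_n[["AD"]], 10)
})

test_that("a converged parallel tick holds its commanded forces steady", {
  sp <- reference_specimen()
  g <- default_gains()
  st <- control_state()
  for (i in 1:2000) {
    out <- parallel_step(sp, g, st, sp = c(50, 10, 0), pv = c(50, 10, 0))
    st <- out$state
  }
  f1 <- out$forces_n
  for (i in 1:100) {
    out <- parallel_step(sp, g, st, sp = c(50, 10, 0), pv = c(50, 10, 0))
    st <- out$state
  }
  expect_equal(out$forces_n, f1, tolerance = 1e-9)
})

test_that("controller ticks are deterministic", {
  sp <- reference_specimen()
  g <- default_gains()
  run <- function() {
    st <- control_state()
    us <- numeric(50)
    for (i in 1:50) {
      out <- cascade_step(sp, g, st, c(30, 0, 0), c(20 + i / 10, 0, 0))
      st <- out$state
      us[i] <- out$forces_n[["MD"]]
    }
    us
  }
  expect_identical(run(), run())
})

test_that("gains files mirror the default table and round-trip", {
  path <- system.file("extdata", "gains_default.yaml", package = "glenosim")
  g <- read_gains_yaml(path)
  expect_equal(unname(g$abd_act_profile), c(2.600, 0.023, 0.000))
  expect_equal(unname(g$abd_act_constant), c(1.400, 0.006, 0.001))
  expect_equal(unname(g$fe_dist_profile), c(0.030, 0.050, 0.000))
  expect_equal(unname(g$fe_dist_constant), c(0.050, 0.070, 0.000))
  expect_equal(unname(g$fe_act), c(0.030, 0.050, 0.000))
  expect_equal(unname(g$ir_dist_profile), c(0.030, 0.060, 0.000))
  expect_equal(unname(g$ir_dist_constant), c(0.050, 0.050, 0.000))
  expect_equal(unname(g$ir_act), c(0.020, 0.050, 0.000))
  tmp <- tempfile(fileext = ".yaml")
  write_gains_yaml(g, tmp)
  expect_equal(read_gains_yaml(tmp), g)
  expect_error(pid_gains(-1, 0.05), "kc")
})
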