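# The virtual specimen: a physics-based stand-in for the cadaver shoulder.
#
# The plant has 3 rotational DOF (Cardan XZY angles) under gravity, passive
# capsular stiffness/damping per DOF, six straight-line cable muscles
# (insertion on the humerus, guide point fixed to the scapula) and a
# quasi-static elastic glenoid translation model. Dynamics are integrated in
# Cardan-angle space with a constant diagonal generalized inertia:
#   I th'' = J(th)^T (tau_muscle + tau_gravity) - k (th - th_rest) - c th'
# where J maps Cardan rates to angular velocity, so the gravity generalized
# force is exactly the gradient of the gravitational potential and the
# passive model is exactly dissipative.

#' Muscle parameters: pCSA, loading ratio and kinetic constraint
#'
#' The kinetic constraint (maximum voluntary contraction, the per-muscle
#' force cap) is the physiological cross-sectional area times the specific
#' strength, rounded to the nearest newton (half up).
#'
#' @param pcsa_cm2 physiological cross-sectional area (cm^2).
#' @param specific_strength_n_cm2 muscle specific strength (default 25 N/cm^2).
#' @return kinetic constraint in N (integer-valued numeric).
#' @export
#' @examples
#' kinetic_constraint(9.64)   # middle deltoid: 241 N
kinetic_constraint <- function(pcsa_cm2, specific_strength_n_cm2 = 25) {
  stopifnot(all(pcsa_cm2 > 0), specific_strength_n_cm2 > 0)
  floor(pcsa_cm2 * specific_strength_n_cm2 + 0.5)  # round half up
}

#' Default per-muscle parameters
#'
#' pCSA and prior loading ratios of the six simulated muscles (three deltoid
#' heads and the rotator cuff). The supraspinatus ratio depends on the
#' abduction angle and is given as a three-knot table. The AD+PD couple is
#' additionally capped at the printed couple constraint.
#'
#' @param specific_strength_n_cm2 specific strength (default 25 N/cm^2).
#' @return list with `pcsa_cm2`, `loading_ratio`, `ssp_table`, `mvc_n`,
#'   `couple_cap_adpd_n`.
#' @export
muscle_params <- function(specific_strength_n_cm2 = 25) {
  pcsa <- c(MD = 9.64, AD = 4.70, PD = 5.44, ISP_TM = 12.30, SSC = 15.60,
            SSP = 5.26)
  list(
    pcsa_cm2 = pcsa,
    loading_ratio = c(MD = 1, AD = 0.43, PD = 0.17, ISP_TM = 0.78, SSC = 0.22),
    ssp_table = cbind(abduction_deg = c(10, 30, 60),
                      ratio = c(0.99, 0.52, 0.30)),
    mvc_n = kinetic_constraint(pcsa, specific_strength_n_cm2),
    couple_cap_adpd_n = kinetic_constraint(pcsa[["AD"]] + pcsa[["PD"]],
                                           specific_strength_n_cm2)
  )
}

#' The reference virtual specimen
#'
#' The cadaver stand-in the synthetic-specimen generator perturbs. All
#' geometry is an explicit invention (no cadaver coordinates are published
#' for this apparatus): attachment and guide coordinates were chosen so that
#' the moment-arm signs match each muscle's anatomical action, the resting
#' equilibrium under 10-20 N pretension sits near 10 degrees abduction, and
#' prime-mover forces and glenohumeral translations during the motion
#' protocols fall in physiological ranges (deltoid of order 100-200 N,
#' translations of a few mm).
#'
#' Coordinates are mm about the humeral-head centre of rotation; the scapula
#' is tilted 10 degrees forward, applied as a constant rotation of gravity
#' into the scapular frame.
#'
#' @param forearm_mass_kg forearm-replacement mass (default 3.0 kg).
#' @param inclination_deg scapular forward inclination (default 10).
#' @param pretension_n initial per-cable centering tension (default 12 N;
#'   also the never-slack force floor via `pretension_floor_n = 10`).
#' @return object of class `gh_specimen`.
#' @export
reference_specimen <- function(forearm_mass_kg = 3.0, inclination_deg = 10,
                               pretension_n = 12) {
  mp <- muscle_params()
  insertion <- cbind(
    MD     = c(0, -60, -10),
    AD     = c(15, -50, -2),
    PD     = c(-15, -50, -2),
    ISP_TM = c(25, -6, 0),
    SSC    = c(-25, -6, 0),
    SSP    = c(0, 18, -20))
  guide <- cbind(
    MD     = c(0, 36, -34),
    AD     = c(50, 25, -5),
    PD     = c(-48, 24, -8),
    ISP_TM = c(30, -10, 85),
    SSC    = c(-30, -10, 85),
    SSP    = c(0, 26, 46))
  rownames(insertion) <- rownames(guide) <- c("x", "y", "z")
  th <- inclination_deg * pi / 180
  spec <- list(
    schema = "glenosim-specimen-1",
    name = "reference",
    seed = NA_integer_,
    insertion_mm = insertion,
    guide_mm = guide,
    pcsa_cm2 = mp$pcsa_cm2,
    mvc_n = mp$mvc_n,
    loading_ratio = mp$loading_ratio,
    ssp_table = mp$ssp_table,
    couple_cap_adpd_n = mp$couple_cap_adpd_n,
    pretension_n = pretension_n,
    pretension_floor_n = 10,
    # humerus segment + forearm-replacement point masses (humeral frame, mm)
    mass_kg = c(humerus = 2.0, forearm = forearm_mass_kg),
    mass_pos_mm = cbind(humerus = c(0, -90, 0), forearm = c(0, -150, 0)),
    inertia_kgm2 = c(0.090, 0.090, 0.004),
    k_passive_nm_rad = c(3.0, 0.8, 1.2),
    c_passive_nms_rad = c(1.2, 1.0, 0.50),
    rest_deg = c(0, 0, 0),
    k_trans_n_mm = c(12, 18, 35),
    head_center_offset_mm = c(3, 4, -4),
    translation_ref_pose_deg = c(10, 0, 0),
    inclination_deg = inclination_deg,
    gravity_ms2 = c(0, -9.81 * cos(th), -9.81 * sin(th)),
    dislocation_limit_mm = 22,
    speed_limit_deg_s = 120,
    noise_sd = c(angle_deg = 0.1, force_n = 0.5, translation_mm = 0.1)
  )
  class(spec) <- "gh_specimen"
  spec
}

#' @export
print.gh_specimen <- function(x, ...) {
  cat(sprintf("Virtual glenohumeral specimen '%s'\n", x$name))
  cat(sprintf("  muscles: %s\n", paste(colnames(x$insertion_mm), collapse = ", ")))
  cat(sprintf("  masses: %.1f kg humerus + %.1f kg forearm replacement\n",
              x$mass_kg[1], x$mass_kg[2]))
  cat(sprintf("  pretension %.0f N; scapular inclination %.0f deg; seed %s\n",
              x$pretension_n, x$inclination_deg, as.character(x$seed)))
  invisible(x)
}

#' Torque of one muscle about the centre of rotation
#'
#' The cable pulls from its humeral insertion toward the guide point:
#' `tau = r x (F u)` with `r` the COR-to-insertion vector and `u` the unit
#' vector from insertion to guide, both expressed in the scapular frame at
#' the current orientation.
#'
#' @param specimen a `gh_specimen`.
#' @param muscle muscle name (one of MD, AD, PD, ISP_TM, SSC, SSP).
#' @param angles Cardan XZY angles (degrees) of the current pose.
#' @param force_n cable force (N, must be non-negative).
#' @return torque 3-vector (N m) in the scapular frame.
#' @export
moment_arm_torque <- function(specimen, muscle, angles, force_n) {
  if (force_n < 0) stop("cables cannot push: force must be non-negative")
  m <- match.arg(muscle, colnames(specimen$insertion_mm))
  R <- compose_orientation(angles)
  p <- as.numeric(R %*% specimen$insertion_mm[, m]) / 1000
  g <- specimen$guide_mm[, m] / 1000
  d <- g - p
  u <- d / sqrt(sum(d^2))
  f <- force_n * u
  unname(c(p[2] * f[3] - p[3] * f[2],
           p[3] * f[1] - p[1] * f[3],
           p[1] * f[2] - p[2] * f[1]))
}

#' Advance the plant by one control step
#'
#' Integrates the rigid-body dynamics with a fixed-step 4th-order
#' Runge-Kutta scheme, the six muscle forces held constant over the step,
#' and updates the quasi-static elastic translation of the humeral head.
#'
#' @param specimen a `gh_specimen`.
#' @param state plant state: list with `angles_deg` (3), `omega_deg_s` (3).
#' @param muscle_forces_n 6-vector of cable forces (N), ordered as
#'   MD, AD, PD, ISP_TM, SSC, SSP.
#' @param dt_s step size in (0, 0.02] seconds.
#' @return updated state list with `angles_deg`, `omega_deg_s`,
#'   `translation_mm` and `energy_j`.
#' @export
step_dynamics <- function(specimen, state, muscle_forces_n, dt_s = 0.005) {
  if (!(dt_s > 0 && dt_s <= 0.02)) stop("dt_s must lie in (0, 0.02]")
  f <- as.numeric(muscle_forces_n)
  if (length(f) != 6 || any(f < 0)) stop("need 6 non-negative muscle forces")
  if (any(f > specimen$mvc_n + 1e-9))
    stop("muscle force exceeds its kinetic constraint")
  y <- c(state$angles_deg, state$omega_deg_s)
  out <- cpp_plant_step(unclass(specimen), y, f, dt_s)
  tr <- out$translation_mm
  if (max(abs(tr)) > specimen$dislocation_limit_mm)
    stop("dislocation: translation exceeds the configured limit")
  if (max(abs(out$state[4:6])) > specimen$speed_limit_deg_s)
    stop("instability: angular speed exceeds the configured bound")
  list(angles_deg = out$state[1:3], omega_deg_s = out$state[4:6],
       translation_mm = tr, energy_j = out$energy_j)
}

#' Settle the plant passively under fixed cable forces
#'
#' Runs the plant from its passive rest configuration with constant muscle
#' forces (e.g. the centering pretension) until `duration_s`; used to find
#' the resting equilibrium that precedes every trial.
#'
#' @inheritParams step_dynamics
#' @param forces_n 6-vector of constant cable forces (N).
#' @param duration_s simulated time (default 12 s).
#' @param record_energy return the per-step mechanical energy trace.
#' @return list with `state` (angles + angular velocity, deg),
#'   `translation_mm`, and optionally `energy_j`.
#' @export
settle_passive <- function(specimen, forces_n, duration_s = 12, dt_s = 0.005,
                           record_energy = FALSE) {
  out <- cpp_passive_sim(unclass(specimen), as.numeric(forces_n), duration_s,
                         dt_s, record_energy)
  res <- list(state = list(angles_deg = out$state[1:3],
                           omega_deg_s = out$state[4:6]),
              translation_mm = out$translation_mm)
  if (record_energy) res$energy_j <- out$energy_j
  res
}

derive_seed <- function(root, index) {
  # documented splitting rule: distinct 31-bit child streams per entity
  as.integer((as.numeric(root) * 1031 + as.numeric(index) * 7919) %% 2147483647)
}

#' Generate a virtual specimen with seeded inter-specimen variability
#'
#' Perturbs the reference specimen: geometry points get isotropic Gaussian
#' offsets scaled by the point's distance from the COR, while masses,
#' inertia, stiffnesses and damping get multiplicative log-normal-like
#' factors. A generated specimen must pass the moment-arm sign checks (each
#' muscle still produces its anatomical action at 30 degrees abduction) and
#' the resting-equilibrium check (settles near 10 degrees abduction under
#' pretension); sampling is retried with perturbed child seeds and an error
#' is raised if no valid specimen is found.
#'
#' @param seed integer seed; the same seed always yields the same specimen.
#' @param variability fractional SD of the perturbations, in [0, 0.3]
#'   (default 0.10, emulating inter-cadaver variability).
#' @param max_tries rejection-sampling budget (default 25).
#' @return a `gh_specimen`.
#' @export
generate_specimen <- function(seed, variability = 0.10, max_tries = 25) {
  if (variability < 0 || variability > 0.3)
    stop("variability must lie in [0, 0.3]")
  base <- reference_specimen()
  if (variability == 0) {
    base$seed <- as.integer(seed)
    base$name <- sprintf("specimen-%d", as.integer(seed))
    return(base)
  }
  for (k in seq_len(max_tries)) {
    sp <- base
    set.seed(derive_seed(seed, 100L + k))
    pert_pts <- function(P) {
      scale <- pmax(sqrt(colSums(P^2)), 20)  # mm
      P + matrix(rnorm(length(P)), nrow(P), ncol(P)) *
        rep(variability * scale / sqrt(3), each = 3)
    }
    sp$insertion_mm <- pert_pts(base$insertion_mm)
    sp$guide_mm <- pert_pts(base$guide_mm)
    fac <- function(n) pmax(0.5, 1 + variability * rnorm(n))
    sp$mass_kg <- base$mass_kg * fac(2)
    sp$mass_pos_mm <- base$mass_pos_mm * rep(fac(2), each = 3)
    sp$inertia_kgm2 <- base$inertia_kgm2 * fac(3)
    sp$k_passive_nm_rad <- base$k_passive_nm_rad * fac(3)
    sp$c_passive_nms_rad <- base$c_passive_nms_rad * fac(3)
    sp$k_trans_n_mm <- base$k_trans_n_mm * fac(3)
    sp$head_center_offset_mm <- base$head_center_offset_mm * fac(3)
    sp$rest_deg <- base$rest_deg + c(variability * 20 * rnorm(1), 0, 0)
    sp$pretension_n <- min(20, max(10, base$pretension_n * fac(1)))
    sp$seed <- as.integer(seed)
    sp$name <- sprintf("specimen-%d", as.integer(seed))
    ok <- tryCatch(validate_specimen(sp), error = function(e) FALSE)
    if (isTRUE(ok)) return(sp)
  }
  stop(sprintf(
    "no valid specimen for seed %d after %d tries (sign or equilibrium check)",
    seed, max_tries))
}

#' Check a specimen's moment-arm signs and resting equilibrium
#'
#' @param specimen a `gh_specimen`.
#' @return `TRUE` invisibly; errors describe the failed check.
#' @export
validate_specimen <- function(specimen) {
  tq <- function(m, pose) moment_arm_torque(specimen, m, pose, 100)
  pose <- c(30, 0, 0)
  if (tq("MD", pose)[1] <= 0) stop("MD must produce positive abduction torque")
  if (tq("SSP", pose)[1] <= 0) stop("SSP must produce positive abduction torque")
  if (tq("AD", pose)[3] <= 0) stop("AD must produce positive flexion torque")
  if (tq("PD", pose)[3] >= 0) stop("PD must produce negative flexion torque")
  if (tq("SSC", pose)[2] <= 0) stop("SSC must produce internal-rotation torque")
  if (tq("ISP_TM", pose)[2] >= 0) stop("ISP/TM must produce external-rotation torque")
  # magnitude checks: the cables must retain enough leverage across the
  # protocol workspace to drive the joint within the kinetic constraints
  if (tq("MD", c(50, 0, 0))[1] < 3.0)
    stop("MD abduction moment arm too small at 50 deg abduction")
  if (tq("AD", c(50, 20, 0))[3] < 2.6 || tq("AD", c(30, 0, 30))[3] < 1.8)
    stop("AD flexion moment arm too small in the protocol workspace")
  if (tq("PD", c(50, -20, 0))[3] > -2.6 || tq("PD", c(30, 0, -30))[3] > -1.8)
    stop("PD extension moment arm too small in the protocol workspace")
  if (tq("SSC", c(30, 0, 35))[2] < 1.6 || tq("SSC", c(40, -25, 25))[2] < 1.2)
    stop("SSC rotation moment arm too small in the protocol workspace")
  if (tq("ISP_TM", c(30, 0, -35))[2] > -1.6)
    stop("ISP/TM rotation moment arm too small in the protocol workspace")
  # static feasibility: gravity demand in flexion/extension must stay within
  # what the AD/PD couple can deliver under its kinetic constraints
  gdem <- function(pose) {
    R <- compose_orientation(pose)
    tz <- 0
    for (j in seq_along(specimen$mass_kg)) {
      p <- as.numeric(R %*% specimen$mass_pos_mm[, j]) / 1000
      fg <- specimen$mass_kg[j] * specimen$gravity_ms2
      tz <- tz + p[1] * fg[2] - p[2] * fg[1]
    }
    tz
  }
  if (abs(gdem(c(50, 30, 0))) > 3.55 || abs(gdem(c(50, -30, 0))) > 3.55)
    stop("gravity flexion/extension demand exceeds couple capability")
  eq <- settle_passive(specimen, rep(specimen$pretension_n, 6), 15)
  if (abs(eq$state$angles_deg[1] - 10) > 6)
    stop(sprintf("resting abduction %.1f deg is not near 10 deg",
                 eq$state$angles_deg[1]))
  if (max(abs(eq$state$omega_deg_s)) > 0.5)
    stop("plant does not settle under pretension")
  if (max(abs(eq$translation_mm)) > 1.5)
    stop("humeral head not centered under pretension")
  invisible(TRUE)
}

#' Add sensor noise to a recorded trial trace
#'
#' Additive Gaussian noise on the reported angles, translations and muscle
#' forces, emulating tracker and load-cell noise. The plant state itself is
#' unaffected (the controller always saw the clean process variable); this
#' is purely observational noise on the recording.
#'
#' @param trace a trial-trace data frame (see [run_trial()]).
#' @param specimen the `gh_specimen` whose `noise_sd` applies.
#' @param seed integer seed for a reproducible noise stream.
#' @return the trace with noisy `pv_*`, `t_*` and `F_*` columns.
#' @export
add_sensor_noise <- function(trace, specimen, seed) {
  sds <- specimen$noise_sd
  if (any(sds < 0)) stop("noise SDs must be non-negative")
  set.seed(as.integer(seed))
  n <- nrow(trace)
  for (col in c("pv_abd", "pv_fe", "pv_rot"))
    trace[[col]] <- trace[[col]] + rnorm(n, 0, sds[["angle_deg"]])
  for (col in c("t_ap", "t_si", "t_ml"))
    trace[[col]] <- trace[[col]] + rnorm(n, 0, sds[["translation_mm"]])
  for (col in paste0("F_", MUSCLES))
    trace[[col]] <- trace[[col]] + rnorm(n, 0, sds[["force_n"]])
  trace
}

#' Read / write a specimen definition as YAML
#'
#' @param specimen a `gh_specimen`.
#' @param path YAML file path.
#' @return `read_specimen_yaml` returns the `gh_specimen`.
#' @export
write_specimen_yaml <- function(specimen, path) {
  x <- unclass(specimen)
  x$insertion_mm <- as.list(as.data.frame(x$insertion_mm))
  x$guide_mm <- as.list(as.data.frame(x$guide_mm))
  x$mass_pos_mm <- as.list(as.data.frame(x$mass_pos_mm))
  x$ssp_table <- as.list(as.data.frame(x$ssp_table))
  for (nm in c("pcsa_cm2", "mvc_n", "loading_ratio", "mass_kg", "noise_sd"))
    x[[nm]] <- as.list(x[[nm]])
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_specimen_yaml
#' @export
read_specimen_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  if (!identical(x$schema, "glenosim-specimen-1"))
    stop("unrecognized specimen schema: ", x$schema)
  mat <- function(l) {
    m <- do.call(cbind, l)
    rownames(m) <- c("x", "y", "z")
    m
  }
  x$insertion_mm <- mat(x$insertion_mm)
  x$guide_mm <- mat(x$guide_mm)
  x$mass_pos_mm <- mat(x$mass_pos_mm)
  x$ssp_table <- do.call(cbind, x$ssp_table)
  for (nm in c("pcsa_cm2", "mvc_n", "loading_ratio"))
    x[[nm]] <- unlist(x[[nm]])
  x$mass_kg <- unlist(x$mass_kg)
  x$noise_sd <- unlist(x$noise_sd)
  for (nm in c("inertia_kgm2", "k_passive_nm_rad", "c_passive_nms_rad",
               "rest_deg", "k_trans_n_mm", "gravity_ms2",
               "head_center_offset_mm", "translation_ref_pose_deg"))
    x[[nm]] <- as.numeric(unlist(x[[nm]]))
  class(x) <- "gh_specimen"
  x
}
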