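# The three-loop muscle-force controller.
#
# Three independent per-DOF loops (abduction, flexion/extension,
# internal/external rotation), each built from PID controllers in the
# time-constant form
#     u = Kc * ( e + (1/Ti) int e dt + Td de/dt ),   e = SP - PV [deg],
# with Ti and Td in minutes (the convention the gain table was tuned in;
# the minutes-to-seconds conversion is explicit and tested). Anti-windup is
# conditional integration: the accumulator freezes while the output is
# clamped and the error pushes further into the clamp.
#
# Two operating sequences:
#  - cascade (active abduction): the abduction activation controller drives
#    the middle deltoid; SSP is slaved through the abduction-dependent prior
#    ratio; the AD+PD and SSC+ISP/TM couple totals are slaved to the MD
#    force through the prior loading ratios; distribution controllers split
#    each total between antagonists (share clamped to 5-95% so neither cable
#    ever unloads).
#  - parallel (active F/E, rotation, or both): each couple total is
#    regulated by its own activation controller; the abduction loop holds
#    its constant setpoint through the MD.
#
# Physical rigs of this class run percent-of-range PID controllers on
# hydraulic actuators, so the gain table is dimensionless; mapping a PID
# output unit onto newtons of cable force (or share fraction) is a property
# of the actuation hardware, exposed here as the actuator scales in the
# gains config.

#' PID gain triple
#'
#' @param kc proportional gain (> 0).
#' @param ti_min integral time in minutes (> 0).
#' @param td_min derivative time in minutes (>= 0).
#' @return numeric length-3 vector `c(kc, ti_min, td_min)`.
#' @export
pid_gains <- function(kc, ti_min, td_min = 0) {
  stopifnot(kc > 0, ti_min > 0, td_min >= 0)
  c(kc = kc, ti_min = ti_min, td_min = td_min)
}

#' Default controller gains
#'
#' The shipped gain table: three loops x activation/distribution controllers,
#' with separate rows for trajectory tracking ("profile") and constant set
#' angles ("constant") where the loop is operated in both modes. The
#' abduction activation controller has both rows; the F/E and IR/ER loops
#' have one activation row each plus profile/constant distribution rows.
#'
#' `act_scale_abd`, `act_scale_couple` and `dist_scale` map a PID output
#' unit onto newtons of MD force, newtons of couple total, and share
#' fraction respectively. `ssp_slaved` keeps SSP slaved to MD through the
#' abduction-dependent ratio in parallel mode as well.
#'
#' @return list of class `gh_gains`.
#' @export
default_gains <- function() {
  g <- list(
    abd_act_profile  = pid_gains(2.600, 0.023, 0.000),
    abd_act_constant = pid_gains(1.400, 0.006, 0.001),
    fe_dist_profile  = pid_gains(0.030, 0.050, 0.000),
    fe_dist_constant = pid_gains(0.050, 0.070, 0.000),
    fe_act           = pid_gains(0.030, 0.050, 0.000),
    ir_dist_profile  = pid_gains(0.030, 0.060, 0.000),
    ir_dist_constant = pid_gains(0.050, 0.050, 0.000),
    ir_act           = pid_gains(0.020, 0.050, 0.000),
    act_scale_abd = 2.0,
    act_scale_couple = 350.0,
    dist_scale = 3.0,
    ssp_slaved = TRUE
  )
  class(g) <- "gh_gains"
  g
}

#' Read / write a gains file (YAML)
#'
#' @param gains a `gh_gains` list.
#' @param path YAML file path.
#' @return `read_gains_yaml` returns the `gh_gains`.
#' @export
write_gains_yaml <- function(gains, path) {
  yaml::write_yaml(lapply(unclass(gains), function(x)
    if (is.numeric(x)) as.numeric(x) else x), path)
  invisible(path)
}

#' @rdname write_gains_yaml
#' @export
read_gains_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  g <- default_gains()
  for (nm in names(x)) {
    if (!nm %in% names(g)) stop("unknown gains field: ", nm)
    g[[nm]] <- if (length(x[[nm]]) == 3)
      pid_gains(x[[nm]][1], x[[nm]][2], x[[nm]][3]) else x[[nm]]
  }
  g
}

#' Fresh (zeroed) PID state
#'
#' @return numeric vector `c(integ, prev_e, dfilt, has_prev)`, all zero.
#' @export
pid_state <- function() {
  c(integ = 0, prev_e = 0, dfilt = 0, has_prev = 0)
}

#' One PID step
#'
#' Advances one controller tick: accumulates the error integral (with
#' conditional-integration anti-windup against the output limits), updates
#' the filtered error derivative, and returns the clamped output.
#'
#' @param gains a [pid_gains()] triple.
#' @param state a [pid_state()] vector (returned updated).
#' @param sp_deg,pv_deg setpoint and process variable (degrees).
#' @param dt_s step size (s, > 0).
#' @param lo,hi output clamp (PID output units).
#' @return list with `u`, updated `state`, and `saturated`.
#' @export
pid_step <- function(gains, state, sp_deg, pv_deg, dt_s,
                     lo = -Inf, hi = Inf) {
  stopifnot(dt_s > 0)
  out <- cpp_pid_step(gains[[1]], gains[[2]], gains[[3]], as.numeric(state),
                      sp_deg, pv_deg, dt_s, lo, hi)
  names(out$state) <- c("integ", "prev_e", "dfilt", "has_prev")
  out
}

#' Supraspinatus loading ratio at a given abduction angle
#'
#' Piecewise-linear interpolation through the three-knot prior-ratio table
#' (0.99 at 10 deg, 0.52 at 30 deg, 0.30 at 60 deg), clamped outside.
#'
#' @param abduction_deg current abduction (degrees).
#' @param table optional 3x2 knot matrix (columns: abduction, ratio).
#' @return ratio of SSP force to MD force.
#' @export
#' @examples
#' ssp_ratio(30)   # 0.52
#' ssp_ratio(45)   # 0.41
ssp_ratio <- function(abduction_deg, table = muscle_params()$ssp_table) {
  stopifnot(all(is.finite(abduction_deg)))
  approx(table[, 1], table[, 2], xout = abduction_deg, rule = 2)$y
}

#' Fresh controller state for all five PID controllers
#'
#' Rows: abduction activation, F/E activation, F/E distribution, IR/ER
#' activation, IR/ER distribution; columns: integrator, previous error,
#' filtered derivative, has-previous flag.
#'
#' @return 5x4 numeric matrix of zeros.
#' @export
control_state <- function() {
  matrix(0, 5, 4, dimnames = list(
    c("abd_act", "fe_act", "fe_dist", "ir_act", "ir_dist"),
    c("integ", "prev_e", "dfilt", "has_prev")))
}

control_tick <- function(specimen, gains, state, sp, pv, dt_s, mode,
                         abd_profile, fe_profile, ir_profile,
                         fe_dir = 1, ir_dir = 1) {
  out <- cpp_control_tick(unclass(specimen), unclass(gains), state,
                          as.numeric(sp), as.numeric(pv), dt_s,
                          as.integer(mode == "parallel"),
                          as.integer(abd_profile), as.integer(fe_profile),
                          as.integer(ir_profile), as.integer(fe_dir),
                          as.integer(ir_dir))
  dimnames(out$state) <- dimnames(control_state())
  names(out$forces_n) <- MUSCLES
  out
}

#' One tick of the cascade loading algorithm (active abduction)
#'
#' The abduction loop runs in profile mode and drives the MD; SSP follows
#' via [ssp_ratio()]; the AD+PD total is `0.60 x MD` and the SSC+ISP/TM
#' total `1.00 x MD` (the prior loading ratios); the distribution
#' controllers split each total with a share clamped to 5-95%, and every
#' muscle is clamped to `[pretension floor, kinetic constraint]`.
#'
#' @param specimen a `gh_specimen`.
#' @param gains a `gh_gains` list.
#' @param state a [control_state()] matrix.
#' @param sp,pv setpoint and measured Cardan angles (deg, length 3).
#' @param dt_s controller step (s).
#' @return list with `forces_n` (6, named), updated `state`, `share_fe`,
#'   `share_ir`, raw couple totals and `sat_flags`.
#' @export
cascade_step <- function(specimen, gains, state, sp, pv, dt_s = 0.005) {
  if (any(!is.finite(pv))) stop("NaN in process variable: aborting trial")
  control_tick(specimen, gains, state, sp, pv, dt_s, "cascade",
               abd_profile = TRUE, fe_profile = FALSE, ir_profile = FALSE)
}

#' One tick of the parallel loading algorithm (active F/E and/or rotation)
#'
#' The F/E and IR/ER couple totals come from their own activation
#' controllers; the abduction loop holds its constant setpoint through the
#' MD (constant-mode gains) with SSP slaved; distribution and clamping as in
#' [cascade_step()].
#'
#' @inheritParams cascade_step
#' @param fe_profile,ir_profile whether each secondary loop tracks a
#'   trajectory (profile distribution gains) or holds constant.
#' @param fe_dir,ir_dir commanded motion direction of each secondary DOF
#'   (+1 or -1); the activation error is signed by it so the couple total
#'   rises while the motion lags in the commanded direction.
#' @export
parallel_step <- function(specimen, gains, state, sp, pv, dt_s = 0.005,
                          fe_profile = TRUE, ir_profile = FALSE,
                          fe_dir = 1, ir_dir = 1) {
  if (any(!is.finite(pv))) stop("NaN in process variable: aborting trial")
  control_tick(specimen, gains, state, sp, pv, dt_s, "parallel",
               abd_profile = FALSE, fe_profile = fe_profile,
               ir_profile = ir_profile, fe_dir = fe_dir, ir_dir = ir_dir)
}

#' Operating sequence and gain rows for a motion protocol
#'
#' Abduction-primary protocols run the cascade loading algorithm; all others
#' run parallel, with each loop assigned its profile or constant gain row.
#'
#' @param motion protocol name (see [build_profile()]).
#' @return list with `algorithm` ("cascade"/"parallel") and logical
#'   `abd_profile`, `fe_profile`, `ir_profile`.
#' @export
#' @examples
#' select_mode("abduction")
#' select_mode("extension_internal_rotation")
select_mode <- function(motion) {
  motion <- match.arg(motion, PROTOCOLS)
  switch(motion,
    abduction = list(algorithm = "cascade", abd_profile = TRUE,
                     fe_profile = FALSE, ir_profile = FALSE),
    flexion = ,
    extension = list(algorithm = "parallel", abd_profile = FALSE,
                     fe_profile = TRUE, ir_profile = FALSE),
    internal_rotation = ,
    external_rotation = list(algorithm = "parallel", abd_profile = FALSE,
                             fe_profile = FALSE, ir_profile = TRUE),
    extension_internal_rotation = list(algorithm = "parallel",
                                       abd_profile = FALSE,
                                       fe_profile = TRUE, ir_profile = TRUE))
}
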