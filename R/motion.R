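# The motion library: time-parameterized setpoint trajectories for the six
# standard protocols (five planar, one non-planar), all at 0.5 deg/s.
#
# Every trial has four phases:
#   load   - cascade muscle loading ramps abduction from the resting posture
#            (~10 deg) to the protocol's start configuration;
#   settle - a hold (default 10 s) so the constant-mode loops converge;
#   scored - the protocol's ramp(s), the only segment entering the metrics;
#   tail   - a short terminal hold.

protocol_table <- function() {
  list(
    abduction = list(start = c(20, 0, 0), primary = "abd",
                     range = c(20, 60)),
    flexion = list(start = c(50, 0, 0), primary = "fe",
                   range = c(0, 30)),
    extension = list(start = c(50, 0, 0), primary = "fe",
                     range = c(0, -30)),
    internal_rotation = list(start = c(30, 0, 0), primary = "rot",
                             range = c(0, 45)),
    external_rotation = list(start = c(30, 0, 0), primary = "rot",
                             range = c(0, -45)),
    extension_internal_rotation = list(start = c(40, 0, 0),
                                       primary = c("fe", "rot"),
                                       range = cbind(fe = c(0, -30),
                                                     rot = c(0, 30)))
  )
}

#' Build a sampled motion profile
#'
#' Returns the setpoint time series for all three rotational DOF of one
#' protocol, sampled at the controller step, including the initial loading
#' ramp from the resting abduction to the protocol's start configuration.
#' Ramps are linear at exactly `velocity_deg_s`; all secondary-DOF setpoints
#' are constant over the scored segment. For the coupled
#' extension+internal-rotation protocol both DOF ramp at the configured
#' velocity and (their ranges being equal) finish together.
#'
#' @param name one of "abduction", "flexion", "extension",
#'   "internal_rotation", "external_rotation",
#'   "extension_internal_rotation".
#' @param velocity_deg_s target angular velocity (default 0.5 deg/s).
#' @param dt_s sample step (default 0.005 s).
#' @param settle_s hold between loading and the scored segment (default 10 s).
#' @param tail_s terminal hold (default 2 s).
#' @param resting_abduction_deg resting abduction the loading ramp starts
#'   from (default 10).
#' @return object of class `motion_profile`: a data frame with columns
#'   `time_s, sp_abd, sp_fe, sp_rot, phase` (0 load, 1 settle, 2 scored,
#'   3 tail) and attributes `name`, `mode` (from [select_mode()]), `primary`,
#'   `range`, `velocity_deg_s`.
#' @export
#' @examples
#' p <- build_profile("abduction", dt_s = 0.05)
#' range(p$sp_abd[p$phase == 2])   # 20..60
build_profile <- function(name, velocity_deg_s = 0.5, dt_s = 0.005,
                          settle_s = 10, tail_s = 2,
                          resting_abduction_deg = 10) {
  name <- match.arg(name, PROTOCOLS)
  if (velocity_deg_s <= 0) stop("velocity must be positive")
  pt <- protocol_table()[[name]]
  start <- pt$start

  load_span <- abs(start[1] - resting_abduction_deg)
  t_load <- load_span / velocity_deg_s
  rng <- pt$range
  span <- if (is.matrix(rng)) max(abs(rng[2, ] - rng[1, ])) else
    abs(rng[2] - rng[1])
  t_scored <- span / velocity_deg_s

  t_end <- t_load + settle_s + t_scored + tail_s
  time <- seq(0, t_end, by = dt_s)
  n <- length(time)

  ramp <- function(t, t0, t1, v0, v1) {
    # linear segment between (t0,v0) and (t1,v1), held outside
    pmin(pmax((t - t0) / max(t1 - t0, .Machine$double.eps), 0), 1) *
      (v1 - v0) + v0
  }

  sp <- matrix(0, n, 3, dimnames = list(NULL, c("abd", "fe", "rot")))
  sp[, "abd"] <- ramp(time, 0, t_load, resting_abduction_deg, start[1])
  sp[, "fe"] <- start[2]
  sp[, "rot"] <- start[3]

  t0 <- t_load + settle_s
  prim <- pt$primary
  if (is.matrix(rng)) {
    for (d in colnames(rng))
      sp[, d] <- ramp(time, t0, t0 + t_scored, rng[1, d], rng[2, d])
  } else {
    sp[, prim] <- ramp(time, t0, t0 + t_scored, rng[1], rng[2])
  }

  phase <- rep(0L, n)
  phase[time >= t_load & time < t0] <- 1L
  phase[time >= t0 & time <= t0 + t_scored] <- 2L
  phase[time > t0 + t_scored] <- 3L

  out <- data.frame(time_s = time, sp_abd = sp[, "abd"], sp_fe = sp[, "fe"],
                    sp_rot = sp[, "rot"], phase = phase)
  attr(out, "name") <- name
  attr(out, "mode") <- select_mode(name)
  attr(out, "primary") <- prim
  attr(out, "range") <- rng
  dirs <- c(fe = 1, rot = 1)
  if (is.matrix(rng)) {
    for (d in colnames(rng)) dirs[d] <- sign(rng[2, d] - rng[1, d])
  } else if (prim %in% names(dirs)) {
    dirs[prim] <- sign(rng[2] - rng[1])
  }
  attr(out, "directions") <- dirs
  attr(out, "velocity_deg_s") <- velocity_deg_s
  class(out) <- c("motion_profile", "data.frame")
  out
}

#' Read custom protocol definitions from YAML
#'
#' A protocol file maps names to `start` (3 angles), `primary` (dof name or
#' two names) and `range` (2 values, or a 2-column matrix for coupled
#' motions), allowing custom ranges and velocities beyond the six built-ins.
#'
#' @param path YAML file.
#' @return named list of protocol definitions.
#' @export
read_protocols_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  lapply(x, function(p) {
    stopifnot(length(p$start) == 3)
    if (is.list(p$range)) p$range <- do.call(cbind, p$range)
    p$start <- as.numeric(p$start)
    p
  })
}
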