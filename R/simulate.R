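# Trial and campaign drivers: run one motion protocol on one specimen, or a
# full campaign (specimens x protocols x repeats), with reproducible seeding
# and optional observational sensor noise.

TRACE_COLS <- c("time_s", "phase", "sp_abd", "sp_fe", "sp_rot",
                "pv_abd", "pv_fe", "pv_rot", "t_ap", "t_si", "t_ml",
                paste0("F_", MUSCLES), "share_fe", "share_ir",
                "tot_fe_raw", "tot_ir_raw", "sat_flags")

#' Run one motion trial
#'
#' Settles the plant under pretension, then runs the protocol's loading
#' phase (cascade), settling hold and scored segment with the controller at
#' every plant step (dt = 5 ms by default). The recorded trace is decimated
#' to `record_dt_s`. Translations are reported raw here; referencing to the
#' 20-degree-abduction pose happens in the evaluation pipeline.
#'
#' @param specimen a `gh_specimen`.
#' @param profile a [build_profile()] object (or protocol name).
#' @param gains a `gh_gains` list (default [default_gains()]).
#' @param dt_s plant/controller step (default 0.005 s).
#' @param record_dt_s recording interval (default 0.05 s).
#' @param noise_seed if non-NULL, apply [add_sensor_noise()] with this seed.
#' @return a `trial_trace` data frame (see `TRACE_COLS`) with metadata
#'   attributes `protocol`, `specimen`, `status`.
#' @export
run_trial <- function(specimen, profile, gains = default_gains(),
                      dt_s = 0.005, record_dt_s = 0.05, noise_seed = NULL) {
  if (is.character(profile)) profile <- build_profile(profile, dt_s = dt_s)
  mode <- attr(profile, "mode")
  decim <- max(1L, as.integer(round(record_dt_s / dt_s)))

  eq <- settle_passive(specimen, rep(specimen$pretension_n, 6), 12, dt_s)
  init <- c(eq$state$angles_deg, eq$state$omega_deg_s)

  pm <- as.matrix(profile[, c("time_s", "sp_abd", "sp_fe", "sp_rot", "phase")])
  dirs <- attr(profile, "directions")
  if (is.null(dirs)) dirs <- c(fe = 1, rot = 1)
  out <- cpp_run_trial(unclass(specimen), unclass(gains), pm,
                       as.integer(mode$algorithm == "parallel"),
                       as.integer(mode$fe_profile),
                       as.integer(mode$ir_profile),
                       as.integer(dirs[["fe"]]), as.integer(dirs[["rot"]]),
                       init, dt_s, decim)
  if (out$status == 1L)
    stop("dislocation: humeral-head translation exceeded the limit")
  if (out$status == 2L)
    stop("instability: angular speed exceeded the configured bound")

  tr <- as.data.frame(out$trace)
  colnames(tr) <- TRACE_COLS
  if (!is.null(noise_seed)) tr <- add_sensor_noise(tr, specimen, noise_seed)
  attr(tr, "protocol") <- attr(profile, "name")
  attr(tr, "primary") <- attr(profile, "primary")
  attr(tr, "specimen") <- specimen$name
  attr(tr, "status") <- out$status
  class(tr) <- c("trial_trace", "data.frame")
  tr
}

#' Simulate a full campaign in memory
#'
#' One trial per specimen x protocol x repeat. Repeats fully re-zero the
#' plant (fresh settle from rest) and differ only in their sensor-noise
#' stream; specimens are generated from seeds derived from `seed`.
#'
#' @param seed root seed; per-specimen and per-repeat child seeds are
#'   derived deterministically from it.
#' @param n_specimens number of virtual specimens (default 3).
#' @param protocols character vector of protocol names (default all six).
#' @param repeats repeats per motion (default 3).
#' @param variability inter-specimen variability fraction (default 0.10).
#' @param noise logical: apply sensor noise (default TRUE).
#' @param gains a `gh_gains` list.
#' @param dt_s,record_dt_s see [run_trial()].
#' @param reference_specimen_first if TRUE the first specimen is the
#'   unperturbed reference.
#' @return object of class `gh_campaign`: list with `traces` (list of
#'   `trial_trace`), `specimens`, and a `manifest` data frame (one row per
#'   trial: specimen, protocol, repeat, seed, status).
#' @export
simulate_campaign <- function(seed = 1, n_specimens = 3,
                              protocols = PROTOCOLS, repeats = 3,
                              variability = 0.10, noise = TRUE,
                              gains = default_gains(), dt_s = 0.005,
                              record_dt_s = 0.05,
                              reference_specimen_first = FALSE) {
  protocols <- match.arg(protocols, PROTOCOLS, several.ok = TRUE)
  specimens <- lapply(seq_len(n_specimens), function(i) {
    if (reference_specimen_first && i == 1) {
      sp <- reference_specimen()
      sp$seed <- 0L
      sp
    } else generate_specimen(derive_seed(seed, i), variability)
  })
  profiles <- lapply(protocols, build_profile, dt_s = dt_s)
  names(profiles) <- protocols

  traces <- list()
  manifest <- list()
  k <- 0L
  for (i in seq_along(specimens)) {
    for (p in protocols) {
      for (r in seq_len(repeats)) {
        k <- k + 1L
        nseed <- if (noise) derive_seed(seed, 10000L + 100L * i +
                                          10L * match(p, PROTOCOLS) + r)
                 else NULL
        tr <- run_trial(specimens[[i]], profiles[[p]], gains, dt_s,
                        record_dt_s, noise_seed = nseed)
        attr(tr, "repeat") <- r
        traces[[k]] <- tr
        manifest[[k]] <- data.frame(
          specimen = specimens[[i]]$name, specimen_index = i, protocol = p,
          rep = r, noise_seed = if (is.null(nseed)) NA_integer_ else nseed,
          status = attr(tr, "status"))
      }
    }
  }
  out <- list(traces = traces, specimens = specimens,
              manifest = do.call(rbind, manifest),
              seed = seed, protocols = protocols, repeats = repeats,
              noise = noise)
  class(out) <- "gh_campaign"
  out
}

#' @export
print.gh_campaign <- function(x, ...) {
  cat(sprintf("Simulation campaign: %d specimens x %d protocols x %d repeats = %d trials (seed %s)\n",
              length(x$specimens), length(x$protocols), x$repeats,
              nrow(x$manifest), as.character(x$seed)))
  cat(sprintf("  protocols: %s\n", paste(x$protocols, collapse = ", ")))
  cat(sprintf("  sensor noise: %s\n", if (x$noise) "on" else "off"))
  invisible(x)
}

#' Write / read a trial trace as CSV
#'
#' One row per recorded control tick: time, setpoints and process variables
#' for the three DOF (deg), AP/SI/ML translations (mm) and the six muscle
#' forces (N), plus controller bookkeeping columns. Metadata is stored in
#' comment-style header lines.
#'
#' @param trace a `trial_trace`.
#' @param path CSV path.
#' @return `read_trace_csv` returns the `trial_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# protocol=%s specimen=%s repeat=%s",
                     attr(trace, "protocol"), attr(trace, "specimen"),
                     as.character(attr(trace, "repeat"))), con)
  write.csv(as.data.frame(trace), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  tr <- read.csv(path, comment.char = "#")
  meta <- regmatches(hdr, gregexpr("[a-z]+=[^ ]+", hdr))[[1]]
  kv <- strsplit(meta, "=")
  for (p in kv) {
    key <- c(protocol = "protocol", specimen = "specimen",
             "repeat" = "repeat")[p[1]]
    if (!is.na(key)) attr(tr, key) <- if (key == "repeat")
      as.integer(p[2]) else p[2]
  }
  attr(tr, "primary") <- protocol_table()[[attr(tr, "protocol")]]$primary
  class(tr) <- c("trial_trace", "data.frame")
  tr
}

#' Plot a trial trace
#'
#' Setpoint and achieved angle for each DOF, plus the deviation, against
#' time (base graphics).
#'
#' @param x a `trial_trace`.
#' @param dof one of "abd", "fe", "rot".
#' @param ... passed to [plot()].
#' @export
plot.trial_trace <- function(x, dof = "abd", ...) {
  dof <- match.arg(dof, DOF_NAMES)
  sp <- x[[paste0("sp_", dof)]]
  pv <- x[[paste0("pv_", dof)]]
  plot(x$time_s, sp, type = "l", col = "blue", xlab = "time (s)",
       ylab = sprintf("%s angle (deg)", dof),
       main = sprintf("%s: %s", attr(x, "protocol"), dof), ...)
  graphics::lines(x$time_s, pv, col = "red")
  graphics::legend("topleft", c("setpoint", "achieved"), lty = 1,
                   col = c("blue", "red"), bty = "n")
  invisible(x)
}
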