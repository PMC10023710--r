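# The data-analysis pipeline: 1-degree resampling, accuracy (mean deviation
# and RMSE between setpoint and achieved angles), repeatability (SD across
# repeats) and reliability (single-measurement absolute-agreement two-way
# ICC with 95% CI) for translations and muscle forces.

#' Resample a trial onto the 1-degree setpoint grid
#'
#' Interpolates the scored segment of a trace onto the integer-degree grid
#' of the profiled DOF's setpoint (inclusive at both ends; descending for
#' negative-going ramps such as external rotation). Translations are
#' referenced to the 20-degree-abduction pose of the loading phase, the
#' point at which initial muscle loading is complete.
#'
#' @param trace a `trial_trace`.
#' @param increment_deg grid step (default 1).
#' @param reference_abduction_deg abduction angle defining the translation
#'   reference pose (default 20).
#' @return data frame: `grid_deg`, `sp_*`, `pv_*` (deg), `t_*` (mm,
#'   referenced), `F_*` (N); attribute `grid_dof`.
#' @export
resample_by_angle <- function(trace, increment_deg = 1,
                              reference_abduction_deg = 20) {
  prim <- attr(trace, "primary")[1]
  sc <- trace[trace$phase == 2, ]
  if (nrow(sc) < 2) stop("trace has no scored segment")
  x <- sc[[paste0("sp_", prim)]]
  dx <- diff(x)
  if (!(all(dx >= 0) || all(dx <= 0)) || x[1] == x[length(x)])
    stop("profiled-DOF setpoint is not monotone over the scored segment")
  desc <- x[length(x)] < x[1]
  grid <- seq(ceiling(min(x)), floor(max(x)), by = increment_deg)
  if (desc) grid <- rev(grid)

  # translation reference: first loading-phase tick at >= 20 deg abduction
  # (or the closest achieved pose when loading starts above it)
  ld <- trace[trace$phase <= 1, ]
  iref <- which(ld$pv_abd >= reference_abduction_deg)[1]
  if (is.na(iref)) iref <- which.max(ld$pv_abd)
  win <- max(1, iref - 10):min(nrow(ld), iref + 10)  # ~1 s averaging window
  tref <- colMeans(ld[win, c("t_ap", "t_si", "t_ml"), drop = FALSE])

  cols <- setdiff(colnames(trace), c("phase", "sat_flags"))
  out <- data.frame(grid_deg = grid)
  for (cl in cols) {
    v <- approx(x, sc[[cl]], xout = grid, ties = mean)$y
    if (cl %in% c("t_ap", "t_si", "t_ml"))
      v <- v - tref[match(cl, c("t_ap", "t_si", "t_ml"))]
    out[[cl]] <- v
  }
  attr(out, "grid_dof") <- prim
  attr(out, "protocol") <- attr(trace, "protocol")
  attr(out, "specimen") <- attr(trace, "specimen")
  attr(out, "repeat") <- attr(trace, "repeat")
  out
}

#' Accuracy: maximum mean deviation and RMSE
#'
#' At each grid point the mean deviation is the across-trace mean of
#' (achieved - setpoint); the reported maximum mean deviation is the largest
#' absolute value of that curve over the grid. The RMSE pools squared
#' deviations over grid points and traces.
#'
#' @param resampled list of [resample_by_angle()] frames on a common grid.
#' @param dof one of "abd", "fe", "rot".
#' @return list with `max_mean_dev_deg`, `rmse_deg` and the per-grid-point
#'   `mean_dev_deg` curve.
#' @export
accuracy_metrics <- function(resampled, dof) {
  dof <- match.arg(dof, DOF_NAMES)
  if (length(resampled) < 1) stop("need at least one trace")
  dev <- sapply(resampled, function(r)
    r[[paste0("pv_", dof)]] - r[[paste0("sp_", dof)]])
  dev <- matrix(dev, ncol = length(resampled))
  mean_dev <- rowMeans(dev)
  list(max_mean_dev_deg = max(abs(mean_dev)),
       rmse_deg = sqrt(mean(dev^2)),
       mean_dev_deg = mean_dev)
}

#' Repeatability: maximum and average SD across repeats
#'
#' Sample SD (n-1) of the achieved angle across repeats at each grid point;
#' reported as its maximum and its grid average.
#'
#' @param resampled list of repeats (>= 2) of one motion on one specimen.
#' @param dof one of "abd", "fe", "rot".
#' @return list with `max_sd_deg`, `avg_sd_deg`, `sd_deg` (per grid point).
#' @export
repeatability_sd <- function(resampled, dof) {
  dof <- match.arg(dof, DOF_NAMES)
  if (length(resampled) < 2) stop("need at least two repeats")
  pv <- sapply(resampled, function(r) r[[paste0("pv_", dof)]])
  s <- apply(pv, 1, sd)
  list(max_sd_deg = max(s), avg_sd_deg = mean(s), sd_deg = s)
}

#' ICC(A,1): single-measurement, absolute-agreement, two-way model
#'
#' From the two-way ANOVA decomposition of an n x k matrix (rows: grid
#' points, columns: repeated measurements),
#' `ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`,
#' with the 95% confidence interval by the F-based absolute-agreement
#' method of McGraw & Wong (1996). Mixed vs random effects changes the
#' interpretation, not the estimate.
#'
#' @param m numeric matrix, n >= 5 rows (subjects/grid points), k >= 2
#'   columns (repeats), finite entries.
#' @param conf confidence level (default 0.95).
#' @return list with `estimate`, `ci_lower`, `ci_upper`, `ms` (MSR, MSC,
#'   MSE) and `degenerate` (TRUE when all entries are equal, in which case
#'   the estimate is 1 with a degenerate CI).
#' @export
icc_a1 <- function(m, conf = 0.95) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 5 || k < 2) stop("need at least 5 rows and 2 columns")
  if (!all(is.finite(m))) stop("matrix entries must be finite")
  gm <- mean(m)
  rm <- rowMeans(m); cm <- colMeans(m)
  SSR <- k * sum((rm - gm)^2)
  SSC <- n * sum((cm - gm)^2)
  SST <- sum((m - gm)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (SST < .Machine$double.eps * n * k) {
    return(list(estimate = 1, ci_lower = NA_real_, ci_upper = NA_real_,
                ms = c(MSR = MSR, MSC = MSC, MSE = MSE), degenerate = TRUE))
  }
  denom <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
  est <- (MSR - MSE) / denom
  alpha <- 1 - conf
  a <- (k * est) / (n * (1 - est))
  b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  if (!is.finite(v)) {
    # perfect agreement (MSE = MSC = 0): the F-based interval collapses
    return(list(estimate = est, ci_lower = NA_real_, ci_upper = NA_real_,
                ms = c(MSR = MSR, MSC = MSC, MSE = MSE), degenerate = FALSE))
  }
  f1 <- qf(1 - alpha / 2, n - 1, v)
  f2 <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - f1 * MSE) /
    (f1 * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (f2 * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * f2 * MSR)
  list(estimate = est, ci_lower = lower, ci_upper = upper,
       ms = c(MSR = MSR, MSC = MSC, MSE = MSE), degenerate = FALSE)
}

#' Interpret an ICC value
#'
#' Reliability bands: below 0.5 poor, 0.5-0.75 moderate, 0.75-0.9 good,
#' 0.90 and above excellent.
#'
#' @param value ICC in [-1, 1].
#' @return one of "poor", "moderate", "good", "excellent".
#' @export
#' @examples
#' interpret_icc(0.95)
interpret_icc <- function(value) {
  if (!is.finite(value) || value < -1 || value > 1)
    stop("ICC must lie in [-1, 1]")
  if (value < 0.5) "poor"
  else if (value < 0.75) "moderate"
  else if (value < 0.9) "good"
  else "excellent"
}

common_grid <- function(resampled) {
  grids <- lapply(resampled, function(r) r$grid_deg)
  g <- grids[[1]]
  for (gg in grids) g <- g[g %in% gg]
  lapply(resampled, function(r) r[match(g, r$grid_deg), , drop = FALSE])
}

#' Evaluate a campaign: the full metrics report
#'
#' Per protocol and rotational DOF: maximum mean deviation and RMSE pooled
#' over all specimens and repeats, and the maximum / average across-repeat
#' SD (computed per specimen, reported as the maximum over specimens). Per
#' translation axis and per muscle: ICC(A,1) with 95% CI over the repeats
#' (rows: 1-degree grid points, pooled across specimens by default) plus the
#' reliability category.
#'
#' @param campaign a `gh_campaign` (or plain list of `trial_trace`s).
#' @param increment_deg evaluation grid step (default 1).
#' @param pool_specimens pool grid points of all specimens into one ICC
#'   matrix (default TRUE); otherwise ICC is averaged per specimen.
#' @return object of class `gh_report`: list with data frames `accuracy`
#'   (protocol x dof), `icc_translation`, `icc_force`.
#' @export
evaluate_campaign <- function(campaign, increment_deg = 1,
                              pool_specimens = TRUE) {
  traces <- if (inherits(campaign, "gh_campaign")) campaign$traces
            else campaign
  meta <- data.frame(
    protocol = vapply(traces, function(t) attr(t, "protocol"), ""),
    specimen = vapply(traces, function(t) attr(t, "specimen"), ""),
    rep = vapply(traces, function(t) as.integer(attr(t, "repeat")), 0L))
  res <- lapply(traces, resample_by_angle, increment_deg = increment_deg)

  acc <- list(); icct <- list(); iccf <- list()
  for (p in unique(meta$protocol)) {
    ip <- which(meta$protocol == p)
    rp <- common_grid(res[ip])
    mp <- meta[ip, ]
    for (d in DOF_NAMES) {
      a <- accuracy_metrics(rp, d)
      sds <- lapply(unique(mp$specimen), function(s)
        repeatability_sd(rp[mp$specimen == s], d))
      acc[[length(acc) + 1]] <- data.frame(
        protocol = p, dof = d,
        max_mean_dev_deg = a$max_mean_dev_deg, rmse_deg = a$rmse_deg,
        max_sd_deg = max(vapply(sds, `[[`, 0, "max_sd_deg")),
        avg_sd_deg = max(vapply(sds, `[[`, 0, "avg_sd_deg")))
    }
    icc_for <- function(col) {
      reps <- sort(unique(mp$rep))
      if (pool_specimens) {
        m <- do.call(rbind, lapply(unique(mp$specimen), function(s) {
          sapply(reps, function(r)
            rp[[which(mp$specimen == s & mp$rep == r)]][[col]])
        }))
        icc_a1(m)
      } else {
        per <- lapply(unique(mp$specimen), function(s) {
          m <- sapply(reps, function(r)
            rp[[which(mp$specimen == s & mp$rep == r)]][[col]])
          icc_a1(m)
        })
        est <- mean(vapply(per, `[[`, 0, "estimate"))
        list(estimate = est,
             ci_lower = mean(vapply(per, `[[`, 0, "ci_lower")),
             ci_upper = mean(vapply(per, `[[`, 0, "ci_upper")),
             degenerate = any(vapply(per, `[[`, TRUE, "degenerate")))
      }
    }
    for (ax in c("t_ap", "t_si", "t_ml")) {
      ic <- icc_for(ax)
      icct[[length(icct) + 1]] <- data.frame(
        protocol = p, axis = sub("t_", "", ax), icc = ic$estimate,
        ci_lower = ic$ci_lower, ci_upper = ic$ci_upper,
        category = interpret_icc(min(1, max(-1, ic$estimate))))
    }
    for (mu in MUSCLES) {
      ic <- icc_for(paste0("F_", mu))
      iccf[[length(iccf) + 1]] <- data.frame(
        protocol = p, muscle = mu, icc = ic$estimate,
        ci_lower = ic$ci_lower, ci_upper = ic$ci_upper,
        category = interpret_icc(min(1, max(-1, ic$estimate))))
    }
  }
  out <- list(accuracy = do.call(rbind, acc),
              icc_translation = do.call(rbind, icct),
              icc_force = do.call(rbind, iccf),
              increment_deg = increment_deg,
              pool_specimens = pool_specimens)
  class(out) <- "gh_report"
  out
}

#' @export
print.gh_report <- function(x, digits = 3, ...) {
  cat("Kinematic accuracy and repeatability (deg):\n")
  print(format(x$accuracy, digits = digits), row.names = FALSE)
  cat("\nICC(A,1), translations:\n")
  print(format(x$icc_translation, digits = digits), row.names = FALSE)
  cat("\nICC(A,1), muscle forces:\n")
  print(format(x$icc_force, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.gh_report <- function(object, icc_threshold = 0.90, ...) {
  a <- object$accuracy
  tf <- object$icc_translation
  ff <- object$icc_force
  out <- list(
    max_mean_dev_deg = max(a$max_mean_dev_deg),
    max_rmse_deg = max(a$rmse_deg),
    max_sd_deg = max(a$max_sd_deg),
    max_avg_sd_deg = max(a$avg_sd_deg),
    icc_threshold = icc_threshold,
    n_force_above = sum(ff$ci_lower > icc_threshold, na.rm = TRUE),
    n_force_total = nrow(ff),
    n_translation_above = sum(tf$ci_lower > icc_threshold, na.rm = TRUE),
    n_translation_total = nrow(tf))
  class(out) <- "summary.gh_report"
  out
}

#' @export
print.summary.gh_report <- function(x, ...) {
  cat(sprintf("Global maxima over protocols and DOF:\n"))
  cat(sprintf("  max mean deviation %.2f deg, RMSE %.2f deg\n",
              x$max_mean_dev_deg, x$max_rmse_deg))
  cat(sprintf("  max SD %.2f deg, average SD %.2f deg\n",
              x$max_sd_deg, x$max_avg_sd_deg))
  cat(sprintf("ICC 95%% CI lower bound > %.2f:\n", x$icc_threshold))
  cat(sprintf("  muscle forces: %d / %d instances\n",
              x$n_force_above, x$n_force_total))
  cat(sprintf("  translations: %d / %d instances\n",
              x$n_translation_above, x$n_translation_total))
  invisible(x)
}

#' Write a metrics report to JSON and flat CSV
#'
#' @param report a `gh_report`.
#' @param path_json JSON output path (NULL to skip).
#' @param path_csv flat CSV output path (NULL to skip); one row per
#'   protocol x DOF / axis / muscle.
#' @return invisible report.
#' @export
write_report <- function(report, path_json = NULL, path_csv = NULL) {
  if (!is.null(path_json)) {
    jsonlite::write_json(list(accuracy = report$accuracy,
                              icc_translation = report$icc_translation,
                              icc_force = report$icc_force),
                         path_json, digits = NA, auto_unbox = TRUE)
  }
  if (!is.null(path_csv)) {
    long <- rbind(
      data.frame(kind = "accuracy", protocol = report$accuracy$protocol,
                 item = report$accuracy$dof, metric = "max_mean_dev_deg",
                 value = report$accuracy$max_mean_dev_deg),
      data.frame(kind = "accuracy", protocol = report$accuracy$protocol,
                 item = report$accuracy$dof, metric = "rmse_deg",
                 value = report$accuracy$rmse_deg),
      data.frame(kind = "accuracy", protocol = report$accuracy$protocol,
                 item = report$accuracy$dof, metric = "max_sd_deg",
                 value = report$accuracy$max_sd_deg),
      data.frame(kind = "accuracy", protocol = report$accuracy$protocol,
                 item = report$accuracy$dof, metric = "avg_sd_deg",
                 value = report$accuracy$avg_sd_deg),
      data.frame(kind = "icc_translation",
                 protocol = report$icc_translation$protocol,
                 item = report$icc_translation$axis, metric = "icc_ci_lower",
                 value = report$icc_translation$ci_lower),
      data.frame(kind = "icc_force", protocol = report$icc_force$protocol,
                 item = report$icc_force$muscle, metric = "icc_ci_lower",
                 value = report$icc_force$ci_lower))
    write.csv(long, path_csv, row.names = FALSE)
  }
  invisible(report)
}
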