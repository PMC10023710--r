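# Cardan XZY kinematics, centre-of-rotation estimation and relative poses.
#
# Frames are right-handed. The scapular frame axes are, in order: the
# abduction axis (X), the long axis of the hanging humerus reversed (Y, so
# the shaft points along -Y at zero angles) and their cross product (Z).
# Glenohumeral orientation is the Cardan sequence XZY: abduction about X,
# flexion(+)/extension(-) about Z, internal(+)/external(-) rotation about Y.
# The XZY order keeps the singular configuration (flexion at +/-90 deg) far
# from the initiation of abduction, where a Y-first sequence is degenerate.

#' Cardan XZY angle triple
#'
#' @param abduction_deg rotation about X (degrees).
#' @param flexion_deg rotation about Z (degrees); extension is negative. Must
#'   lie strictly inside (-90, 90), the unambiguous branch of the middle axis.
#' @param rotation_deg rotation about Y (degrees); internal positive,
#'   external negative.
#' @return object of class `cardan_xzy` (named numeric length 3).
#' @export
#' @examples
#' cardan_xzy(20, 0, 0)
cardan_xzy <- function(abduction_deg, flexion_deg, rotation_deg) {
  a <- c(abduction = abduction_deg, flexion = flexion_deg,
         rotation = rotation_deg)
  if (!all(is.finite(a))) stop("Cardan angles must be finite")
  if (abs(flexion_deg) >= 90)
    stop("flexion must lie strictly inside (-90, 90) degrees")
  structure(a, class = "cardan_xzy")
}

#' @export
print.cardan_xzy <- function(x, ...) {
  cat(sprintf("Cardan XZY: abduction %.3f, flexion %.3f, rotation %.3f (deg)\n",
              x[1], x[2], x[3]))
  invisible(x)
}

rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, -s, 0, s, c), 3, 3, byrow = TRUE)
}
rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, s, 0, 1, 0, -s, 0, c), 3, 3, byrow = TRUE)
}
rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, -s, 0, s, c, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

#' Compose a direction-cosine matrix from Cardan XZY angles
#'
#' Returns `R = Rx(abduction) %*% Rz(flexion) %*% Ry(rotation)`, the matrix
#' mapping humeral-frame vectors into the scapular frame.
#'
#' @param angles a [cardan_xzy()] triple or numeric length-3 vector
#'   (abduction, flexion, rotation in degrees).
#' @return 3x3 orthonormal rotation matrix with determinant +1.
#' @export
#' @examples
#' compose_orientation(c(0, 0, 0))        # identity
#' compose_orientation(cardan_xzy(90, 0, 0))
compose_orientation <- function(angles) {
  angles <- as.numeric(angles)
  stopifnot(length(angles) == 3, all(is.finite(angles)))
  th <- angles * pi / 180
  rot_x(th[1]) %*% rot_z(th[2]) %*% rot_y(th[3])
}

assert_orientation <- function(R, tol = 1e-9) {
  if (!is.matrix(R) || any(dim(R) != c(3, 3)))
    stop("orientation must be a 3x3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > tol * 100)
    stop("orientation is not orthonormal")
  if (det(R) < 0) stop("orientation must be proper (det +1)")
  invisible(R)
}

#' Decompose a rotation matrix into Cardan XZY angles
#'
#' Inverts [compose_orientation()]. The flexion angle (middle axis) is
#' restricted to (-90, 90) degrees, which makes the triple unique; at
#' +/-90 degrees the sequence is singular (gimbal lock) and an error is
#' raised.
#'
#' @param R 3x3 orthonormal rotation matrix.
#' @param tol singularity tolerance on `|sin(flexion)|` (default 1e-9).
#' @return a [cardan_xzy()] triple (degrees).
#' @export
#' @examples
#' decompose_orientation(compose_orientation(c(10, 20, -30)))
decompose_orientation <- function(R, tol = 1e-9) {
  assert_orientation(R)
  # R = Rx(a) Rz(f) Ry(r):
  #   R[1,1] = cf*cr,  R[1,2] = -sf,      R[1,3] = cf*sr
  #   R[2,2] = ca*cf,  R[3,2] = sa*cf
  sf <- -R[1, 2]
  if (abs(sf) >= 1 - tol)
    stop("gimbal lock: flexion at +/-90 degrees, XZY decomposition undefined")
  f <- asin(sf)
  a <- atan2(R[3, 2], R[2, 2])
  r <- atan2(R[1, 3], R[1, 1])
  cardan_xzy(a * 180 / pi, f * 180 / pi, r * 180 / pi)
}

#' Re-orthonormalize a drifting rotation matrix
#'
#' Projects `R` onto the nearest proper rotation (polar decomposition via
#' SVD). Used to keep long products of orientations orthonormal.
#'
#' @param R approximate rotation matrix.
#' @return orthonormal matrix with determinant +1.
#' @export
orthonormalize <- function(R) {
  s <- svd(R)
  U <- s$u %*% t(s$v)
  if (det(U) < 0) {
    s$v[, 3] <- -s$v[, 3]
    U <- s$u %*% t(s$v)
  }
  U
}

#' A rigid-body marker-frame sample
#'
#' One time-stamped pose of a marker cluster: orientation plus position of
#' the cluster origin, both expressed in a common (tracker or scapular)
#' frame.
#'
#' @param time_s time stamp (seconds).
#' @param R 3x3 orientation matrix.
#' @param t position 3-vector (mm).
#' @return object of class `marker_frame`.
#' @export
marker_frame <- function(time_s, R, t) {
  assert_orientation(R)
  stopifnot(is.finite(time_s), length(t) == 3, all(is.finite(t)))
  structure(list(time_s = time_s, R = R, t = as.numeric(t)),
            class = "marker_frame")
}

#' Estimate the centre of rotation by linear pivot calibration
#'
#' Finds the point that moves least across a recording of the humerus
#' cluster relative to the scapula: the pair (p_h in the moving frame,
#' p_s in the fixed frame) minimizing `sum_i |R_i p_h + t_i - p_s|^2`,
#' solved as a linear least-squares problem on the stacked system
#' `[R_i  -I] [p_h; p_s] = -t_i`.
#'
#' @param samples list of [marker_frame()] poses of the humerus cluster
#'   expressed in the scapular frame; at least 10 samples spanning rotations
#'   about two or more independent axes.
#' @param cond_tol rank-deficiency threshold on the smallest singular value
#'   of the normalized design matrix (default 1e-6).
#' @return list with `pivot_scapular_mm`, `pivot_humeral_mm` and `rms_mm`
#'   (root-mean-square residual displacement of the pivot image).
#' @export
estimate_center_of_rotation <- function(samples, cond_tol = 1e-6) {
  n <- length(samples)
  if (n < 10) stop("need at least 10 samples for pivot calibration")
  A <- matrix(0, 3 * n, 6)
  b <- numeric(3 * n)
  for (i in seq_len(n)) {
    s <- samples[[i]]
    rows <- (3 * i - 2):(3 * i)
    A[rows, 1:3] <- s$R
    A[rows, 4:6] <- -diag(3)
    b[rows] <- -s$t
  }
  sv <- svd(A)
  if (sv$d[6] / sv$d[1] < cond_tol)
    stop("rank-deficient motion: rotations do not constrain the pivot")
  x <- sv$v %*% ((t(sv$u) %*% b) / sv$d)
  res <- A %*% x - b
  list(pivot_humeral_mm = as.numeric(x[1:3]),
       pivot_scapular_mm = as.numeric(x[4:6]),
       rms_mm = sqrt(mean(matrix(res^2, ncol = 3, byrow = TRUE) %*% c(1, 1, 1))))
}

#' Relative pose of the humerus in the scapular frame
#'
#' Combines simultaneous marker-frame samples of the humerus and scapula
#' clusters into the pose of the humeral anatomical frame expressed in the
#' scapular anatomical frame. The translation is the position of the humeral
#' centre of rotation (given as `cor_offsets$humerus`, a fixed point in the
#' humerus cluster frame) relative to its scapular-frame reference
#' (`cor_offsets$scapula`).
#'
#' @param humerus,scapula [marker_frame()] samples at the same time stamp.
#' @param cor_offsets list with 3-vectors `humerus` and `scapula` (mm);
#'   defaults to zero offsets.
#' @param time_tol maximum allowed time-stamp mismatch (s).
#' @return list of class `gh_pose` with `orientation` (3x3) and
#'   `translation_mm` (AP/SI/ML 3-vector).
#' @export
relative_pose <- function(humerus, scapula,
                          cor_offsets = list(humerus = c(0, 0, 0),
                                             scapula = c(0, 0, 0)),
                          time_tol = 1e-6) {
  if (abs(humerus$time_s - scapula$time_s) > time_tol)
    stop("humerus and scapula samples are not simultaneous")
  R <- t(scapula$R) %*% humerus$R
  tr <- as.numeric(t(scapula$R) %*%
                     (humerus$t + humerus$R %*% cor_offsets$humerus -
                        scapula$t)) - cor_offsets$scapula
  structure(list(orientation = R, translation_mm = tr,
                 time_s = humerus$time_s), class = "gh_pose")
}

#' @export
print.gh_pose <- function(x, ...) {
  a <- decompose_orientation(x$orientation)
  cat(sprintf(
    "GH pose: abd %.2f, flex %.2f, rot %.2f deg; AP/SI/ML %.2f/%.2f/%.2f mm\n",
    a[1], a[2], a[3], x$translation_mm[1], x$translation_mm[2],
    x$translation_mm[3]))
  invisible(x)
}

#' Read / write marker-frame recordings as CSV
#'
#' The layout is one header row, then one row per sample: `time_s` followed
#' by 12 columns per rigid body (the row-flattened 3x3 orientation and the
#' 3-vector position, suffixed by the body name).
#'
#' @param samples named list of marker-frame lists (one entry per body, each
#'   a list of [marker_frame()]).
#' @param path CSV file path.
#' @return `read_marker_csv` returns the named list of marker-frame lists.
#' @export
write_marker_csv <- function(samples, path) {
  bodies <- names(samples)
  stopifnot(length(bodies) >= 1)
  n <- length(samples[[1]])
  rows <- lapply(seq_len(n), function(i) {
    out <- c(time_s = samples[[1]][[i]]$time_s)
    for (b in bodies) {
      s <- samples[[b]][[i]]
      v <- c(as.vector(t(s$R)), s$t)
      names(v) <- paste0(c(paste0("r", c(11, 12, 13, 21, 22, 23, 31, 32, 33)),
                           "tx", "ty", "tz"), "_", b)
      out <- c(out, v)
    }
    out
  })
  df <- as.data.frame(do.call(rbind, rows))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_csv
#' @export
read_marker_csv <- function(path) {
  df <- read.csv(path)
  cn <- colnames(df)
  bodies <- unique(sub("^r11_", "", cn[grepl("^r11_", cn)]))
  out <- list()
  for (b in bodies) {
    rcols <- paste0("r", c(11, 12, 13, 21, 22, 23, 31, 32, 33), "_", b)
    tcols <- paste0(c("tx", "ty", "tz"), "_", b)
    out[[b]] <- lapply(seq_len(nrow(df)), function(i) {
      marker_frame(df$time_s[i],
                   matrix(as.numeric(df[i, rcols]), 3, 3, byrow = TRUE),
                   as.numeric(df[i, tcols]))
    })
  }
  out
}
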