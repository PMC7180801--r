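# Segment frames and the z-x-y Euler machinery shared by both kinematic models.

# Geometric tolerance (mm) below which a construction vector is degenerate.
EPS_GEOM <- 1e-6

vec3_unit <- function(v, what = "vector") {
  n <- sqrt(sum(v^2))
  if (n <= EPS_GEOM) {
    stop("singular geometry: ", what, " has (near-)zero length", call. = FALSE)
  }
  v / n
}

vec3_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Row-wise cross product / norms for T x 3 matrices (vectorized frame building).
rows_cross <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

rows_norm <- function(A) sqrt(rowSums(A^2))

rows_unit <- function(A) A / rows_norm(A)

#' Construct a segment frame
#'
#' A `segment_frame` is an origin plus a right-handed orthonormal axis set; the
#' columns of `axes` are the segment's x, y and z axes expressed in the global
#' system.
#'
#' @param origin numeric length-3 origin (mm).
#' @param x,y,z numeric length-3 unit axes.
#' @return an object of class `segment_frame` with elements `origin` and `axes`.
#' @export
segment_frame <- function(origin, x, y, z) {
  axes <- cbind(x = x, y = y, z = z)
  fr <- structure(list(origin = as.numeric(origin), axes = axes),
                  class = "segment_frame")
  validate_segment_frame(fr)
  fr
}

validate_segment_frame <- function(fr, tol = 1e-9) {
  A <- fr$axes
  if (!is.matrix(A) || any(dim(A) != c(3L, 3L)) || any(!is.finite(A))) {
    stop("segment frame axes must be a finite 3x3 matrix", call. = FALSE)
  }
  if (max(abs(crossprod(A) - diag(3))) > tol) {
    stop("segment frame axes are not orthonormal", call. = FALSE)
  }
  if (abs(det(A) - 1) > 1e-6) {
    stop("segment frame is not right-handed (det != +1)", call. = FALSE)
  }
  invisible(fr)
}

#' @export
print.segment_frame <- function(x, ...) {
  cat("<segment_frame>\n origin:", format(x$origin, digits = 6), "\n")
  print(round(x$axes, 6))
  invisible(x)
}

#' Compose a rotation matrix from z-x-y Euler angles
#'
#' Builds `R = Rz(fe) %*% Rx(aa) %*% Ry(ie)`: an ordered flexion/extension
#' (about z), adduction/abduction (about x), internal/external rotation
#' (about y) sequence, the convention used for all shoulder and elbow
#' decompositions in the package.
#'
#' @param fe,aa,ie angles in degrees.
#' @return 3x3 rotation matrix.
#' @export
euler_zxy_compose <- function(fe, aa, ie) {
  f <- fe * pi / 180; a <- aa * pi / 180; i <- ie * pi / 180
  cf <- cos(f); sf <- sin(f); ca <- cos(a); sa <- sin(a); ci <- cos(i); si <- sin(i)
  matrix(c(cf * ci - sf * sa * si,  sf * ci + cf * sa * si, -ca * si,
           -sf * ca,                cf * ca,                 sa,
           cf * si + sf * sa * ci,  sf * si - cf * sa * ci,  ca * ci),
         nrow = 3, ncol = 3)
}

#' Decompose a rotation matrix into z-x-y Euler angles
#'
#' Inverts [euler_zxy_compose()]: `aa = asin(R[3,2])`,
#' `ie = atan2(-R[3,1], R[3,3])`, `fe = atan2(-R[1,2], R[2,2])`. Within one
#' degree of the gimbal singularity (`|aa| = 90` deg) the y-rotation becomes
#' unobservable: `ie` is set to 0, `fe` absorbs the full outer rotation
#' (`atan2(R[2,1], R[1,1])`), and `gimbal` is flagged.
#'
#' @param R 3x3 rotation matrix.
#' @param check validate that `R` is a rotation matrix (default TRUE).
#' @return list with `fe`, `aa`, `ie` (degrees) and logical `gimbal`.
#' @export
euler_zxy_decompose <- function(R, check = TRUE) {
  if (check) {
    if (max(abs(crossprod(R) - diag(3))) > 1e-6) {
      stop("input is not a rotation matrix", call. = FALSE)
    }
  }
  R <- unname(R)
  s <- min(1, max(-1, R[3, 2]))
  aa <- asin(s) * 180 / pi
  if (abs(s) > cos(pi / 180)) {     # within 1 degree of |aa| = 90
    fe <- atan2(R[2, 1], R[1, 1]) * 180 / pi
    return(list(fe = fe, aa = aa, ie = 0, gimbal = TRUE))
  }
  list(fe = atan2(-R[1, 2], R[2, 2]) * 180 / pi,
       aa = aa,
       ie = atan2(-R[3, 1], R[3, 3]) * 180 / pi,
       gimbal = FALSE)
}

# Vectorized z-x-y decomposition for a T-frame stack of rotations given as
# columns of the parent/child axis arrays. R_t = t(parent_t) %*% child_t.
# parent, child: T x 9 matrices (columns xx,xy,xz,yx,...) i.e. axes flattened
# column-major. Returns T x 3 matrix (fe, aa, ie in degrees) + gimbal flags.
euler_zxy_decompose_traj <- function(Rflat) {
  # Rflat: T x 9, columns R11,R21,R31,R12,R22,R32,R13,R23,R33 (column-major)
  R11 <- Rflat[, 1]; R21 <- Rflat[, 2]; R31 <- Rflat[, 3]
  R12 <- Rflat[, 4]; R22 <- Rflat[, 5]; R32 <- Rflat[, 6]
  R33 <- Rflat[, 9]
  s <- pmin(1, pmax(-1, R32))
  aa <- asin(s) * 180 / pi
  gim <- abs(s) > cos(pi / 180)
  fe <- atan2(-R12, R22) * 180 / pi
  ie <- atan2(-R31, R33) * 180 / pi
  if (any(gim)) {
    fe[gim] <- atan2(R21[gim], R11[gim]) * 180 / pi
    ie[gim] <- 0
  }
  list(angles = cbind(fe = fe, aa = aa, ie = ie), gimbal = gim)
}

# Relative rotations between two frame trajectories, flattened column-major.
# parent/child: lists of T x 3 matrices x, y, z (unit axes per frame).
relative_rotation_traj <- function(parent, child) {
  P <- list(parent$x, parent$y, parent$z)
  C <- list(child$x, child$y, child$z)
  out <- matrix(NA_real_, nrow = nrow(parent$x), ncol = 9)
  k <- 0
  for (j in 1:3) {      # child axis -> column block j
    for (i in 1:3) {    # parent axis -> row i
      k <- k + 1
      out[, k] <- rowSums(P[[i]] * C[[j]])
    }
  }
  out
}

#' Unwrap an angle trajectory
#'
#' Removes artificial +/-360 degree jumps between consecutive samples by
#' nearest-revolution continuity; the first sample is anchored to
#' (-180, 180].
#'
#' @param x numeric vector of angles in degrees.
#' @return unwrapped vector.
#' @export
unwrap_degrees <- function(x) {
  if (length(x) < 2) return(x)
  x0 <- x[1]
  x0 <- ((x0 + 180) %% 360) - 180
  if (x0 == -180) x0 <- 180
  d <- diff(x)
  d <- d - 360 * round(d / 360)
  cumsum(c(x0, d))
}
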