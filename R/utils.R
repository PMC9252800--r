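#' @useDynLib rigidom, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim rnorm runif setNames dist sd
#' @importFrom utils head read.table
NULL

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Rotation matrix for intrinsic Z-Y-X Euler angles (radians).
euler_to_matrix <- function(ang) {
  a <- ang[1]; b <- ang[2]; g <- ang[3]
  Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(g), -sin(g), 0, sin(g), cos(g)), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# Inverse of euler_to_matrix; gimbal-lock safe (|R[3,1]| ~ 1).
matrix_to_euler <- function(R) {
  sb <- -R[3, 1]
  sb <- max(-1, min(1, sb))
  b <- asin(sb)
  if (abs(sb) < 1 - 1e-10) {
    a <- atan2(R[2, 1], R[1, 1])
    g <- atan2(R[3, 2], R[3, 3])
  } else {
    # cos(b) ~ 0: only a +/- g is determined; fix g = 0
    a <- atan2(-R[1, 2], R[2, 2])
    g <- 0
  }
  c(a, b, g)
}

# Rotation by `angle` radians about unit `axis` (Rodrigues).
axis_angle_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

random_rotation <- function() {
  # uniform axis, uniform angle in [0, pi] -- adequate for seeding/decoys
  ax <- rnorm(3)
  axis_angle_matrix(ax, runif(1, 0, pi))
}

centroid <- function(xyz) colMeans(xyz)

radius_of_gyration <- function(xyz) {
  c0 <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, c0)^2)))
}

# Natural cubic spline second derivatives at the knots (tridiagonal solve).
natural_spline_m <- function(x, y) {
  n <- length(x)
  if (n < 3) return(numeric(n))
  h <- diff(x)
  a <- b <- d <- r <- numeric(n)
  b[1] <- b[n] <- 1
  for (i in 2:(n - 1)) {
    a[i] <- h[i - 1]
    b[i] <- 2 * (h[i - 1] + h[i])
    d[i] <- h[i]
    r[i] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  # Thomas algorithm
  for (i in 2:n) {
    w <- a[i] / b[i - 1]
    b[i] <- b[i] - w * d[i - 1]
    r[i] <- r[i] - w * r[i - 1]
  }
  m <- numeric(n)
  m[n] <- r[n] / b[n]
  for (i in (n - 1):1) m[i] <- (r[i] - d[i] * m[i + 1]) / b[i]
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
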