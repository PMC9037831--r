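# Internal numerical helpers shared across modules.

# sin(x)/x with the correct limit at x = 0.
sinc <- function(x) {
  out <- rep(1, length(x))
  big <- abs(x) > 1e-8
  out[big] <- sin(x[big]) / x[big]
  out
}

trapz_weights <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least two grid points")
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dx[-(n - 1)] + dx[-1]) / 2
  w
}

# Rotation matrix for angle (radians) about unit axis, Rodrigues form.
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Radius of gyration of a coordinate matrix with optional weights.
coords_rg <- function(xyz, w = NULL) {
  if (is.null(w)) w <- rep(1, nrow(xyz))
  com <- colSums(xyz * w) / sum(w)
  d2 <- rowSums(sweep(xyz, 2, com)^2)
  sqrt(sum(w * d2) / sum(w))
}

coords_com <- function(xyz, w = NULL) {
  if (is.null(w)) w <- rep(1, nrow(xyz))
  colSums(xyz * w) / sum(w)
}

# Maximum pairwise distance (Dmax) of a coordinate set.
coords_dmax <- function(xyz) {
  if (nrow(xyz) < 2) return(0)
  max(stats::dist(xyz))
}
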