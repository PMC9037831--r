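# Shared fixtures, all built in code.

# Exact form-factor intensity of a uniform sphere of radius R (I(0) = 1).
sphere_intensity <- function(q, R) {
  x <- q * R
  (3 * (sin(x) - x * cos(x)) / x^3)^2
}

# Noiseless sphere profile with a small sigma floor (the form factor has
# zeros, so a purely relative sigma would blow up the weights there).
sphere_profile <- function(R = 50, qmax = 0.25, n = 200, rel = 0.01,
                           floor_frac = 1e-4) {
  q <- seq(0.002, qmax, length.out = n)
  I <- sphere_intensity(q, R)
  scattering_profile(q, I, pmax(rel * I, floor_frac * max(I)))
}

# Random uniform fill of a sphere (n points), deterministic per seed.
sphere_fill <- function(R, n, seed) {
  withr::with_seed(seed, {
    p <- matrix(stats::runif(n * 9, -R, R), ncol = 3)
    p <- p[rowSums(p^2) <= R^2, , drop = FALSE]
    p[seq_len(n), , drop = FALSE]
  })
}

# Two-lobed dumbbell model (two sphere fills on the x axis).
dumbbell_model <- function(R = 15, sep = 50, n = 120) {
  pts <- rbind(sweep(sphere_fill(R, n, 1), 2, c(-sep / 2, 0, 0), "+"),
               sweep(sphere_fill(R, n, 2), 2, c(sep / 2, 0, 0), "+"))
  atomic_model(pts, bead_radius = 2.5,
               domain = rep(c("L", "R"), each = n))
}

# Small antibody surrogate shared across tests (cached per session).
test_surrogate <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_antibody_surrogate()
    cache
  }
})

# Noiseless Debye profile of a model with a sigma floor.
model_profile <- function(model, q = seq(0.004, 0.3, length.out = 150),
                          rel = 0.01, floor_frac = 1e-4) {
  p <- debye_profile(model, q)
  p$sigma <- pmax(rel * p$I, floor_frac * max(p$I))
  p
}

# Rotation helper visible to tests.
rot_axis <- function(axis, angle_deg) {
  flexsaxs:::rotation_about_axis(axis, angle_deg * pi / 180)
}

# Fab elbow fixture: variable module (VL, VH) related by a ~170 degree
# internal rotation about the x axis, constant module a rigid translate
# along -z. `dyad_rot_deg` then rotates the whole constant module about
# the inter-module (z) axis, tilting its pseudo-dyad by that amount.
elbow_fixture <- function(dyad_rot_deg = 0) {
  blob <- withr::with_seed(2, matrix(stats::rnorm(45), ncol = 3) * 4)
  Rv <- rot_axis(c(1, 0, 0), 170)
  VL <- sweep(blob, 2, c(0, -8, 0), "+")
  VH <- sweep(blob %*% t(Rv), 2, c(0, 8, 0), "+")
  CL <- sweep(VL, 2, c(0, 0, -30), "+")
  CH1 <- sweep(VH, 2, c(0, 0, -30), "+")
  if (dyad_rot_deg != 0) {
    Rc <- rot_axis(c(0, 0, 1), dyad_rot_deg)
    comC <- colMeans(rbind(CL, CH1))
    CL <- sweep(sweep(CL, 2, comC) %*% t(Rc), 2, comC, "+")
    CH1 <- sweep(sweep(CH1, 2, comC) %*% t(Rc), 2, comC, "+")
  }
  n <- nrow(blob)
  list(xyz = rbind(VL, VH, CL, CH1),
       selectors = list(VL = 1:n, VH = n + 1:n,
                        CL = 2 * n + 1:n, CH1 = 3 * n + 1:n))
}

# O(N^2) double-loop Debye sum: the brute-force oracle.
debye_direct <- function(xyz, f, q) {
  n <- nrow(xyz)
  vapply(q, function(qq) {
    acc <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        acc <- acc + f[i] * f[j] *
          (if (qq * d < 1e-12) 1 else sin(qq * d) / (qq * d))
      }
    }
    acc
  }, 0)
}

max_intra_domain_distortion <- function(model, new_xyz) {
  max(vapply(unique(model$domain), function(d) {
    i <- model$domain == d
    max(abs(stats::dist(new_xyz[i, , drop = FALSE]) -
              stats::dist(model$xyz[i, , drop = FALSE])))
  }, 0))
}
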