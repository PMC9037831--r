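test_that("domain assignment follows the arm-distance rule", {
  tpl <- test_surrogate()
  # push one arm farther out so Fa/Fb are unambiguous
  far <- flexsaxs:::apply_hinge(tpl, "Fb", bend = -25, twist = 0)
  far$domain[far$domain == "Fa"] <- "arm1"
  far$domain[far$domain == "Fb"] <- "arm2"
  asg <- assign_domains(far, list(fc = "Fc", arms = c("arm1", "arm2")))
  map <- attr(asg, "domain_map")
  com <- function(m, d) colMeans(m$xyz[m$domain == d, , drop = FALSE])
  dist_fc <- function(m, d) sqrt(sum((com(m, d) - com(m, "Fc"))^2))
  expect_gt(dist_fc(asg, "Fa"), dist_fc(asg, "Fb"))

  # swapping the arm order in the config leaves the labels unchanged
  asg2 <- assign_domains(far, list(fc = "Fc", arms = c("arm2", "arm1")))
  expect_identical(asg$domain, asg2$domain)

  # equidistant arms fall back to chain order, with a message
  sym <- atomic_model(rbind(c(-20, 0, 0), c(20, 0, 0), c(0, 0, -20)),
                      chain = c("A", "B", "C"),
                      domain = c("a1", "a2", "fc"))
  expect_message(
    asg3 <- assign_domains(sym, list(fc = "fc", arms = c("a2", "a1"))),
    "tie")
  expect_identical(asg3$domain, c("Fa", "Fb", "Fc"))
})

test_that("geometry features match symmetric hand constructions", {
  tri <- atomic_model(30 * rbind(c(1, 0, 0),
                                 c(-0.5, sqrt(3) / 2, 0),
                                 c(-0.5, -sqrt(3) / 2, 0)),
                      domain = c("A", "B", "C"))
  gf <- geometry_features(tri, sasa = FALSE)
  expect_equal(unname(gf$angles_at_center), rep(120, 3), tolerance = 1e-9)
  expect_equal(unname(gf$distances), rep(30 * sqrt(3), 3), tolerance = 1e-9)

  # coplanar flat domains: inter-plane angles 0
  flat <- withr::with_seed(3, cbind(stats::rnorm(60, 0, 8),
                                    stats::rnorm(60, 0, 4),
                                    rep(0, 60)))
  m <- atomic_model(rbind(flat, sweep(flat, 2, c(40, 0, 0), "+")),
                    domain = rep(c("A", "B"), each = 60))
  gf2 <- geometry_features(m, sasa = FALSE)
  expect_equal(unname(gf2$plane_angles), 0, tolerance = 1e-6)

  # rigid-motion invariance of distances and angles
  moved <- m
  moved$xyz <- sweep(m$xyz %*% t(rot_axis(c(1, 1, 0), 35)), 2,
                     c(12, -300, 8), "+")
  gf3 <- geometry_features(moved, sasa = FALSE)
  expect_equal(gf3$distances, gf2$distances, tolerance = 1e-8)
  expect_equal(gf3$angles_at_center, gf2$angles_at_center, tolerance = 1e-8)
  expect_equal(gf3$rg, gf2$rg, tolerance = 1e-8)
})

test_that("SASA matches the analytic isolated sphere and buries contacts", {
  a <- 3; p <- 1.4
  s1 <- sasa_shrake_rupley(matrix(0, 1, 3), radii = a, probe_radius = p)
  expect_equal(s1, 4 * pi * (a + p)^2, tolerance = 0.02)

  # two overlapping atoms expose less than two isolated ones
  s2 <- sasa_shrake_rupley(rbind(c(0, 0, 0), c(2, 0, 0)), radii = a,
                           probe_radius = p)
  expect_lt(sum(s2), 2 * 4 * pi * (a + p)^2)
})

test_that("elbow angles follow the dyad convention", {
  fx0 <- elbow_fixture(0)
  expect_equal(as.numeric(elbow_angle(fx0$xyz, fx0$selectors)), 180,
               tolerance = 1e-6)

  fx37 <- elbow_fixture(-37)
  e37 <- as.numeric(elbow_angle(fx37$xyz, fx37$selectors))
  expect_equal(e37, 143, tolerance = 0.01)

  # the opposite rotation lands on the reflex branch
  fxr <- elbow_fixture(37)
  expect_equal(as.numeric(elbow_angle(fxr$xyz, fxr$selectors)), 217,
               tolerance = 0.01)

  # swapping the correspondence direction leaves the angle unchanged
  swapped <- list(VL = fx37$selectors$VH, VH = fx37$selectors$VL,
                  CL = fx37$selectors$CH1, CH1 = fx37$selectors$CL)
  expect_equal(as.numeric(elbow_angle(fx37$xyz, swapped)), e37,
               tolerance = 0.01)

  # near-identity internal rotation: dyad undefined
  blob <- withr::with_seed(4, matrix(stats::rnorm(45), ncol = 3) * 4)
  flatfab <- rbind(blob, sweep(blob, 2, c(10, 0, 0), "+"),
                   sweep(blob, 2, c(0, 0, -20), "+"),
                   sweep(blob, 2, c(10, 0, -20), "+"))
  n <- nrow(blob)
  sel <- list(VL = 1:n, VH = n + 1:n, CL = 2 * n + 1:n, CH1 = 3 * n + 1:n)
  expect_error(elbow_angle(flatfab, sel), "ill-defined")
})

test_that("Kabsch superposition is exact, symmetric, and calibrated", {
  A <- withr::with_seed(5, matrix(stats::rnorm(600), ncol = 3) * 8)
  expect_equal(superpose_rmsd(A, A)$rmsd, 0, tolerance = 1e-12)

  B <- sweep(A %*% t(rot_axis(c(1, -1, 2), 46)), 2, c(3, 4, -1), "+")
  expect_lt(superpose_rmsd(A, B)$rmsd, 1e-9)
  expect_equal(superpose_rmsd(A, B)$rmsd, superpose_rmsd(B, A)$rmsd,
               tolerance = 1e-9)

  # Gaussian perturbation sigma = 1 A on N = 200: RMSD near sigma * sqrt(3)
  rmsds <- withr::with_seed(6, vapply(1:30, function(i) {
    superpose_rmsd(A, A + matrix(stats::rnorm(600), ncol = 3))$rmsd
  }, 0))
  expect_true(all(rmsds > 1.5 & rmsds < 2.0))

  line <- cbind(1:10, 0, 0)
  expect_warning(superpose_rmsd(line, line), "collinear")
  expect_error(superpose_rmsd(A[1:2, ], A[1:2, ]), ">= 3")
})
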