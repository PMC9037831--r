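test_that("envelope potential matches its formula and finite differences", {
  g1 <- voxelize(matrix(0, 1, 3), spacing = 1, blur_sigma = 2)
  par <- envelope_potential_params(k = 0.7)
  mx <- which(g1$rho == g1$rho_max, arr.ind = TRUE)[1, ]
  at_max <- g1$origin + (mx - 1) * g1$spacing
  expect_equal(envelope_energy_force(g1, par, rbind(at_max))$energy, 0)

  far <- envelope_energy_force(g1, par, rbind(c(500, 500, 500)))
  expect_equal(far$energy, 0.7)
  expect_equal(far$forces, matrix(0, 1, 3))

  # linear ramp rho = rho_max * x / L: |F| = k / L everywhere inside
  L <- 30
  ax <- seq(0, L, length.out = 31)
  ramp <- density_grid(c(0, 0, 0), ax[2] - ax[1],
                       array(rep(ax / L, 21 * 21), dim = c(31, 21, 21)))
  pos <- withr::with_seed(1, cbind(stats::runif(40, 2, L - 2),
                                   stats::runif(40, 2, 18),
                                   stats::runif(40, 2, 18)))
  ef <- envelope_energy_force(ramp, par, pos)
  expect_equal(ef$forces[, 1], rep(0.7 / L, 40), tolerance = 1e-12)
  expect_equal(ef$forces[, 2], rep(0, 40), tolerance = 1e-12)

  h <- 1e-5
  fd <- vapply(1:10, function(i) {
    vapply(1:3, function(c) {
      pp <- pos; pp[i, c] <- pp[i, c] + h
      pm <- pos; pm[i, c] <- pm[i, c] - h
      -(envelope_energy_force(ramp, par, pp)$energy -
          envelope_energy_force(ramp, par, pm)$energy) / (2 * h)
    }, 0)
  }, numeric(3))
  expect_lt(max(abs(fd - t(ef$forces[1:10, ]))) / max(abs(fd)), 1e-6)

  expect_error(envelope_energy_force(density_grid(c(0, 0, 0), 1,
                                                  array(0, c(3, 3, 3))),
                                     par, rbind(c(1, 1, 1))), "rho_max")
})

test_that("force-energy consistency holds on a random smooth grid", {
  g <- voxelize(sphere_fill(12, 40, 8), spacing = 2, blur_sigma = 4)
  par <- envelope_potential_params(k = 0.3)
  pos <- withr::with_seed(5, {
    lo <- g$origin + 2 * g$spacing
    hi <- g$origin + (dim(g$rho) - 3) * g$spacing
    cbind(stats::runif(100, lo[1], hi[1]),
          stats::runif(100, lo[2], hi[2]),
          stats::runif(100, lo[3], hi[3]))
  })
  ef <- envelope_energy_force(g, par, pos)
  h <- 1e-5
  worst <- 0
  for (i in seq_len(100)) {
    for (c in 1:3) {
      pp <- pos; pp[i, c] <- pp[i, c] + h
      pm <- pos; pm[i, c] <- pm[i, c] - h
      fd <- -(envelope_energy_force(g, par, pp)$energy -
                envelope_energy_force(g, par, pm)$energy) / (2 * h)
      worst <- max(worst, abs(fd - ef$forces[i, c]))
    }
  }
  expect_lt(worst / max(abs(ef$forces)), 1e-5)
})

test_that("restraint networks are intra-domain only and complete", {
  m2 <- atomic_model(rbind(c(0, 0, 0), c(5, 0, 0)), domain = c("A", "A"))
  expect_length(build_restraint_network(m2, cutoff = 12)$i, 1L)

  m2b <- atomic_model(rbind(c(0, 0, 0), c(5, 0, 0)), domain = c("A", "B"))
  expect_length(build_restraint_network(m2b, cutoff = 12)$i, 0L)

  # brute-force pair enumeration oracle on a 100-atom fixture
  xyz <- sphere_fill(15, 100, 13)
  doms <- rep(c("X", "Y"), each = 50)
  net <- build_restraint_network(atomic_model(xyz, domain = doms),
                                 cutoff = 8)
  count <- 0L
  for (i in 1:99) for (j in (i + 1):100) {
    if (doms[i] == doms[j] &&
        sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= 8) count <- count + 1L
  }
  expect_identical(length(net$i), count)
  expect_equal(net$r0,
               sqrt(rowSums((xyz[net$i, ] - xyz[net$j, ])^2)),
               tolerance = 1e-12)
})

test_that("refinement is stationary at its own envelope and seeded", {
  m <- dumbbell_model(R = 10, sep = 30, n = 40)
  grid <- voxelize(m, spacing = 2.5, blur_sigma = 5)
  net <- build_restraint_network(m, cutoff = 10, spring_k = 1)
  traj <- restrained_refine(m, grid, net, envelope_potential_params(k = 0.1),
                            steps = 800, step_size = 0.05, stride = 200,
                            blur_sigma = 5)
  drift <- sqrt(rowSums((traj$final$xyz - m$xyz)^2))
  expect_lt(max(drift), 0.1)

  # determinism with thermal noise
  t1 <- restrained_refine(m, grid, net, steps = 50, step_size = 0.05,
                          temperature = 0.001, seed = 7, stride = 25,
                          blur_sigma = 5)
  t2 <- restrained_refine(m, grid, net, steps = 50, step_size = 0.05,
                          temperature = 0.001, seed = 7, stride = 25,
                          blur_sigma = 5)
  expect_identical(t1$final$xyz, t2$final$xyz)
})

test_that("best-model selection uses the earliest chi-square minimum", {
  m <- test_surrogate()
  q <- seq(0.02, 0.2, length.out = 20)
  prof <- model_profile(m, q)
  fake <- list(snapshots = list(m$xyz, m$xyz, m$xyz, m$xyz),
               metrics = data.frame(step = 1:4, energy = 0,
                                    chi2 = c(3, 1, 2, 1),
                                    envelope_cor = NA, rg = NA),
               model = m)
  sel <- select_best_model(fake, prof)
  expect_identical(sel$frame, 2L)       # earliest of the tied minima
  expect_identical(sel$chi2, 1)

  mono <- fake
  mono$metrics$chi2 <- c(4, 3, 2, 1)
  expect_identical(select_best_model(mono, prof)$frame, 4L)

  expect_error(select_best_model(list(snapshots = list(), metrics = NULL),
                                 prof), "empty")
})

test_that("envelope correlation is 1 on self and ~0 when displaced", {
  m <- dumbbell_model(R = 10, sep = 30, n = 40)
  grid <- voxelize(m, spacing = 2.5, blur_sigma = 5)
  expect_equal(envelope_correlation(m, grid, blur_sigma = 5), 1,
               tolerance = 1e-9)

  moved <- m
  moved$xyz <- m$xyz + 500
  expect_lt(abs(envelope_correlation(moved, grid, blur_sigma = 5)), 0.05)

  flat <- density_grid(c(0, 0, 0), 1, array(1, c(4, 4, 4)))
  expect_error(envelope_correlation(m, flat), "variance")
})
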