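test_that("NSD is a symmetric shape metric matching direct enumeration", {
  A <- sphere_fill(20, 100, 1)
  B <- sphere_fill(20, 100, 2)
  expect_equal(nsd(A, A), 0, tolerance = 1e-7)
  expect_equal(nsd(A, B), nsd(B, A), tolerance = 1e-12)
  expect_gt(nsd(A, B), 0)

  # brute-force oracle on two offset unit cubic lattices
  g <- as.matrix(expand.grid(0:3, 0:3, 0:3))
  h <- sweep(g, 2, c(0.5, 0, 0), "+")
  nn_mean <- function(X) {
    mean(vapply(seq_len(nrow(X)), function(i) {
      min(sqrt(rowSums(sweep(X[-i, , drop = FALSE], 2, X[i, ])^2)))
    }, 0))
  }
  min2 <- function(X, Y) {
    vapply(seq_len(nrow(X)), function(i) {
      min(rowSums(sweep(Y, 2, X[i, ])^2))
    }, 0)
  }
  oracle <- sqrt(0.5 * (mean(min2(g, h)) / nn_mean(h)^2 +
                          mean(min2(h, g)) / nn_mean(g)^2))
  expect_equal(nsd(g, h), oracle, tolerance = 1e-12)

  expect_error(nsd(matrix(0, 1, 3), A), "two points")
})

test_that("alignment recovers rotations, mirrors, and never hurts", {
  A <- dumbbell_model()$xyz
  R <- rot_axis(c(1, 2, 3), 63)
  B <- sweep(A %*% t(R), 2, c(10, -4, 2), "+")
  al <- align_models(B, A)
  expect_lt(al$nsd, 0.05)

  Bm <- B
  Bm[, 1] <- -Bm[, 1]
  al2 <- align_models(Bm, A)
  expect_lt(al2$nsd, 0.05)
  expect_true(al2$inverted)

  # never worse than centre-of-mass-only superposition
  C <- sphere_fill(20, 80, 9)
  D <- sweep(sphere_fill(22, 90, 10) %*% t(rot_axis(c(0, 1, 1), 40)),
             2, c(5, 5, 5), "+")
  com_only <- nsd(sweep(D, 2, colMeans(D) - colMeans(C)), C)
  expect_lte(align_models(D, C)$nsd, com_only + 1e-9)
})

test_that("envelope clustering separates constructed shape families", {
  X <- sphere_fill(18, 70, 1)
  Y <- dumbbell_model(R = 10, sep = 60, n = 35)$xyz
  jig <- function(P, s) withr::with_seed(s, P + matrix(stats::rnorm(length(P), 0, 0.3), ncol = 3))
  models <- list(jig(X, 1), jig(X, 2), jig(X, 3), jig(Y, 4), jig(Y, 5), jig(Y, 6))
  cl <- cluster_envelopes(models, linkage_threshold = 0.7)
  expect_length(cl$clusters, 2L)
  expect_setequal(lengths(cl$clusters), c(3L, 3L))
  expect_length(cl$isolated, 0L)

  # threshold below every pairwise NSD: all isolated
  offd <- cl$nsd_matrix[upper.tri(cl$nsd_matrix)]
  cl0 <- cluster_envelopes(models, linkage_threshold = 0.9 * min(offd))
  expect_length(cl0$isolated, length(models))

  # within-cluster NSDs do not exceed between-cluster NSDs here
  within <- c(cl$nsd_matrix[1:3, 1:3][upper.tri(diag(3))],
              cl$nsd_matrix[4:6, 4:6][upper.tri(diag(3))])
  between <- as.vector(cl$nsd_matrix[1:3, 4:6])
  expect_lt(max(within), min(between))
})

test_that("envelope averaging keeps consensus sites only", {
  lat <- flexsaxs:::hcp_lattice(20, 4)
  occ <- rowSums(lat^2) <= 15^2
  member <- bead_model(lat, occ, 2)
  same <- average_envelopes(list(member, member, member))
  expect_identical(same$model$occupied, member$occupied)

  # a noise bead present in half the members misses the 0.5 cut...
  extra_site <- which(!occ)[1]
  occ_noise <- occ
  occ_noise[extra_site] <- TRUE
  noisy <- bead_model(lat, occ_noise, 2)
  avg <- average_envelopes(list(member, noisy, member, noisy))
  expect_identical(avg$model$occupied, member$occupied |
                     (seq_along(occ) == extra_site))
  # ...strictly below half it is dropped
  avg2 <- average_envelopes(list(member, noisy, member, member))
  expect_identical(avg2$model$occupied, member$occupied)

  expect_error(average_envelopes(list(member), threshold = 2), "empty")
})

test_that("voxelization conserves kernel mass and blurs peaks down", {
  one <- matrix(c(1.2, -0.7, 2.1), 1)
  g0 <- voxelize(one, spacing = 1, blur_sigma = 0)
  idx <- which(g0$rho == g0$rho_max, arr.ind = TRUE)[1, ]
  centre <- g0$origin + (idx - 1) * g0$spacing
  expect_true(all(abs(centre - one) <= 0.5 + 1e-9))

  pts <- sphere_fill(10, 30, 4)
  sp <- 1.5
  bl <- 2
  g <- voxelize(pts, spacing = sp, blur_sigma = bl)
  # unit mass per centre: sum(rho) * voxel volume = N within 1%
  expect_equal(sum(g$rho) * sp^3, nrow(pts), tolerance = 0.01)

  g2 <- voxelize(matrix(0, 1, 3), spacing = 1, blur_sigma = 2)
  g4 <- voxelize(matrix(0, 1, 3), spacing = 1, blur_sigma = 4)
  expect_lt(g4$rho_max, g2$rho_max)
  expect_equal(sum(g4$rho), sum(g2$rho), tolerance = 0.01)

  expect_error(voxelize(pts, spacing = -1), "spacing")
})

test_that("density grids round-trip through the text format", {
  g <- voxelize(sphere_fill(8, 20, 6), spacing = 2, blur_sigma = 3)
  f <- withr::local_tempfile(fileext = ".grid")
  write_density_grid(g, f)
  g2 <- read_density_grid(f)
  expect_equal(g2$origin, g$origin)
  expect_equal(g2$spacing, g$spacing)
  expect_equal(g2$rho, g$rho)
})

test_that("annealing is seeded, monotone in best objective, and connected", {
  ps <- sphere_profile(R = 20, qmax = 0.35, n = 60, floor_frac = 1e-4)
  sched <- list(n_temps = 14, moves_per_temp = 300)
  e1 <- anneal_envelope(ps, dmax = 40, seed = 3, schedule = sched)
  e2 <- anneal_envelope(ps, dmax = 40, seed = 3, schedule = sched)
  expect_identical(e1$occupied, e2$occupied)

  tr <- attr(e1, "objective_trace")
  expect_true(all(diff(tr) <= 1e-9))

  # single connected component via neighbour-graph flood fill
  ctr <- e1$centers
  a <- 2 * e1$bead_radius
  adj <- flexsaxs:::cross_dist2(ctr, ctr) <= (1.05 * a)^2
  reached <- rep(FALSE, nrow(ctr))
  reached[1] <- TRUE
  repeat {
    new <- as.vector(adj %*% reached > 0) & !reached
    if (!any(new)) break
    reached <- reached | new
  }
  expect_true(all(reached))

  expect_error(anneal_envelope(ps, dmax = 40, schedule = list(cool = 1.2)),
               "cooling")
  expect_error(anneal_envelope(ps), "dmax")
})
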