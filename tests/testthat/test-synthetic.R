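test_that("surrogate construction is deterministic and antibody-sized", {
  m1 <- build_antibody_surrogate(surrogate_spec(seed = 1))
  m2 <- build_antibody_surrogate(surrogate_spec(seed = 1))
  expect_identical(m1$xyz, m2$xyz)
  m3 <- build_antibody_surrogate(surrogate_spec(seed = 2))
  expect_false(identical(m1$xyz, m3$xyz))

  # direct mass-weighted Rg oracle
  w <- m1$f
  com <- colSums(m1$xyz * w) / sum(w)
  rg_direct <- sqrt(sum(w * rowSums(sweep(m1$xyz, 2, com)^2)) / sum(w))
  expect_equal(model_rg(m1), rg_direct, tolerance = 1e-12)
  expect_gt(rg_direct, 30)
  expect_lt(rg_direct, 70)

  expect_setequal(unique(m1$domain), c("Fa", "Fb", "Fc"))
  # no inter-domain clash: beads of different domains one diameter apart
  expect_gt(flexsaxs:::min_interdomain_distance(m1), 2 * m1$bead_radius)
})

test_that("conformer sampling keeps domains rigid and is seeded", {
  tpl <- test_surrogate()
  zero <- list(bend = c(0, 0), twist = c(0, 0))
  same <- sample_conformers(tpl, zero, n = 3, seed = 1)
  for (m in same) expect_equal(m$xyz, tpl$xyz, tolerance = 1e-12)

  wide <- list(bend = c(-35, 35), twist = c(-60, 60))
  pool1 <- sample_conformers(tpl, wide, n = 8, seed = 4)
  pool2 <- sample_conformers(tpl, wide, n = 8, seed = 4)
  pool3 <- sample_conformers(tpl, wide, n = 8, seed = 5)
  expect_identical(lapply(pool1, `[[`, "xyz"), lapply(pool2, `[[`, "xyz"))
  expect_false(identical(pool1[[1]]$xyz, pool3[[1]]$xyz))

  # rigid-domain conservation: intra-domain distances preserved < 1e-9 A;
  # per-domain Rg identical across conformers while global Rg varies
  ref_dists <- lapply(split(seq_len(nrow(tpl$xyz)), tpl$domain),
                      function(i) stats::dist(tpl$xyz[i, ]))
  global_rg <- vapply(pool1, model_rg, 0)
  for (m in pool1) {
    for (d in names(ref_dists)) {
      i <- which(m$domain == d)
      expect_lt(max(abs(stats::dist(m$xyz[i, ]) - ref_dists[[d]])), 1e-9)
    }
  }
  expect_gt(diff(range(global_rg)), 0.1)
})

test_that("simulated profiles follow the stated noise model", {
  tpl <- test_surrogate()
  q <- seq(0.01, 0.3, length.out = 50)
  ideal <- debye_profile(tpl, q)

  # zero-noise limit
  p0 <- simulate_profile(tpl, q, noise_spec(counts_scale = 1e18))
  expect_lt(max(abs(p0$I - ideal$I) / ideal$I), 1e-9)

  # sigma strictly positive with monotonically growing relative error
  p1 <- simulate_profile(tpl, q, noise_spec(error_growth = 0.1, seed = 2))
  expect_true(all(p1$sigma > 0))
  expect_true(all(diff(p1$sigma / ideal$I) > 0))

  # Monte-Carlo: per-point mean within 3 standard errors of the ideal
  small <- atomic_model(sphere_fill(20, 40, 3))
  qs <- seq(0.02, 0.25, length.out = 20)
  ideal_s <- debye_profile(small, qs)$I
  n_rep <- 400
  sims <- vapply(seq_len(n_rep), function(s) {
    simulate_profile(small, qs, noise_spec(seed = s))$I
  }, numeric(length(qs)))
  se <- apply(sims, 1, stats::sd) / sqrt(n_rep)
  expect_true(all(abs(rowMeans(sims) - ideal_s) < 3.5 * se + 1e-9))
})

test_that("temperature series mixes folded and expanded states", {
  tpl <- test_surrogate()
  expect_error(simulate_temperature_series(tpl, c(20, 30),
                                           expansion_factor = 0.9),
               "expansion_factor")
  noiseless <- noise_spec(counts_scale = 1e18)
  q <- seq(0.008, 0.2, length.out = 80)
  low <- simulate_temperature_series(tpl, c(5, 15, 25), unfold_midpoint = 70,
                                     noise = noiseless, q_grid = q)
  fold_I <- debye_profile(tpl, q)$I
  for (p in low) expect_lt(max(abs(p$I - fold_I) / fold_I), 1e-6)

  mid <- simulate_temperature_series(tpl, 70, unfold_midpoint = 70,
                                     noise = noiseless, q_grid = q)
  expect_equal(mid[[1]]$metadata$unfolded_fraction, 0.5)

  hot <- simulate_temperature_series(tpl, c(60, 90), unfold_midpoint = 70,
                                     noise = noiseless, q_grid = q)
  rg_fold <- guinier_fit(model_profile(tpl, q))$Rg
  rg_hot <- guinier_fit(hot[[2]])$Rg
  expect_gt(rg_hot, rg_fold)
})

test_that("concentration series produces the dimer mixture", {
  tpl <- test_surrogate()
  noiseless <- noise_spec(counts_scale = 1e18)
  q <- seq(0.008, 0.2, length.out = 80)
  mono_I <- debye_profile(tpl, q)$I

  none <- simulate_concentration_series(tpl, c(1, 4, 8),
                                        dimer_fraction_fn = function(c) 0 * c,
                                        noise = noiseless, q_grid = q)
  for (p in none) expect_lt(max(abs(p$I - mono_I) / mono_I), 1e-9)

  all_dimer <- simulate_concentration_series(tpl, 8,
                                             dimer_fraction_fn = function(c) rep(1, length(c)),
                                             noise = noiseless, q_grid = q)
  dimer <- flexsaxs:::build_dimer(tpl)
  rg_d <- model_rg(dimer)
  expect_equal(guinier_fit(all_dimer[[1]])$Rg, rg_d, tolerance = 0.02 * rg_d)

  expect_error(
    simulate_concentration_series(tpl, 5,
                                  dimer_fraction_fn = function(c) c / 2,
                                  noise = noiseless, q_grid = q),
    "\\[0, 1\\]")

  agg <- simulate_concentration_series(tpl, c(1, 2, 4, 6, 8),
                                       noise = noise_spec(counts_scale = 100, seed = 9),
                                       q_grid = q)
  rgs <- vapply(agg, function(p) guinier_fit(p)$Rg, 0)
  expect_gt(stats::cor(c(1, 2, 4, 6, 8), rgs), 0.9)
})
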