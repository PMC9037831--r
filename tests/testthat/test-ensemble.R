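test_that("pools are seeded with precomputed sizes and profiles", {
  tpl <- test_surrogate()
  q <- seq(0.02, 0.25, length.out = 40)
  zero <- list(bend = c(0, 0), twist = c(0, 0))
  p0 <- build_pool(tpl, zero, n = 6, q_grid = q, seed = 1)
  expect_true(all(apply(p0$profiles, 2, function(col) diff(range(col)) == 0)))

  wide <- list(bend = c(-35, 35), twist = c(-60, 60))
  p1 <- build_pool(tpl, wide, n = 30, q_grid = q, seed = 2)
  p2 <- build_pool(tpl, wide, n = 30, q_grid = q, seed = 2)
  expect_identical(p1$profiles, p2$profiles)
  expect_lt(min(p1$rg), model_rg(tpl))
  expect_gt(max(p1$rg), model_rg(tpl))
  expect_error(build_pool(tpl, wide, n = 1, q_grid = q), "n >= 2")
})

test_that("the genetic algorithm recovers a planted single truth", {
  tpl <- test_surrogate()
  q <- seq(0.02, 0.25, length.out = 40)
  pool <- build_pool(tpl, n = 40, q_grid = q, seed = 3)
  target <- 17L
  obs <- scattering_profile(q, pool$profiles[target, ],
                            pmax(0.002 * pool$profiles[target, ],
                                 1e-6 * max(pool$profiles[target, ])))
  sel <- select_ensemble(pool, obs, ensemble_size = 1, seed = 4)
  expect_identical(sel$members, target)
  expect_lt(sel$chi2, 1e-10)
  expect_equal(sum(sel$weights), 1)

  # identical-model pool: any selection gives the single-model chi2
  same <- pool
  same$profiles <- matrix(rep(pool$profiles[1, ], 10), nrow = 10,
                          byrow = TRUE)
  same$rg <- rep(pool$rg[1], 10)
  same$dmax <- rep(pool$dmax[1], 10)
  obs1 <- scattering_profile(q, pool$profiles[1, ],
                             pmax(0.01 * pool$profiles[1, ],
                                  1e-6 * max(pool$profiles[1, ])))
  s1 <- select_ensemble(same, obs1, ensemble_size = 3, seed = 1,
                        ga_params = list(population = 20, generations = 10))
  expect_equal(s1$chi2,
               fit_chi2(scattering_profile(q, pool$profiles[1, ]), obs1)$chi2_reduced,
               tolerance = 1e-9)

  expect_error(select_ensemble(pool, obs, ensemble_size = 40), "larger")
})

test_that("GA best fitness never increases across generations", {
  tpl <- test_surrogate()
  q <- seq(0.02, 0.25, length.out = 40)
  pool <- build_pool(tpl, n = 25, q_grid = q, seed = 5)
  Imix <- colMeans(pool$profiles[c(3, 8, 20), ])
  obs <- withr::with_seed(6, scattering_profile(
    q, Imix + stats::rnorm(40, 0, 0.01 * Imix), 0.01 * Imix))
  sel <- select_ensemble(pool, obs, ensemble_size = 5, seed = 2,
                         ga_params = list(population = 40, generations = 60))
  expect_true(all(diff(sel$fitness_trace) <= 1e-9))
})

test_that("Rflex matches hand-computed entropies and is affine invariant", {
  edges8 <- seq(0, 8, by = 1)
  expect_equal(rflex(rep(0.5, 20), edges8), 0)
  expect_equal(rflex(rep(seq(0.5, 7.5, by = 1), 3), edges8), 100)
  # two equally filled bins of eight: 100 * 1 / log2(8)
  expect_equal(rflex(c(rep(0.5, 5), rep(3.5, 5)), edges8), 100 / 3,
               tolerance = 1e-9)

  vals <- withr::with_seed(2, stats::runif(200, 30, 60))
  edges <- seq(30, 60, length.out = 21)
  a <- rflex(vals, edges)
  b <- rflex(vals * 2 + 5, edges * 2 + 5)
  expect_equal(a, b, tolerance = 1e-12)

  expect_error(rflex(numeric(0), edges8), "values")
  expect_error(rflex(1, c(0, 0, 1)), "increasing")
})

test_that("Rsigma is the dispersion ratio", {
  pool <- c(40, 42, 44, 46, 48, 50)
  expect_equal(rsigma(pool, pool), 1)
  expect_equal(rsigma(rep(44, 5), pool), 0)
  shrunk <- mean(pool) + 0.5 * (pool - mean(pool))
  expect_equal(rsigma(shrunk, pool), 0.5, tolerance = 1e-12)
  expect_error(rsigma(pool, rep(1, 5)), "zero")
})

test_that("flexibility reports order rigid vs flexible truths correctly", {
  tpl <- test_surrogate()
  q <- seq(0.02, 0.25, length.out = 40)
  pool <- build_pool(tpl, n = 60, q_grid = q, seed = 7)

  # rigid planted truth: narrow selection
  tgt <- pool$profiles[11, ]
  obs <- scattering_profile(q, tgt, pmax(0.01 * tgt, 1e-6 * max(tgt)))
  sel <- select_ensemble(pool, obs, ensemble_size = 8, seed = 3)
  fr <- flexibility_report(pool, sel)
  expect_lt(fr$rsigma, 1)
  expect_lt(fr$rflex_selected, fr$rflex_pool)

  # two-state truth sits between the rigid case and the pool
  Imix <- 0.5 * pool$profiles[which.min(pool$rg), ] +
    0.5 * pool$profiles[which.max(pool$rg), ]
  obs2 <- scattering_profile(q, Imix, pmax(0.01 * Imix, 1e-6 * max(Imix)))
  sel2 <- select_ensemble(pool, obs2, ensemble_size = 8, seed = 3)
  fr2 <- flexibility_report(pool, sel2)
  expect_gt(fr2$rsigma, fr$rsigma)

  # selection = whole pool: metrics coincide
  all_sel <- list(members = seq_len(60), weights = rep(1 / 60, 60),
                  multiset = seq_len(60), rg = pool$rg, dmax = pool$dmax)
  fr3 <- flexibility_report(pool, all_sel)
  expect_equal(fr3$rflex_selected, fr3$rflex_pool)
  expect_equal(fr3$rsigma, 1)
})
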