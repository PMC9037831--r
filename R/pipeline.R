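#' Load a run configuration
#'
#' Reads a per-stage YAML configuration (or accepts a list) and fills in
#' stage defaults. Every stochastic stage must carry an explicit seed.
#'
#' @param config path to a YAML file or a nested list.
#' @return The validated configuration list.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  defaults <- list(
    seed = 1,
    surrogate = list(),
    noise = list(),
    q_grid = list(min = 0.008, max = 0.35, n = 120),
    invariants = list(dmax_scan = TRUE),
    envelope = list(n_models = 6, cluster_threshold = 0.7),
    refine = list(steps = 4000, step_size = 2, k = 0.1, spring_k = 0.03,
                  cutoff = 12, stride = 100),
    ensemble = list(pool_size = 200, ensemble_size = 5, bins = 20)
  )
  utils::modifyList(defaults, config)
}

config_q_grid <- function(config) {
  g <- config$q_grid
  seq(g$min, g$max, length.out = g$n)
}

config_surrogate <- function(config) {
  do.call(surrogate_spec, c(config$surrogate,
                            list(seed = config$surrogate$seed %||% config$seed)))
}

config_noise <- function(config, offset = 0) {
  do.call(noise_spec, utils::modifyList(
    list(seed = config$seed + offset), config$noise))
}

#' Static characterization workflow
#'
#' Runs the single-conformation pipeline on a profile: model-free
#' invariants (Guinier, P(r), Dmax scan), ab initio envelope
#' reconstruction with NSD clustering and averaging, voxelization, then
#' envelope-restrained refinement of a starting model and reciprocal-space
#' selection of the best frame. When no profile is supplied, a synthetic
#' surrogate is generated from the config and its simulated profile used,
#' giving a fully self-contained ground-truth run.
#'
#' @param config list or YAML path (see [read_run_config()]).
#' @param profile optional [scattering_profile()] (overrides synthesis).
#' @param start_model optional starting [atomic_model()] for refinement;
#'   `NULL` with `envelope_only = TRUE` skips the refinement stage.
#' @param envelope_only stop after envelope averaging.
#' @return Report list with stage results (`guinier`, `pr`, `dmax_scan`,
#'   `envelopes`, `clustering`, `average`, `trajectory`, `best`).
#' @export
run_static <- function(config = list(), profile = NULL, start_model = NULL,
                       envelope_only = FALSE) {
  config <- read_run_config(config)
  truth <- NULL
  if (is.null(profile)) {
    truth <- build_antibody_surrogate(config_surrogate(config))
    profile <- simulate_profile(truth, config_q_grid(config),
                                config_noise(config))
    if (is.null(start_model)) start_model <- truth
  }
  gn <- guinier_fit(profile)
  dmax_grid <- seq(1.5 * gn$Rg, 3.5 * gn$Rg, length.out = 9)
  scan <- if (isTRUE(config$invariants$dmax_scan)) {
    scan_dmax(profile, dmax_grid)
  } else NULL
  dmax <- scan$optimal_dmax %||% (2.6 * gn$Rg)
  pr <- ift_pr(profile, dmax)
  env_seeds <- config$seed + seq_len(config$envelope$n_models)
  envelopes <- lapply(env_seeds, function(s) {
    anneal_envelope(pr, seed = s)
  })
  clustering <- cluster_envelopes(envelopes,
                                  config$envelope$cluster_threshold)
  avg <- if (length(clustering$averages) && !is.null(clustering$averages[[1]])) {
    clustering$averages[[1]]
  } else {
    average_envelopes(envelopes[1], reference = 1)
  }
  report <- list(guinier = gn, pr = pr, dmax_scan = scan,
                 pr_peaks = pr_peaks(pr),
                 envelopes = envelopes, clustering = clustering,
                 average = avg, truth = truth)
  if (!is.null(start_model) && !envelope_only) {
    rc <- config$refine
    grid <- avg$grid
    # dock the starting model into the (arbitrarily oriented) envelope
    docked <- start_model
    docked$xyz <- align_models(start_model$xyz, avg$model$centers)$points
    start_model <- docked
    net <- build_restraint_network(start_model, cutoff = rc$cutoff,
                                   spring_k = rc$spring_k)
    traj <- restrained_refine(start_model, grid, net,
                              envelope_potential_params(k = rc$k),
                              steps = rc$steps, step_size = rc$step_size,
                              seed = config$seed, profile = profile,
                              stride = rc$stride)
    report$trajectory <- traj
    report$best <- select_best_model(traj, profile)
  }
  report
}

#' Flexibility analysis workflow
#'
#' Builds a hinge-conformer pool, selects the sub-ensemble best fitting
#' the profile, and quantifies flexibility (Rflex of the pool and of the
#' selection, Rsigma, size histograms).
#'
#' @param config list or YAML path.
#' @param profile optional observed [scattering_profile()]; default: the
#'   simulated profile of the generated surrogate.
#' @param template optional hinged template model.
#' @return Report list (`pool`, `selection`, `flexibility`).
#' @export
run_flexibility <- function(config = list(), profile = NULL, template = NULL) {
  config <- read_run_config(config)
  if (is.null(template)) template <- build_antibody_surrogate(config_surrogate(config))
  q <- config_q_grid(config)
  pool <- build_pool(template, n = config$ensemble$pool_size, q_grid = q,
                     seed = config$seed)
  if (is.null(profile)) {
    profile <- simulate_profile(template, q, config_noise(config))
  }
  sel <- select_ensemble(pool, profile,
                         ensemble_size = config$ensemble$ensemble_size,
                         seed = config$seed + 1)
  list(pool = pool, selection = sel,
       flexibility = flexibility_report(pool, sel,
                                        n_bins = config$ensemble$bins))
}

#' Condition-comparison workflow
#'
#' Per-condition invariants plus profile-space PCA and size-trend
#' statistics across two or more condition series (e.g. concentration
#' series with and without a protective additive).
#'
#' @param config list or YAML path.
#' @param series named list of condition series; each series is a list of
#'   [scattering_profile()]s carrying `concentration` metadata.
#' @return Report list: per-series invariant tables, `pca` on the pooled
#'   log-profile matrix, per-series `trend` correlations.
#' @export
run_comparison <- function(config = list(), series) {
  config <- read_run_config(config)
  if (length(series) < 2) stop("need >= 2 condition series")
  invariants <- lapply(series, function(profiles) {
    do.call(rbind, lapply(profiles, function(p) {
      gn <- guinier_fit(p)
      pr <- ift_pr(p, Dmax = 2.8 * gn$Rg)
      data.frame(concentration = p$metadata$concentration %||% NA_real_,
                 temperature = p$metadata$temperature %||% NA_real_,
                 rg = gn$Rg, i0 = gn$I0, rg_pr = pr$Rg,
                 dmax = pr$Dmax)
    }))
  })
  all_profiles <- unlist(series, recursive = FALSE)
  pm <- profile_matrix(all_profiles)
  pca <- saxs_pca(pm)
  trends <- lapply(invariants, function(tab) {
    if (all(is.finite(tab$concentration)) && nrow(tab) >= 3) {
      size_vs_concentration(tab)
    } else NULL
  })
  list(invariants = invariants, pca = pca, trend = trends,
       labels = rep(names(series), vapply(series, length, 1L)))
}
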