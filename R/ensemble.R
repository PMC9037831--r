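#' Build a conformer pool with precomputed profiles
#'
#' Samples clash-free hinge conformers of the rigid-domain surrogate (via
#' [sample_conformers()]) and precomputes, per conformer, its Debye
#' profile on a common q grid, its Rg and its Dmax.
#'
#' @param template hinged [atomic_model()].
#' @param hinge_ranges list with `bend` / `twist` degree ranges.
#' @param n pool size (>= 2).
#' @param q_grid shared q grid for all precomputed profiles.
#' @param seed integer RNG seed.
#' @return A `conformer_pool`: `models`, `profiles` (intensity matrix,
#'   one row per model), `q`, `rg`, `dmax`.
#' @export
build_pool <- function(template, hinge_ranges = NULL, n = 200,
                       q_grid = seq(0.01, 0.3, length.out = 60), seed = 1) {
  if (n < 2) stop("pool needs n >= 2")
  models <- sample_conformers(template, hinge_ranges, n = n, seed = seed)
  I <- t(vapply(models, function(m) debye_profile(m, q_grid)$I,
                numeric(length(q_grid))))
  structure(list(models = models,
                 profiles = I,
                 q = q_grid,
                 rg = vapply(models, model_rg, 0),
                 dmax = vapply(models, model_dmax, 0)),
            class = "conformer_pool")
}

#' @export
print.conformer_pool <- function(x, ...) {
  cat(sprintf("<conformer_pool> %d conformers, Rg in [%.1f, %.1f] A\n",
              length(x$models), min(x$rg), max(x$rg)))
  invisible(x)
}

# chi2 of the uniform-weighted mean profile of pool members `idx`
# against obs (scale fitted per evaluation).
ensemble_chi2 <- function(pool, idx, obs) {
  Im <- colMeans(pool$profiles[idx, , drop = FALSE])
  w <- 1 / obs$sigma^2
  cs <- sum(w * obs$I * Im) / sum(w * Im^2)
  sum(w * (obs$I - cs * Im)^2) / max(1, length(obs$I) - 1)
}

#' Genetic-algorithm sub-ensemble selection
#'
#' Selects a multiset of `ensemble_size` pool members whose
#' uniform-weighted mean profile best fits the observation (reduced
#' chi-square with a fitted scale). Chromosomes are member multisets;
#' evolution uses tournament selection, uniform member-exchange crossover,
#' member-replacement mutation and single elitism. Deterministic per seed.
#'
#' @param pool a [build_pool()] result.
#' @param obs observed [scattering_profile()] on the pool q grid.
#' @param ensemble_size members per ensemble (repeats allowed).
#' @param ga_params list: `population`, `generations`, `mutation_rate`,
#'   `tournament`, `patience` (generations without improvement before an
#'   early stop with a warning flag).
#' @param seed integer RNG seed.
#' @return An `ensemble_selection`: `members` (unique indices), `weights`
#'   (multiplicity / ensemble_size), `multiset`, `chi2`, `rg`, `dmax`,
#'   `fitness_trace`, `warning_flag`.
#' @export
select_ensemble <- function(pool, obs, ensemble_size = 5,
                            ga_params = list(), seed = 1) {
  stopifnot_profile(obs)
  npool <- nrow(pool$profiles)
  if (ensemble_size < 1) stop("ensemble_size must be >= 1")
  if (npool <= ensemble_size) stop("pool must be larger than ensemble_size")
  if (!same_q_grid(list(q = pool$q), obs)) {
    stop("observed profile must share the pool q grid")
  }
  gp <- utils::modifyList(list(population = 100, generations = 200,
                               mutation_rate = 0.1, tournament = 5,
                               patience = Inf), ga_params)
  with_seed_(seed, {
    popmat <- matrix(sample.int(npool, gp$population * ensemble_size,
                                replace = TRUE),
                     nrow = gp$population)
    fitness <- apply(popmat, 1, function(ch) ensemble_chi2(pool, ch, obs))
    trace <- numeric(gp$generations)
    stall <- 0L
    warn <- FALSE
    for (g in seq_len(gp$generations)) {
      newpop <- matrix(0L, gp$population, ensemble_size)
      best <- which.min(fitness)
      newpop[1, ] <- popmat[best, ]          # elitism
      for (p in 2:gp$population) {
        pick <- function() {
          cand <- sample.int(gp$population, gp$tournament)
          cand[which.min(fitness[cand])]
        }
        pa <- popmat[pick(), ]; pb <- popmat[pick(), ]
        take <- stats::runif(ensemble_size) < 0.5
        child <- ifelse(take, pa, pb)
        mut <- stats::runif(ensemble_size) < gp$mutation_rate
        if (any(mut)) child[mut] <- sample.int(npool, sum(mut), replace = TRUE)
        newpop[p, ] <- child
      }
      popmat <- newpop
      fitness <- apply(popmat, 1, function(ch) ensemble_chi2(pool, ch, obs))
      trace[g] <- min(fitness)
      if (g > 1 && trace[g] >= trace[g - 1] - 1e-12) stall <- stall + 1L
      else stall <- 0L
      if (stall > gp$patience) {
        warn <- TRUE
        trace <- trace[seq_len(g)]
        break
      }
    }
    best_ch <- popmat[which.min(fitness), ]
    tab <- table(best_ch)
    members <- as.integer(names(tab))
    structure(list(members = members,
                   weights = as.numeric(tab) / ensemble_size,
                   multiset = sort(best_ch),
                   chi2 = min(fitness),
                   rg = pool$rg[best_ch],
                   dmax = pool$dmax[best_ch],
                   fitness_trace = trace,
                   warning_flag = warn),
              class = "ensemble_selection")
  })
}

#' Entropy-based flexibility percentage (Rflex)
#'
#' Histogram entropy of a size distribution on fixed bins:
#' `Rflex = 100 * (-sum p log2 p) / log2(n_bins)` with `0 log 0 = 0`.
#' 0% for a distribution concentrated in one bin (rigid), 100% for a
#' uniform occupation of all bins (fully flexible).
#'
#' @param values Rg (or Dmax) values.
#' @param bin_edges strictly increasing bin edges (>= 3 values: >= 2 bins).
#' @return Rflex in percent.
#' @export
rflex <- function(values, bin_edges) {
  if (!length(values)) stop("no values")
  if (length(bin_edges) < 3 || any(diff(bin_edges) <= 0)) {
    stop("bin_edges must define at least 2 strictly increasing bins")
  }
  h <- graphics::hist(pmin(pmax(values, bin_edges[1]),
                           bin_edges[length(bin_edges)]),
                      breaks = bin_edges, plot = FALSE)
  p <- h$counts / sum(h$counts)
  p <- p[p > 0]
  ent <- -sum(p * log2(p))
  100 * ent / log2(length(bin_edges) - 1) + 0   # + 0 normalizes -0

}

#' Size-dispersion ratio (Rsigma)
#'
#' Ratio of the standard deviation of the selected ensemble's sizes to
#' that of the random pool; values below 1 indicate that the data select
#' a narrower (more rigid) distribution than free hinge sampling.
#'
#' @param selected,pool_values numeric vectors (>= 2 values each).
#' @return Dimensionless ratio.
#' @export
rsigma <- function(selected, pool_values) {
  if (length(selected) < 2 || length(pool_values) < 2) {
    stop("need >= 2 values in both the selection and the pool")
  }
  sp <- stats::sd(pool_values)
  if (sp == 0) stop("pool standard deviation is zero")
  stats::sd(selected) / sp
}

#' Flexibility report for a selection against its pool
#'
#' Computes Rflex for the selected ensemble and the pool on shared bins
#' spanning the pool range, Rsigma, and the weighted Rg/Dmax histograms.
#'
#' @param pool a [build_pool()] result.
#' @param selection an [select_ensemble()] result.
#' @param n_bins histogram bins over the pool's `[min, max]` range.
#' @return List with `rflex_selected`, `rflex_pool`, `rsigma`,
#'   `rg_bins`, `rg_hist_pool`, `rg_hist_selected`, `dmax_bins`,
#'   `dmax_hist_pool`, `dmax_hist_selected`.
#' @export
flexibility_report <- function(pool, selection, n_bins = 20) {
  edges <- function(v) {
    lo <- min(v); hi <- max(v)
    if (hi - lo < 1e-9) { lo <- lo - 0.5; hi <- hi + 0.5 }
    seq(lo, hi, length.out = n_bins + 1)
  }
  rg_e <- edges(pool$rg); dm_e <- edges(pool$dmax)
  histw <- function(v, e) {
    graphics::hist(pmin(pmax(v, e[1]), e[length(e)]), breaks = e,
                   plot = FALSE)$counts
  }
  list(rflex_selected = rflex(selection$rg, rg_e),
       rflex_pool = rflex(pool$rg, rg_e),
       rsigma = rsigma(selection$rg, pool$rg),
       rg_bins = rg_e,
       rg_hist_pool = histw(pool$rg, rg_e) / length(pool$rg),
       rg_hist_selected = histw(selection$rg, rg_e) / length(selection$rg),
       dmax_bins = dm_e,
       dmax_hist_pool = histw(pool$dmax, dm_e) / length(pool$dmax),
       dmax_hist_selected = histw(selection$dmax, dm_e) / length(selection$dmax))
}
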