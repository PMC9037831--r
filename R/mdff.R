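#' Parameters of the envelope restraint potential
#'
#' The density potential `V(r) = k * (1 - rho(r) / rho_max)` drives atoms
#' toward high-density regions of a molecular envelope: it is zero at the
#' density maximum and `k` outside the envelope. Applied to the model's
#' bead (C-alpha level) coordinates.
#'
#' @param k energy scale of the restraint (arbitrary units, default 0.1).
#' @param selection `"all"` or a logical/integer selector of restrained
#'   beads.
#' @return An `envelope_potential_params` list.
#' @export
envelope_potential_params <- function(k = 0.1, selection = "all") {
  if (k < 0) stop("k must be >= 0")
  structure(list(k = k, selection = selection),
            class = "envelope_potential_params")
}

# Trilinear interpolation of rho and its analytic gradient at positions
# (N x 3). Outside the grid the density clamps to 0 with zero force.
trilinear_rho_grad <- function(grid, pos) {
  dims <- dim(grid$rho)
  h <- grid$spacing
  t <- sweep(pos, 2, grid$origin) / h
  i0 <- floor(t)
  fr <- t - i0
  ok <- i0[, 1] >= 0 & i0[, 1] <= dims[1] - 2 &
    i0[, 2] >= 0 & i0[, 2] <= dims[2] - 2 &
    i0[, 3] >= 0 & i0[, 3] <= dims[3] - 2
  n <- nrow(pos)
  rho <- numeric(n)
  grad <- matrix(0, n, 3)
  if (any(ok)) {
    ii <- i0[ok, 1]; jj <- i0[ok, 2]; kk <- i0[ok, 3]
    fx <- fr[ok, 1]; fy <- fr[ok, 2]; fz <- fr[ok, 3]
    corner <- function(dx, dy, dz) {
      grid$rho[cbind(ii + dx + 1, jj + dy + 1, kk + dz + 1)]
    }
    c000 <- corner(0, 0, 0); c100 <- corner(1, 0, 0)
    c010 <- corner(0, 1, 0); c110 <- corner(1, 1, 0)
    c001 <- corner(0, 0, 1); c101 <- corner(1, 0, 1)
    c011 <- corner(0, 1, 1); c111 <- corner(1, 1, 1)
    # interpolate along x, then y, then z
    a00 <- c000 + fx * (c100 - c000); a10 <- c010 + fx * (c110 - c010)
    a01 <- c001 + fx * (c101 - c001); a11 <- c011 + fx * (c111 - c011)
    b0 <- a00 + fy * (a10 - a00); b1 <- a01 + fy * (a11 - a01)
    rho[ok] <- b0 + fz * (b1 - b0)
    # analytic partials of the trilinear form
    dx00 <- c100 - c000; dx10 <- c110 - c010
    dx01 <- c101 - c001; dx11 <- c111 - c011
    gx0 <- dx00 + fy * (dx10 - dx00); gx1 <- dx01 + fy * (dx11 - dx01)
    grad[ok, 1] <- (gx0 + fz * (gx1 - gx0)) / h
    gy0 <- a10 - a00; gy1 <- a11 - a01
    grad[ok, 2] <- (gy0 + fz * (gy1 - gy0)) / h
    grad[ok, 3] <- (b1 - b0) / h
  }
  list(rho = rho, grad = grad, inside = ok)
}

#' Envelope potential energy and forces
#'
#' Evaluates `V = k * sum_selected (1 - rho(r_i) / rho_max)` with `rho`
#' trilinearly interpolated from the grid, and the per-atom force
#' `F_i = (k / rho_max) * grad rho(r_i)` from the analytic derivative of
#' the trilinear form. Positions outside the grid contribute `V = k` with
#' zero force.
#'
#' @param grid a [density_grid()] with `rho_max > 0`.
#' @param params an [envelope_potential_params()].
#' @param positions N x 3 coordinate matrix.
#' @return List with `energy` and `forces` (N x 3; zero rows for
#'   unselected atoms).
#' @export
envelope_energy_force <- function(grid, params, positions) {
  if (grid$rho_max <= 0) stop("rho_max must be > 0")
  positions <- as.matrix(positions)
  n <- nrow(positions)
  sel <- params$selection
  idx <- if (identical(sel, "all")) seq_len(n) else
    if (is.logical(sel)) which(sel) else as.integer(sel)
  tri <- trilinear_rho_grad(grid, positions[idx, , drop = FALSE])
  energy <- params$k * sum(1 - tri$rho / grid$rho_max)
  forces <- matrix(0, n, 3)
  forces[idx, ] <- (params$k / grid$rho_max) * tri$grad
  list(energy = energy, forces = forces)
}

#' Build an intra-domain elastic restraint network
#'
#' Harmonic springs between all intra-domain bead pairs closer than
#' `cutoff`, with rest lengths equal to the current distances. No
#' inter-domain pairs are created, so hinge motions stay unrestrained
#' while domain interiors are held rigid (the coarse-grained counterpart
#' of secondary-structure restraints).
#'
#' @param model an [atomic_model()].
#' @param partition optional per-bead domain labels; defaults to
#'   `model$domain`.
#' @param cutoff pair cutoff (Angstrom).
#' @param spring_k spring constant (energy / Angstrom^2); the default is
#'   matched to the default integration step of [restrained_refine()]
#'   (explicit-Euler stability requires `step_size * spring_k * degree`
#'   well below 2).
#' @return A `restraint_network` list with `i`, `j`, `r0`, `spring_k`.
#' @export
build_restraint_network <- function(model, partition = NULL, cutoff = 12,
                                    spring_k = 0.03) {
  labels <- partition %||% model$domain
  if (length(labels) != nrow(model$xyz)) {
    stop("partition must label every atom")
  }
  xyz <- model$xyz
  d <- as.matrix(stats::dist(xyz))
  same <- outer(labels, labels, "==")
  sel <- which(upper.tri(d) & same & d <= cutoff, arr.ind = TRUE)
  structure(list(i = sel[, 1], j = sel[, 2],
                 r0 = d[sel], spring_k = spring_k,
                 n_atoms = nrow(xyz)),
            class = "restraint_network")
}

# Energy and forces of the harmonic network at given positions.
network_energy_force <- function(network, pos) {
  dv <- pos[network$i, , drop = FALSE] - pos[network$j, , drop = FALSE]
  d <- sqrt(rowSums(dv^2))
  stretch <- d - network$r0
  energy <- 0.5 * network$spring_k * sum(stretch^2)
  fmag <- -network$spring_k * stretch / pmax(d, 1e-12)
  fvec <- dv * fmag
  forces <- matrix(0, network$n_atoms, 3)
  for (c in 1:3) {
    forces[, c] <- forces[, c] +
      tapply(c(fvec[, c], -fvec[, c]),
             factor(c(network$i, network$j), levels = seq_len(network$n_atoms)),
             sum, default = 0)
  }
  list(energy = energy, forces = forces)
}

#' Envelope-restrained flexible refinement
#'
#' Overdamped Langevin dynamics (pure gradient descent at temperature 0)
#' of the bead coordinates under the envelope potential plus the elastic
#' restraint network. Snapshots and per-frame metrics (chi-square against
#' a profile when given, Pearson correlation with the envelope grid,
#' global Rg) are recorded every `stride` steps. Deterministic per seed.
#'
#' @param model starting [atomic_model()].
#' @param grid target [density_grid()].
#' @param network a [build_restraint_network()] result.
#' @param params an [envelope_potential_params()].
#' @param steps integration steps.
#' @param step_size Euler step (reduced units; damping absorbed).
#' @param temperature thermal noise scale (0 = deterministic descent).
#' @param seed integer RNG seed (used when `temperature > 0`).
#' @param profile optional [scattering_profile()] for chi-square tracking.
#' @param stride snapshot interval (steps).
#' @param blur_sigma blur used for envelope-correlation tracking; default
#'   twice the model bead radius.
#' @param diverge_patience consecutive energy increases (at temperature 0)
#'   tolerated before aborting with a step-size diagnostic.
#' @return A `trajectory` list: `snapshots` (list of coordinate
#'   matrices), `metrics` data frame (`step`, `energy`, `chi2`,
#'   `envelope_cor`, `rg`), `final` (final [atomic_model()]).
#' @export
restrained_refine <- function(model, grid, network,
                              params = envelope_potential_params(),
                              steps = 5000, step_size = 2, temperature = 0,
                              seed = 1, profile = NULL, stride = 50,
                              blur_sigma = NULL, diverge_patience = 100) {
  pos <- model$xyz
  blur_sigma <- blur_sigma %||% (2 * (model$bead_radius %||% 2))
  record <- function(pos, step, energy) {
    m <- model; m$xyz <- pos
    chi2 <- NA_real_
    if (!is.null(profile)) {
      calc <- debye_profile(m, profile$q)
      chi2 <- fit_chi2(calc, profile)$chi2_reduced
    }
    ec <- envelope_correlation(m, grid, blur_sigma)
    data.frame(step = step, energy = energy, chi2 = chi2,
               envelope_cor = ec, rg = coords_rg(pos, model$f))
  }
  run <- function() {
    snapshots <- list()
    metrics <- list()
    rising <- 0L
    prev_energy <- Inf
    for (s in seq_len(steps)) {
      env <- envelope_energy_force(grid, params, pos)
      net <- network_energy_force(network, pos)
      energy <- env$energy + net$energy
      if (temperature == 0) {
        if (energy > prev_energy + 1e-12) rising <- rising + 1L else rising <- 0L
        if (rising > diverge_patience) {
          stop("refinement diverging: energy rose for ", rising,
               " consecutive steps; reduce step_size (", step_size, ")")
        }
        prev_energy <- energy
      }
      force <- env$forces + net$forces
      if (anyNA(force) || !all(is.finite(range(force)))) {
        stop("refinement diverged to non-finite forces at step ", s,
             "; reduce step_size or spring_k")
      }
      pos <<- pos + step_size * force +
        if (temperature > 0) {
          matrix(stats::rnorm(length(pos), 0,
                              sqrt(2 * step_size * temperature)), ncol = 3)
        } else 0
      if (s %% stride == 0 || s == steps) {
        snapshots[[length(snapshots) + 1]] <- pos
        metrics[[length(metrics) + 1]] <- record(pos, s, energy)
      }
    }
    final <- model; final$xyz <- pos
    structure(list(snapshots = snapshots,
                   metrics = do.call(rbind, metrics),
                   final = final, model = model),
              class = "trajectory")
  }
  if (temperature > 0) with_seed_(seed, run()) else run()
}

#' Select the best model along a trajectory
#'
#' Returns the frame with the lowest chi-square against the profile
#' (recomputing the metric when the trajectory was run without one); ties
#' are broken by the earliest frame.
#'
#' @param traj a `trajectory` from [restrained_refine()].
#' @param profile a [scattering_profile()].
#' @return List with `model` ([atomic_model()]), `frame`, `chi2`.
#' @export
select_best_model <- function(traj, profile) {
  if (!length(traj$snapshots)) stop("empty trajectory")
  chi2 <- traj$metrics$chi2
  if (all(is.na(chi2))) {
    chi2 <- vapply(traj$snapshots, function(p) {
      m <- traj$model; m$xyz <- p
      fit_chi2(debye_profile(m, profile$q), profile)$chi2_reduced
    }, 0)
  }
  k <- which.min(chi2)  # which.min returns the earliest minimum
  m <- traj$model; m$xyz <- traj$snapshots[[k]]
  list(model = m, frame = k, chi2 = chi2[k])
}

#' Pearson correlation between a model and an envelope grid
#'
#' Voxelizes the model into the grid's own frame (same origin, spacing and
#' dimensions) and computes the Pearson correlation over the union support
#' of the two densities. A model that contributes no density inside the
#' grid returns 0.
#'
#' @param model an [atomic_model()] or [bead_model()].
#' @param grid reference [density_grid()].
#' @param blur_sigma Gaussian width for the model voxelization.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
envelope_correlation <- function(model, grid, blur_sigma = NULL) {
  if (grid$rho_max <= 0 || stats::sd(grid$rho) == 0) {
    stop("reference grid has zero variance")
  }
  calc <- voxelize(model, spacing = grid$spacing, blur_sigma = blur_sigma,
                   extent = list(origin = grid$origin, dim = dim(grid$rho)))
  a <- as.vector(grid$rho); b <- as.vector(calc$rho)
  if (max(b) == 0 || stats::sd(b) == 0) return(0)
  mask <- a > 1e-8 * max(a) | b > 1e-8 * max(b)
  if (sum(mask) < 3 || stats::sd(b[mask]) == 0) return(0)
  stats::cor(a[mask], b[mask])
}
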