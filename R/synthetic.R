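#' Specification of the antibody-like surrogate
#'
#' The surrogate is a ~150 kDa three-domain molecule: a central Fc stem and
#' two Fab arms, each modelled as an ellipsoidal cloud of uniform dummy
#' scatterers on a jittered lattice, joined to the stem by two flexible
#' hinges. At SAXS resolution (tens of Angstrom) this bead-level description
#' carries the same information as an atomistic model.
#'
#' @param beads_per_domain target bead count per domain.
#' @param domain_shape semi-axis lengths (Angstrom) of the ellipsoidal
#'   domains, longest first.
#' @param hinge_lengths hinge (pivot-to-domain) gap per arm, Angstrom.
#' @param hinge_angle_ranges list with `bend` and `twist` ranges (degrees)
#'   used as defaults for conformer sampling.
#' @param bead_scattering_length scattering length per bead (arbitrary).
#' @param seed integer RNG seed for the lattice jitter.
#' @return A `surrogate_spec` list.
#' @export
surrogate_spec <- function(beads_per_domain = 80,
                           domain_shape = c(30, 18, 14),
                           hinge_lengths = c(15, 15),
                           hinge_angle_ranges = list(bend = c(-35, 35),
                                                     twist = c(-60, 60)),
                           bead_scattering_length = 1,
                           seed = 1) {
  if (beads_per_domain < 1) stop("beads_per_domain must be >= 1")
  if (length(domain_shape) != 3 || any(domain_shape <= 0)) {
    stop("domain_shape must be three positive semi-axes")
  }
  if (any(hinge_lengths < 0)) stop("hinge_lengths must be >= 0")
  structure(list(beads_per_domain = beads_per_domain,
                 domain_shape = as.numeric(domain_shape),
                 hinge_lengths = rep_len(as.numeric(hinge_lengths), 2),
                 hinge_angle_ranges = hinge_angle_ranges,
                 bead_scattering_length = bead_scattering_length,
                 seed = as.integer(seed)),
            class = "surrogate_spec")
}

#' Noise model for simulated profiles
#'
#' Emulates photon-statistics errors on a reduced SAXS curve:
#' `sigma(q) = I(q) * (relative_error_floor + error_growth * q) /
#' sqrt(counts_scale)`, so the relative error grows linearly with q and
#' shrinks with counting statistics.
#'
#' @param relative_error_floor relative error at q = 0 (fraction).
#' @param error_growth linear growth of the relative error with q
#'   (fraction per 1/Angstrom).
#' @param counts_scale counting-statistics scale; `Inf` gives noiseless
#'   profiles with vanishing nominal sigma.
#' @param seed integer RNG seed for the Gaussian draw.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(relative_error_floor = 0.01, error_growth = 0.05,
                       counts_scale = 1, seed = 1) {
  if (relative_error_floor < 0 || error_growth < 0 || counts_scale <= 0) {
    stop("noise parameters must be >= 0 and counts_scale > 0")
  }
  structure(list(relative_error_floor = relative_error_floor,
                 error_growth = error_growth,
                 counts_scale = counts_scale,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

# Jittered-lattice bead fill of an ellipsoid centred at the origin with
# semi-axes `shape` and its long axis along z. Deterministic per seed.
ellipsoid_beads <- function(n, shape, seed, jitter_frac = 0.15) {
  vol <- 4 / 3 * pi * prod(shape)
  s <- (vol / n)^(1 / 3)                      # lattice spacing
  ax <- shape[2]; ay <- shape[3]; az <- shape[1]
  gx <- seq(-ax, ax, by = s); gy <- seq(-ay, ay, by = s)
  gz <- seq(-az, az, by = s)
  g <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  inside <- (g[, 1] / ax)^2 + (g[, 2] / ay)^2 + (g[, 3] / az)^2 <= 1
  pts <- g[inside, , drop = FALSE]
  pts <- with_seed_(seed, {
    pts + matrix(stats::runif(length(pts), -jitter_frac * s, jitter_frac * s),
                 ncol = 3)
  })
  list(xyz = pts, spacing = s)
}

#' Build the three-domain antibody surrogate
#'
#' Constructs a Y-shaped model: Fc stem below the origin, two Fab arms
#' splayed at +/-50 degrees from the vertical, each connected through a
#' hinge pivot at the top of the stem. The hinge pivots, bend axes
#' (out-of-plane) and arm axes are stored on the model so conformers can be
#' generated by rigid rotations about them. Deterministic for a fixed seed.
#'
#' @param spec a [surrogate_spec()].
#' @return An [atomic_model()] with domains `Fa`, `Fb`, `Fc` (chains A/B/C)
#'   and two hinge descriptors.
#' @export
build_antibody_surrogate <- function(spec = surrogate_spec()) {
  stopifnot(inherits(spec, "surrogate_spec"))
  shape <- spec$domain_shape
  a_long <- shape[1]
  splay <- deg2rad(50)
  dirs <- list(Fa = c(-sin(splay), 0, cos(splay)),
               Fb = c(sin(splay), 0, cos(splay)))
  pivots <- list(Fa = c(-4, 0, a_long), Fb = c(4, 0, a_long))

  fc <- ellipsoid_beads(spec$beads_per_domain, shape, spec$seed)
  parts <- list()
  parts$Fc <- sweep(fc$xyz, 2, c(0, 0, 0), "+")
  for (k in c("Fa", "Fb")) {
    arm <- ellipsoid_beads(spec$beads_per_domain, shape,
                           spec$seed + match(k, c("Fa", "Fb")))
    d <- dirs[[k]]
    # rotate local +z onto the arm direction
    axis <- c(-d[2], d[1], 0)
    if (sqrt(sum(axis^2)) < 1e-12) axis <- c(0, 1, 0)
    R <- rotation_about_axis(axis, acos(min(1, max(-1, d[3]))))
    hl <- spec$hinge_lengths[match(k, c("Fa", "Fb"))]
    centre <- pivots[[k]] + d * (hl + a_long)
    parts[[k]] <- sweep(arm$xyz %*% t(R), 2, centre, "+")
  }
  xyz <- rbind(parts$Fa, parts$Fb, parts$Fc)
  n_a <- nrow(parts$Fa); n_b <- nrow(parts$Fb); n_c <- nrow(parts$Fc)
  model <- atomic_model(
    xyz,
    f = spec$bead_scattering_length,
    chain = c(rep("A", n_a), rep("B", n_b), rep("C", n_c)),
    domain = c(rep("Fa", n_a), rep("Fb", n_b), rep("Fc", n_c)),
    bead_radius = fc$spacing / 2,
    hinges = list(
      Fa = list(pivot = pivots$Fa, axis_bend = c(0, 1, 0), axis_arm = dirs$Fa),
      Fb = list(pivot = pivots$Fb, axis_bend = c(0, 1, 0), axis_arm = dirs$Fb)
    )
  )
  if (min_interdomain_distance(model) <= 2 * model$bead_radius) {
    stop("surrogate geometry produced inter-domain clashes; ",
         "increase hinge_lengths or shrink domain_shape")
  }
  attr(model, "spec") <- spec
  model
}

# Apply (bend, twist) hinge rotations (degrees) to one arm of a model.
apply_hinge <- function(model, domain, bend, twist) {
  h <- model$hinges[[domain]]
  if (is.null(h)) stop("model has no hinge for domain ", domain)
  idx <- which(model$domain == domain)
  R <- rotation_about_axis(h$axis_bend, deg2rad(bend)) %*%
    rotation_about_axis(h$axis_arm, deg2rad(twist))
  rel <- sweep(model$xyz[idx, , drop = FALSE], 2, h$pivot)
  model$xyz[idx, ] <- sweep(rel %*% t(R), 2, h$pivot, "+")
  model
}

#' Sample hinge conformers of a surrogate
#'
#' Draws independent (bend, twist) hinge angles for each arm from the given
#' ranges, applies them as rigid rotations about the stored pivots, and
#' keeps only clash-free conformers (minimum inter-domain bead distance
#' greater than one bead diameter). Domains remain internally rigid.
#'
#' @param template an [atomic_model()] with hinge descriptors.
#' @param hinge_ranges list with `bend` and `twist` degree ranges; defaults
#'   to the ranges stored on the template's build spec.
#' @param n number of conformers to return.
#' @param seed integer RNG seed.
#' @param max_attempts clash-resampling budget as a multiple of `n`.
#' @return List of `n` [atomic_model()]s; sampled angles attached as the
#'   `hinge_angles` attribute of each.
#' @export
sample_conformers <- function(template, hinge_ranges = NULL, n = 100,
                              seed = 1, max_attempts = 20) {
  if (is.null(template$hinges)) stop("template has no hinge pivots")
  if (n < 1) stop("n must be >= 1")
  if (is.null(hinge_ranges)) {
    sp <- attr(template, "spec")
    hinge_ranges <- if (!is.null(sp)) sp$hinge_angle_ranges else
      list(bend = c(-35, 35), twist = c(-60, 60))
  }
  arms <- names(template$hinges)
  out <- vector("list", n)
  with_seed_(seed, {
    got <- 0L
    attempts <- 0L
    while (got < n) {
      if (attempts >= max_attempts * n) {
        stop("clash filtering exhausted the sampling budget (",
             attempts, " attempts for ", n, " conformers)")
      }
      attempts <- attempts + 1L
      ang <- lapply(arms, function(a) {
        c(bend = stats::runif(1, hinge_ranges$bend[1], hinge_ranges$bend[2]),
          twist = stats::runif(1, hinge_ranges$twist[1], hinge_ranges$twist[2]))
      })
      names(ang) <- arms
      cand <- template
      for (a in arms) cand <- apply_hinge(cand, a, ang[[a]]["bend"],
                                          ang[[a]]["twist"])
      if (min_interdomain_distance(cand) > 2 * template$bead_radius) {
        got <- got + 1L
        attr(cand, "hinge_angles") <- ang
        out[[got]] <- cand
      }
    }
  })
  out
}

#' Simulate a noisy scattering profile from a model
#'
#' Computes the Debye intensity of the model on `q_grid` and adds Gaussian
#' noise with the sigma(q) model of [noise_spec()]; the same sigma is stored
#' in the returned profile.
#'
#' @param model an [atomic_model()].
#' @param q_grid strictly increasing q values (> 0), 1/Angstrom.
#' @param noise a [noise_spec()].
#' @param metadata metadata list to attach to the profile.
#' @return A [scattering_profile()].
#' @export
simulate_profile <- function(model, q_grid, noise = noise_spec(),
                             metadata = list()) {
  stopifnot(inherits(noise, "noise_spec"))
  ideal <- debye_profile(model, q_grid)
  rel <- (noise$relative_error_floor + noise$error_growth * q_grid) /
    sqrt(noise$counts_scale)
  sigma <- abs(ideal$I) * rel
  if (all(sigma == 0)) {
    return(scattering_profile(q_grid, ideal$I,
                              pmax(sigma, 1e-12 * max(abs(ideal$I))),
                              metadata))
  }
  if (any(sigma <= 0)) sigma <- pmax(sigma, 1e-12 * max(abs(ideal$I)))
  Iobs <- with_seed_(noise$seed, ideal$I + stats::rnorm(length(sigma), 0, sigma))
  scattering_profile(q_grid, Iobs, sigma, metadata)
}

#' Simulate a temperature series with thermal unfolding
#'
#' Each profile is a population-weighted mixture of the folded template and
#' an expanded (unfolded) state obtained by isotropic scaling of the folded
#' coordinates about the centre of mass. The unfolded fraction follows a
#' logistic melt curve `w(T) = 1 / (1 + exp(-(T - midpoint)/width))`, so the
#' apparent size is stable far below the midpoint and rises through it.
#'
#' @param template folded [atomic_model()].
#' @param temperatures ascending temperatures (degrees C).
#' @param unfold_midpoint melt midpoint (degrees C).
#' @param expansion_factor linear expansion of the unfolded state (> 1).
#' @param noise a [noise_spec()].
#' @param seed integer seed; per-temperature noise seeds derive from it.
#' @param q_grid q values for all profiles.
#' @param unfold_width logistic width (degrees C).
#' @return List of [scattering_profile()]s with `temperature` and
#'   `unfolded_fraction` metadata.
#' @export
simulate_temperature_series <- function(template, temperatures,
                                        unfold_midpoint = 70,
                                        expansion_factor = 1.6,
                                        noise = noise_spec(), seed = 1,
                                        q_grid = seq(0.008, 0.35, length.out = 120),
                                        unfold_width = 2.5) {
  if (expansion_factor <= 1) stop("expansion_factor must exceed 1")
  if (is.unsorted(temperatures, strictly = FALSE)) {
    stop("temperatures must be sorted ascending")
  }
  com <- coords_com(template$xyz, template$f)
  expanded <- template
  expanded$xyz <- sweep(sweep(template$xyz, 2, com) * expansion_factor, 2,
                        com, "+")
  I_fold <- debye_profile(template, q_grid)$I
  I_exp <- debye_profile(expanded, q_grid)$I
  lapply(seq_along(temperatures), function(i) {
    Tc <- temperatures[i]
    w <- 1 / (1 + exp(-(Tc - unfold_midpoint) / unfold_width))
    ideal <- (1 - w) * I_fold + w * I_exp
    rel <- (noise$relative_error_floor + noise$error_growth * q_grid) /
      sqrt(noise$counts_scale)
    sigma <- pmax(abs(ideal) * rel, 1e-12 * max(abs(ideal)))
    Iobs <- with_seed_(seed + i, ideal + stats::rnorm(length(sigma), 0, sigma))
    scattering_profile(q_grid, Iobs, sigma,
                       metadata = list(temperature = Tc,
                                       unfolded_fraction = w))
  })
}

# Clash-free side-by-side dimer of a model (translation along x).
build_dimer <- function(model, gap = 2) {
  shift <- diff(range(model$xyz[, 1])) + 2 * model$bead_radius + gap
  second <- model$xyz
  second[, 1] <- second[, 1] + shift
  atomic_model(rbind(model$xyz, second),
               f = c(model$f, model$f),
               chain = c(model$chain, tolower(model$chain)),
               domain = c(paste0(model$domain, "_1"),
                          paste0(model$domain, "_2")),
               bead_radius = model$bead_radius)
}

#' Simulate a concentration series with self-association
#'
#' At each concentration `c` the intensity is the two-state mixture
#' `(1 - f) * I_monomer + f * I_dimer` with `f = dimer_fraction_fn(c)`; the
#' dimer is a clash-free side-by-side pair of the template. A monotonically
#' rising `f` produces the simultaneous growth of apparent Rg and Dmax seen
#' in aggregating concentration series; `f = 0` everywhere emulates a
#' non-aggregating (e.g. surfactant-protected) series.
#'
#' @param template monomer [atomic_model()].
#' @param concentrations positive concentrations (mg/ml).
#' @param dimer_fraction_fn function mapping concentration to a dimer
#'   fraction in `[0, 1]`.
#' @param noise a [noise_spec()].
#' @param seed integer seed; per-concentration noise seeds derive from it.
#' @param q_grid q values for all profiles.
#' @return List of [scattering_profile()]s with `concentration` and
#'   `dimer_fraction` metadata.
#' @export
simulate_concentration_series <- function(template, concentrations,
                                          dimer_fraction_fn = function(c) pmin(1, pmax(0, (c - 4) / 12)),
                                          noise = noise_spec(), seed = 1,
                                          q_grid = seq(0.008, 0.35, length.out = 120)) {
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  dimer <- build_dimer(template)
  I_mono <- debye_profile(template, q_grid)$I
  I_di <- debye_profile(dimer, q_grid)$I
  lapply(seq_along(concentrations), function(i) {
    cc <- concentrations[i]
    f <- dimer_fraction_fn(cc)
    if (!is.finite(f) || f < 0 || f > 1) {
      stop("dimer fraction outside [0, 1] at c = ", cc)
    }
    ideal <- (1 - f) * I_mono + f * I_di
    rel <- (noise$relative_error_floor + noise$error_growth * q_grid) /
      sqrt(noise$counts_scale)
    sigma <- pmax(abs(ideal) * rel, 1e-12 * max(abs(ideal)))
    Iobs <- with_seed_(seed + i, ideal + stats::rnorm(length(sigma), 0, sigma))
    scattering_profile(q_grid, Iobs, sigma,
                       metadata = list(concentration = cc, dimer_fraction = f))
  })
}
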