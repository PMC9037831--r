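#' Voxelized density grid
#'
#' @param origin grid origin (Angstrom, coordinates of the first voxel
#'   center).
#' @param spacing voxel edge length (Angstrom, > 0).
#' @param rho 3-D numeric array of non-negative densities.
#' @return A `density_grid` with cached `rho_max`.
#' @export
density_grid <- function(origin, spacing, rho) {
  if (spacing <= 0) stop("spacing must be > 0")
  if (any(rho < 0)) stop("densities must be >= 0")
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 rho = rho, rho_max = max(rho)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %s voxels, spacing %.2f A, rho_max %.4g\n",
              paste(dim(x$rho), collapse = "x"), x$spacing, x$rho_max))
  invisible(x)
}

#' Write / read a density grid as plain text
#'
#' Simple whitespace text serialization (header line with dims, origin and
#' spacing, then values in column-major order); round-trips exactly.
#'
#' @param grid a [density_grid()].
#' @param path file path.
#' @return `path` (write) or a [density_grid()] (read).
#' @export
write_density_grid <- function(grid, path) {
  hdr <- sprintf("# density_grid dims=%s origin=%s spacing=%.17g",
                 paste(dim(grid$rho), collapse = ","),
                 paste(format(grid$origin, digits = 17), collapse = ","),
                 grid$spacing)
  writeLines(c(hdr, format(as.vector(grid$rho), digits = 17)), path)
  invisible(path)
}

#' @rdname write_density_grid
#' @export
read_density_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[1]
  gv <- function(key) strsplit(sub(paste0(".*", key, "="), "", hdr), "[ ,]")[[1]]
  dims <- as.integer(gv("dims")[1:3])
  origin <- as.numeric(gv("origin")[1:3])
  spacing <- as.numeric(gv("spacing")[1])
  vals <- as.numeric(lines[-1])
  density_grid(origin, spacing, array(vals, dim = dims))
}

# Hexagonal-close-packed lattice points filling a sphere of radius R
# centred at the origin, with nearest-neighbour spacing a.
hcp_lattice <- function(R, a) {
  nmax <- ceiling(R / a) + 2
  k <- -nmax:nmax; j <- -nmax:nmax; i <- -nmax:nmax
  g <- expand.grid(i = i, j = j, k = k)
  x <- a * (g$i + ((g$j + g$k) %% 2) / 2)
  y <- a * sqrt(3) / 2 * (g$j + (g$k %% 2) / 3)
  z <- a * sqrt(6) / 3 * g$k
  pts <- cbind(x, y, z)
  pts[rowSums(pts^2) <= R^2, , drop = FALSE]
}

#' Dummy-atom bead model
#'
#' @param lattice M x 3 matrix of search-lattice sites.
#' @param occupied logical M-vector of occupancy flags.
#' @param bead_radius bead radius (Angstrom).
#' @return A `bead_model`; `centers` gives the occupied coordinates.
#' @export
bead_model <- function(lattice, occupied, bead_radius) {
  structure(list(lattice = lattice, occupied = occupied,
                 centers = lattice[occupied, , drop = FALSE],
                 bead_radius = bead_radius),
            class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("<bead_model> %d/%d beads, radius %.2f A\n",
              sum(x$occupied), length(x$occupied), x$bead_radius))
  invisible(x)
}

# Point-set coordinates of any supported model type.
model_points <- function(x) {
  if (is.matrix(x)) return(x)
  if (inherits(x, "bead_model")) return(x$centers)
  if (inherits(x, "atomic_model")) return(x$xyz)
  stop("unsupported model type")
}

# Squared-distance matrix between two point sets (rows).
cross_dist2 <- function(A, B) {
  out <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  pmax(out, 0)
}

#' Normalized spatial discrepancy between two point sets
#'
#' `NSD^2 = 0.5 * [ mean_i min_j |a_i - b_j|^2 / d_B^2 +
#' mean_j min_i |b_j - a_i|^2 / d_A^2 ]` where `d_X` is the mean
#' nearest-neighbour distance within set X. Zero for identical sets;
#' values below ~0.7 conventionally indicate similar shapes.
#'
#' @param A,B models or N x 3 coordinate matrices (N >= 2 each).
#' @return Dimensionless NSD.
#' @export
nsd <- function(A, B) {
  A <- model_points(A); B <- model_points(B)
  if (nrow(A) < 2 || nrow(B) < 2) {
    stop("NSD needs at least two points per set (nearest-neighbour scale)")
  }
  nn_scale <- function(X) {
    d2 <- cross_dist2(X, X)
    diag(d2) <- Inf
    mean(sqrt(apply(d2, 1, min)))
  }
  dA <- nn_scale(A); dB <- nn_scale(B)
  d2 <- cross_dist2(A, B)
  term_a <- mean(apply(d2, 1, min)) / dB^2
  term_b <- mean(apply(d2, 2, min)) / dA^2
  sqrt(0.5 * (term_a + term_b))
}

# Kabsch rotation matrix superposing P onto Q (both centred), proper.
kabsch_rotation <- function(P, Q) {
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
}

#' Align one point-set model onto a reference
#'
#' Minimizes NSD over rigid motions: centre-of-mass translation, then a
#' principal-axes initialization tried over all four proper axis flips and
#' the enantiomeric inversion, each refined by iterative-closest-point
#' steps (nearest-neighbour correspondences + Kabsch rotation).
#'
#' @param mobile,reference models or coordinate matrices.
#' @param refine_iters ICP refinement iterations per branch.
#' @return List with `points` (transformed mobile coordinates), `nsd`,
#'   `inverted` (enantiomer flag).
#' @export
align_models <- function(mobile, reference, refine_iters = 12) {
  M0 <- model_points(mobile); Rf <- model_points(reference)
  cm <- colMeans(M0); cr <- colMeans(Rf)
  M <- sweep(M0, 2, cm); Q <- sweep(Rf, 2, cr)
  paxes <- function(X) {
    e <- eigen(stats::cov(X), symmetric = TRUE)
    V <- e$vectors
    if (det(V) < 0) V[, 3] <- -V[, 3]
    V
  }
  Vq <- paxes(Q)
  best <- NULL
  for (inv in c(1, -1)) {
    Mi <- M * inv
    Vm <- paxes(Mi)
    for (flip in list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))) {
      R <- Vq %*% diag(flip) %*% t(Vm)
      X <- Mi %*% t(R)
      for (it in seq_len(refine_iters)) {
        d2 <- cross_dist2(X, Q)
        nn <- apply(d2, 1, which.min)
        Rl <- kabsch_rotation(X, Q[nn, , drop = FALSE])
        Xn <- X %*% t(Rl)
        if (max(abs(Xn - X)) < 1e-9) { X <- Xn; break }
        X <- Xn
      }
      val <- nsd(X, Q)
      if (is.null(best) || val < best$nsd) {
        best <- list(points = X, nsd = val, inverted = inv < 0)
      }
    }
  }
  best$points <- sweep(best$points, 2, cr, "+")
  best
}

#' Cluster envelope models by pairwise aligned NSD
#'
#' Computes the pairwise NSD matrix after rigid alignment of each pair,
#' applies average-linkage hierarchical clustering cut at
#' `linkage_threshold`, and reports singleton clusters as isolated models.
#' Each multi-member cluster is averaged with [average_envelopes()] after
#' aligning members onto the cluster member with the lowest mean NSD.
#'
#' @param models list of `bead_model`s (or coordinate matrices), length >= 2.
#' @param linkage_threshold dendrogram cut height (NSD units).
#' @return List with `nsd_matrix`, `assignments`, `isolated`, `clusters`
#'   (member index lists, largest first) and `averages` (one averaged
#'   model per multi-member cluster, or NULL when averaging is impossible).
#' @export
cluster_envelopes <- function(models, linkage_threshold = 0.7) {
  k <- length(models)
  if (k < 2) stop("need at least two models to cluster")
  D <- matrix(0, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      D[i, j] <- D[j, i] <- align_models(models[[i]], models[[j]])$nsd
    }
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  assign <- stats::cutree(hc, h = linkage_threshold)
  sizes <- table(assign)
  isolated <- which(assign %in% as.integer(names(sizes)[sizes == 1]))
  cl_ids <- as.integer(names(sort(sizes[sizes > 1], decreasing = TRUE)))
  clusters <- lapply(cl_ids, function(id) which(assign == id))
  averages <- lapply(clusters, function(members) {
    mean_nsd <- vapply(members, function(i) mean(D[i, setdiff(members, i)]), 0)
    ref <- members[which.min(mean_nsd)]
    aligned <- lapply(members, function(i) {
      if (i == ref) models[[i]] else {
        al <- align_models(models[[i]], models[[ref]])
        m <- models[[i]]
        if (inherits(m, "bead_model")) {
          bead_model(al$points, rep(TRUE, nrow(al$points)), m$bead_radius)
        } else al$points
      }
    })
    tryCatch(average_envelopes(aligned, reference = match(ref, members)),
             error = function(e) NULL)
  })
  list(nsd_matrix = D, assignments = assign, isolated = isolated,
       clusters = clusters, averages = averages, hclust = hc)
}

#' Average aligned envelope models
#'
#' Maps every member onto the reference member's lattice (a site counts as
#' occupied in a member when a member bead lies within one bead radius of
#' it), computes per-site occupancy frequencies, and keeps sites with
#' frequency at or above `threshold`.
#'
#' @param members list of aligned `bead_model`s or coordinate matrices.
#' @param reference index of the member whose lattice is used.
#' @param threshold occupancy-frequency cut (default 0.5).
#' @return List with `model` (averaged [bead_model()]), `frequency`
#'   (per-site occupancy) and `grid` (voxelized average, from
#'   [voxelize()]).
#' @export
average_envelopes <- function(members, reference = 1, threshold = 0.5) {
  if (!length(members)) stop("no members to average")
  refm <- members[[reference]]
  if (inherits(refm, "bead_model")) {
    sites <- refm$lattice
    radius <- refm$bead_radius
  } else {
    sites <- model_points(refm)
    nn2 <- cross_dist2(sites, sites); diag(nn2) <- Inf
    radius <- mean(sqrt(apply(nn2, 1, min))) / 2
  }
  freq <- rep(0, nrow(sites))
  for (m in members) {
    pts <- model_points(m)
    d2 <- cross_dist2(sites, pts)
    freq <- freq + (sqrt(apply(d2, 1, min)) <= radius * 1.001)
  }
  freq <- freq / length(members)
  occ <- freq >= threshold
  if (!any(occ)) stop("empty average: no lattice site reaches frequency ",
                      threshold)
  avg <- bead_model(sites, occ, radius)
  list(model = avg, frequency = freq,
       grid = voxelize(avg, spacing = radius, blur_sigma = 2 * radius))
}

#' Deposit a model onto a voxel grid
#'
#' Adds a mass-normalized Gaussian kernel of width `blur_sigma` at every
#' bead/atom centre onto a grid padded by `3 * blur_sigma`; `blur_sigma =
#' 0` deposits each centre into its nearest voxel. Each centre carries
#' unit mass, so `sum(rho) * spacing^3` approximates the number of
#' centres and widening the blur lowers peaks without changing the total.
#'
#' @param model a [bead_model()], [atomic_model()] or coordinate matrix.
#' @param spacing voxel edge (Angstrom).
#' @param blur_sigma Gaussian width (Angstrom, >= 0); default twice the
#'   bead radius (or `spacing` for bare matrices).
#' @param extent optional list(`origin`, `dim`) forcing the grid frame
#'   (used to voxelize trajectories into a fixed reference frame).
#' @return A [density_grid()].
#' @export
voxelize <- function(model, spacing = 3, blur_sigma = NULL, extent = NULL) {
  pts <- model_points(model)
  if (is.null(blur_sigma)) {
    blur_sigma <- if (!is.matrix(model) && !is.null(model$bead_radius)) {
      2 * model$bead_radius
    } else spacing
  }
  if (spacing <= 0) stop("spacing must be > 0")
  if (blur_sigma < 0) stop("blur_sigma must be >= 0")
  pad <- 3 * blur_sigma + spacing
  if (is.null(extent)) {
    lo <- apply(pts, 2, min) - pad
    hi <- apply(pts, 2, max) + pad
    dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
    origin <- lo
  } else {
    origin <- extent$origin
    dims <- extent$dim
  }
  rho <- array(0, dim = dims)
  if (blur_sigma == 0) {
    for (p in seq_len(nrow(pts))) {
      ctr <- round((pts[p, ] - origin) / spacing) + 1
      if (any(ctr < 1) || any(ctr > dims)) next
      rho[ctr[1], ctr[2], ctr[3]] <- rho[ctr[1], ctr[2], ctr[3]] +
        1 / spacing^3
    }
  } else {
    reach <- ceiling(3 * blur_sigma / spacing)
    knorm <- (2 * pi * blur_sigma^2)^(3 / 2)
    ax <- lapply(1:3, function(k) origin[k] + spacing * (seq_len(dims[k]) - 1))
    for (p in seq_len(nrow(pts))) {
      ctr <- round((pts[p, ] - origin) / spacing) + 1
      lo <- pmax(1, ctr - reach)
      hi <- pmin(dims, ctr + reach)
      if (any(lo > hi)) next                # centre far outside this frame
      rng <- lapply(1:3, function(k) lo[k]:hi[k])
      gx <- exp(-(ax[[1]][rng[[1]]] - pts[p, 1])^2 / (2 * blur_sigma^2))
      gy <- exp(-(ax[[2]][rng[[2]]] - pts[p, 2])^2 / (2 * blur_sigma^2))
      gz <- exp(-(ax[[3]][rng[[3]]] - pts[p, 3])^2 / (2 * blur_sigma^2))
      rho[rng[[1]], rng[[2]], rng[[3]]] <-
        rho[rng[[1]], rng[[2]], rng[[3]]] + outer(outer(gx, gy), gz) / knorm
    }
  }
  density_grid(origin, spacing, rho)
}

# Target intensity and sigma for envelope fitting from either a
# pair_distribution (P(r)-smoothed intensity, the default route) or a
# raw profile.
envelope_target <- function(target, q_grid) {
  if (inherits(target, "pair_distribution")) {
    q <- q_grid %||% seq(0.01, 0.25, length.out = 40)
    md <- moore_design(q, target$r, target$n_basis, target$Dmax)
    I <- as.numeric(md$design %*% target$coefficients)
    list(q = q, I = I, sigma = pmax(0.01 * abs(I), 1e-12 * max(abs(I))),
         dmax = target$Dmax)
  } else {
    stopifnot_profile(target)
    q <- target$q; I <- target$I
    keep <- if (is.null(q_grid)) rep(TRUE, length(q)) else
      q >= min(q_grid) & q <= max(q_grid)
    s <- target$sigma %||% (0.01 * abs(I))
    list(q = q[keep], I = I[keep], sigma = s[keep], dmax = NULL)
  }
}

#' Ab initio envelope reconstruction by simulated annealing
#'
#' Dummy-atom modelling: bead occupancy flips on a hexagonal-close-packed
#' lattice inside the Dmax search sphere are annealed against the target
#' intensity. The objective is the reduced chi-square of the bead-model
#' Debye curve (scale fitted) plus a looseness penalty
#' `lambda_p * mean fraction of empty neighbour sites`; connectivity of the
#' occupied set is maintained as a hard constraint (growth moves attach to
#' the surface, removal moves that would disconnect the model are
#' rejected), so the final model is always one connected component. The
#' fit is restricted to `q <= pi / (4 * lattice spacing)` -- beyond that
#' the lattice granularity dominates the residuals and the chi-square
#' ranking no longer reflects shape agreement. Deterministic per seed.
#'
#' @param target a `pair_distribution` (preferred: its smoothed intensity
#'   is fitted, mirroring standard dummy-atom practice) or a
#'   [scattering_profile()].
#' @param dmax search-sphere diameter; defaults to the target's Dmax.
#' @param bead_radius lattice bead radius; default `dmax / 24`.
#' @param lambda_p looseness penalty weight.
#' @param schedule list with `t0` (initial temperature; NULL = auto),
#'   `cool` (< 1), `n_temps`, `moves_per_temp` (NULL = lattice size),
#'   `patience` (temperature levels without improvement before stopping).
#' @param q_grid q values used when the target is a pair distribution.
#' @param seed integer RNG seed.
#' @return A [bead_model()] with attributes `objective_trace` (best-so-far
#'   objective per temperature level), `chi2_reduced` and `warning_flag`.
#' @export
anneal_envelope <- function(target, dmax = NULL, bead_radius = NULL,
                            lambda_p = 2, schedule = list(), seed = 1,
                            q_grid = NULL) {
  tg <- envelope_target(target, q_grid)
  dmax <- dmax %||% tg$dmax
  if (is.null(dmax)) stop("dmax must be given when the target is a profile")
  bead_radius <- bead_radius %||% (dmax / 24)
  a <- 2 * bead_radius
  sched <- utils::modifyList(
    list(t0 = NULL, cool = 0.8, n_temps = 28, moves_per_temp = NULL,
         patience = Inf), schedule)
  if (sched$cool >= 1 || sched$cool <= 0) stop("cooling factor must be in (0,1)")
  sites <- hcp_lattice(dmax / 2, a)
  ns <- nrow(sites)
  qmax_fit <- pi / (4 * a)
  keepq <- tg$q <= qmax_fit
  if (sum(keepq) < 5) keepq <- seq_along(tg$q) <= max(5, length(tg$q))
  q <- tg$q[keepq]; Iobs <- tg$I[keepq]; sig <- tg$sigma[keepq]
  wfit <- 1 / sig^2
  nq <- length(q)

  # neighbour lists (sites within 1.05 * a)
  d2 <- cross_dist2(sites, sites)
  nbr <- apply(d2 <= (1.05 * a)^2, 1, which, simplify = FALSE)
  nbr <- lapply(seq_len(ns), function(i) setdiff(nbr[[i]], i))
  nnbr <- lengths(nbr)

  with_seed_(seed, {
    # initial blob: connected compact seed around the centre
    occ <- rowSums(sites^2) <= (dmax / 5)^2
    if (sum(occ) < 5) occ <- rank(rowSums(sites^2)) <= 15
    occ_idx <- which(occ)
    # raw Debye amplitude of the occupied set per q (self terms included)
    pts <- sites[occ_idx, , drop = FALSE]
    dv <- as.vector(stats::dist(pts))
    Aq <- vapply(q, function(qq) length(occ_idx) + 2 * sum(sinc(qq * dv)), 0)
    occ_nbr <- vapply(seq_len(ns), function(i) sum(occ[nbr[[i]]]), 0L)

    chi2_of <- function(Aq, nb) {
      cs <- sum(wfit * Iobs * Aq) / sum(wfit * Aq^2)
      sum(wfit * (Iobs - cs * Aq)^2) / max(1, nq - 1)
    }
    loose_of <- function() {
      oi <- which(occ)
      mean(1 - occ_nbr[oi] / pmax(nnbr[oi], 1))
    }
    objective <- function(Aq) chi2_of(Aq) + lambda_p * loose_of()

    # local connectivity check: would removing site k disconnect its
    # occupied neighbours? BFS from one neighbour with early stop.
    stays_connected <- function(k) {
      nb <- nbr[[k]][occ[nbr[[k]]]]
      if (length(nb) <= 1) return(sum(occ) > 1)  # leaf bead: safe
      target_set <- nb[-1]
      seen <- rep(FALSE, ns); seen[k] <- TRUE  # k removed
      queue <- nb[1]; seen[nb[1]] <- TRUE
      found <- rep(FALSE, length(target_set))
      while (length(queue)) {
        cur <- queue[1]; queue <- queue[-1]
        hits <- match(cur, target_set)
        if (!is.na(hits)) {
          found[hits] <- TRUE
          if (all(found)) return(TRUE)
        }
        nxt <- nbr[[cur]]
        nxt <- nxt[occ[nxt] & !seen[nxt]]
        if (length(nxt)) { seen[nxt] <- TRUE; queue <- c(queue, nxt) }
      }
      FALSE
    }

    delta_A <- function(k) {
      oi <- which(occ); oi <- oi[oi != k]
      if (!length(oi)) return(rep(1, nq))
      dk <- sqrt(rowSums(sweep(sites[oi, , drop = FALSE], 2, sites[k, ])^2))
      vapply(q, function(qq) 1 + 2 * sum(sinc(qq * dk)), 0)
    }

    cur_obj <- objective(Aq)
    best <- list(occ = occ, obj = cur_obj, Aq = Aq)
    trace <- numeric(0)
    Tcur <- sched$t0 %||% max(cur_obj * 0.05, 1)
    moves <- sched$moves_per_temp %||% max(600L, 2L * sum(occ))
    warn_flag <- FALSE
    stall <- 0L
    for (lev in seq_len(sched$n_temps)) {
      for (mv in seq_len(moves)) {
        grow <- stats::runif(1) < 0.5
        if (grow) {
          # candidate: empty neighbour of a random occupied bead
          ob <- which(occ)
          src <- ob[sample.int(length(ob), 1)]
          cand <- nbr[[src]][!occ[nbr[[src]]]]
          if (!length(cand)) next
          k <- cand[sample.int(length(cand), 1)]
          dA <- delta_A(k)
          Anew <- Aq + dA
          occ[k] <- TRUE; occ_nbr[nbr[[k]]] <- occ_nbr[nbr[[k]]] + 1L
          new_obj <- objective(Anew)
          if (new_obj <= cur_obj ||
              stats::runif(1) < exp(-(new_obj - cur_obj) / Tcur)) {
            Aq <- Anew; cur_obj <- new_obj
          } else {
            occ[k] <- FALSE; occ_nbr[nbr[[k]]] <- occ_nbr[nbr[[k]]] - 1L
          }
        } else {
          ob <- which(occ)
          if (length(ob) <= 5) next
          k <- ob[sample.int(length(ob), 1)]
          if (!stays_connected(k)) next
          dA <- delta_A(k)
          Anew <- Aq - dA
          occ[k] <- FALSE; occ_nbr[nbr[[k]]] <- occ_nbr[nbr[[k]]] - 1L
          new_obj <- objective(Anew)
          if (new_obj <= cur_obj ||
              stats::runif(1) < exp(-(new_obj - cur_obj) / Tcur)) {
            Aq <- Anew; cur_obj <- new_obj
          } else {
            occ[k] <- TRUE; occ_nbr[nbr[[k]]] <- occ_nbr[nbr[[k]]] + 1L
          }
        }
        if (cur_obj < best$obj) {
          best <- list(occ = occ, obj = cur_obj, Aq = Aq)
          stall <- 0L
        }
      }
      trace <- c(trace, best$obj)
      stall <- stall + 1L
      if (stall > sched$patience) { warn_flag <- TRUE; break }
      Tcur <- Tcur * sched$cool
    }
    out <- bead_model(sites, best$occ, bead_radius)
    attr(out, "objective_trace") <- trace
    attr(out, "chi2_reduced") <- chi2_of(best$Aq)
    attr(out, "warning_flag") <- warn_flag
    if (warn_flag && stall > sched$patience) {
      # patience exhaustion after convergence is the normal stop; only
      # flag when the anneal never improved at all
      attr(out, "warning_flag") <- length(unique(trace)) == 1
    }
    out
  })
}
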