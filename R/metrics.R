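#' Assign Fa/Fb/Fc domain labels
#'
#' Relabels a three-domain model using the arm-distance convention: the
#' Fab arm whose centre of mass lies farther from the Fc centre of mass
#' becomes `Fa`, the closer arm `Fb`. Near-equidistant arms (within
#' `tie_tol`) are disambiguated by chain-identifier order, with a message.
#'
#' @param model an [atomic_model()].
#' @param config list with `fc` (chain or domain label of the stem) and
#'   `arms` (labels of the two arms); defaults to domains `Fc` and
#'   `Fa`/`Fb` as built by [build_antibody_surrogate()].
#' @param tie_tol distance tie tolerance (Angstrom).
#' @return The model with reassigned `domain` labels; the mapping is in
#'   the `domain_map` attribute.
#' @export
assign_domains <- function(model, config = NULL, tie_tol = 1e-6) {
  config <- config %||% list(fc = "Fc", arms = setdiff(unique(model$domain),
                                                       "Fc"))
  if (length(config$arms) != 2) stop("exactly two arm labels required")
  lab <- model$domain
  if (!all(c(config$fc, config$arms) %in% lab)) {
    stop("config selectors do not cover the model's domains")
  }
  com <- function(sel) coords_com(model$xyz[lab == sel, , drop = FALSE],
                                  model$f[lab == sel])
  fc_com <- com(config$fc)
  d <- vapply(config$arms, function(a) sqrt(sum((com(a) - fc_com)^2)), 0)
  arms <- config$arms
  if (abs(d[1] - d[2]) < tie_tol) {
    chains <- vapply(arms, function(a) model$chain[lab == a][1], "")
    ord <- order(chains)
    message("arms equidistant from Fc; tie broken by chain order (",
            paste(chains[ord], collapse = " < "), ")")
    arms <- arms[ord]
  } else {
    arms <- arms[order(-d)]           # farther arm first -> Fa
  }
  map <- c("Fa", "Fb", "Fc")
  names(map) <- c(arms, config$fc)
  new_lab <- unname(map[lab])
  model$domain <- new_lab
  attr(model, "domain_map") <- map
  model
}

# Golden-spiral unit sphere points (near-uniform).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe of radius `probe_radius` over the atom set: each atom's
#' expanded sphere (`r_atom + probe`) is sampled with `n_points`
#' golden-spiral points and the accessible fraction (points not buried in
#' any neighbour's expanded sphere) scaled by the sphere area.
#'
#' @param xyz N x 3 coordinates.
#' @param radii per-atom radii (Angstrom); recycled.
#' @param probe_radius probe radius (default 1.4, water).
#' @param n_points test points per atom (default 960).
#' @return Per-atom SASA vector (Angstrom^2); `sum()` gives the total.
#' @export
sasa_shrake_rupley <- function(xyz, radii = 1.8, probe_radius = 1.4,
                               n_points = 960) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  radii <- rep_len(radii, n)
  rexp <- radii + probe_radius
  pts <- sphere_points(n_points)
  d2 <- cross_dist2(xyz, xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rexp[i] + rexp)^2 & seq_len(n) != i)
    surf <- sweep(pts * rexp[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      buried <- rep(FALSE, n_points)
      for (j in nb) {
        buried <- buried |
          rowSums(sweep(surf, 2, xyz[j, ])^2) < rexp[j]^2
        if (all(buried)) break
      }
      acc <- sum(!buried)
    } else {
      acc <- n_points
    }
    out[i] <- 4 * pi * rexp[i]^2 * acc / n_points
  }
  out
}

# Principal axes of the (optionally mass-weighted) gyration tensor.
gyration_axes <- function(xyz, w = NULL) {
  if (is.null(w)) w <- rep(1, nrow(xyz))
  com <- coords_com(xyz, w)
  X <- sweep(xyz, 2, com)
  S <- crossprod(X * w, X) / sum(w)
  eigen(S, symmetric = TRUE)
}

#' Geometric descriptors of a multi-domain model
#'
#' Mass-weighted centres of mass (whole and per domain), pairwise
#' inter-domain COM distances, the angles the domain COMs subtend at the
#' whole-molecule COM, the acute angles between domain inertia planes
#' (each plane spanned by the two largest-variance principal axes of the
#' domain gyration tensor), per-domain Rg, and per-domain SASA
#' (Shrake-Rupley on the domain's own atoms).
#'
#' @param model an [atomic_model()] (with domain labels).
#' @param partition optional per-atom labels overriding `model$domain`.
#' @param probe_radius SASA probe radius (Angstrom).
#' @param mass_weighted use scattering lengths as weights for COM/tensors.
#' @param sasa compute per-domain SASA (the expensive part).
#' @return A `geometry_features` list: `com_whole`, `com` (per domain),
#'   `distances`, `angles_at_center`, `plane_angles`, `rg`, `sasa`.
#' @export
geometry_features <- function(model, partition = NULL, probe_radius = 1.4,
                              mass_weighted = TRUE, sasa = TRUE) {
  lab <- partition %||% model$domain
  doms <- sort(unique(lab))
  w <- if (mass_weighted) model$f else rep(1, nrow(model$xyz))
  com_whole <- coords_com(model$xyz, w)
  coms <- lapply(doms, function(d) {
    coords_com(model$xyz[lab == d, , drop = FALSE], w[lab == d])
  })
  names(coms) <- doms
  pairs <- utils::combn(doms, 2, simplify = FALSE)
  distances <- vapply(pairs, function(p) {
    sqrt(sum((coms[[p[1]]] - coms[[p[2]]])^2))
  }, 0)
  names(distances) <- vapply(pairs, paste, "", collapse = "-")
  angle_between <- function(u, v) {
    cu <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    rad2deg(acos(min(1, max(-1, cu))))
  }
  angles <- vapply(pairs, function(p) {
    angle_between(coms[[p[1]]] - com_whole, coms[[p[2]]] - com_whole)
  }, 0)
  names(angles) <- names(distances)
  planes <- lapply(doms, function(d) {
    X <- model$xyz[lab == d, , drop = FALSE]
    if (nrow(X) < 3) return(NULL)
    ev <- gyration_axes(X, w[lab == d])
    ev$vectors[, 3]                    # normal = smallest-variance axis
  })
  names(planes) <- doms
  plane_angles <- vapply(pairs, function(p) {
    n1 <- planes[[p[1]]]; n2 <- planes[[p[2]]]
    if (is.null(n1) || is.null(n2)) return(NA_real_)
    ang <- angle_between(n1, n2)
    min(ang, 180 - ang)                # acute angle between planes
  }, 0)
  names(plane_angles) <- names(distances)
  rg <- vapply(doms, function(d) {
    coords_rg(model$xyz[lab == d, , drop = FALSE], w[lab == d])
  }, 0)
  names(rg) <- doms
  sasa_v <- if (sasa) {
    sv <- vapply(doms, function(d) {
      idx <- lab == d
      sum(sasa_shrake_rupley(model$xyz[idx, , drop = FALSE],
                             radii = model$bead_radius %||% 1.8,
                             probe_radius = probe_radius))
    }, 0)
    names(sv) <- doms
    sv
  } else NULL
  structure(list(com_whole = com_whole, com = coms, distances = distances,
                 angles_at_center = angles, plane_angles = plane_angles,
                 rg = rg, sasa = sasa_v),
            class = "geometry_features")
}

#' Optimal rigid superposition and RMSD (Kabsch)
#'
#' Superposes `A` onto `B` over the given correspondence with the Kabsch
#' algorithm (proper rotation enforced) and reports the post-fit RMSD.
#' Collinear/degenerate point sets yield a non-unique rotation and a
#' warning.
#'
#' @param A,B N x 3 coordinate matrices.
#' @param correspondence integer matrix/data frame with columns (index in
#'   A, index in B); default pairs rows in order.
#' @return List with `rmsd` (Angstrom), `rotation` (3 x 3, applied to
#'   centred A), `translation`, `transformed` (all of A, superposed).
#' @export
superpose_rmsd <- function(A, B, correspondence = NULL) {
  A <- as.matrix(A); B <- as.matrix(B)
  corr <- correspondence %||% cbind(seq_len(min(nrow(A), nrow(B))),
                                    seq_len(min(nrow(A), nrow(B))))
  corr <- as.matrix(corr)
  if (nrow(corr) < 3) stop("need >= 3 corresponding points")
  P <- A[corr[, 1], , drop = FALSE]
  Q <- B[corr[, 2], , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv <- svd(t(Pc) %*% Qc)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1)) {
    warning("degenerate (collinear) point set: rotation not unique")
  }
  R <- kabsch_rotation(Pc, Qc)
  fitted <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  transformed <- sweep(sweep(A, 2, cp) %*% t(R), 2, cq, "+")
  list(rmsd = rmsd, rotation = R, translation = cq - cp %*% t(R),
       transformed = transformed)
}

# Rotation axis (unit) and angle (radians, in (0, pi]) of a rotation
# matrix; axis oriented so the angle is positive.
rotation_axis_angle <- function(R) {
  ang <- acos(min(1, max(-1, (sum(diag(R)) - 1) / 2)))
  if (ang < 1e-8) stop("near-identity rotation: axis ill-defined")
  if (abs(ang - pi) < 1e-6) {
    # 180 degrees: axis from the symmetric part, sign fixed by convention
    M <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(M), 0))
    k <- which.max(ax)
    if (ax[k] > 0) {
      ax[-k] <- M[k, -k] / ax[k]
    }
    u <- ax / sqrt(sum(ax^2))
    if (u[which.max(abs(u))] < 0) u <- -u
  } else {
    u <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
      (2 * sin(ang))
  }
  list(axis = u, angle = ang)
}

#' Fab elbow angle
#'
#' The angle between the pseudo-two-fold axes of the variable and constant
#' modules of a Fab. Each axis is the rotation axis of the Kabsch
#' superposition of the light-chain half onto the heavy-chain half
#' (VL onto VH for the variable module, CL onto CH1 for the constant
#' module). The reported elbow is `180 - theta` (theta = angle between
#' the two axes), pushed into the reflex range `(180, 270)` when the
#' triple product `(u_V x u_C) . (COM_C - COM_V)` is negative, matching
#' the convention in which parallel dyads give a fully extended 180
#' degree elbow.
#'
#' @param fab an [atomic_model()] or N x 3 coordinate matrix.
#' @param selectors list of integer index vectors `VL`, `VH`, `CL`, `CH1`
#'   into the Fab's atoms.
#' @param correspondence list with `V` (VL->VH index pairs) and `C`
#'   (CL->CH1 index pairs) relative to the selector vectors; default
#'   pairs them in order (selectors must then have equal lengths).
#' @return Elbow angle in degrees; dyad axes in the `axes` attribute.
#' @export
elbow_angle <- function(fab, selectors, correspondence = NULL) {
  xyz <- model_points(fab)
  need <- c("VL", "VH", "CL", "CH1")
  if (!all(need %in% names(selectors))) {
    stop("selectors must name VL, VH, CL and CH1")
  }
  dyad <- function(from, to, pairs) {
    P <- xyz[from, , drop = FALSE]; Q <- xyz[to, , drop = FALSE]
    if (is.null(pairs)) {
      if (nrow(P) != nrow(Q)) stop("selector lengths differ; supply a correspondence")
      pairs <- cbind(seq_len(nrow(P)), seq_len(nrow(Q)))
    }
    sp <- superpose_rmsd(P, Q, pairs)
    aa <- tryCatch(rotation_axis_angle(sp$rotation), error = function(e) {
      stop("pseudo-dyad ill-defined: superposition rotation below 5 degrees")
    })
    if (rad2deg(aa$angle) < 5) {
      stop("pseudo-dyad ill-defined: superposition rotation below 5 degrees")
    }
    aa$axis
  }
  uV <- dyad(selectors$VL, selectors$VH, correspondence$V)
  uC <- dyad(selectors$CL, selectors$CH1, correspondence$C)
  ct <- min(1, max(-1, sum(uV * uC)))
  theta <- rad2deg(acos(ct))
  elbow <- 180 - theta
  comV <- colMeans(xyz[c(selectors$VL, selectors$VH), , drop = FALSE])
  comC <- colMeans(xyz[c(selectors$CL, selectors$CH1), , drop = FALSE])
  tp <- sum((cross3(uV, uC)) * (comC - comV))
  if (theta > 1e-6 && tp < 0) elbow <- 360 - elbow
  structure(elbow, axes = list(V = uV, C = uC))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
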