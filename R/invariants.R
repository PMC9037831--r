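#' Guinier analysis of a scattering profile
#'
#' Weighted linear fit of `ln I` versus `q^2` on the widest low-q window
#' satisfying `q * Rg <= qRg_limit`, iterated to self-consistency from an
#' initial window of `min_points` points. `Rg = sqrt(-3 * slope)`,
#' `I0 = exp(intercept)`. An optional guard advances the window start past
#' a low-q upturn (aggregation signature) detected as a run of strongly
#' positive leading residuals.
#'
#' @param profile a [scattering_profile()] with `I > 0` at low q.
#' @param qRg_limit upper validity limit of the Guinier regime
#'   (default 1.3, the conventional globular-particle bound).
#' @param min_points minimum number of points in the fit window; takes
#'   precedence over `qRg_limit` on coarse q grids (the reported
#'   `qmax_Rg` then exceeds the limit).
#' @param guard_upturn drop leading points showing a systematic positive
#'   residual run (> 2 sigma) before fitting.
#' @param refine_curvature shrink the window while a weighted `q^4` term
#'   is statistically significant (|t| > 3); removes the systematic Rg
#'   overestimate that the full `qRg <= 1.3` window produces on sharply
#'   curved (e.g. globular) profiles while leaving noisy windows intact.
#' @return List with `Rg`, `I0`, `Rg_se`, `window` (index range),
#'   `qmin_Rg`, `qmax_Rg`, `n_iter`.
#' @export
guinier_fit <- function(profile, qRg_limit = 1.3, min_points = 10,
                        guard_upturn = TRUE, refine_curvature = TRUE) {
  stopifnot_profile(profile)
  q <- profile$q; I <- profile$I
  s <- profile$sigma %||% rep(stats::median(abs(I)) * 0.01, length(I))
  pos <- I > 0
  if (sum(pos[seq_len(min(length(q), 3 * min_points))]) < min_points) {
    stop("not enough positive low-q intensities for a Guinier fit")
  }
  start <- 1L
  fit_window <- function(i0, i1) {
    idx <- i0:i1
    idx <- idx[I[idx] > 0]
    x <- q[idx]^2; y <- log(I[idx])
    w <- (I[idx] / s[idx])^2          # delta-method weights for ln I
    fit <- stats::lm.wfit(cbind(1, x), y, w)
    list(idx = idx, slope = unname(fit$coefficients[2]),
         intercept = unname(fit$coefficients[1]),
         residuals = fit$residuals, w = w)
  }
  iterate <- function(start) {
    i1 <- min(length(q), start + min_points - 1L)
    prev_i1 <- -1L
    n_iter <- 0L
    repeat {
      n_iter <- n_iter + 1L
      f <- fit_window(start, i1)
      if (!is.finite(f$slope) || f$slope >= 0) {
        stop("Guinier fit failed: non-negative slope (Rg^2 < 0)")
      }
      Rg <- sqrt(-3 * f$slope)
      new_i1 <- max(i1, start + min_points - 1L)
      ok <- which(q * Rg <= qRg_limit)
      if (length(ok)) new_i1 <- max(start + min_points - 1L, max(ok))
      new_i1 <- min(new_i1, length(q))
      if (new_i1 == i1 || n_iter > 50) {
        if (n_iter > 50) warning("Guinier window iteration did not settle")
        return(list(fit = f, Rg = Rg, i1 = i1, n_iter = n_iter))
      }
      prev_i1 <- i1
      i1 <- new_i1
    }
  }
  res <- iterate(start)
  if (guard_upturn) {
    # aggregation upturn: leading residuals all positive and large
    r <- res$fit$residuals
    sr <- r * sqrt(res$fit$w)
    lead <- seq_len(min(5, length(sr)))
    if (all(sr[lead] > 0) && mean(sr[lead]) > 2) {
      start <- start + max(lead)
      res <- iterate(start)
    }
  }
  if (refine_curvature) {
    i1 <- max(res$fit$idx)
    repeat {
      idx <- start:i1
      idx <- idx[I[idx] > 0]
      if (length(idx) <= min_points) break
      x2 <- q[idx]^2; y <- log(I[idx])
      w <- (I[idx] / s[idx])^2
      cf <- tryCatch(summary(stats::lm(y ~ x2 + I(x2^2), weights = w)),
                     error = function(e) NULL)
      t4 <- if (!is.null(cf) && nrow(cf$coefficients) == 3) {
        cf$coefficients[3, "t value"]
      } else 0
      if (!is.finite(t4) || abs(t4) < 3) break
      new_i1 <- max(start + min_points - 1L,
                    floor(start + (i1 - start) * 0.85))
      if (new_i1 >= i1) break
      i1 <- new_i1
    }
    f <- fit_window(start, i1)
    if (!is.finite(f$slope) || f$slope >= 0) {
      stop("Guinier fit failed: non-negative slope (Rg^2 < 0)")
    }
    res$fit <- f
    res$Rg <- sqrt(-3 * f$slope)
  }
  f <- res$fit
  # standard error of slope from the weighted fit
  x <- q[f$idx]^2
  xw <- sum(f$w * x) / sum(f$w)
  dof <- length(f$idx) - 2
  s2 <- sum(f$w * f$residuals^2) / max(dof, 1)
  var_slope <- s2 / sum(f$w * (x - xw)^2)
  Rg <- res$Rg
  Rg_se <- sqrt(var_slope) * 3 / (2 * Rg)
  list(Rg = Rg,
       I0 = exp(f$intercept),
       Rg_se = Rg_se,
       window = range(f$idx),
       qmin_Rg = q[min(f$idx)] * Rg,
       qmax_Rg = q[max(f$idx)] * Rg,
       n_iter = res$n_iter)
}

#' Dimensionless (normalized) Kratky curve
#'
#' `(q Rg)^2 I(q) / I0` versus `q Rg`. Compact globular particles peak at
#' `q Rg = sqrt(3)` with height `3/e`; flexible or multi-domain particles
#' shift the first peak outward and upward.
#'
#' @param profile a [scattering_profile()].
#' @param Rg,I0 Guinier parameters (e.g. from [guinier_fit()]).
#' @return Data frame with columns `qRg` and `kratky`.
#' @export
kratky_normalized <- function(profile, Rg, I0) {
  stopifnot_profile(profile)
  if (Rg <= 0 || I0 <= 0) stop("Rg and I0 must be > 0")
  x <- profile$q * Rg
  data.frame(qRg = x, kratky = x^2 * profile$I / I0)
}

# Sine-basis transform matrix: I_model(q) = 4*pi * integral P(r) sinc(qr) dr
# evaluated by trapezoid on the r grid. Returns list(design = |q| x n_basis,
# phi = |r| x n_basis basis values).
moore_design <- function(q, r, n_basis, Dmax) {
  phi <- vapply(seq_len(n_basis),
                function(n) sin(n * pi * r / Dmax), numeric(length(r)))
  wr <- trapz_weights(r)
  S <- vapply(q, function(qq) sinc(qq * r), numeric(length(r)))  # |r| x |q|
  design <- 4 * pi * t(S * wr) %*% phi                            # |q| x n
  list(design = design, phi = phi)
}

#' Pair distance distribution by regularized indirect Fourier transform
#'
#' Expands `P(r)` in a sine basis on `[0, Dmax]` (so `P(0) = P(Dmax) = 0`
#' by construction) and fits its closed-form reciprocal-space transform to
#' the data, minimizing `chi^2 + alpha * sum |second derivative of P|`
#' with an optional fitted constant background. The L1 smoothness penalty
#' is minimized by iteratively reweighted least squares. Derived values:
#' `Rg^2 = integral(r^2 P) / (2 integral(P))`, `I0 = 4 pi integral(P)`.
#'
#' @param profile a [scattering_profile()] with positive sigma.
#' @param Dmax maximum particle dimension (Angstrom).
#' @param n_basis number of sine terms; default `ceiling(qmax * Dmax / pi)`
#'   (the Shannon channel count of the data).
#' @param alpha non-negative regularization weight; `NULL` selects the
#'   largest alpha whose chi-square stays within 10% of the best
#'   achievable one over an internal grid (discrepancy principle).
#' @param fit_background fit a constant background term.
#' @param n_r number of r-grid points.
#' @return A `pair_distribution` list: `r`, `P`, `Dmax`, `alpha`,
#'   `background`, `Rg`, `I0`, `chi2_reduced`, `coefficients`.
#' @export
ift_pr <- function(profile, Dmax, n_basis = NULL, alpha = NULL,
                   fit_background = TRUE, n_r = 201) {
  stopifnot_profile(profile)
  if (Dmax <= 0) stop("Dmax must be > 0")
  if (!is.null(alpha) && alpha < 0) stop("alpha must be >= 0")
  q <- profile$q; I <- profile$I
  s <- profile$sigma %||% rep(stats::median(abs(I)) * 0.01, length(I))
  if (is.null(n_basis)) n_basis <- max(4L, ceiling(max(q) * Dmax / pi))
  npar <- n_basis + as.integer(fit_background)
  if (npar >= length(q)) {
    stop("underdetermined system: ", npar, " parameters for ", length(q),
         " data points")
  }
  r <- seq(0, Dmax, length.out = n_r)
  md <- moore_design(q, r, n_basis, Dmax)
  A <- md$design / s
  y <- I / s
  if (fit_background) A <- cbind(A, 1 / s)
  # discrete second-derivative operator on the r grid applied to P = phi a
  n_inner <- n_r - 2
  D2phi <- md$phi[1:n_inner, , drop = FALSE] -
    2 * md$phi[2:(n_inner + 1), , drop = FALSE] +
    md$phi[3:n_r, , drop = FALSE]
  if (fit_background) D2phi <- cbind(D2phi, 0)

  solve_alpha <- function(alpha) {
    # IRLS for the L1 penalty: w_k = 1 / max(|v_k|, eps)
    AtA <- crossprod(A)
    rhs <- crossprod(A, y)
    ridged_solve <- function(H) {
      H <- H + diag(1e-10 * max(diag(H)), ncol(H))
      solve(H, rhs)
    }
    x <- ridged_solve(AtA + alpha * crossprod(D2phi))
    eps <- 1e-6 * max(abs(D2phi %*% x), 1e-12)
    for (it in 1:80) {
      v <- as.numeric(D2phi %*% x)
      w <- 1 / pmax(abs(v), eps)
      x_new <- tryCatch(
        ridged_solve(AtA + alpha * crossprod(D2phi * sqrt(w))),
        error = function(e) x)
      if (max(abs(x_new - x)) < 1e-9 * max(abs(x), 1e-300)) {
        x <- x_new; break
      }
      x <- x_new
    }
    x
  }
  result_for <- function(alpha) {
    x <- solve_alpha(alpha)
    a <- x[seq_len(n_basis)]
    bg <- if (fit_background) x[n_basis + 1] else 0
    P <- as.numeric(md$phi %*% a)
    res <- y - A %*% x
    chi2 <- sum(res^2) / max(1, length(q) - npar)
    pen <- sum(abs(D2phi %*% x))
    list(a = a, bg = bg, P = P, chi2 = chi2, pen = pen)
  }
  if (is.null(alpha)) {
    # discrepancy principle: the largest (smoothest) alpha whose misfit
    # stays within 10% of the best achievable chi-square
    agrid <- 10^seq(-6, 2, length.out = 17) * length(q)
    fits <- lapply(agrid, result_for)
    chis <- vapply(fits, `[[`, 0, "chi2")
    k <- max(which(chis <= 1.1 * min(chis)))
    alpha <- agrid[k]
    best <- fits[[k]]
  } else {
    best <- result_for(alpha)
  }
  wr <- trapz_weights(r)
  m0 <- sum(wr * best$P)
  m2 <- sum(wr * r^2 * best$P)
  structure(list(r = r, P = best$P, Dmax = Dmax, alpha = alpha,
                 background = best$bg,
                 Rg = sqrt(max(0, m2 / (2 * m0))),
                 I0 = 4 * pi * m0,
                 chi2_reduced = best$chi2,
                 coefficients = best$a,
                 n_basis = n_basis),
            class = "pair_distribution")
}

#' @export
print.pair_distribution <- function(x, ...) {
  cat(sprintf(
    "<pair_distribution> Dmax = %.1f A, Rg = %.2f A, alpha = %.3g, chi2_red = %.3g\n",
    x$Dmax, x$Rg, x$alpha, x$chi2_reduced))
  invisible(x)
}

#' Scan candidate Dmax values
#'
#' Runs [ift_pr()] over a grid of candidate `Dmax` and regularization
#' weights and scores each fit by `exp(-chi2_red / 2)` multiplied by
#' `(1 - negative P(r) area fraction)`, so over-short Dmax (misfit) and
#' over-long Dmax (oscillating, partly negative P) are both penalized.
#' Reports the per-Dmax maximum over alpha and its argmax, plus a
#' suggested usable `qmax` (largest q where the smoothed `q * I` signal to
#' noise stays above `snr_threshold`).
#'
#' @param profile a [scattering_profile()].
#' @param dmax_grid candidate Dmax values (Angstrom).
#' @param alpha_grid regularization weights scanned per candidate.
#' @param snr_threshold signal-to-noise cut for the qmax suggestion.
#' @return List with `dmax_grid`, `score`, `optimal_dmax`,
#'   `suggested_qmax`, and the per-candidate `detail` data frame.
#' @export
scan_dmax <- function(profile, dmax_grid,
                      alpha_grid = 10^seq(-4, 1, length.out = 6),
                      snr_threshold = 2) {
  stopifnot_profile(profile)
  if (!length(dmax_grid) || !length(alpha_grid)) stop("empty scan grid")
  score_one <- function(D) {
    best <- 0; best_alpha <- NA_real_
    for (al in alpha_grid * length(profile$q)) {
      pr <- tryCatch(ift_pr(profile, D, alpha = al), error = function(e) NULL)
      if (is.null(pr)) next
      wr <- trapz_weights(pr$r)
      neg <- sum(wr * pmax(-pr$P, 0))
      tot <- sum(wr * abs(pr$P))
      neg_frac <- if (tot > 0) neg / tot else 1
      sc <- exp(-pr$chi2_reduced / 2) * (1 - neg_frac)
      if (sc > best) { best <- sc; best_alpha <- al }
    }
    c(score = best, alpha = best_alpha)
  }
  res <- vapply(dmax_grid, score_one, c(score = 0, alpha = 0))
  if (all(res["score", ] == 0)) stop("all P(r) fits failed in the Dmax scan")
  s <- profile$sigma %||% rep(stats::median(abs(profile$I)) * 0.01,
                              length(profile$q))
  snr <- (profile$q * profile$I) / (profile$q * s)
  k <- max(3, min(11, 2 * (length(snr) %/% 20) + 1))
  snr_s <- stats::filter(snr, rep(1 / k, k), sides = 2)
  snr_s[is.na(snr_s)] <- snr[is.na(snr_s)]
  above <- which(snr_s >= snr_threshold)
  suggested_qmax <- if (length(above)) profile$q[max(above)] else max(profile$q)
  score <- unname(res["score", ])
  # parsimony on a flat plateau: the smallest Dmax within 1% of the best
  # score (longer Dmax values fit equally well once P(r) can decay early)
  optimal <- dmax_grid[min(which(score >= max(score) * 0.99))]
  list(dmax_grid = dmax_grid,
       score = score,
       optimal_dmax = optimal,
       suggested_qmax = suggested_qmax,
       detail = data.frame(dmax = dmax_grid, score = res["score", ],
                           alpha = res["alpha", ]))
}

#' Locate maxima of a pair distribution
#'
#' Local maxima of `P(r)` with topographic prominence at least
#' `min_prominence` (as a fraction of `max(P)`), sorted by `r`. Multi-domain
#' particles typically show one intra-domain peak and one or more
#' inter-domain peaks.
#'
#' @param pr a `pair_distribution` from [ift_pr()], or a list with `r`, `P`.
#' @param min_prominence minimum prominence as a fraction of the global
#'   maximum.
#' @return Numeric vector of peak positions (Angstrom), possibly empty.
#' @export
pr_peaks <- function(pr, min_prominence = 0.05) {
  P <- pr$P; r <- pr$r
  n <- length(P)
  if (n < 3) return(numeric(0))
  cand <- which(diff(sign(diff(P))) < 0) + 1L
  cand <- cand[P[cand] > 0]
  if (!length(cand)) return(numeric(0))
  prom <- vapply(cand, function(i) {
    # prominence: height above the highest saddle separating the peak
    # from higher terrain on either side
    left <- P[1:i]; right <- P[i:n]
    hl <- which(left > P[i]); hr <- which(right > P[i]) + i - 1L
    lowL <- if (length(hl)) min(P[(max(hl)):i]) else min(left)
    lowR <- if (length(hr)) min(P[i:(min(hr))]) else min(right)
    P[i] - max(lowL, lowR)
  }, 0)
  keep <- prom >= min_prominence * max(P)
  sort(r[cand[keep]])
}
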