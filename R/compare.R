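#' Principal component analysis with a fixed sign convention
#'
#' Thin wrapper around [stats::prcomp()] returning loadings, scores and
#' explained-variance fractions with a deterministic sign convention
#' (each loading vector's largest-magnitude element is positive), so
#' score plots are reproducible across platforms.
#'
#' @param x numeric matrix, rows = observations.
#' @param center,scale. centering/autoscaling flags (autoscaling fails on
#'   constant columns, as for a correlation-matrix PCA).
#' @param n_components number of components to retain (default all).
#' @return A `pca_result` list: `loadings`, `scores`, `explained`,
#'   `preprocessing`.
#' @export
saxs_pca <- function(x, center = TRUE, scale. = FALSE, n_components = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) stop("need >= 2 rows and >= 2 columns")
  if (any(!is.finite(x))) stop("non-finite entries in the data matrix")
  if (scale. && any(apply(x, 2, stats::sd) == 0)) {
    stop("constant column: autoscaled PCA undefined")
  }
  pc <- stats::prcomp(x, center = center, scale. = scale.)
  k <- min(n_components %||% ncol(pc$rotation), ncol(pc$rotation))
  L <- pc$rotation[, seq_len(k), drop = FALSE]
  S <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    m <- which.max(abs(L[, j]))
    if (L[m, j] < 0) { L[, j] <- -L[, j]; S[, j] <- -S[, j] }
  }
  ev <- pc$sdev^2
  structure(list(loadings = L, scores = S,
                 explained = (ev / sum(ev))[seq_len(k)],
                 preprocessing = list(center = center, scale = scale.)),
            class = "pca_result")
}

#' Matrix of log-intensity profile rows
#'
#' Stacks `log I(q)` over a shared q range, one row per profile, for
#' profile-space PCA and clustering. Profiles with non-positive
#' intensities inside the range are excluded with a message (they cannot
#' be log-transformed), mirroring standard practice of dropping corrupted
#' samples from comparative analysis.
#'
#' @param profiles list of [scattering_profile()]s on a shared q grid.
#' @param q_range `c(qlo, qhi)` analysis window; default full grid.
#' @return Matrix of `log I` rows; kept profile indices in the `kept`
#'   attribute, metadata rows in the `metadata` attribute.
#' @export
profile_matrix <- function(profiles, q_range = NULL) {
  if (!length(profiles)) stop("no profiles")
  lapply(profiles, stopifnot_profile)
  q <- profiles[[1]]$q
  for (p in profiles) if (!same_q_grid(p, profiles[[1]])) {
    stop("profiles are not on a shared q grid")
  }
  sel <- if (is.null(q_range)) rep(TRUE, length(q)) else
    q >= q_range[1] & q <= q_range[2]
  if (!any(sel)) stop("q_range excludes all points")
  ok <- vapply(profiles, function(p) all(p$I[sel] > 0), TRUE)
  if (any(!ok)) {
    message(sum(!ok), " profile(s) with non-positive intensity excluded")
  }
  rows <- t(vapply(profiles[ok], function(p) log(p$I[sel]),
                   numeric(sum(sel))))
  attr(rows, "q") <- q[sel]
  attr(rows, "kept") <- which(ok)
  attr(rows, "metadata") <- lapply(profiles[ok], function(p) p$metadata)
  rows
}

#' Average-linkage hierarchical clustering of a distance matrix
#'
#' @param d symmetric non-negative distance matrix (zero diagonal) or a
#'   `dist` object.
#' @param linkage linkage method (default `"average"`).
#' @param threshold dendrogram cut height.
#' @return Integer cluster assignments; the `hclust` object is attached
#'   as an attribute.
#' @export
hierarchical_cluster <- function(d, linkage = "average", threshold) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (any(d < 0) || any(abs(diag(d)) > 1e-12) ||
        any(abs(d - t(d)) > 1e-8 * (1 + max(d)))) {
      stop("d must be symmetric, non-negative, with zero diagonal")
    }
    d <- stats::as.dist(d)
  }
  hc <- stats::hclust(d, method = linkage)
  out <- stats::cutree(hc, h = threshold)
  attr(out, "hclust") <- hc
  out
}

#' Correlation of particle size with concentration
#'
#' Pearson correlation of Rg (and Dmax) against concentration across a
#' series; strong positive correlation is the signature of progressive
#' self-association, near-zero correlation of a stable (or protected)
#' sample.
#'
#' @param series data frame with columns `concentration`, `rg` and
#'   optionally `dmax`.
#' @return List with `r_rg` and `r_dmax` (NA with a `flag` when a metric
#'   has zero variance).
#' @export
size_vs_concentration <- function(series) {
  if (nrow(series) < 3) stop("need >= 3 points")
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      structure(NA_real_, flag = "zero variance")
    } else stats::cor(x, y)
  }
  list(r_rg = safe_cor(series$concentration, series$rg),
       r_dmax = if ("dmax" %in% names(series)) {
         safe_cor(series$concentration, series$dmax)
       } else NULL)
}
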