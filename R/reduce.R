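#' Average repeated exposure frames with outlier rejection
#'
#' Frames whose Pearson correlation with the pointwise-median frame falls
#' below `reject_threshold` are excluded (radiation-damage screening); the
#' remainder are averaged with standard error propagation
#' `sigma = sqrt(sum(sigma_i^2)) / n_kept`. The correlation is computed on
#' log-intensities when all frames are positive (shape changes at high q
#' are invisible to a raw-intensity correlation, which the decades-larger
#' low-q values dominate).
#'
#' @param frames list of [scattering_profile()]s on an identical q grid.
#' @param reject_threshold minimum Pearson correlation with the median
#'   frame for a frame to be kept.
#' @return Averaged [scattering_profile()]; kept/rejected indices in the
#'   `kept` / `rejected` attributes.
#' @export
average_frames <- function(frames, reject_threshold = 0.995) {
  if (!length(frames)) stop("no frames supplied")
  lapply(frames, stopifnot_profile)
  q <- frames[[1]]$q
  for (f in frames) {
    if (!same_q_grid(f, frames[[1]])) stop("frames are not on a shared q grid")
  }
  if (length(frames) == 1) {
    out <- frames[[1]]
    attr(out, "kept") <- 1L
    attr(out, "rejected") <- integer(0)
    return(out)
  }
  Im <- vapply(frames, function(f) f$I, numeric(length(q)))
  Icor <- if (all(Im > 0)) log(Im) else Im
  med <- apply(Icor, 1, stats::median)
  cors <- apply(Icor, 2, function(col) suppressWarnings(stats::cor(col, med)))
  cors[is.na(cors)] <- 1  # constant frames: no evidence of damage
  keep <- which(cors >= reject_threshold)
  if (!length(keep)) stop("all frames rejected at threshold ", reject_threshold)
  Ik <- Im[, keep, drop = FALSE]
  sig <- vapply(frames[keep], function(f) {
    f$sigma %||% rep(NA_real_, length(q))
  }, numeric(length(q)))
  sigma <- if (any(is.na(sig))) NULL else sqrt(rowSums(sig^2)) / length(keep)
  out <- scattering_profile(q, rowMeans(Ik), sigma,
                            metadata = frames[[1]]$metadata)
  attr(out, "kept") <- keep
  attr(out, "rejected") <- setdiff(seq_along(frames), keep)
  out
}

#' Subtract a buffer profile from a sample profile
#'
#' `I = I_sample - I_buffer` with `sigma = sqrt(sigma_s^2 + sigma_b^2)`.
#' The q grids must match exactly; no silent interpolation is performed.
#'
#' @param sample,buffer [scattering_profile()]s on the same q grid.
#' @return Background-subtracted [scattering_profile()].
#' @export
subtract_buffer <- function(sample, buffer) {
  stopifnot_profile(sample); stopifnot_profile(buffer)
  if (!same_q_grid(sample, buffer)) {
    stop("sample and buffer q grids differ; resample upstream explicitly")
  }
  sigma <- if (!is.null(sample$sigma) && !is.null(buffer$sigma)) {
    sqrt(sample$sigma^2 + buffer$sigma^2)
  } else {
    sample$sigma %||% buffer$sigma
  }
  scattering_profile(sample$q, sample$I - buffer$I, sigma,
                     metadata = sample$metadata)
}

# Error-weighted least-squares scale between two profiles on an index set.
fit_scale_on <- function(ref_I, other_I, other_sigma, idx) {
  w <- 1 / other_sigma[idx]^2
  sum(w * ref_I[idx] * other_I[idx]) / sum(w * other_I[idx]^2)
}

#' Merge a concentration series of profiles
#'
#' Iterative pairwise merge of profiles measured at increasing
#' concentration: the low-concentration curve supplies the low-q region
#' (free of inter-particle interference), the high-concentration curve the
#' high-q region (better statistics). For each consecutive pair, a scale
#' factor is fitted on the overlap window by error-weighted least squares
#' and the crossover q is chosen inside the window to minimize the local
#' scaled discrepancy.
#'
#' @param profiles list of [scattering_profile()]s ordered low to high
#'   concentration, on a common q spacing (grids may cover different
#'   ranges; the overlap is matched by q value).
#' @param overlap_window optional `c(qlo, qhi)` restricting the overlap
#'   region used for scaling; default = full common q range.
#' @param crossover optional fixed crossover q (overrides the search).
#' @return Merged [scattering_profile()]; fitted scales in the `scales`
#'   attribute.
#' @export
merge_concentration_series <- function(profiles, overlap_window = NULL,
                                       crossover = NULL) {
  if (length(profiles) < 2) stop("need at least two profiles to merge")
  lapply(profiles, stopifnot_profile)
  merged <- profiles[[1]]
  scales <- numeric(0)
  for (k in 2:length(profiles)) {
    hi <- profiles[[k]]
    qtol <- 1e-9
    common <- intersect(round(merged$q / qtol), round(hi$q / qtol))
    if (!length(common)) stop("empty q overlap between profiles ", k - 1,
                              " and ", k)
    qc <- common * qtol
    if (!is.null(overlap_window)) {
      qc <- qc[qc >= overlap_window[1] & qc <= overlap_window[2]]
      if (!length(qc)) stop("overlap window excludes all common q points")
    }
    i_lo <- match(round(qc / qtol), round(merged$q / qtol))
    i_hi <- match(round(qc / qtol), round(hi$q / qtol))
    sig_hi <- hi$sigma %||% rep(1, length(hi$q))
    w <- 1 / sig_hi[i_hi]^2
    # sc = fitted intensity ratio high/low; the high curve is divided by it
    sc <- sum(w * hi$I[i_hi] * merged$I[i_lo]) / sum(w * merged$I[i_lo]^2)
    scales <- c(scales, sc)
    # crossover: q in the window minimizing the scaled discrepancy locally
    if (is.null(crossover)) {
      disc <- abs(merged$I[i_lo] - hi$I[i_hi] / sc) /
        pmax(sig_hi[i_hi] / sc, .Machine$double.eps)
      sm <- stats::filter(disc, rep(1 / 5, 5), sides = 2)
      sm[is.na(sm)] <- disc[is.na(sm)]
      qx <- qc[which.min(sm)]
    } else {
      qx <- crossover
    }
    keep_lo <- merged$q <= qx
    keep_hi <- hi$q > qx
    q_new <- c(merged$q[keep_lo], hi$q[keep_hi])
    I_new <- c(merged$I[keep_lo], hi$I[keep_hi] / sc)
    s_lo <- merged$sigma %||% rep(NA_real_, length(merged$q))
    s_new <- c(s_lo[keep_lo], sig_hi[keep_hi] / sc)
    if (any(is.na(s_new))) s_new <- NULL
    merged <- scattering_profile(q_new, I_new, s_new,
                                 metadata = profiles[[1]]$metadata)
    attr(merged, "crossover_q") <- qx
  }
  attr(merged, "scales") <- scales
  merged
}
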