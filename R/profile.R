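#' One-dimensional scattering profile
#'
#' Container for a reduced SAXS curve: momentum transfer `q` (1/Angstrom,
#' strictly increasing), intensity `I` (arbitrary units), pointwise
#' uncertainty `sigma`, and free-form sample metadata (concentration in
#' mg/ml, temperature in degrees C, buffer/additive identifiers, ...).
#'
#' @param q numeric vector of momentum-transfer values, strictly increasing.
#' @param I numeric vector of intensities, same length as `q`.
#' @param sigma numeric vector of uncertainties (> 0), or `NULL` when the
#'   experiment did not report errors.
#' @param metadata named list of sample annotations.
#' @return An object of class `scattering_profile`.
#' @export
scattering_profile <- function(q, I, sigma = NULL, metadata = list()) {
  q <- as.numeric(q); I <- as.numeric(I)
  if (length(q) != length(I)) stop("q and I must have equal length")
  if (length(q) == 0) stop("empty profile")
  if (any(!is.finite(q)) || any(!is.finite(I))) stop("non-finite q or I")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) stop("sigma length mismatch")
    if (any(!is.finite(sigma)) || any(sigma <= 0)) {
      stop("sigma must be finite and > 0")
    }
  }
  structure(list(q = q, I = I, sigma = sigma, metadata = metadata),
            class = "scattering_profile")
}

#' @export
print.scattering_profile <- function(x, ...) {
  cat(sprintf("<scattering_profile> %d points, q in [%.4g, %.4g] 1/A\n",
              length(x$q), min(x$q), max(x$q)))
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.scattering_profile <- function(x) length(x$q)

stopifnot_profile <- function(p) {
  if (!inherits(p, "scattering_profile")) stop("expected a scattering_profile")
  invisible(p)
}

same_q_grid <- function(a, b, tol = 1e-9) {
  length(a$q) == length(b$q) && all(abs(a$q - b$q) <= tol * pmax(1, abs(a$q)))
}

#' Read a profile from 3-column text
#'
#' Parses whitespace-delimited `q I sigma` text files in the common `.dat`
#' dialects: `#`-prefixed (or leading non-numeric) header lines are skipped
#' and `key=value` pairs found in them are kept as metadata. Rows with
#' non-finite values are dropped with a message. Two-column files get a
#' sigma imputed as `impute_sigma_frac * |I|` with a warning.
#'
#' @param path file path.
#' @param dialect `"generic-dat"` or `"sasbdb-dat"` (identical parsing; the
#'   SASBDB dialect additionally tolerates trailing annotation columns).
#' @param impute_sigma_frac fraction of |I| used for a missing sigma column.
#' @return A [scattering_profile()].
#' @export
read_profile <- function(path, dialect = c("generic-dat", "sasbdb-dat"),
                         impute_sigma_frac = 0.02) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  rows <- list()
  for (ln in lines) {
    s <- trimws(ln)
    if (!nzchar(s)) next
    toks <- strsplit(s, "\\s+")[[1]]
    first <- suppressWarnings(as.numeric(toks[1]))
    if (startsWith(s, "#") || is.na(first)) {
      for (kv in regmatches(s, gregexpr("[A-Za-z_][A-Za-z0-9_.-]*=[^ \t]+", s))[[1]]) {
        p <- strsplit(kv, "=", fixed = TRUE)[[1]]
        val <- suppressWarnings(as.numeric(p[2]))
        meta[[p[1]]] <- if (is.na(val)) p[2] else val
      }
      next
    }
    rows[[length(rows) + 1]] <- suppressWarnings(as.numeric(toks))
  }
  if (!length(rows)) stop("no numeric data rows in ", path)
  ncols <- min(vapply(rows, length, 1L))
  if (ncols < 2) stop("parse failure: fewer than 2 numeric columns")
  m <- do.call(rbind, lapply(rows, function(r) r[seq_len(min(ncols, 3))]))
  keep <- apply(is.finite(m), 1, all)
  if (any(!keep)) message(sum(!keep), " rows with non-finite values dropped")
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) stop("no finite data rows in ", path)
  if (any(diff(m[, 1]) <= 0)) stop("q column is not strictly increasing")
  if (ncol(m) >= 3 && all(m[, 3] > 0)) {
    sigma <- m[, 3]
  } else {
    warning("no usable sigma column; imputing sigma = ",
            impute_sigma_frac, " * |I|")
    sigma <- pmax(impute_sigma_frac * abs(m[, 2]), .Machine$double.eps)
  }
  scattering_profile(m[, 1], m[, 2], sigma, metadata = meta)
}

#' Write a profile as 3-column text
#'
#' Inverse of [read_profile()]: metadata is written as `# key=value` header
#' lines and the data as full-precision whitespace-delimited columns.
#'
#' @param profile a [scattering_profile()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot_profile(profile)
  hdr <- character(0)
  if (length(profile$metadata)) {
    hdr <- sprintf("# %s=%s", names(profile$metadata),
                   vapply(profile$metadata, function(v) format(v, digits = 17),
                          character(1)))
  }
  sigma <- profile$sigma %||% rep(NA_real_, length(profile$q))
  body <- sprintf("%s %s %s",
                  format(profile$q, digits = 17, trim = TRUE, scientific = TRUE),
                  format(profile$I, digits = 17, trim = TRUE, scientific = TRUE),
                  format(sigma, digits = 17, trim = TRUE, scientific = TRUE))
  writeLines(c("# q I sigma", hdr, body), path)
  invisible(path)
}
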