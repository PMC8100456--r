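#' Construct a SAXS scattering profile
#'
#' Holds an experimental (or synthetic) small-angle scattering curve: the
#' scattering vector grid `q` (inverse Angstrom), intensities `I(q)`
#' (arbitrary units) and their uncertainties `sigma` (same units as `I`).
#'
#' @param q strictly increasing positive scattering vectors, 1/Angstrom
#' @param intensity intensities `I(q)`
#' @param sigma positive uncertainties on `intensity`
#' @return An object of class `scattering_profile` (also a data frame with
#'   columns `q`, `intensity`, `sigma`).
#' @export
scattering_profile <- function(q, intensity, sigma) {
  .assert(length(q) == length(intensity) && length(q) == length(sigma),
          "q, intensity and sigma must have equal length")
  .assert(length(q) >= 2, "a profile needs at least 2 points")
  .assert(all(is.finite(q)) && all(is.finite(intensity)) && all(is.finite(sigma)),
          "profile contains non-finite values")
  .assert(all(q > 0), "q must be positive")
  .assert(all(diff(q) > 0), "q must be strictly increasing")
  .assert(all(sigma > 0), "sigma must be positive")
  structure(data.frame(q = as.numeric(q), intensity = as.numeric(intensity),
                       sigma = as.numeric(sigma)),
            class = c("scattering_profile", "data.frame"))
}

#' @export
print.scattering_profile <- function(x, ...) {
  cat(sprintf("scattering_profile: %d points, q in [%.4g, %.4g] 1/Angstrom\n",
              nrow(x), min(x$q), max(x$q)))
  invisible(x)
}

.as_profile <- function(x) {
  if (inherits(x, "scattering_profile")) return(x)
  .assert(is.data.frame(x) || is.list(x), "cannot interpret object as a profile")
  .assert(all(c("q", "intensity", "sigma") %in% names(x)),
          "need columns q, intensity, sigma")
  scattering_profile(x$q, x$intensity, x$sigma)
}

#' Load a SAXS profile from 3-column text
#'
#' Reads the common whitespace-separated `q I(q) sigma` dialect.  Lines
#' starting with `#`, blank lines and non-numeric header lines are skipped; a
#' fourth column, if present, is ignored with a warning.  Rows with
#' non-positive `sigma` are dropped with a warning reporting the count.
#'
#' @param path file to read
#' @return A [scattering_profile()].  Errors if fewer than 2 valid rows
#'   remain or if q is not strictly increasing.
#' @export
load_saxs_profile <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\\s+")
  numeric_rows <- vapply(fields, function(f) {
    length(f) >= 3 && !anyNA(suppressWarnings(as.numeric(f[1:3])))
  }, logical(1))
  fields <- fields[numeric_rows]
  .assert(length(fields) >= 2, "fewer than 2 valid data rows in %s", path)
  if (any(vapply(fields, length, integer(1)) > 3)) {
    warning(sprintf("extra columns beyond q, I, sigma in %s ignored", path))
  }
  m <- t(vapply(fields, function(f) as.numeric(f[1:3]), numeric(3)))
  bad <- m[, 3] <= 0
  if (any(bad)) {
    warning(sprintf("dropped %d rows with non-positive sigma from %s",
                    sum(bad), path))
    m <- m[!bad, , drop = FALSE]
  }
  .assert(nrow(m) >= 2, "fewer than 2 valid data rows in %s", path)
  .assert(all(diff(m[, 1]) > 0), "q values in %s are not strictly increasing", path)
  scattering_profile(m[, 1], m[, 2], m[, 3])
}

#' Write a SAXS profile as 3-column text
#'
#' @param profile a [scattering_profile()]
#' @param path output file
#' @return `path`, invisibly.  Values are written with 14 significant digits
#'   so a write/read round trip preserves at least 12 significant digits.
#' @export
write_saxs_profile <- function(profile, path) {
  profile <- .as_profile(profile)
  writeLines(c("# q intensity sigma",
               sprintf("%.14g %.14g %.14g", profile$q, profile$intensity,
                       profile$sigma)), path)
  invisible(path)
}

#' Re-bin a SAXS profile onto a coarser grid
#'
#' Points falling in each of `n_bins` equal-width bins on
#' `[q_min, q_max]` are combined by inverse-variance weighting: the bin
#' intensity is the weighted mean of member intensities, the bin q the
#' weighted mean q, and the bin uncertainty is
#' \eqn{1/\sqrt{\sum \sigma^{-2}}}.  Used, e.g., to reduce a measured curve
#' to a small set of intensities (such as 19 points on 0.01–0.20 1/Angstrom)
#' before repeated forward-model evaluation.
#'
#' @param profile a [scattering_profile()]
#' @param n_bins number of output points (>= 2)
#' @param q_min,q_max bin range, 1/Angstrom; must lie within the profile range
#' @return A [scattering_profile()] with `n_bins` points.  Errors if any bin
#'   is empty.
#' @export
rebin_profile <- function(profile, n_bins, q_min, q_max) {
  profile <- .as_profile(profile)
  .assert(n_bins >= 2, "n_bins must be at least 2")
  .assert(q_min < q_max, "q_min must be below q_max")
  .assert(q_min >= min(profile$q) && q_max <= max(profile$q),
          "[q_min, q_max] must lie within the profile q range")
  breaks <- seq(q_min, q_max, length.out = n_bins + 1)
  keep <- profile$q >= q_min & profile$q <= q_max
  q <- profile$q[keep]; I <- profile$intensity[keep]; s <- profile$sigma[keep]
  bin <- findInterval(q, breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  if (any(counts == 0)) {
    stop(sprintf("bin %d of %d is empty; use fewer bins",
                 which(counts == 0)[1], n_bins), call. = FALSE)
  }
  u <- 1 / s^2
  su <- rowsum(u, bin)[, 1]
  qb <- rowsum(u * q, bin)[, 1] / su
  Ib <- rowsum(u * I, bin)[, 1] / su
  sb <- 1 / sqrt(su)
  scattering_profile(qb, Ib, sb)
}
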