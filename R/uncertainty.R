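# Block-averaging error estimation for time-correlated ensembles and
# weighted distribution densities.

#' Block-averaging standard error of a weighted ensemble average
#'
#' Splits the (trajectory-ordered) frame series into contiguous blocks of
#' increasing size, computes weighted block means, and reports the standard
#' error across blocks at each size.  For correlated series the block error
#' grows with block size until blocks become effectively independent; the
#' final estimate is the plateau value, taken as the maximum over the three
#' largest usable block sizes.  For unordered ensembles use
#' `method = "bootstrap"` (weighted bootstrap of the mean).
#'
#' @param series per-frame values
#' @param weights per-frame weights; default uniform.  Rescaling the weights
#'   leaves the result unchanged (they are renormalized internally).
#' @param block_sizes block lengths to evaluate; default powers of 2 from 16
#'   to `n/8`, so every default size admits at least 8 blocks and the
#'   cross-block standard error is itself stable.  Sizes admitting fewer
#'   than 2 blocks are skipped with a warning.
#' @param method `"blocks"` (default, contiguous-in-time) or `"bootstrap"`
#' @param n_boot bootstrap resamples (default 1000)
#' @param seed RNG seed for the bootstrap
#' @return list of class `block_error` with `error` (the estimate), `mean`
#'   (the weighted mean), `curve` (data frame `block_size`, `n_blocks`,
#'   `se`) and `method`.
#' @export
block_error <- function(series, weights = NULL, block_sizes = NULL,
                        method = c("blocks", "bootstrap"), n_boot = 1000,
                        seed = NULL) {
  method <- match.arg(method)
  n <- length(series)
  .assert(n >= 2, "series must have at least 2 values")
  if (is.null(weights)) weights <- rep(1, n)
  .assert(length(weights) == n, "one weight per frame required")
  weights <- .normalize_weights(weights, quiet = TRUE)
  wm <- sum(weights * series)
  if (method == "bootstrap") {
    if (!is.null(seed)) set.seed(seed)
    means <- replicate(n_boot, {
      idx <- sample.int(n, n, replace = TRUE)
      sum(weights[idx] * series[idx]) / sum(weights[idx])
    })
    return(structure(list(error = sd(means), mean = wm, curve = NULL,
                          method = "bootstrap"), class = "block_error"))
  }
  if (is.null(block_sizes)) {
    # cap at n/8 so every default size admits >= 8 blocks: the standard
    # error across B blocks has relative sampling error ~ 1/sqrt(2(B-1)),
    # which is unusable below ~8 blocks
    top <- floor(log2(n / 8))
    .assert(top >= 4,
            "series too short for default block sizes; supply block_sizes")
    block_sizes <- 2^(4:top)
  }
  rows <- list()
  for (B in sort(unique(block_sizes))) {
    nb <- floor(n / B)
    if (nb < 2) {
      warning(sprintf("block size %d admits fewer than 2 blocks; skipped", B))
      next
    }
    idx <- rep(seq_len(nb), each = B)
    used <- seq_len(nb * B)
    Wb <- rowsum(weights[used], idx)[, 1]
    mb <- rowsum(weights[used] * series[used], idx)[, 1] / Wb
    u <- Wb / sum(Wb)
    mbar <- sum(u * mb)
    se <- sqrt(sum(u * (mb - mbar)^2) / (nb - 1))
    rows[[length(rows) + 1]] <- data.frame(block_size = B, n_blocks = nb, se = se)
  }
  .assert(length(rows) > 0, "no usable block size")
  curve <- do.call(rbind, rows)
  est <- max(tail(curve$se, 3))
  structure(list(error = est, mean = wm, curve = curve, method = "blocks"),
            class = "block_error")
}

#' @export
print.block_error <- function(x, ...) {
  cat(sprintf("block_error: mean = %.6g, se = %.4g (%s)\n", x$mean, x$error,
              x$method))
  invisible(x)
}

#' Weighted probability density with block-averaged bin errors
#'
#' Normalized weighted histogram of a per-frame quantity (e.g. R_g), with a
#' per-bin standard error obtained by applying [block_error()] to the bin
#' indicator series — the construction behind error shades on reweighted
#' R_g/R_h distributions.
#'
#' @param values per-frame values
#' @param weights per-frame weights; default uniform
#' @param bins number of equal-width bins, or an explicit breaks vector
#' @param block_sizes passed to [block_error()]
#' @param method passed to [block_error()]
#' @return data frame with columns `lower`, `upper`, `mid`, `density`,
#'   `error`; `sum(density * (upper - lower)) == 1`.
#' @export
weighted_density <- function(values, weights = NULL, bins = 30,
                             block_sizes = NULL, method = "blocks") {
  n <- length(values)
  .assert(n >= 1, "values must be non-empty")
  .assert(all(is.finite(values)), "values contain non-finite entries")
  if (is.null(weights)) weights <- rep(1, n)
  weights <- .normalize_weights(weights, quiet = TRUE)
  if (length(bins) == 1) {
    .assert(bins >= 2, "need at least 2 bins")
    lo <- min(values); hi <- max(values)
    if (lo == hi) { lo <- lo - 0.5; hi <- hi + 0.5 }
    breaks <- seq(lo, hi, length.out = bins + 1)
  } else {
    breaks <- sort(bins)
    .assert(length(breaks) >= 3, "breaks must define at least 2 bins")
    .assert(min(values) >= breaks[1] && max(values) <= breaks[length(breaks)],
            "breaks do not cover the data range")
  }
  nb <- length(breaks) - 1
  bin <- findInterval(values, breaks, rightmost.closed = TRUE)
  width <- diff(breaks)
  mass <- tapply(weights, factor(bin, levels = seq_len(nb)), sum)
  mass <- as.vector(ifelse(is.na(mass), 0, mass))
  density <- mass / width
  err <- rep(NA_real_, nb)
  can_block <- n >= 64 || !is.null(block_sizes) || method == "bootstrap"
  for (k in seq_len(nb)) {
    ind <- as.numeric(bin == k) / width[k]
    err[k] <- if (can_block) {
      block_error(ind, weights, block_sizes = block_sizes,
                  method = method)$error
    } else {
      # short series: plain weighted SE of the mean indicator
      sqrt(sum(weights^2 * (ind - sum(weights * ind))^2))
    }
  }
  data.frame(lower = breaks[-length(breaks)], upper = breaks[-1],
             mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
             density = density, error = err)
}
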