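# L-curve scan over theta and elbow selection.

#' Scan the BME hyperparameter along a theta ladder
#'
#' Runs [bme_optimize()] for every value of `theta_grid` (processed in
#' decreasing order, warm-starting each solve from the previous
#' multipliers), collecting the trade-off between data fit
#' (\eqn{\chi^2_{red}}) and prior retention (\eqn{\phi_{eff}}).
#' Non-converged points are retained but flagged.
#'
#' @inheritParams bme_optimize
#' @param theta_grid at least 3 positive values; default 20 log-spaced
#'   points on `[1, 1e6]`
#' @param keep_results keep the full `bme_result` for every point
#'   (attribute `"results"`)?
#' @return An object of class `bme_lcurve`: a data frame with columns
#'   `theta`, `chi2_red`, `phi_eff`, `s_rel`, `converged`, ordered by
#'   decreasing theta.
#' @export
lcurve_scan <- function(F_matrix, exp_profile, w0 = NULL,
                        theta_grid = 10^seq(0, 6, length.out = 20),
                        scale_mode = "scale+offset", keep_results = FALSE) {
  .assert(length(theta_grid) >= 3, "theta_grid needs at least 3 values")
  .assert(all(theta_grid > 0), "theta values must be positive")
  .assert(!any(duplicated(theta_grid)), "theta_grid contains duplicates")
  theta_grid <- sort(theta_grid, decreasing = TRUE)
  lambda <- NULL
  rows <- vector("list", length(theta_grid))
  results <- if (keep_results) vector("list", length(theta_grid)) else NULL
  for (k in seq_along(theta_grid)) {
    res <- bme_optimize(F_matrix, exp_profile, w0 = w0, theta = theta_grid[k],
                        scale_mode = scale_mode, lambda_init = lambda)
    lambda <- res$lambda
    rows[[k]] <- data.frame(theta = theta_grid[k], chi2_red = res$chi2_red,
                            phi_eff = res$phi_eff, s_rel = res$s_rel,
                            converged = res$converged)
    if (keep_results) results[[k]] <- res
  }
  out <- do.call(rbind, rows)
  .assert(any(out$converged), "no theta point converged")
  rownames(out) <- NULL
  structure(out, class = c("bme_lcurve", "data.frame"), results = results)
}

#' @export
print.bme_lcurve <- function(x, ...) {
  cat(sprintf("bme_lcurve: %d theta points in [%g, %g] (%d converged)\n",
              nrow(x), min(x$theta), max(x$theta), sum(x$converged)))
  print.data.frame(x, digits = 4)
  invisible(x)
}

# Menger curvature of consecutive point triples in the (x, y) plane
.discrete_curvature <- function(x, y) {
  n <- length(x)
  kappa <- rep(NA_real_, n)
  for (i in 2:(n - 1)) {
    a <- c(x[i - 1], y[i - 1]); b <- c(x[i], y[i]); cc <- c(x[i + 1], y[i + 1])
    area2 <- (b[1] - a[1]) * (cc[2] - a[2]) - (cc[1] - a[1]) * (b[2] - a[2])
    l1 <- sqrt(sum((b - a)^2)); l2 <- sqrt(sum((cc - b)^2))
    l3 <- sqrt(sum((cc - a)^2))
    if (isTRUE(l1 * l2 * l3 > 0)) kappa[i] <- 2 * abs(area2) / (l1 * l2 * l3)
  }
  kappa
}

#' Select the regularization hyperparameter from an L-curve
#'
#' `"max-curvature"` operationalizes the visual "elbow" criterion as the
#' theta maximizing the discrete (Menger) curvature of the converged
#' \eqn{(\log \phi_{eff}, \log \chi^2_{red})} points; a degenerate
#' (collinear) curve falls back to `"chi2-threshold"` with a warning.
#' `"chi2-threshold"` picks the largest theta with
#' \eqn{\chi^2_{red} \le} `chi2_max`.  `"manual"` echoes the supplied value.
#'
#' @param curve a [lcurve_scan()] result
#' @param method `"max-curvature"` (default), `"chi2-threshold"` or
#'   `"manual"`
#' @param chi2_max bound for the threshold method (default 1)
#' @param theta user value for `method = "manual"`
#' @return list of class `theta_selection` with `theta`, `method` and the
#'   selected row of the curve (`point`; `NULL` for manual values off the
#'   grid).
#' @export
select_theta <- function(curve, method = c("max-curvature", "chi2-threshold",
                                           "manual"),
                         chi2_max = 1, theta = NULL) {
  method <- match.arg(method)
  .assert(inherits(curve, "bme_lcurve"), "curve must come from lcurve_scan()")
  conv <- curve[curve$converged, , drop = FALSE]
  pick <- function(theta_sel, method_used, idx = NULL) {
    structure(list(theta = theta_sel, method = method_used,
                   point = if (!is.null(idx)) conv[idx, ] else NULL),
              class = "theta_selection")
  }
  if (method == "manual") {
    .assert(!is.null(theta), "manual selection needs a theta value")
    idx <- which(abs(conv$theta - theta) / theta < 1e-9)
    return(pick(theta, "manual", if (length(idx)) idx[1] else NULL))
  }
  threshold <- function() {
    ok <- which(conv$chi2_red <= chi2_max)
    if (length(ok) == 0) {
      warning(sprintf("no theta reaches chi2_red <= %g; using the minimum-chi2 point",
                      chi2_max))
      ok <- which.min(conv$chi2_red)
    }
    idx <- ok[which.max(conv$theta[ok])]
    pick(conv$theta[idx], "chi2-threshold", idx)
  }
  if (method == "chi2-threshold") return(threshold())
  .assert(nrow(conv) >= 5, "max-curvature needs at least 5 converged points")
  x <- log(conv$phi_eff); y <- log(conv$chi2_red)
  kappa <- if (all(is.finite(x)) && all(is.finite(y))) {
    .discrete_curvature(x, y)
  } else NA_real_  # perfect fits (chi2 = 0) leave no usable log-log geometry
  if (all(is.na(kappa)) || max(kappa, na.rm = TRUE) < 1e-8) {
    warning("L-curve is (near-)collinear; falling back to chi2-threshold")
    sel <- threshold()
    sel$method <- "chi2-threshold (curvature fallback)"
    return(sel)
  }
  idx <- which.max(kappa)
  pick(conv$theta[idx], "max-curvature", idx)
}

#' @export
print.theta_selection <- function(x, ...) {
  cat(sprintf("theta_selection: theta = %g (%s)\n", x$theta, x$method))
  if (!is.null(x$point)) print.data.frame(x$point, digits = 4)
  invisible(x)
}
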