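# Bayesian/Maximum Entropy reweighting core: the objective
#   L(w) = 1/2 chi^2(w) - theta * S_rel(w)
# minimized over the probability simplex, solved in the convex dual.

#' Fit a multiplicative scale and constant offset between curves
#'
#' Weighted least-squares solution of
#' \eqn{\min_{a,b} \sum_i ((a\,c_i + b - y_i)/\sigma_i)^2}, the nuisance
#' transformation between calculated and experimental SAXS intensities.
#' Closed-form 2x2 solve; `b` is fixed at 0 when `fit_offset = FALSE`.
#'
#' @param calc calculated intensities
#' @param exp_profile a [scattering_profile()] (or data frame with
#'   `intensity` and `sigma`) of the same length
#' @param fit_offset also fit the constant background `b`?
#' @return list with elements `scale` and `offset`.  Errors on a degenerate
#'   design (constant `calc` with `fit_offset = TRUE`, or all-zero `calc`).
#' @export
fit_scale_offset <- function(calc, exp_profile, fit_offset = TRUE) {
  p <- .as_profile(exp_profile)
  y <- p$intensity; s <- p$sigma
  .assert(length(calc) == length(y), "calc and experiment differ in length")
  u <- 1 / s^2
  if (fit_offset) {
    A <- matrix(c(sum(u * calc^2), sum(u * calc),
                  sum(u * calc),   sum(u)), 2, 2)
    det <- A[1, 1] * A[2, 2] - A[1, 2]^2
    .assert(abs(det) > 1e-12 * max(A[1, 1] * A[2, 2], 1),
            "degenerate design: calc is (near-)constant, cannot fit offset")
    sol <- solve(A, c(sum(u * calc * y), sum(u * y)))
    list(scale = sol[1], offset = sol[2])
  } else {
    denom <- sum(u * calc^2)
    .assert(denom > 0, "degenerate design: calc is identically zero")
    list(scale = sum(u * calc * y) / denom, offset = 0)
  }
}

.apply_scale_mode <- function(calc, p, scale_mode) {
  switch(scale_mode,
         "none" = list(scale = 1, offset = 0),
         "scale" = fit_scale_offset(calc, p, fit_offset = FALSE),
         "scale+offset" = fit_scale_offset(calc, p, fit_offset = TRUE),
         stop("unknown scale_mode: ", scale_mode, call. = FALSE))
}

#' Reduced chi-square between calculated and experimental intensities
#'
#' \eqn{\chi^2_{red} = \frac{1}{m}\sum_i ((a\,I_{calc,i} + b - I_{exp,i})/\sigma_i)^2}
#' after fitting the nuisance scale/offset according to `scale_mode`.  The
#' normalization divides by the number of data points `m` (not `m` minus the
#' number of fitted nuisance parameters).
#'
#' @inheritParams fit_scale_offset
#' @param scale_mode `"none"`, `"scale"` or `"scale+offset"`
#' @return dimensionless reduced chi-square.
#' @export
chi2_reduced <- function(calc, exp_profile, scale_mode = "none") {
  p <- .as_profile(exp_profile)
  m <- nrow(p)
  .assert(m >= 1 && length(calc) == m, "calc and experiment differ in length")
  ab <- .apply_scale_mode(calc, p, scale_mode)
  mean(((ab$scale * calc + ab$offset - p$intensity) / p$sigma)^2)
}

#' Relative entropy between posterior and prior weights
#'
#' \eqn{S_{rel} = -\sum_j w_j \log(w_j / w^0_j) \le 0}, with equality iff
#' `w == w0`; the convention \eqn{0 \log 0 = 0} applies.  Posterior mass on a
#' frame with zero prior weight violates absolute continuity and is an error.
#'
#' @param w posterior weights (normalized)
#' @param w0 prior weights (normalized)
#' @return non-positive scalar.
#' @export
relative_entropy <- function(w, w0) {
  .assert(length(w) == length(w0), "w and w0 differ in length")
  w <- .normalize_weights(w, "posterior weights")
  w0 <- .normalize_weights(w0, "prior weights")
  .assert(!any(w > 0 & w0 == 0),
          "posterior has mass where the prior is zero (absolute continuity violated)")
  pos <- w > 0
  -sum(w[pos] * log(w[pos] / w0[pos]))
}

#' Effective fraction of retained frames
#'
#' \eqn{\phi_{eff} = \exp(S_{rel}) \in (0, 1]}: close to 1 when most prior
#' frames still contribute after reweighting, close to 0 when the posterior
#' is dominated by a few highly weighted frames (the signature of a poor
#' prior ensemble).
#'
#' @inheritParams relative_entropy
#' @return scalar in (0, 1].
#' @export
phi_eff <- function(w, w0) exp(relative_entropy(w, w0))

# Convex dual of the BME objective for fixed scale/offset.  With
# y' = (y - b)/a and sig' = sig/a the dual variable lambda (one per data
# point) minimizes
#   G(lambda) = log Z(lambda) + sum_i lambda_i y'_i
#               + (theta/2) sum_i lambda_i^2 sig'_i^2,
# where Z = sum_j w0_j exp(-sum_i lambda_i F_ij); the primal solution is
# w_j proportional to w0_j exp(-sum_i lambda_i F_ij).
.bme_dual_solve <- function(Fm, y, sig, logw0, theta, lambda0,
                            max_iter = 5000, grad_tol = 1e-8) {
  weights_of <- function(l) {
    s <- logw0 - as.vector(crossprod(Fm, l))
    s <- s - max(s)
    w <- exp(s)
    w / sum(w)
  }
  obj <- function(l) {
    s <- logw0 - as.vector(crossprod(Fm, l))
    smax <- max(s)
    smax + log(sum(exp(s - smax))) + sum(l * y) + 0.5 * theta * sum((l * sig)^2)
  }
  grad <- function(l) {
    w <- weights_of(l)
    -as.vector(Fm %*% w) + y + theta * sig^2 * l
  }
  fit <- optim(lambda0, obj, grad, method = "L-BFGS-B",
               control = list(maxit = max_iter, factr = 1e1, pgtol = 0))
  l <- fit$par
  # Newton polish: the dual Hessian Cov_w(F) + theta diag(sig^2) is a small
  # m x m matrix, so a few damped steps reach the gradient tolerance cheaply
  iters <- fit$counts[["function"]]
  for (it in 1:30) {
    g <- grad(l)
    if (max(abs(g)) <= grad_tol) break
    w <- weights_of(l)
    Fw <- sweep(Fm, 2, w, "*")
    avg <- rowSums(Fw)
    H <- tcrossprod(Fw, Fm) - tcrossprod(avg) + diag(theta * sig^2, length(sig))
    step <- tryCatch(solve(H, -g), error = function(e) -g)
    f0 <- obj(l)
    alpha <- 1
    repeat {
      cand <- l + alpha * step
      if (obj(cand) <= f0 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    if (alpha < 1e-8) break
    l <- l + alpha * step
    iters <- iters + 1
  }
  g <- grad(l)
  list(lambda = l, w = weights_of(l),
       converged = max(abs(g)) <= grad_tol,
       grad_norm = max(abs(g)), iterations = iters)
}

#' BME reweighting at a fixed hyperparameter
#'
#' Minimizes \eqn{L(w) = \tfrac12 \chi^2(w) - \theta S_{rel}(w)} over the
#' probability simplex.  The problem is solved in its convex dual
#' (dimension = number of data points), where the optimal weights have the
#' exponential-family form
#' \eqn{w_j \propto w^0_j \exp(-\sum_i \lambda_i F_{ij})}; the Gaussian error
#' model adds a \eqn{\theta}-scaled quadratic regularization of the Lagrange
#' multipliers \eqn{\lambda}.  The nuisance intensity scale/offset is
#' refitted against the current ensemble average inside the optimization
#' (profile likelihood) according to `scale_mode`.
#'
#' @param F_matrix observable matrix `F[i, j]` = observable `i`
#'   back-calculated for frame `j` (e.g. from [saxs_matrix()])
#' @param exp_profile a [scattering_profile()] with one row per observable
#' @param w0 prior weights; default uniform
#' @param theta positive regularization hyperparameter
#' @param scale_mode `"none"`, `"scale"` or `"scale+offset"` (default)
#' @param lambda_init optional warm-start Lagrange multipliers
#' @param max_iter dual iteration cap
#' @return An object of class `bme_result`: list with `weights`, `theta`,
#'   `chi2_red` (posterior), `chi2_red_prior`, `s_rel`, `phi_eff`, `scale`,
#'   `offset`, `lambda`, `objective` (value of L at the optimum, using
#'   unreduced chi-square), `converged`, `iterations`.  A non-converged
#'   optimization is returned flagged, not hidden.
#' @export
bme_optimize <- function(F_matrix, exp_profile, w0 = NULL, theta,
                         scale_mode = "scale+offset", lambda_init = NULL,
                         max_iter = 5000) {
  p <- .as_profile(exp_profile)
  Fm <- as.matrix(F_matrix)
  m <- nrow(Fm); n <- ncol(Fm)
  .assert(all(is.finite(Fm)), "observable matrix contains non-finite values")
  .assert(nrow(p) == m, "experimental profile length (%d) != observable rows (%d)",
          nrow(p), m)
  .assert(is.finite(theta) && theta > 0, "theta must be positive")
  if (is.null(w0)) w0 <- rep(1 / n, n)
  .assert(length(w0) == n, "w0 must have one weight per frame")
  w0 <- .normalize_weights(w0, "prior weights")
  logw0 <- log(w0)

  # work in units where intensities are O(1): chi2, weights and the fitted
  # scale are invariant under joint rescaling of (F, I, sigma)
  unit <- max(abs(p$intensity), max(abs(Fm)))
  Fm <- Fm / unit
  p$intensity <- p$intensity / unit
  p$sigma <- p$sigma / unit

  lambda <- if (is.null(lambda_init)) rep(0, m) else lambda_init * unit
  .assert(length(lambda) == m, "lambda_init must have one value per data point")
  ab <- .apply_scale_mode(as.vector(Fm %*% w0), p, scale_mode)
  chi2_prior <- mean(((ab$scale * (Fm %*% w0) + ab$offset - p$intensity) / p$sigma)^2)

  sol <- NULL
  for (outer in 1:200) {
    yp <- (p$intensity - ab$offset) / ab$scale
    sigp <- p$sigma / ab$scale
    sol <- .bme_dual_solve(Fm, yp, sigp, logw0, theta, lambda,
                           max_iter = max_iter)
    lambda <- sol$lambda
    if (scale_mode == "none") break
    calc <- as.vector(Fm %*% sol$w)
    ab_new <- .apply_scale_mode(calc, p, scale_mode)
    delta <- max(abs(ab_new$scale - ab$scale), abs(ab_new$offset - ab$offset))
    ab <- ab_new
    if (delta < 1e-12 * max(1, abs(ab$scale))) break
  }
  w <- sol$w
  calc <- as.vector(Fm %*% w)
  chi2 <- sum(((ab$scale * calc + ab$offset - p$intensity) / p$sigma)^2)
  srel <- relative_entropy(w, w0)
  structure(list(weights = w, theta = theta, chi2_red = chi2 / m,
                 chi2_red_prior = chi2_prior, s_rel = srel,
                 phi_eff = exp(srel), scale = ab$scale,
                 offset = ab$offset * unit,
                 lambda = lambda / unit, objective = 0.5 * chi2 - theta * srel,
                 converged = sol$converged, grad_norm = sol$grad_norm,
                 iterations = sol$iterations, n_frames = n, n_data = m,
                 scale_mode = scale_mode),
            class = "bme_result")
}

#' @export
print.bme_result <- function(x, ...) {
  cat(sprintf(paste0("bme_result: theta = %g\n",
                     "  chi2_red  %.4g (prior %.4g)\n",
                     "  S_rel     %.4g   phi_eff %.4g\n",
                     "  scale     %.4g   offset  %.4g   converged: %s\n"),
              x$theta, x$chi2_red, x$chi2_red_prior, x$s_rel, x$phi_eff,
              x$scale, x$offset, x$converged))
  invisible(x)
}
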