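# Toy multi-replica metainference: Metropolis sampling of synthetic chains
# under an on-the-fly replica-averaged SAXS restraint with explicit
# per-data-point uncertainty parameters and a sampled intensity scale.

# Gaussian metainference restraint (kT units): one Gaussian per data point on
# the scale-multiplied replica-averaged intensity, with total variance
# sigma_sem^2 + sigma_b^2 and the Gaussian normalization term in sigma.
.mi_restraint <- function(Ibar, y, sigma_sem, sigma_b, scale) {
  v <- sigma_sem^2 + sigma_b^2
  sum((scale * Ibar - y)^2 / (2 * v) + 0.5 * log(2 * pi * v))
}

# standard error of the scaled replica mean, from the replica spread
.mi_sem <- function(Icurves, scale) {
  R <- ncol(Icurves)
  scale * apply(Icurves, 1, sd) / sqrt(R)
}

#' Metainference energy of a replica state
#'
#' Total energy (in kT) of a multi-replica state under the Gaussian-noise
#' metainference restraint: the sum of the chain potential over replicas
#' plus, per data point,
#' \deqn{\frac{(s\,\bar I_i - y_i)^2}{2(\sigma_{SEM,i}^2 + \sigma_{b,i}^2)}
#'   + \tfrac12 \log\!\big(2\pi(\sigma_{SEM,i}^2 + \sigma_{b,i}^2)\big),}
#' where \eqn{\bar I} is the replica-averaged Debye intensity, `s` the
#' data/forward scaling factor and \eqn{\sigma_{SEM}} the standard error of
#' the scaled replica mean estimated from the replica spread.
#'
#' @param replica_coords list of `n_beads x 3` coordinate matrices (>= 2
#'   replicas)
#' @param data a [scattering_profile()]
#' @param chain a [chain_config()] defining the chain potential
#' @param sigma_b per-data-point uncertainty parameter (scalar recycled)
#' @param scale intensity scaling factor, must lie in `[0.5, 2]`
#' @param form_factors per-bead form factors for the Debye model
#' @return energy in kT, with attributes `chain` and `restraint`.  Errors if
#'   any replica yields a non-finite forward value.
#' @export
mi_energy <- function(replica_coords, data, chain, sigma_b, scale = 1,
                      form_factors = 1) {
  .assert(length(replica_coords) >= 2, "need at least 2 replicas")
  .assert(scale >= 0.5 && scale <= 2, "scale must lie in [0.5, 2]")
  p <- .as_profile(data)
  m <- nrow(p)
  sigma_b <- rep_len(sigma_b, m)
  .assert(all(sigma_b > 0), "sigma_b must be positive")
  Icurves <- vapply(seq_along(replica_coords), function(r) {
    I <- debye_saxs_frame(replica_coords[[r]], form_factors, p$q)
    .assert(all(is.finite(I)), "non-finite forward intensity for replica %d", r)
    I
  }, numeric(m))
  e_chain <- sum(vapply(replica_coords, chain_energy, numeric(1), cfg = chain))
  e_restr <- .mi_restraint(rowMeans(Icurves), p$intensity,
                           .mi_sem(Icurves, scale), sigma_b, scale)
  structure(e_chain + e_restr, chain = e_chain, restraint = e_restr)
}

#' Run the toy multi-replica metainference sampler
#'
#' Metropolis Monte Carlo over replica chain coordinates, the per-data-point
#' uncertainty \eqn{\sigma_b} (random walk on \eqn{\log\sigma_b}) and the
#' intensity scale (flat prior on `[0.5, 2.0]`, reflected proposals).
#' Coordinate moves always feel the chain potential; the restraint state
#' (\eqn{\sigma_{SEM}} from the replica spread, and the \eqn{\sigma_b} and
#' scale updates) is refreshed every `restraint_every` sweeps.  The
#' replica-averaged intensity is additionally averaged over a rolling
#' `weight_window`-sweep window to give the stable reported curve.  With
#' `restraint_on = FALSE` the same protocol samples the chain potential only
#' (the reference/control run).
#'
#' @param chain a [chain_config()] (the "force field" prior)
#' @param data a [scattering_profile()] to restrain against
#' @param n_replicas number of replicas (>= 2, default 8)
#' @param n_sweeps Monte Carlo sweeps; one sweep attempts
#'   `moves_per_sweep` coordinate moves per replica
#' @param restraint_on apply the SAXS restraint?
#' @param seed RNG seed
#' @param restraint_every sweeps between restraint-state updates (default 10)
#' @param weight_window rolling-average window, sweeps (default 200)
#' @param moves_per_sweep coordinate moves per replica per sweep
#' @param form_factors per-bead form factors for the Debye model
#' @param record_stride sweeps between recorded frames (second half of the
#'   run, all replicas)
#' @return list of class `metainference_run` with `trace` (per sweep:
#'   `chi2_red` with a fitted scale, `correlation`, `scale`,
#'   `sigma_b_median`, `acceptance`), `ensemble` (recorded frames),
#'   `window_curve` (window-averaged replica-mean intensity), `final`
#'   (state summary), `config`.  Aborts if the coordinate acceptance rate
#'   falls below 1% over the first 10% of the run.
#' @export
run_metainference <- function(chain, data, n_replicas = 8, n_sweeps = 400,
                              restraint_on = TRUE, seed = NULL,
                              restraint_every = 10, weight_window = 200,
                              moves_per_sweep = 1, form_factors = 1,
                              record_stride = 10) {
  .assert(n_replicas >= 2, "need at least 2 replicas")
  p <- .as_profile(data)
  m <- nrow(p)
  if (!is.null(seed)) set.seed(seed)

  X <- lapply(seq_len(n_replicas), function(r) .grow_chain(chain))
  e_chain <- vapply(X, chain_energy, numeric(1), cfg = chain)
  Icurves <- vapply(X, debye_saxs_frame, numeric(m), form_factors = form_factors,
                    q_grid = p$q)
  scale <- 1
  sigma_b <- p$sigma
  sigma_b_lo <- 0.05 * p$sigma
  sigma_b_hi <- 20 * p$sigma
  sigma_sem <- .mi_sem(Icurves, scale)
  Ibar <- rowMeans(Icurves)

  restr <- function(Ibar_, scale_, sigma_sem_, sigma_b_) {
    if (!restraint_on) return(0)
    .mi_restraint(Ibar_, p$intensity, sigma_sem_, sigma_b_, scale_)
  }
  e_restr <- restr(Ibar, scale, sigma_sem, sigma_b)

  window <- matrix(NA_real_, m, weight_window)
  trace <- data.frame(sweep = seq_len(n_sweeps), chi2_red = NA_real_,
                      correlation = NA_real_, scale = NA_real_,
                      sigma_b_median = NA_real_, acceptance = NA_real_)
  frames <- list()
  acc <- 0L; tot <- 0L
  check_at <- max(10L, ceiling(0.1 * n_sweeps))

  for (sweep in seq_len(n_sweeps)) {
    for (r in seq_len(n_replicas)) {
      for (mv in seq_len(moves_per_sweep)) {
        st <- .chain_move_proposal(X[[r]], chain)
        tot <- tot + 1L
        if (is.null(st)) next
        e_chain_new <- chain_energy(st, chain)
        if (!is.finite(e_chain_new)) next
        I_new <- debye_saxs_frame(st, form_factors, p$q)
        Ibar_new <- Ibar + (I_new - Icurves[, r]) / n_replicas
        e_restr_new <- restr(Ibar_new, scale, sigma_sem, sigma_b)
        dE <- (e_chain_new - e_chain[r]) + (e_restr_new - e_restr)
        if (dE <= 0 || runif(1) < exp(-dE)) {
          X[[r]] <- st
          e_chain[r] <- e_chain_new
          Icurves[, r] <- I_new
          Ibar <- Ibar_new
          e_restr <- e_restr_new
          acc <- acc + 1L
        }
      }
    }
    if (restraint_on && sweep %% restraint_every == 0) {
      sigma_sem <- .mi_sem(Icurves, scale)
      # scale: reflected uniform proposal on [0.5, 2]
      s_new <- scale + runif(1, -0.1, 0.1)
      if (s_new < 0.5) s_new <- 1 - s_new
      if (s_new > 2.0) s_new <- 4 - s_new
      dE <- .mi_restraint(Ibar, p$intensity, .mi_sem(Icurves, s_new), sigma_b,
                          s_new) -
            .mi_restraint(Ibar, p$intensity, sigma_sem, sigma_b, scale)
      if (dE <= 0 || runif(1) < exp(-dE)) {
        scale <- s_new
        sigma_sem <- .mi_sem(Icurves, scale)
      }
      # sigma_b: per-point random walk on log sigma_b (energy separable)
      sb_new <- sigma_b * exp(rnorm(m, 0, 0.3))
      inside <- sb_new >= sigma_b_lo & sb_new <= sigma_b_hi
      v_old <- sigma_sem^2 + sigma_b^2
      v_new <- sigma_sem^2 + sb_new^2
      res2 <- (scale * Ibar - p$intensity)^2
      dEi <- res2 / (2 * v_new) - res2 / (2 * v_old) + 0.5 * log(v_new / v_old)
      take <- inside & (dEi <= 0 | runif(m) < exp(-dEi))
      sigma_b[take] <- sb_new[take]
      e_restr <- restr(Ibar, scale, sigma_sem, sigma_b)
    }
    window[, (sweep - 1) %% weight_window + 1] <- Ibar
    fitted <- fit_scale_offset(Ibar, p, fit_offset = FALSE)$scale
    trace$chi2_red[sweep] <- mean(((fitted * Ibar - p$intensity) / p$sigma)^2)
    trace$correlation[sweep] <- cor(Ibar, p$intensity)
    trace$scale[sweep] <- scale
    trace$sigma_b_median[sweep] <- stats::median(sigma_b)
    trace$acceptance[sweep] <- acc / tot
    if (sweep == check_at && acc / tot < 0.01) {
      stop(sprintf(paste0("coordinate acceptance %.2f%% after %d sweeps; ",
                          "reduce max_pivot_angle or the bias strength"),
                   100 * acc / tot, sweep), call. = FALSE)
    }
    if (sweep > n_sweeps / 2 && sweep %% record_stride == 0) {
      frames <- c(frames, X)
    }
  }
  win <- rowMeans(window, na.rm = TRUE)
  structure(list(trace = trace,
                 ensemble = conformational_ensemble(frames),
                 window_curve = data.frame(q = p$q, intensity = win),
                 final = list(scale = scale, sigma_b = sigma_b,
                              sigma_sem = sigma_sem, I_avg = Ibar,
                              acceptance = acc / tot),
                 config = list(n_replicas = n_replicas, n_sweeps = n_sweeps,
                               restraint_on = restraint_on, seed = seed,
                               restraint_every = restraint_every,
                               weight_window = weight_window,
                               moves_per_sweep = moves_per_sweep,
                               record_stride = record_stride)),
            class = "metainference_run")
}

#' @export
print.metainference_run <- function(x, ...) {
  n <- nrow(x$trace)
  cat(sprintf(paste0("metainference_run: %d sweeps x %d replicas, restraint %s\n",
                     "  final chi2_red = %.4g, correlation = %.4f, ",
                     "scale = %.3f, acceptance = %.2f\n"),
              n, x$config$n_replicas,
              if (x$config$restraint_on) "on" else "off",
              x$trace$chi2_red[n], x$trace$correlation[n],
              x$final$scale, x$final$acceptance))
  invisible(x)
}

# propose a coordinate move without the Metropolis step (used by the
# replica sampler, which evaluates its own total energy); returns the
# proposed coordinates or NULL for a degenerate proposal
.chain_move_proposal <- function(x, cfg) {
  n <- nrow(x)
  xn <- x
  if (runif(1) < cfg$p_pivot) {
    p <- sample.int(n - 1, 1)
    R <- .rotation_matrix(.random_unit_vector(),
                          runif(1, -cfg$max_pivot_angle, cfg$max_pivot_angle))
    if (runif(1) < 0.5) {
      xn[(p + 1):n, ] <- .rotate_about(x[(p + 1):n, , drop = FALSE], R, x[p, ])
    } else {
      if (p == 1) return(NULL)
      xn[1:(p - 1), ] <- .rotate_about(x[1:(p - 1), , drop = FALSE], R, x[p, ])
    }
  } else {
    i <- sample.int(n - 2, 1)
    span <- sample.int(min(cfg$crank_max_span, n - i) - 1, 1) + 1L
    j <- i + span
    axis <- x[j, ] - x[i, ]
    if (sum(axis^2) < 1e-10) return(NULL)
    R <- .rotation_matrix(axis, runif(1, -pi, pi))
    xn[(i + 1):(j - 1), ] <- .rotate_about(x[(i + 1):(j - 1), , drop = FALSE],
                                           R, x[i, ])
  }
  xn
}
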