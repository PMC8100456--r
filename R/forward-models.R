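# Forward models: map bead-level structures to SAXS, R_g, R_h and PRE
# observables.  All distances in Angstrom, q in 1/Angstrom.

# neutral amino-acid residue electron counts (residue = amino acid - water)
.residue_electrons <- c(
  ALA = 38, ARG = 84, ASN = 60, ASP = 60, CYS = 54, GLN = 68, GLU = 68,
  GLY = 30, HIS = 72, ILE = 62, LEU = 62, LYS = 70, MET = 70, PHE = 78,
  PRO = 52, SER = 46, THR = 54, TRP = 98, TYR = 86, VAL = 54)

#' Residue electron counts for coarse-grained form factors
#'
#' Per-residue electron counts of the 20 neutral amino-acid residues, used as
#' constant (q-independent) bead form factors in the coarse-grained Debye
#' model.  With `normalize = "glycine"` counts are divided by glycine's 30
#' electrons, so a poly-glycine bead has unit weight; because the global
#' intensity scale is refitted against experiment downstream, only relative
#' values matter.
#'
#' @param resnames optional character vector of three-letter residue names;
#'   unknown names fall back to the glycine value with a warning.
#' @param normalize `"glycine"` (default) or `"none"`.
#' @return Named numeric vector: for `resnames = NULL` the full table,
#'   otherwise one value per input residue.
#' @export
residue_electron_counts <- function(resnames = NULL,
                                    normalize = c("glycine", "none")) {
  normalize <- match.arg(normalize)
  tab <- .residue_electrons
  if (normalize == "glycine") tab <- tab / tab[["GLY"]]
  if (is.null(resnames)) return(tab)
  resnames <- toupper(resnames)
  out <- tab[resnames]
  if (anyNA(out)) {
    warning(sprintf("unknown residue name(s) %s; using glycine weight",
                    paste(unique(resnames[is.na(out)]), collapse = ", ")))
    out[is.na(out)] <- tab[["GLY"]]
  }
  unname(out)
}

#' Radius of gyration of one frame
#'
#' Weighted root-mean-square distance of the beads from their weighted
#' centroid:
#' \deqn{R_g = \sqrt{\sum_b m_b |r_b - \bar r|^2 / \sum_b m_b}.}
#'
#' @param coords `n_beads x 3` coordinate matrix (Angstrom)
#' @param weights per-bead mass/scattering weights; default uniform
#' @return R_g in Angstrom (0 for a single bead).
#' @export
compute_rg <- function(coords, weights = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- nrow(coords)
  .assert(n >= 1, "need at least one bead")
  if (is.null(weights)) weights <- rep(1, n)
  .assert(length(weights) == n, "one weight per bead required")
  tw <- sum(weights)
  .assert(tw > 0, "total bead weight is zero")
  ctr <- colSums(coords * weights) / tw
  d2 <- rowSums(sweep(coords, 2, ctr)^2)
  sqrt(sum(weights * d2) / tw)
}

#' Per-frame radii of gyration of an ensemble
#'
#' @param ensemble a [conformational_ensemble()]
#' @param use_bead_weights weight beads by the ensemble's scattering weights
#'   (default) rather than uniformly
#' @return numeric vector of per-frame R_g (Angstrom).
#' @export
ensemble_rg <- function(ensemble, use_bead_weights = TRUE) {
  w <- if (use_bead_weights) ensemble$bead_weights else NULL
  vapply(seq_len(n_frames(ensemble)),
         function(j) compute_rg(frame_coords(ensemble, j), w), numeric(1))
}

#' Hydrodynamic radius from the radius of gyration
#'
#' Empirical relation for disordered chains (Nygaard et al. 2017) linking the
#' per-conformation radius of gyration to the hydrodynamic radius probed by
#' translational diffusion:
#' \deqn{\frac{R_g}{R_h} = \frac{a_1 (R_g - a_2 N^{1/3})}{N^{0.6} - N^{1/3}} + a_3}
#' with \eqn{a_1 = 0.216\,A^{-1}}, \eqn{a_2 = 4.06\,A}, \eqn{a_3 = 0.821},
#' and `N` the number of residues.  The ensemble-level R_h is the weighted
#' mean of the per-frame values (see [ensemble_rh()]).
#'
#' @param rg radius (or radii) of gyration, Angstrom; must be positive
#' @param n_residues chain length (>= 2)
#' @return R_h in Angstrom, same length as `rg`.
#' @export
compute_rh_from_rg <- function(rg, n_residues) {
  .assert(all(is.finite(rg)) && all(rg > 0), "rg must be positive and finite")
  .assert(n_residues >= 2, "n_residues must be at least 2")
  a1 <- 0.216; a2 <- 4.06; a3 <- 0.821
  N <- n_residues
  ratio <- a1 * (rg - a2 * N^(1 / 3)) / (N^0.6 - N^(1 / 3)) + a3
  .assert(all(ratio > 0), "R_g/R_h relation left its domain (rg = %.3g)", rg[1])
  rg / ratio
}

#' Ensemble-averaged hydrodynamic radius
#'
#' @param ensemble a [conformational_ensemble()]
#' @param weights per-frame weights; default the ensemble prior weights
#' @return weighted mean of per-frame R_h (Angstrom).
#' @export
ensemble_rh <- function(ensemble, weights = NULL) {
  if (is.null(weights)) weights <- ensemble$prior_weights
  weights <- .normalize_weights(weights)
  rh <- compute_rh_from_rg(ensemble_rg(ensemble), ensemble$n_residues)
  sum(weights * rh)
}

#' Debye-equation SAXS intensity of a single frame
#'
#' Exact orientation-averaged scattering of a bead model:
#' \deqn{I(q) = \sum_a \sum_b f_a(q) f_b(q) \frac{\sin(q r_{ab})}{q r_{ab}}}
#' with the self term \eqn{f_a(q)^2} at \eqn{r_{aa}=0}.  No hydration-shell
#' term is included.  Form factors are constant per bead; an optional
#' Gaussian bead smearing \eqn{f_b(q) = f_{0,b}\exp(-q^2 R_{bead}^2/2)}
#' multiplies the intensity by \eqn{\exp(-q^2 R_{bead}^2)}.
#'
#' @param coords `n_beads x 3` coordinates (Angstrom)
#' @param form_factors per-bead scalar \eqn{f_0}; a single value is recycled.
#'   Default 1.
#' @param q_grid positive scattering vectors, 1/Angstrom
#' @param smearing_radius Gaussian bead radius R_bead in Angstrom (0 = point
#'   beads)
#' @return numeric vector `I(q)`, same length as `q_grid`.
#' @export
debye_saxs_frame <- function(coords, form_factors = 1, q_grid,
                             smearing_radius = 0) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  .assert(all(is.finite(coords)), "coordinates contain non-finite values")
  .assert(all(q_grid > 0), "q_grid must be positive")
  n <- nrow(coords)
  f <- rep_len(as.numeric(form_factors), n)
  if (n == 1) {
    I <- rep(f[1]^2, length(q_grid))
  } else {
    d <- as.vector(dist(coords))
    M <- tcrossprod(f)
    wpair <- M[lower.tri(M)]
    sc <- .sinc(outer(d, q_grid))      # n_pairs x n_q
    I <- sum(f^2) + 2 * as.vector(crossprod(sc, wpair))
  }
  if (smearing_radius > 0) I <- I * exp(-q_grid^2 * smearing_radius^2)
  I
}

#' Per-frame SAXS observable matrix
#'
#' Back-calculates the Debye intensity of every frame on a common q grid,
#' returning the matrix `F[i, j] = I_i(frame j)` whose weighted column
#' average enters the reweighting chi-square.
#'
#' @param ensemble a [conformational_ensemble()]
#' @param q_grid positive scattering vectors, 1/Angstrom
#' @param form_factors per-bead form factors; default the ensemble's bead
#'   weights (residue electron counts for loaded structures)
#' @param smearing_radius Gaussian bead radius, Angstrom
#' @return `length(q_grid) x n_frames` matrix with rownames `q`.
#' @export
saxs_matrix <- function(ensemble, q_grid, form_factors = NULL,
                        smearing_radius = 0) {
  if (is.null(form_factors)) form_factors <- ensemble$bead_weights
  nf <- n_frames(ensemble)
  out <- matrix(NA_real_, length(q_grid), nf)
  for (j in seq_len(nf)) {
    out[, j] <- debye_saxs_frame(frame_coords(ensemble, j), form_factors,
                                 q_grid, smearing_radius)
  }
  rownames(out) <- sprintf("q=%g", q_grid)
  out
}

#' Ensemble-averaged SAXS curve
#'
#' Weighted arithmetic mean of per-frame Debye intensities.
#'
#' @inheritParams saxs_matrix
#' @param weights per-frame probabilities; default the ensemble prior weights
#' @return data frame with columns `q` and `intensity`.
#' @export
ensemble_saxs <- function(ensemble, weights = NULL, q_grid,
                          form_factors = NULL, smearing_radius = 0) {
  if (is.null(weights)) weights <- ensemble$prior_weights
  .assert(length(weights) == n_frames(ensemble),
          "need one weight per frame (%d weights, %d frames)",
          length(weights), n_frames(ensemble))
  weights <- .normalize_weights(weights)
  Fm <- saxs_matrix(ensemble, q_grid, form_factors, smearing_radius)
  data.frame(q = q_grid, intensity = as.vector(Fm %*% weights))
}

#' Guinier analysis of a SAXS profile
#'
#' Fits \eqn{\ln I(q)} against \eqn{q^2} on the largest low-q window whose
#' upper edge satisfies \eqn{q \cdot R_g \le} `max_qrg`, iterating the window
#' until self-consistent.  The radius of gyration is
#' \eqn{R_g = \sqrt{-3 \times slope}} and `i0` the extrapolated forward
#' scattering.
#'
#' @param profile a [scattering_profile()] or data frame with `q`,
#'   `intensity`
#' @param max_qrg upper limit for \eqn{q R_g} in the fitted window
#'   (default 1.1, a conservative choice for expanded chains)
#' @param min_points smallest admissible window (default 3)
#' @return A list of class `guinier_fit` with elements `rg`, `i0`,
#'   `q_range_used`, `max_qrg`, `n_points`, `fit_residual` (standard error of
#'   the slope).  A flat or rising profile yields `rg = 0` with a warning
#'   that no Guinier regime was found.
#' @export
guinier_fit <- function(profile, max_qrg = 1.1, min_points = 3) {
  q <- profile$q
  I <- profile$intensity
  .assert(length(q) >= min_points, "need at least %d points", min_points)
  .assert(all(I > 0), "Guinier analysis requires positive intensities")
  k <- length(q)
  for (iter in 1:100) {
    fit <- lm(log(I[1:k]) ~ I(q[1:k]^2))
    slope <- coef(fit)[[2]]
    if (slope >= -1e-10) {  # flat within numerical noise: no Guinier regime
      warning("no Guinier regime: non-negative slope; reporting rg = 0")
      return(structure(list(rg = 0, i0 = exp(coef(fit)[[1]]),
                            q_range_used = c(q[1], q[k]), max_qrg = max_qrg,
                            n_points = k, fit_residual = NA_real_),
                       class = "guinier_fit"))
    }
    rg <- sqrt(-3 * slope)
    k_new <- max(which(q * rg <= max_qrg), 0)
    if (k_new < min_points) {
      stop(sprintf("Guinier window smaller than %d points (rg about %.1f A)",
                   min_points, rg), call. = FALSE)
    }
    if (k_new >= k) break
    k <- k_new
  }
  # exact synthetic curves trigger summary.lm's perfect-fit warning
  se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  structure(list(rg = rg, i0 = exp(coef(fit)[[1]]),
                 q_range_used = c(q[1], q[k]), max_qrg = max_qrg,
                 n_points = k, fit_residual = se),
            class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf("guinier_fit: rg = %.3f A, I(0) = %.4g, %d points, q in [%.4g, %.4g]\n",
              x$rg, x$i0, x$n_points, x$q_range_used[1], x$q_range_used[2]))
  invisible(x)
}

#' PRE spectroscopic parameters
#'
#' Constants entering the Solomon-Bloembergen transverse PRE rate and its
#' conversion to an intensity ratio.  Defaults describe a typical nitroxide
#' label on a disordered protein at a 700 MHz spectrometer; all values can be
#' overridden.
#'
#' @param tau_c effective correlation time, nanoseconds
#' @param larmor_frequency proton Larmor frequency, MHz
#' @param r2_diamagnetic intrinsic transverse relaxation rate R2, 1/s
#' @param total_evolution_time transverse evolution delay t, seconds
#' @param k_const dipolar constant K, Angstrom^6 / s^2 (nitroxide:
#'   1.23e16, i.e. 1.23e-32 cm^6/s^2)
#' @return list of class `pre_parameters`.
#' @export
pre_parameters <- function(tau_c = 1.0, larmor_frequency = 700,
                           r2_diamagnetic = 10, total_evolution_time = 0.01,
                           k_const = 1.23e16) {
  vals <- c(tau_c, larmor_frequency, r2_diamagnetic, total_evolution_time,
            k_const)
  .assert(all(is.finite(vals)) && all(vals > 0),
          "all PRE parameters must be strictly positive")
  structure(list(tau_c = tau_c, larmor_frequency = larmor_frequency,
                 r2_diamagnetic = r2_diamagnetic,
                 total_evolution_time = total_evolution_time,
                 k_const = k_const),
            class = "pre_parameters")
}

# Solomon-Bloembergen transverse rate from a population-averaged <r^-6>
.pre_gamma2 <- function(mean_r6, params) {
  tau <- params$tau_c * 1e-9                       # ns -> s
  omega <- 2 * pi * params$larmor_frequency * 1e6  # MHz -> rad/s
  spectral <- 4 * tau + 3 * tau / (1 + (omega * tau)^2)
  params$k_const * mean_r6 * spectral
}

# intensity ratio from Gamma2
.pre_ratio <- function(gamma2, params) {
  r2 <- params$r2_diamagnetic
  r2 * exp(-gamma2 * params$total_evolution_time) / (r2 + gamma2)
}

# pseudo-atom for the unpaired electron: displaced from the labeled residue's
# C-alpha along the local chain normal (cross product of the two bonds)
.label_position <- function(coords, site_idx, offset) {
  n <- nrow(coords)
  i <- site_idx
  if (i == 1) {
    u <- coords[2, ] - coords[1, ]; v <- coords[min(3, n), ] - coords[1, ]
  } else if (i == n) {
    u <- coords[n - 1, ] - coords[n, ]; v <- coords[max(1, n - 2), ] - coords[n, ]
  } else {
    u <- coords[i - 1, ] - coords[i, ]; v <- coords[i + 1, ] - coords[i, ]
  }
  nrm <- .cross3(u, v)
  if (sum(nrm^2) < 1e-8) {
    # collinear neighbours: deterministic perpendicular to u
    ref <- if (abs(u[1]) < 0.9 * sqrt(sum(u^2))) c(1, 0, 0) else c(0, 1, 0)
    nrm <- .cross3(u, ref)
  }
  coords[i, ] + offset * nrm / sqrt(sum(nrm^2))
}

#' Back-calculate PRE intensity ratios for one label site
#'
#' For each residue, the population-weighted \eqn{\langle r^{-6} \rangle}
#' between the spin-label pseudo-atom and the residue's C-alpha is averaged
#' over frames, converted to the transverse PRE rate via the
#' Solomon-Bloembergen term
#' \eqn{\Gamma_2 = K \langle r^{-6}\rangle (4\tau_c + 3\tau_c/(1+\omega_H^2\tau_c^2))},
#' and reported as the intensity ratio
#' \eqn{I_{para}/I_{dia} = R_2 \exp(-\Gamma_2 t) / (R_2 + \Gamma_2)}.
#'
#' The label pseudo-atom sits `label_offset` Angstrom from the labeled
#' residue's C-alpha along the local chain normal; per-frame label positions
#' can instead be supplied explicitly via `label_coords`.
#'
#' @param ensemble a [conformational_ensemble()]
#' @param weights per-frame weights; default the ensemble prior weights
#' @param label_site residue index carrying the paramagnetic label
#' @param params a [pre_parameters()] object
#' @param label_offset label displacement from the C-alpha, Angstrom
#' @param label_coords optional `n_frames x 3` matrix of explicit label
#'   positions (overrides the pseudo-atom construction)
#' @return data frame with columns `label_site`, `residue`, `mean_r6`
#'   (Angstrom^-6), `gamma2` (1/s) and `ratio`.  Residues at zero distance
#'   from the label in any frame are excluded with a message.
#' @export
pre_ratio_profile <- function(ensemble, weights = NULL, label_site,
                              params = pre_parameters(), label_offset = 6,
                              label_coords = NULL) {
  nb <- ensemble$n_residues
  resno <- ensemble$bead_labels$resno
  site_idx <- match(label_site, resno)
  .assert(!is.na(site_idx), "label_site %s not in the chain", label_site)
  if (is.null(weights)) weights <- ensemble$prior_weights
  weights <- .normalize_weights(weights)
  nf <- n_frames(ensemble)
  if (!is.null(label_coords)) {
    label_coords <- matrix(as.numeric(label_coords), ncol = 3)
    .assert(nrow(label_coords) == nf, "need one label position per frame")
  }
  sum_r6 <- rep(0, nb)
  zero_dist <- rep(FALSE, nb)
  for (j in seq_len(nf)) {
    x <- frame_coords(ensemble, j)
    lab <- if (is.null(label_coords)) .label_position(x, site_idx, label_offset)
           else label_coords[j, ]
    d2 <- rowSums(sweep(x, 2, lab)^2)
    zero_dist <- zero_dist | d2 == 0
    d2[d2 == 0] <- Inf
    sum_r6 <- sum_r6 + weights[j] / d2^3
  }
  keep <- !zero_dist
  if (any(zero_dist)) {
    message(sprintf("excluded residue(s) at zero label distance: %s",
                    paste(resno[zero_dist], collapse = ", ")))
  }
  gamma2 <- .pre_gamma2(sum_r6[keep], params)
  data.frame(label_site = label_site, residue = resno[keep],
             mean_r6 = sum_r6[keep], gamma2 = gamma2,
             ratio = .pre_ratio(gamma2, params))
}
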