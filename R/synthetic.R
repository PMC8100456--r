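# Synthetic ensembles with known ground truth: a C-alpha-resolution
# self-avoiding chain sampled by Metropolis pivot/crankshaft moves, and
# exponential-family "truth" sub-ensembles with synthetic SAXS/PRE data.

#' Configuration of the coarse-grained chain model
#'
#' One bead per residue with fixed virtual bond length, hard-sphere excluded
#' volume between non-bonded beads, an optional harmonic bias steering the
#' radius of gyration toward a target (emulating force fields of differing
#' compaction), and optional harmonic bond-angle stiffness.
#'
#' @param n_residues chain length (>= 5)
#' @param bond_length virtual C-alpha bond, Angstrom (default 3.8)
#' @param excluded_volume hard-sphere diameter for beads `|i - j| >= 2`,
#'   Angstrom (default 4.0; 0 disables)
#' @param compaction target R_g in Angstrom, or `NULL`/`"none"` for an
#'   unbiased chain.  Targets below the globule limit `2.2 n^(1/3)` are
#'   rejected.
#' @param spring_k harmonic R_g bias spring constant, kT/Angstrom^2
#' @param angle_k optional bond-angle stiffness, kT/rad^2 (default 0)
#' @param angle_theta0 rest bond angle, radians
#' @param max_pivot_angle largest pivot rotation, radians
#' @param crank_max_span largest crankshaft segment, beads
#' @param p_pivot probability of proposing a pivot (vs crankshaft) move
#' @return list of class `chain_config`.
#' @export
chain_config <- function(n_residues, bond_length = 3.8, excluded_volume = 4.0,
                         compaction = NULL, spring_k = 1.0, angle_k = 0,
                         angle_theta0 = 2.0, max_pivot_angle = pi,
                         crank_max_span = 12, p_pivot = 0.5) {
  .assert(n_residues >= 5, "n_residues must be at least 5")
  if (identical(compaction, "none")) compaction <- NULL
  if (!is.null(compaction)) {
    limit <- 2.2 * n_residues^(1 / 3)
    .assert(compaction >= limit,
            "target R_g %.1f A is below the globule limit %.1f A for n = %d",
            compaction, limit, n_residues)
  }
  structure(list(n_residues = n_residues, bond_length = bond_length,
                 excluded_volume = excluded_volume, compaction = compaction,
                 spring_k = spring_k, angle_k = angle_k,
                 angle_theta0 = angle_theta0,
                 max_pivot_angle = max_pivot_angle,
                 crank_max_span = crank_max_span, p_pivot = p_pivot),
            class = "chain_config")
}

# chain potential (kT units): Inf on hard-sphere overlap, plus harmonic
# R_g bias and optional bond-angle stiffness
chain_energy <- function(x, cfg) {
  n <- nrow(x)
  if (cfg$excluded_volume > 0) {
    d <- as.vector(dist(x))
    # positions of bonded pairs (i, i+1) in the dist vector
    i <- seq_len(n - 1)
    bonded <- n * (i - 1) - i * (i - 1) / 2 + 1
    d[bonded] <- Inf
    if (any(d < cfg$excluded_volume)) return(Inf)
  }
  e <- 0
  if (!is.null(cfg$compaction)) {
    e <- e + 0.5 * cfg$spring_k * (compute_rg(x) - cfg$compaction)^2
  }
  if (cfg$angle_k > 0) {
    v <- diff(x)
    vn <- v / sqrt(rowSums(v^2))
    cosang <- pmin(1, pmax(-1, rowSums(vn[-nrow(vn), , drop = FALSE] *
                                         vn[-1, , drop = FALSE])))
    theta <- pi - acos(cosang)  # bond angle at interior beads
    e <- e + sum(0.5 * cfg$angle_k * (theta - cfg$angle_theta0)^2)
  }
  e
}

# grow an initial self-avoiding configuration
.grow_chain <- function(cfg) {
  n <- cfg$n_residues
  for (attempt in 1:200) {
    x <- matrix(NA_real_, n, 3)
    x[1, ] <- 0
    ok <- TRUE
    for (k in 2:n) {
      placed <- FALSE
      for (try in 1:300) {
        cand <- x[k - 1, ] + cfg$bond_length * .random_unit_vector()
        if (k > 2 && cfg$excluded_volume > 0) {
          d2 <- rowSums(sweep(x[1:(k - 2), , drop = FALSE], 2, cand)^2)
          if (min(d2) < cfg$excluded_volume^2) next
        }
        x[k, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(x)
  }
  stop("failed to grow an initial self-avoiding chain", call. = FALSE)
}

# one Metropolis move under the chain potential (kT = 1)
.chain_move <- function(x, e_old, cfg) {
  xn <- .chain_move_proposal(x, cfg)
  if (is.null(xn)) return(list(x = x, accepted = FALSE, energy = e_old))
  e_new <- chain_energy(xn, cfg)
  if (is.finite(e_new) && (e_new <= e_old || runif(1) < exp(e_old - e_new))) {
    list(x = xn, accepted = TRUE, energy = e_new)
  } else {
    list(x = x, accepted = FALSE, energy = e_old)
  }
}

#' Generate a synthetic C-alpha chain ensemble
#'
#' Samples a self-avoiding chain (fixed 3.8 Angstrom virtual bonds,
#' 4.0 Angstrom hard-sphere excluded volume) by seeded Metropolis
#' pivot/crankshaft moves, optionally biased toward a target radius of
#' gyration by a harmonic spring — a minimal stand-in for priors of
#' differing compaction.  Frames are recorded every `stride` accepted-or-
#' rejected moves after `burnin` moves.
#'
#' @param n_frames number of recorded frames (>= 10)
#' @param n_residues chain length (>= 5)
#' @param compaction target R_g (Angstrom), `"none"` or `NULL` for unbiased
#' @param seed RNG seed; identical seed + configuration gives bit-identical
#'   coordinates
#' @param config optional [chain_config()] overriding the defaults
#' @param burnin equilibration moves before recording (default 600)
#' @param stride moves between recorded frames (default 3)
#' @return A [conformational_ensemble()] with uniform prior weights; the
#'   sampler settings are stored in `attr(, "config")` together with the
#'   move acceptance rate.
#' @export
generate_chain_ensemble <- function(n_frames, n_residues, compaction = NULL,
                                    seed = NULL, config = NULL, burnin = 600,
                                    stride = 3) {
  .assert(n_frames >= 10, "n_frames must be at least 10")
  cfg <- if (is.null(config)) chain_config(n_residues, compaction = compaction)
         else config
  .assert(cfg$n_residues == n_residues, "config n_residues mismatch")
  if (!is.null(seed)) set.seed(seed)
  x <- .grow_chain(cfg)
  e <- chain_energy(x, cfg)
  # bias may start far from its target: relax downhill first
  acc <- 0L; tot <- 0L
  for (k in seq_len(burnin)) {
    st <- .chain_move(x, e, cfg)
    x <- st$x; e <- st$energy
  }
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    for (k in seq_len(stride)) {
      st <- .chain_move(x, e, cfg)
      x <- st$x; e <- st$energy
      acc <- acc + st$accepted; tot <- tot + 1L
    }
    frames[[f]] <- x
  }
  ens <- conformational_ensemble(frames)
  attr(ens, "config") <- c(unclass(cfg),
                           list(seed = seed, burnin = burnin, stride = stride,
                                acceptance_rate = acc / tot))
  ens
}

#' Build a synthetic "truth" case from a prior ensemble
#'
#' Defines ground-truth weights as an exponential tilt on the per-frame
#' radius of gyration, \eqn{w^{truth}_j \propto \exp(\kappa R_{g,j})} — a
#' truth exactly reachable by the exponential-family form of BME, so
#' recovery is a sharp test — and generates a noisy synthetic SAXS profile
#' and PRE intensity ratios from that truth.
#'
#' @param prior a [conformational_ensemble()]
#' @param kappa tilt strength, 1/Angstrom (positive favours expanded
#'   frames).  Tilts collapsing the truth below `phi_eff = 0.01` against the
#'   uniform prior are rejected.
#' @param q_grid SAXS grid; default 19 points on 0.01–0.20 1/Angstrom
#' @param noise_level fractional Gaussian noise on I(q) (default 0.02)
#' @param noise_floor sigma floor as a fraction of max I (default 1e-3)
#' @param seed RNG seed (noise reproducibility)
#' @param pre_sites label sites; default the canonical five (24, 42, 62, 87,
#'   103) when the chain is long enough, otherwise five evenly spaced sites
#' @param pre_noise Gaussian noise on PRE ratios (default 0.05)
#' @param smearing_radius Gaussian bead radius for the Debye model
#' @return list of class `truth_case`: `ensemble`, `truth_weights`,
#'   `saxs` (noisy [scattering_profile()]), `saxs_noiseless`, `F`
#'   (the [saxs_matrix()] of the prior), `rg` (per-frame), `pre`
#'   ([pre_dataset()] or `NULL`), `config`.
#' @export
make_truth_case <- function(prior, kappa = 0.15,
                            q_grid = seq(0.01, 0.20, length.out = 19),
                            noise_level = 0.02, noise_floor = 1e-3,
                            seed = NULL, pre_sites = NULL, pre_noise = 0.05,
                            smearing_radius = 0) {
  if (!is.null(seed)) set.seed(seed)
  rg <- ensemble_rg(prior)
  lw <- kappa * rg
  tw <- exp(lw - max(lw))
  tw <- tw / sum(tw)
  pe <- phi_eff(tw, rep(1 / length(tw), length(tw)))
  .assert(pe >= 0.01,
          "degenerate tilt: phi_eff = %.3g < 0.01 against the uniform prior", pe)
  Fm <- saxs_matrix(prior, q_grid, smearing_radius = smearing_radius)
  I0 <- as.vector(Fm %*% tw)
  sigma <- noise_level * I0 + noise_floor * max(I0)
  Iobs <- I0 + rnorm(length(I0), 0, sigma)
  nres <- prior$n_residues
  if (is.null(pre_sites)) {
    pre_sites <- if (nres >= 103) c(24, 42, 62, 87, 103)
                 else pmax(1, round(seq(0.15, 0.85, length.out = 5) * nres))
  }
  pre <- NULL
  if (length(pre_sites) > 0) {
    tabs <- lapply(pre_sites, function(s) {
      prof <- pre_ratio_profile(prior, tw, label_site = s)
      data.frame(label_site = s, residue = prof$residue,
                 ratio = pmax(prof$ratio + rnorm(nrow(prof), 0, pre_noise), 1e-6),
                 error = pre_noise)
    })
    pre <- pre_dataset(do.call(rbind, tabs), n_residues = nres)
  }
  structure(list(ensemble = prior, truth_weights = tw,
                 saxs = scattering_profile(q_grid, Iobs, sigma),
                 saxs_noiseless = data.frame(q = q_grid, intensity = I0),
                 F = Fm, rg = rg, pre = pre,
                 config = list(kappa = kappa, noise_level = noise_level,
                               noise_floor = noise_floor, seed = seed,
                               pre_sites = pre_sites, pre_noise = pre_noise,
                               smearing_radius = smearing_radius,
                               phi_eff_truth = pe)),
            class = "truth_case")
}

#' @export
print.truth_case <- function(x, ...) {
  cat(sprintf(paste0("truth_case: %d frames, kappa = %g, phi_eff(truth) = %.3f\n",
                     "  truth <R_g> = %.2f A, SAXS %d points, PRE sites: %s\n"),
              n_frames(x$ensemble), x$config$kappa, x$config$phi_eff_truth,
              sum(x$truth_weights * x$rg), nrow(x$saxs),
              paste(x$config$pre_sites, collapse = ", ")))
  invisible(x)
}

#' Persist a truth case as a directory of plain-text files
#'
#' Writes `ensemble.dat` (coordinate table), `truth_weights.dat`,
#' `saxs.dat`, `pre.csv` (if present) and `config.json`.
#'
#' @param case a [make_truth_case()] result
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly.
#' @export
save_truth_case <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ensemble_table(case$ensemble, file.path(dir, "ensemble.dat"))
  save_weights(case$truth_weights, file.path(dir, "truth_weights.dat"))
  write_saxs_profile(case$saxs, file.path(dir, "saxs.dat"))
  if (!is.null(case$pre)) write_pre_table(case$pre, file.path(dir, "pre.csv"))
  jsonlite::write_json(case$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
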