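test_that("radius of gyration matches closed forms", {
  expect_equal(compute_rg(matrix(c(5, 2, -1), 1, 3)), 0)
  expect_equal(compute_rg(rbind(c(0, 0, 0), c(2, 0, 0))), 1.0)
  square <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0))
  expect_equal(compute_rg(square), sqrt(2), tolerance = 1e-12)
  # weighting moves the centroid
  expect_equal(compute_rg(rbind(c(0, 0, 0), c(2, 0, 0)), c(3, 1)),
               sqrt(0.75 * 0.5^2 + 0.25 * 1.5^2))
  expect_error(compute_rg(square, rep(0, 4)), "zero")
})

test_that("the empirical R_g to R_h relation evaluates and orders correctly", {
  # direct hand evaluation of the published relation at rg = 29.7 A, N = 140:
  # ratio = 0.216*(29.7 - 4.06*140^(1/3))/(140^0.6 - 140^(1/3)) + 0.821
  ratio <- 0.216 * (29.7 - 4.06 * 140^(1 / 3)) / (140^0.6 - 140^(1 / 3)) + 0.821
  expect_equal(compute_rh_from_rg(29.7, 140), 29.7 / ratio, tolerance = 1e-12)
  expect_equal(compute_rh_from_rg(29.7, 140), 31.1946, tolerance = 1e-4)
  expect_lt(compute_rh_from_rg(20, 140), compute_rh_from_rg(30, 140))
  expect_error(compute_rh_from_rg(-1, 140), "positive")

  # compact vs expanded synthetic ensembles preserve the R_g ordering in R_h
  expanded <- generate_chain_ensemble(40, 40, seed = 21)
  compact <- generate_chain_ensemble(40, 40, compaction = 9, seed = 21)
  expect_gt(mean(ensemble_rg(expanded)), mean(ensemble_rg(compact)))
  expect_gt(ensemble_rh(expanded), ensemble_rh(compact))
})

test_that("Debye intensities match closed forms and the brute-force oracle", {
  q <- c(0.02, 0.1, 0.25)
  expect_equal(debye_saxs_frame(matrix(0, 1, 3), 1, q), rep(1, 3))
  two <- rbind(c(0, 0, 0), c(7.5, 0, 0))
  expect_equal(debye_saxs_frame(two, 1, q),
               2 * (1 + sin(q * 7.5) / (q * 7.5)), tolerance = 1e-12)
  set.seed(31)
  X <- matrix(rnorm(60, sd = 12), 20, 3)
  f <- runif(20, 0.5, 2)
  qg <- seq(0.01, 0.3, length.out = 9)
  expect_equal(debye_saxs_frame(X, f, qg), debye_brute(X, f, qg),
               tolerance = 1e-10)
  # forward limit: I(q -> 0) = (sum f)^2
  expect_equal(debye_saxs_frame(X, f, 1e-6) / sum(f)^2, 1, tolerance = 1e-6)
  # Gaussian smearing multiplies by exp(-q^2 R^2)
  expect_equal(debye_saxs_frame(X, f, qg, smearing_radius = 3),
               debye_brute(X, f, qg) * exp(-qg^2 * 9), tolerance = 1e-10)
  expect_error(debye_saxs_frame(rbind(c(NA, 0, 0), c(1, 0, 0)), 1, q),
               "non-finite")
})

test_that("ensemble averages are linear in the weights", {
  set.seed(32)
  ens <- generate_chain_ensemble(20, 15, seed = 32)
  qg <- seq(0.02, 0.2, length.out = 5)
  # delta weights select one frame exactly
  w1 <- c(1, rep(0, 19))
  expect_equal(ensemble_saxs(ens, w1, qg)$intensity,
               debye_saxs_frame(frame_coords(ens, 1), ens$bead_weights, qg))
  # equal weights average two frames
  w12 <- c(0.5, 0.5, rep(0, 18))
  expect_equal(ensemble_saxs(ens, w12, qg)$intensity,
               0.5 * ensemble_saxs(ens, w1, qg)$intensity +
                 0.5 * ensemble_saxs(ens, c(0, 1, rep(0, 18)), qg)$intensity)
  # alpha-mixtures for random weight pairs
  for (k in 1:3) {
    wa <- .normalize_runif(20); wb <- .normalize_runif(20); a <- runif(1)
    mix <- ensemble_saxs(ens, a * wa + (1 - a) * wb, qg)$intensity
    expect_equal(mix, a * ensemble_saxs(ens, wa, qg)$intensity +
                   (1 - a) * ensemble_saxs(ens, wb, qg)$intensity,
                 tolerance = 1e-10)
  }
  expect_error(ensemble_saxs(ens, c(0.5, 0.5), qg), "one weight per frame")
})

test_that("Guinier analysis recovers exact and noisy synthetic curves", {
  for (rg in c(10, 20, 35.5, 50)) {
    qmax <- min(1.0 / rg, 0.03)
    p <- gaussian_profile(rg, q = seq(0.002, qmax, length.out = 30))
    fit <- guinier_fit(p)
    expect_equal(fit$rg, rg, tolerance = 1e-3)
    expect_equal(fit$i0, 100, tolerance = 1e-3)
  }
  set.seed(35)
  p <- gaussian_profile(35.5)
  noisy <- scattering_profile(p$q, p$intensity + rnorm(nrow(p), 0, 0.01 * p$intensity),
                              0.01 * p$intensity)
  expect_equal(guinier_fit(noisy)$rg, 35.5, tolerance = 0.02)
  # flat curve has no Guinier regime
  flat <- scattering_profile(p$q, rep(5, nrow(p)), rep(0.1, nrow(p)))
  expect_warning(fit0 <- guinier_fit(flat), "no Guinier regime")
  expect_equal(fit0$rg, 0)
})

test_that("PRE ratios follow the r^-6 law and the hand-evaluated formula", {
  # two frames, label fixed at the origin, observed bead at 15 A and 40 A
  ens <- two_frame_distance_ensemble(15, 40, n_beads = 2)
  lab <- rbind(c(0, 0, 0), c(0, 0, 0))
  prof <- pre_ratio_profile(ens, weights = c(0.1, 0.9), label_site = 1,
                            label_coords = lab)
  r2 <- prof[prof$residue == 2, ]
  # independent hand evaluation with the default constants
  mean_r6 <- 0.1 * 15^-6 + 0.9 * 40^-6
  omega <- 2 * pi * 700e6
  tau <- 1e-9
  gamma2 <- 1.23e16 * mean_r6 * (4 * tau + 3 * tau / (1 + (omega * tau)^2))
  ratio <- 10 * exp(-gamma2 * 0.01) / (10 + gamma2)
  expect_equal(r2$mean_r6, mean_r6, tolerance = 1e-12)
  expect_equal(r2$ratio, ratio, tolerance = 1e-10)
  expect_equal(r2$ratio, 0.9517297, tolerance = 1e-6)

  # halving every distance multiplies <r^-6> by 64
  half <- two_frame_distance_ensemble(7.5, 20, n_beads = 2)
  prof_half <- pre_ratio_profile(half, weights = c(0.1, 0.9), label_site = 1,
                                 label_coords = lab)
  expect_equal(prof_half$mean_r6[prof_half$residue == 2] / r2$mean_r6, 64,
               tolerance = 1e-10)

  # distances to infinity: Gamma2 -> 0, ratio -> 1
  far <- two_frame_distance_ensemble(5e3, 8e3, n_beads = 2)
  pf <- pre_ratio_profile(far, weights = c(0.5, 0.5), label_site = 1,
                          label_coords = lab)
  expect_equal(pf$ratio[pf$residue == 2], 1, tolerance = 1e-6)

  # monotone non-decreasing in every pairwise distance: uniform expansion
  ens2 <- generate_chain_ensemble(10, 20, seed = 41)
  base <- pre_ratio_profile(ens2, label_site = 10)
  grown <- conformational_ensemble(lapply(1:10, function(j) 1.25 * frame_coords(ens2, j)))
  up <- pre_ratio_profile(grown, label_site = 10, label_offset = 6 * 1.25)
  expect_true(all(up$ratio >= base$ratio - 1e-12))
})

test_that("a zero label distance excludes the residue with a message", {
  ens <- two_frame_distance_ensemble(10, 12, n_beads = 3)
  lab <- rbind(c(0, 0, 0), c(0, 0, 0))  # exactly on bead 1
  expect_message(prof <- pre_ratio_profile(ens, weights = c(0.5, 0.5),
                                           label_site = 1, label_coords = lab),
                 "zero label distance")
  expect_false(1 %in% prof$residue)
})
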