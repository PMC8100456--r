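test_that("scale/offset fitting solves the weighted least-squares problem", {
  q <- seq(0.01, 0.1, length.out = 19)
  set.seed(51)
  calc <- 100 * exp(-q^2 * 200) + rnorm(19, 0, 2)
  p <- scattering_profile(q, calc, 0.02 * abs(calc) + 0.5)
  fit <- fit_scale_offset(calc, p)
  expect_equal(fit$scale, 1, tolerance = 1e-10)
  expect_equal(fit$offset, 0, tolerance = 1e-6)

  p2 <- scattering_profile(q, 2 * calc, rep(1, 19))
  expect_equal(fit_scale_offset(calc, p2, fit_offset = FALSE)$scale, 2)
  # calculated curve twice the experiment: scale comes back as 0.5
  expect_equal(fit_scale_offset(2 * calc,
                                scattering_profile(q, calc, rep(1, 19)),
                                fit_offset = FALSE)$scale, 0.5)

  # independent solver oracle: weighted lm
  y <- rnorm(19, 50, 10); s <- runif(19, 0.5, 2)
  po <- scattering_profile(q, y, s)
  ab <- fit_scale_offset(calc, po)
  ref <- coef(lm(y ~ calc, weights = 1 / s^2))
  expect_equal(ab$scale, unname(ref[2]), tolerance = 1e-10)
  expect_equal(ab$offset, unname(ref[1]), tolerance = 1e-10)

  expect_error(fit_scale_offset(rep(3, 19), po), "degenerate")
})

test_that("reduced chi-square matches its definition and is noise-consistent", {
  q <- seq(0.01, 0.1, length.out = 19)
  I <- 100 * exp(-q^2 * 300)
  p <- scattering_profile(q, I, 0.02 * I)
  expect_equal(chi2_reduced(I, p), 0)
  expect_equal(chi2_reduced(I + p$sigma, p), 1.0)
  # sigma-consistent noise: mean chi2_red over replicates is about 1
  set.seed(52)
  reps <- replicate(200, chi2_reduced(I + rnorm(19, 0, p$sigma), p))
  se <- sqrt(2 / 19 / 200)
  expect_lt(abs(mean(reps) - 1), 3 * se)
})

test_that("relative entropy and phi_eff match closed forms", {
  w0 <- rep(1 / 100, 100)
  expect_equal(relative_entropy(w0, w0), 0)
  one <- c(1, rep(0, 99))
  expect_equal(relative_entropy(one, w0), -log(100))
  expect_equal(phi_eff(one, w0), 0.01)
  half <- c(rep(2 / 100, 50), rep(0, 50))
  expect_equal(relative_entropy(half, w0), -log(2))
  expect_equal(phi_eff(half, w0), 0.5)
  expect_equal(phi_eff(w0, w0), 1.0)
  # absolute continuity
  expect_error(relative_entropy(c(0.5, 0.5, 0), c(0.5, 0, 0.5)),
               "absolute continuity")
})

test_that("the dual optimizer solves tiny problems to the primal optimum", {
  # entropy-dominated limit returns the prior
  set.seed(53)
  Fm <- matrix(rnorm(6), 2, 3)
  p <- scattering_profile(c(0.1, 0.2), rnorm(2), c(0.05, 0.1))
  res <- bme_optimize(Fm, p, theta = 1e12, scale_mode = "none")
  expect_equal(res$weights, rep(1 / 3, 3), tolerance = 1e-6)
  expect_equal(res$phi_eff, 1, tolerance = 1e-6)
  expect_equal(res$chi2_red, res$chi2_red_prior, tolerance = 1e-6)

  # symmetric fixed point: prior already optimal (observable duplicated so
  # the profile has the minimum two rows)
  F1 <- matrix(c(0, 0, 1, 1), 2, 2)
  p1 <- scattering_profile(c(0.1, 0.2), c(0.5, 0.5), c(0.01, 0.01))
  sym <- bme_optimize(F1, p1, theta = 1, scale_mode = "none")
  expect_equal(sym$weights, c(0.5, 0.5), tolerance = 1e-8)

  # dual objective beats an exhaustive primal grid (10 seeded instances)
  for (k in 1:10) {
    set.seed(100 + k)
    m <- sample(2:3, 1)
    Fm <- matrix(rnorm(m * 3), m, 3)
    y <- rnorm(m); sig <- runif(m, 0.05, 0.3)
    theta <- 10^runif(1, -0.5, 1)
    pk <- scattering_profile(seq(0.1, 0.3, length.out = m), y, sig)
    res <- bme_optimize(Fm, pk, theta = theta, scale_mode = "none")
    gmin <- primal_grid_min(Fm, y, sig, rep(1 / 3, 3), theta)
    expect_lte(res$objective, gmin + 1e-4)
  }
})

test_that("returned weights have the exponential-family optimality form", {
  set.seed(54)
  ens <- generate_chain_ensemble(60, 20, seed = 54)
  tc <- make_truth_case(ens, kappa = 0.2, seed = 55, pre_sites = integer(0))
  res <- bme_optimize(tc$F, tc$saxs, theta = 50)
  lw <- -as.vector(crossprod(tc$F, res$lambda))
  wf <- exp(lw - max(lw)); wf <- wf / sum(wf)
  expect_equal(wf, res$weights, tolerance = 1e-8)
  expect_true(res$converged)
  expect_lte(res$s_rel, 1e-12)
  expect_equal(sum(res$weights), 1, tolerance = 1e-10)
  expect_equal(res$phi_eff, exp(res$s_rel))
})

test_that("chi2 and phi_eff are monotone along a decreasing theta ladder", {
  ens <- generate_chain_ensemble(150, 25, seed = 57)
  tc <- make_truth_case(ens, kappa = 0.25, seed = 58, pre_sites = integer(0))
  lc <- lcurve_scan(tc$F, tc$saxs, theta_grid = 10^seq(0, 5, length.out = 12))
  expect_true(all(diff(lc$chi2_red) <= 1e-6))
  expect_true(all(diff(lc$phi_eff) <= 1e-6))
})
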