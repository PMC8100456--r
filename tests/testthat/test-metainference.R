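test_that("the metainference energy matches a hand-evaluated formula", {
  chain <- chain_config(5, excluded_volume = 0)
  # two replicas on a line, one data point
  mk <- function(step) cbind(seq(0, by = step, length.out = 5), 0, 0)
  reps <- list(mk(3.8), mk(3.8))
  q <- 0.05
  data1 <- scattering_profile(c(q, 0.1), c(30, 20), c(1, 1))
  I1 <- debye_saxs_frame(reps[[1]], 1, data1$q)
  # identical replicas: sigma_sem = 0; hand-evaluate the restraint
  sb <- c(2, 3); sc <- 1.5
  hand <- sum((sc * I1 - data1$intensity)^2 / (2 * sb^2) +
                0.5 * log(2 * pi * sb^2))
  e <- mi_energy(reps, data1, chain, sigma_b = sb, scale = sc)
  expect_equal(as.numeric(e), hand, tolerance = 1e-12)
  expect_equal(attr(e, "chain"), 0)

  # zero residual: only the normalization terms remain
  data0 <- scattering_profile(data1$q, sc * I1, c(1, 1))
  e0 <- mi_energy(reps, data0, chain, sigma_b = sb, scale = sc)
  expect_equal(as.numeric(e0), sum(0.5 * log(2 * pi * sb^2)), tolerance = 1e-12)
  # doubling sigma_b at zero residual changes the energy by m*log(2)
  e2 <- mi_energy(reps, data0, chain, sigma_b = 2 * sb, scale = sc)
  expect_equal(as.numeric(e2) - as.numeric(e0), 2 * log(2), tolerance = 1e-12)

  expect_error(mi_energy(reps, data1, chain, sigma_b = sb, scale = 3),
               "scale")
  expect_error(mi_energy(reps[1], data1, chain, sigma_b = sb), "2 replicas")
})

test_that("a restrained run beats its unrestrained control on the data", {
  prior <- generate_chain_ensemble(400, 50, seed = 111)
  tc <- make_truth_case(prior, kappa = 0.15, seed = 112,
                        pre_sites = integer(0))
  chain <- chain_config(50, compaction = 12, spring_k = 0.5)
  runR <- run_metainference(chain, tc$saxs, n_replicas = 6, n_sweeps = 250,
                            restraint_on = TRUE, seed = 113)
  runC <- run_metainference(chain, tc$saxs, n_replicas = 6, n_sweeps = 250,
                            restraint_on = FALSE, seed = 113)
  chi_w <- function(run) chi2_reduced(run$window_curve$intensity, tc$saxs,
                                      "scale")
  expect_lt(chi_w(runR), chi_w(runC))
  expect_gte(cor(runR$window_curve$intensity, tc$saxs$intensity),
             cor(runC$window_curve$intensity, tc$saxs$intensity) - 1e-6)
  # the sampled scale honours its flat prior bounds
  expect_gte(min(runR$trace$scale), 0.5)
  expect_lte(max(runR$trace$scale), 2.0)
  # restraint pulls the ensemble toward the (more expanded) truth
  expect_gt(mean(ensemble_rg(runR$ensemble)), mean(ensemble_rg(runC$ensemble)))
})

test_that("with the restraint off the sampler reduces to prior sampling", {
  cfg <- chain_config(30)
  direct <- generate_chain_ensemble(300, 30, seed = 114, config = cfg)
  p <- scattering_profile(c(0.05, 0.1), c(900, 800), c(10, 10))
  run <- run_metainference(cfg, p, n_replicas = 4, n_sweeps = 300,
                           restraint_on = FALSE, seed = 115,
                           record_stride = 5)
  rg_direct <- ensemble_rg(direct)
  rg_mc <- ensemble_rg(run$ensemble)
  # recorded replica frames are not time-contiguous: bootstrap errors
  se <- sqrt(block_error(rg_direct, method = "bootstrap", seed = 1)$error^2 +
               block_error(rg_mc, method = "bootstrap", seed = 2)$error^2)
  expect_lt(abs(mean(rg_mc) - mean(rg_direct)), 4 * se)
})

test_that("unrestrained sampling obeys detailed balance on a harmonic angle", {
  # ideal chain with a harmonic bond-angle potential: the MC-sampled interior
  # angle must match direct Boltzmann sampling of p(theta) ~ sin(theta)exp(-U)
  k <- 4; theta0 <- 1.9
  cfg <- chain_config(5, excluded_volume = 0, angle_k = k,
                      angle_theta0 = theta0)
  ens <- generate_chain_ensemble(3000, 5, seed = 116, config = cfg,
                                 burnin = 500, stride = 4)
  angle_at <- function(x, i) {
    u <- x[i - 1, ] - x[i, ]; v <- x[i + 1, ] - x[i, ]
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
  }
  mc <- vapply(seq_len(n_frames(ens)),
               function(j) angle_at(frame_coords(ens, j), 3), numeric(1))
  set.seed(117)
  direct <- numeric(0)
  while (length(direct) < 3000) {
    th <- runif(6000, 0, pi)
    f <- sin(th) * exp(-0.5 * k * (th - theta0)^2)
    direct <- c(direct, th[runif(6000) < f / max(f)])
  }
  ks <- suppressWarnings(stats::ks.test(mc, direct[1:3000]))
  expect_gt(ks$p.value, 0.01)
})
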