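# saxsbme

Bayesian/Maximum-Entropy refinement of disordered-protein conformational
ensembles against small-angle X-ray scattering (SAXS) data.

## What this package is for

Intrinsically disordered proteins (IDPs) must be described as ensembles,
and experiments on them (SAXS, NMR diffusion, paramagnetic relaxation
enhancement) measure ensemble averages. Simulated ensembles, meanwhile,
depend strongly on the force field: some protein/water combinations yield
chains far more compact than the scattering data imply. `saxsbme` is for
structural biologists and simulators who want to reconcile the two — to
reweight a simulated ("prior") ensemble minimally so that it matches a
measured SAXS curve, to diagnose when the prior is simply too poor to be
rescued, and to validate the refined ensemble against observables that
were not fitted (hydrodynamic radius, PRE intensity ratios).

## The method

Given per-frame observables `F[i, j]` (data point *i*, frame *j*), prior
weights `w0` and a measured profile `I ± σ`, BME reweighting minimizes
over the probability simplex

    L(w) = ½ χ²(w) − θ S_rel(w)

with `χ²(w) = Σ_i ((a·Σ_j w_j F_ij + b − I_i)/σ_i)²` (nuisance scale `a`
and offset `b` refitted by weighted least squares inside the
optimization) and `S_rel = −Σ_j w_j log(w_j / w0_j) ≤ 0` the relative
entropy to the prior. The hyperparameter θ balances data fit against
prior fidelity and is chosen from the L-curve of reduced χ² against the
effective retained fraction `φ_eff = exp(S_rel)`.

The problem is solved in its convex dual (one Lagrange multiplier per
data point, dimension *m* ≈ 19 rather than *n* ≈ thousands of frames).
The optimal weights take the exponential-family form
`w_j ∝ w0_j exp(−Σ_i λ_i F_ij)`, where λ minimizes the dual objective

    G(λ) = log Σ_j w0_j exp(−Σ_i λ_i F_ij) + Σ_i λ_i I'_i + (θ/2) Σ_i λ_i² σ'_i²

with `I' = (I − b)/a`, `σ' = σ/a` (the quadratic term is the
Gaussian-error regularization that θ applies to the multipliers; the
primal objective above states only the weight-space form, so the dual is
documented here). L-BFGS-B plus damped Newton polishing on the exact
*m × m* Hessian drives the gradient below 1e-8; scale/offset and λ are
alternated to a joint fixed point.

Around this core the package provides Debye-equation SAXS forward models
on one-bead-per-residue structures, Guinier analysis, the Nygaard
empirical R_g→R_h relation, Solomon–Bloembergen PRE intensity ratios,
block-averaged uncertainties and weighted densities, a self-avoiding
chain Monte Carlo generator producing synthetic ensembles with exactly
known ground truth, and a toy multi-replica metainference sampler that
applies the SAXS restraint on the fly (Gaussian noise model per data
point, sampled per-point uncertainty σ_b, intensity scale sampled with a
flat prior on [0.5, 2.0]).

## Worked example

Build a synthetic prior, define a ground truth as an exponential tilt
toward expanded conformations, synthesize a noisy 19-point SAXS profile
from it, and recover the truth by reweighting:

```r
library(saxsbme)

prior <- generate_chain_ensemble(n_frames = 800, n_residues = 80, seed = 7)
truth <- make_truth_case(prior, kappa = 0.15, seed = 8)
truth
#> truth_case: 800 frames, kappa = 0.15, phi_eff(truth) = 0.797
#>   truth <R_g> = 28.03 A, SAXS 19 points, PRE sites: 12, 26, 40, 54, 68

lc  <- lcurve_scan(truth$F, truth$saxs, theta_grid = 10^seq(0, 5, length.out = 12))
sel <- select_theta(lc)
sel
#> theta_selection: theta = 2.84804 (max-curvature)
#>    theta chi2_red phi_eff   s_rel converged
#> 11 2.848   0.5884  0.7211 -0.3269      TRUE

fit <- bme_optimize(truth$F, truth$saxs, theta = sel$theta)
fit
#> bme_result: theta = 2.84804
#>   chi2_red  0.5884 (prior 3.635)
#>   S_rel     -0.3269   phi_eff 0.7211
#>   scale     0.9923   offset  17.43   converged: TRUE

rg <- truth$rg
sprintf("prior <Rg> = %.1f A, reweighted <Rg> = %.1f +/- %.1f A, truth <Rg> = %.1f A",
        sum(prior$prior_weights * rg), sum(fit$weights * rg),
        block_error(rg, fit$weights)$error, sum(truth$truth_weights * rg))
#> "prior <Rg> = 25.1 A, reweighted <Rg> = 27.5 +/- 0.5 A, truth <Rg> = 28.0 A"
```

Reading the output: the prior fits the synthetic data poorly
(χ²_red = 3.6) and underestimates the ensemble size; after reweighting at
the L-curve elbow the fit is noise-level (χ²_red = 0.59), 72% of the
prior frames still contribute (φ_eff = 0.72, a healthy refinement rather
than a collapse onto a few frames), and the reweighted mean radius of
gyration moves to within one block-averaged standard error of the truth.
A compact prior whose most expanded frame lies below the truth average
shows the opposite signature — χ²_red stuck far above 1 with φ_eff of
order 1e-3 — which is how a hopeless prior is diagnosed in practice.

Real data enter through `load_ensemble()` (multi-model PDB, DCD +
topology, or a plain coordinate table), `load_saxs_profile()` /
`rebin_profile()` (3-column `q I σ` text, e.g. re-binned to 19 points on
0.01–0.20 Å⁻¹) and `load_pre_table()`. `run_pipeline()` drives the whole
analysis from a YAML config and writes weights, L-curve, R_g/R_h
densities and PRE RMSD tables to a results directory; see
`inst/extdata/demo_config.yaml` and the thin wrapper
`inst/cli/run_pipeline.R` for shell use.

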