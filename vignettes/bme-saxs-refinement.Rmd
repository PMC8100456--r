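---
title: "Ensemble refinement of disordered proteins against SAXS data"
author: "saxsbme"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble refinement of disordered proteins against SAXS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saxsbme)
```

## The problem

Intrinsically disordered proteins (IDPs) have no single native structure;
their state is a broad conformational ensemble, and almost every experiment
on them — small-angle X-ray scattering (SAXS), NMR diffusion, paramagnetic
relaxation enhancement (PRE) — reports an *ensemble average*. Molecular
simulations provide candidate ensembles, but force fields differ widely in
how compact a disordered chain they produce. This package implements the
two standard ways of reconciling a simulated ("prior") ensemble with
measured SAXS data:

* **post-hoc Bayesian/Maximum-Entropy (BME) reweighting** of an existing
  ensemble, and
* an **on-the-fly metainference restraint** applied while sampling
  (provided here as a desk-scale multi-replica Monte Carlo analogue),

together with the forward models (Debye-equation SAXS, Guinier analysis,
an empirical hydrodynamic radius, PRE intensity ratios), the L-curve
machinery for choosing the regularization strength, block-averaged
uncertainties, and a synthetic-data generator with exactly known ground
truth so that every stage can be validated end to end.

## The BME objective and its dual

Given per-frame observables $F_{ij}$ (observable $i$, frame $j$), prior
weights $w^0_j$ (uniform by default) and experimental values $I_i \pm
\sigma_i$, BME minimizes over the probability simplex

$$ L(w) \;=\; \tfrac12 \chi^2(w) \;-\; \theta\, S_{rel}(w), \qquad
   \chi^2(w) = \sum_i \left( \frac{a \sum_j w_j F_{ij} + b - I_i}{\sigma_i}
   \right)^2, $$

where $S_{rel} = -\sum_j w_j \log (w_j / w^0_j) \le 0$ is the relative
entropy to the prior and $\theta > 0$ sets the balance between fitting the
data and staying close to the prior. The nuisance scale $a$ and offset $b$
between calculated and measured intensities are refitted by weighted least
squares inside every optimization (profile likelihood, `scale_mode`),
because a SAXS experiment determines intensities only up to calibration
and residual background.

`bme_optimize()` solves the problem in its **convex dual**: with one
Lagrange multiplier $\lambda_i$ per data point, the optimal weights have
the exponential-family form

$$ w_j \;\propto\; w^0_j \exp\Big( -\sum_i \lambda_i F_{ij} \Big), $$

and $\lambda$ minimizes

$$ G(\lambda) = \log \sum_j w^0_j e^{-\sum_i \lambda_i F_{ij}}
   + \sum_i \lambda_i I'_i
   + \frac{\theta}{2} \sum_i \lambda_i^2 \sigma'^2_i , $$

where $I' = (I - b)/a$ and $\sigma' = \sigma/a$ fold in the current
nuisance parameters; the quadratic term is the Gaussian-error
regularization that ties $\theta$ to the multipliers. The dual has
dimension $m$ (number of data points, typically 19) rather than $n$
(frames, thousands), and is strictly convex. We solve it with L-BFGS-B
followed by damped Newton steps on the exact $m \times m$ Hessian
$\mathrm{Cov}_w(F) + \theta\,\mathrm{diag}(\sigma'^2)$, declaring
convergence at a gradient max-norm of $10^{-8}$ after internally rescaling
all intensities to order 1 (results are invariant under joint rescaling of
$F$, $I$, $\sigma$). Scale/offset and $\lambda$ are alternated to a joint
fixed point. Non-converged solves are returned flagged, never silently.
The test suite verifies the dual solution against exhaustive primal grid
search on small simplices and checks the exponential-family optimality
form of the returned weights.

Two diagnostics summarize a reweighting: $\chi^2_{red} = \chi^2/m$ (we
divide by the number of data points, not by $m$ minus the number of fitted
nuisance parameters; the convention is recorded in all outputs) and the
effective retained fraction $\phi_{e\!f\!f} = \exp(S_{rel})$. A posterior
dominated by a few frames ($\phi_{e\!f\!f} \to 0$) while $\chi^2_{red}$
stays large is the signature of a *poor prior*: the data lie outside what
the prior ensemble can express by reweighting.

## Choosing the hyperparameter

`lcurve_scan()` traces $(\theta, \chi^2_{red}, \phi_{e\!f\!f})$ along a
ladder of $\theta$ values (default 20 log-spaced points on $[1, 10^6]$,
which brackets the values of order $10^3$ typically selected for real
SAXS refinements), warm-starting each solve from the previous multipliers.
Along a decreasing ladder $\chi^2_{red}$ and $\phi_{e\!f\!f}$ are both
non-increasing, which the tests check to $10^{-6}$. `select_theta()`
offers:

* `max-curvature` — the "elbow": the $\theta$ maximizing discrete Menger
  curvature of the $(\log \phi_{e\!f\!f}, \log \chi^2_{red})$ polyline.
  Published analyses usually select the elbow visually from a marked
  region; an explicit curvature maximum makes the choice reproducible, and
  the method tag is always recorded in the output. Collinear or degenerate
  curves fall back to the threshold rule with a warning.
* `chi2-threshold` — the largest $\theta$ with $\chi^2_{red}$ below a
  bound (default 1, the discrepancy principle). We use this rule in the
  ground-truth recovery checks because it has a sharp statistical
  interpretation against noise of known scale.
* `manual` — echo a user value, recorded as such.

Selection is invariant under jointly rescaling all $\sigma_i$ by $c$ and
the $\theta$ grid by $1/c^2$ (tested).

## Forward models

**SAXS.** Frames are reduced to one bead per residue (C$\alpha$ by
default, residue centroid optionally). The Debye equation gives the exact
orientation-averaged intensity of the bead model,
$I(q) = \sum_{a,b} f_a f_b \, \mathrm{sinc}(q r_{ab})$, with constant
per-bead form factors taken from a bundled table of neutral amino-acid
residue electron counts (glycine-normalized; only relative values matter
because the global scale is refitted downstream) and an optional Gaussian
bead smearing $f(q) = f_0 e^{-q^2 R_{bead}^2/2}$ with $R_{bead} = 3$ Å.
No hydration-shell term is included — the known consequence is that the
coordinate-based $R_g$ need not match the Guinier $R_g$ of a measured
curve exactly, one reason to fit intensities rather than $R_g$ itself.
The implementation is verified against an $O(n^2)$ brute-force double loop
at $10^{-10}$ relative tolerance and against the forward limit
$I(q \to 0) = (\sum_b f_b)^2$.

**Guinier analysis.** `guinier_fit()` fits $\ln I$ vs $q^2$ on the
largest low-$q$ window satisfying $q R_g \le 1.1$, iterating the window to
self-consistency; $R_g = \sqrt{-3 \times \mathrm{slope}}$. The 1.1 cutoff
is a deliberately conservative default for expanded chains and is recorded
in the fit object. Exact Gaussian curves are recovered to 0.1% for
$R_g \in \{10, 20, 35.5, 50\}$ Å and to 2% under 1% intensity noise.

**Hydrodynamic radius.** Per-frame $R_h$ uses the empirical
disordered-chain relation of Nygaard and co-workers,
$R_g/R_h = a_1 (R_g - a_2 N^{1/3}) / (N^{0.6} - N^{1/3}) + a_3$ with
$a_1 = 0.216$ Å$^{-1}$, $a_2 = 4.06$ Å, $a_3 = 0.821$; the ensemble value
is the weighted mean of per-frame values. $R_h$ is useful as
cross-validation because NMR diffusion does not enter the SAXS fit.

**PRE.** For a spin label at a given residue, a pseudo-atom is placed 6 Å
from the labeled C$\alpha$ along the local chain normal (a rotamer-library
treatment of the nitroxide is out of scope at C$\alpha$ resolution;
explicit per-frame label coordinates can be supplied instead). The
population-weighted $\langle r^{-6} \rangle$ to every residue's C$\alpha$
is converted to the transverse Solomon–Bloembergen rate
$\Gamma_2 = K \langle r^{-6} \rangle\, (4\tau_c + 3\tau_c/(1 +
\omega_H^2 \tau_c^2))$ and reported as the intensity ratio
$I_{para}/I_{dia} = R_2 e^{-\Gamma_2 t} / (R_2 + \Gamma_2)$. Defaults
($\tau_c = 1$ ns, 700 MHz, $R_2 = 10\,\mathrm{s}^{-1}$, $t = 10$ ms,
$K = 1.23 \times 10^{16}$ Å$^6$s$^{-2}$) describe a typical nitroxide
label on an IDP and are all overridable; they are declared explicitly
rather than inherited from any external tool. The $r^{-6}$ law makes the
observable exquisitely sensitive to transient short distances, which is
why PRE is the natural cross-check on long-range contacts after SAXS
refinement.

## Uncertainties

Frames from a trajectory are time-correlated, so naive standard errors
underestimate. `block_error()` implements block averaging: contiguous
blocks of increasing size, weighted block means, standard error across
blocks, with the plateau taken as the maximum over the three largest
evaluated sizes. The default size ladder runs in powers of two from 16 up
to $n/8$: the standard error estimated from $B$ blocks carries a relative
sampling error of roughly $1/\sqrt{2(B-1)}$, so sizes admitting fewer than
8 blocks produce estimates too noisy to anchor a plateau and are excluded
by default (any explicit ladder is honoured, with under-filled sizes
skipped and warned about). For ensembles without time ordering a seeded
weighted bootstrap is provided instead. `weighted_density()` builds the
normalized weighted histograms used for $p(R_g)$ and $p(R_h)$ with
per-bin block errors on the indicator series — after a poor-prior
reweighting these densities become visibly spiky because a few frames
carry most of the weight, and the error shades show it.

## The synthetic study system

`generate_chain_ensemble()` samples a C$\alpha$-resolution self-avoiding
chain: virtual bonds fixed at 3.8 Å, hard-sphere excluded volume 4.0 Å
between beads at least two positions apart, seeded Metropolis sampling
mixing pivot and crankshaft moves (acceptance rates 0.3–0.6 across the
conditions used here), with an optional harmonic spring
$\tfrac12 k (R_g - R_g^{target})^2$ emulating force fields of differing
compaction; targets below the globule limit $2.2 N^{1/3}$ Å are refused.
An optional harmonic bond-angle stiffness exists mainly to give the
detailed-balance test an exactly solvable marginal. The defaults (burn-in
600 moves, stride 3, spring $k = 1\,k_BT/$Å$^2$) were chosen once as
reasonable for 40–140-residue chains and are recorded in the ensemble's
attributes.

`make_truth_case()` then defines ground-truth weights as an exponential
tilt on the per-frame radius of gyration,
$w^{truth}_j \propto e^{\kappa R_{g,j}}$ — deliberately inside the
exponential family that BME can represent exactly, so that recovery is a
sharp test of the machinery rather than an approximation study — and
synthesizes a noisy experiment from the truth: 19 SAXS intensities on
$q \in [0.01, 0.20]$ Å$^{-1}$ (the grid resolution typically used when a
curve must be re-evaluated inside a simulation) with Gaussian noise of 2%
of $I(q)$ plus a small floor ($10^{-3}$ of the maximum), typical of
modern size-exclusion SAXS data, and PRE ratios from five label sites
with 0.05 absolute noise. Tilts that collapse the truth below
$\phi_{e\!f\!f} = 0.01$ are refused as degenerate.

What the generator does *not* emulate: real force-field energetics,
secondary structure, hydration effects, or experimental systematics such
as imperfect buffer subtraction. Passing the recovery tests therefore
demonstrates the correctness of the inference machinery, not the accuracy
of any particular force field or forward model on real data.

The study conditions used by the acceptance checks are: 2000 frames of an
80-residue chain (unbiased prior, $\approx 24$–26 Å mean $R_g$), truth
tilt $\kappa = 0.15$ Å$^{-1}$, and a deliberately poor prior biased to
$R_g = 13$ Å whose most expanded frame still lies below the truth
average. On these conditions the overlapping prior refines to
$\chi^2_{red} \approx 1$ while retaining most frames
($\phi_{e\!f\!f} \gtrsim 0.9$), whereas the compact prior stalls at
$\chi^2_{red} \gg 1$ with $\phi_{e\!f\!f}$ of order $10^{-3}$ — the two
regimes one sees when refining real ensembles generated with
protein-water interactions that are respectively adequate or too weak.
In the recovery check we evaluate the posterior at the discrepancy-principle
$\theta$ (largest $\theta$ with $\chi^2_{red} \le 1$, falling back to the
minimum-$\chi^2$ point when the ladder never crosses 1); note that with a
floating scale and offset the SAXS curve pins the ensemble $R_g$ only
loosely, so the recovered mean can sit one-to-two combined standard
errors from the truth at 2% noise.

## The toy metainference sampler

`run_metainference()` is the desk-scale analogue of restraining a
multi-replica simulation on the fly. $R$ replicas of the chain are
sampled by Metropolis Monte Carlo; every data point contributes a single
Gaussian restraint on the scale-multiplied replica-averaged intensity
with total variance $\sigma_{SEM}^2 + \sigma_b^2$, plus the
$\tfrac12 \log 2\pi(\sigma_{SEM}^2 + \sigma_b^2)$ normalization term that
lets the per-point uncertainty $\sigma_b$ be sampled rather than fixed.
The implemented estimator, precisely: $\sigma_{SEM}$ is the standard
error of the scaled replica mean estimated from the instantaneous replica
spread; it and the $\sigma_b$/scale Metropolis updates are refreshed every
10 sweeps (matching the cadence at which an MD implementation would apply
the restraint); $\sigma_b$ performs a reflected random walk on
$\log \sigma_b$ within $[0.05, 20] \times \sigma_{exp}$ per point (the
energy is separable, so the updates vectorize); the intensity scale has a
flat prior on $[0.5, 2.0]$ with reflected uniform proposals; and the
reported curve is additionally averaged over a rolling 200-sweep window to
suppress fluctuations, mirroring the windowed weight averaging used to
stabilize on-the-fly restraints. Coordinate moves always feel the chain
potential plus the current restraint. Replica count defaults to 8
(configurable; production MD studies use 64), and Monte Carlo replaces
Langevin dynamics because engine-level details are out of scope here.

With the restraint off, the identical protocol samples the bare chain
potential; the test suite checks this control against direct chain
sampling, verifies detailed balance on a harmonic-angle marginal against
direct Boltzmann sampling, and — the headline property — runs 10 paired
restrained/control simulations of a compact-biased chain against
expanded-truth data and requires the restrained run to fit the data
better in at least 9.

## Numerical choices and edge cases

* Coordinates are Å and $q$ is Å$^{-1}$ everywhere; residue numbering is
  1-based in all I/O, frames are 0-correlated internal indices.
* Profile re-binning pools points by inverse variance within equal-width
  bins ($\sigma_{bin} = 1/\sqrt{\sum \sigma^{-2}}$, intensity and $q$ as
  the matching weighted means); empty bins are an error suggesting fewer
  bins. The re-binned grid is not uniquely determined by a target count
  and range — only the count and range are standard — so the equal-width
  convention is this package's choice.
* Degenerate inputs fail loudly and early: zero frames, inconsistent bead
  counts (naming the offending frame), non-monotone $q$, non-positive
  $\sigma$ (dropped with a counted warning), posterior mass off the
  prior's support, a constant calculated curve under offset fitting, flat
  profiles in Guinier analysis ($R_g = 0$ with a warning rather than a
  crash), spin labels at zero distance (residue excluded, logged).
* $0 \log 0 = 0$ in $S_{rel}$; $\mathrm{sinc}(0) = 1$ in the Debye sum.
* All stochastic functions take a `seed` and are bit-reproducible from
  seed plus configuration; loaders are deterministic and round-trip to at
  least 12 significant digits.

## Known limitations

The forward models are coarse: no hydration layer or atomic form factors
(so absolute agreement with measured curves relies on the fitted scale
and offset), an approximate label geometry for PRE, and an empirical
$R_g \to R_h$ map whose validity is itself a research question. The
synthetic truth lies inside BME's exponential family; real ensembles need
not. $\chi^2_{red}$ uses the divide-by-$m$ convention, so absolute values
are comparable across this package but may differ by $m/(m-k)$ from tools
that subtract fitted parameters. These are the reasons the package's
claims are about the refinement machinery, not about any particular
molecular system.
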