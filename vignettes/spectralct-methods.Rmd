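---
title: "One-step spectral CT material decomposition: models, solver, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-step spectral CT material decomposition: models, solver, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
polychromatic measurement model, the one-step reconstruction solver, the
synthetic study it reproduces, and the numerical decisions taken where the
design was genuinely open. It states no empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## The measurement model

A photon-counting fan-beam acquisition measures, for each energy bin $s$ and
ray $j$, the negative-log transmission

$$ p_{sj}(b) \;=\; -\log \sum_{m=1}^{M} S_{sm}
   \exp\Big(-\sum_{k=1}^{K} \mu_{mk}\, [A b_k]_j\Big), $$

where $A$ is the discrete X-ray transform (exact Siddon intersection lengths,
in mm), $b_k$ the dimensionless coefficient image of basis material $k$
(1.0 = reference density: tissue 1.0 g/cm³, bone 1.92 g/cm³, iodine
10 mg/mL), $\mu_{mk}$ the tabulated linear attenuation (1/mm per unit
coefficient) and $S_{sm}$ the normalized per-bin spectrum. Because the
spectrum is polychromatic, $p$ is a *sub-linear* function of path length —
beam hardening — and the per-bin effective attenuation
$\bar\mu_{sjk} = \partial p_{sj}/\partial [A b_k]_j$ depends on the object
itself (`linearization_weights()`).

Spectra come from a Kramers-form bremsstrahlung model
($N(E) \propto \mathrm{kVp}/E - 1$) filtered through aluminum and split at
the detector thresholds. This is a deliberate, declared simplification: the
original study used an external tube-spectrum simulator plus a detector
response model that are not reproducible from the publication. All downstream
quantities are therefore expected to land in the same *regime* as the
published ones rather than reproduce them digit by digit; the package's
simulation and reconstruction share one spectral model, so its own
experiments are exactly self-consistent.

Attenuation tables are embedded coarse knot sets (standard published
mass-attenuation values for water, cortical bone, iodine, aluminum over
20–150 keV) interpolated log-log; the iodine K edge at 33.17 keV is
represented by a double knot so interpolation never bridges the jump.

Measurement noise follows the photon-counting model: transmitted counts
$c_{sj} \sim \mathrm{Poisson}(I_0 e^{-p_{sj}})$ independently per bin, with
the log-domain datum $-\log(\max(c_{sj},1)/I_0)$. The one-photon clamp
bounds the projection by $\log I_0$ and is the standard convention for zero
counts; intensities above $10^8$ use the Gaussian limit of the Poisson so
counts never overflow integer storage.

## The one-step reconstruction model

Material images are estimated in a single optimization,

$$ \min_b \; \tfrac12 \lVert P(b) - P^M \rVert_2^2
   \;+\; \sum_k \lambda_k \lVert (\nabla b)_k \rVert_1 , $$

with anisotropic total variation (the $\ell_1$ norm is applied to each
forward-difference component separately, matching the scalar soft-shrink the
solver uses; replicate boundary). The solver is a proximal splitting with an
adaptive descent step:

1. **Proximal step.** $u = (\alpha I + \partial G)^{-1}(\alpha b - \lambda
   K^T y)$ — an approximate resolvent of the data term computed by
   ordered-subsets extended-SART sweeps (below); then the midpoint
   $\hat y = (1-t)b + tu$ and the shrunk dual surrogate
   $v = \mathrm{shrink}(\lambda K \hat y + y/\beta,\, 1/\beta)$.
2. **Descent step.** Directions $d_1 = \alpha(b-u) + \beta K^T \lambda
   (\lambda K \hat y - v)$ and $d_2 = v - \lambda K u$, step size
   $\gamma = \theta\,[\alpha\lVert b-u\rVert^2 + \beta\langle \lambda K b -
   v, \lambda K \hat y - v\rangle] / (\lVert d_1\rVert^2 + \lVert
   d_2\rVert^2)$, and updates $b \leftarrow b - \gamma d_1$,
   $y \leftarrow y - \gamma d_2$.

Convergence requires $\alpha > \beta > 0$, $\theta \in (0,2)$ and the
constant $c = 1 - t\beta\lVert\lambda K\rVert^2/(2\alpha) \ge 0$, which
`ipad_params()` enforces at construction using the classical bound
$\lVert K\rVert^2 \le 8$ for the 2-D forward-difference operator
(`op_norm_sq()` also provides a power-iteration estimate, used in the test
suite against a dense SVD).

### The inner resolvent

The resolvent of $G$ has no closed form; the package realizes it with
ordered-subsets extended-SART sweeps. Per subset of views, the polychromatic
model is linearized at the current iterate; each ray's $K \times K$ linear
spectral system $\bar\mu_j \,\delta t_j = r_j$ is solved exactly (a
vectorized cofactor solve when bins = materials = 3; near-singular rays get
a zero correction), and the path-length corrections $\delta t$ are
distributed over pixels with the SART normalization (divide by ray length,
accumulate, divide by pixel weight). After each subset the iterate is pulled
toward the proximal center with weight $\alpha\,\omega/n_{\mathrm{subsets}}$
and clamped to non-negative coefficients.

Two design points matter and were settled by measurement during development:

* **Per-ray spectral inversion, not gradient updates.** The three bins'
  effective-attenuation rows are nearly collinear, so bin-wise
  gradient-type corrections crawl in the ill-conditioned material
  directions (and, summed across bins, overshoot into a period-2
  oscillation). Inverting the small per-ray system — the approach of the
  extended-SART literature — decouples the material mixture exactly at each
  linearization point.
* **Warm starting across outer iterations.** The resolvent is defined as an
  argmin, which does not depend on the initializer; restarting the inner
  iterate at the proximal center every outer iteration caps the resolvent
  accuracy at one sweep and stalls the outer loop two orders of magnitude
  above its achievable floor. `ipad_run()` therefore warm-starts each inner
  solve at the previous proximal point.

### Parameters, units, defaults

| parameter | meaning | default | basis |
|---|---|---|---|
| `t` | balance of current vs proximal point in the midpoint | 0.02 | study setting |
| `theta` | step-size scaling in (0,2) | 0.2 | study setting |
| `n_subsets` | ordered subsets | 90 | study setting |
| `n_iter` | outer iterations | 100 | study setting |
| `alpha`, `beta` | proximal penalties, α>β>0 | 0.1, 0.05 | calibrated (below) |
| `lam` | per-material TV weights | 1e-6, 1e-6, 1e-5 | study setting (see below) |
| `relax` | inner relaxation ω in (0,1] | 1.0 | convention |
| `inner_passes` | sweeps per resolvent | 1 | cost parity with the unregularized baseline |

$\alpha$ and $\beta$ were never reported by the original study. They are not
free of consequence: the proximal anchor competes with the data term's
curvature, and an anchor of the same order as the SART-normalized curvature
(α = 1) freezes the slowest modes — the noise-free 128²/OS-90 run stalls
near total RMSE $3\times10^{-4}$ at 100 iterations, two orders above the
published regime. At α = 0.1 the same run reaches $2\times10^{-6}$. The
default is therefore 0.1/0.05, calibrated once against the published
noise-free convergence behavior.

The study's TV weights $\lambda = [10^{-6}, 10^{-6}, 10^{-5}]$ are kept as
the defaults. One property of these values deserves an honest statement: a
regularization weight is only meaningful relative to the fidelity scaling,
and against this package's fidelity ($\tfrac12\lVert\cdot\rVert_2^2$ over
all $S\!\cdot\!J$ ray-bin entries) the asymptotic TV force on the
reconstruction is bounded by $\lambda$ per unit gradient — five orders of
magnitude below the data term. At these weights the TV term is numerically
inert: the regularized and unregularized solvers differ on noisy data only
through the damped proximal-descent trajectory (the iterate moves a fraction
$\approx \theta$ toward the proximal point per iteration), which delays but
does not change the noisy fixed point. Scanning the weight scale confirms
there is no better operating point for this splitting: raising $\lambda$ by
three to four orders leaves the noisy error unchanged, and a further order
adds bias without suppressing noise (the dual variable's $1/(\gamma\lambda)$
timescale makes the $\ell_1$ prox act too slowly to denoise within 100
iterations). The package reports what the algorithm as published computes;
its noisy-data advantage over the unregularized baseline in the original
study is therefore attributed to that implementation's inner-solver
inexactness and detector model rather than to the written TV term, and this
package does not reproduce the full published margin.

## Phantoms — what the generator emulates

`disc_phantom()` reproduces the study's ground truth: a 14 mm tissue disc,
12 bone inserts (radii 0.2–2.4 mm), 8 iodine inserts (radii 0.2–1.6 mm,
concentrations 12 down to 5 mg/mL, i.e. coefficients 1.2–0.5). The insert
counts, radii and concentrations are specified by the study; the ring
layout (bone on a 6.5 mm ring with alternating small/large radii so inserts
stay disjoint, iodine on an 11 mm ring) is this package's convention — the
publication's exact positions are unrecoverable from its text and affect no
evaluated quantity materially. Edges are anti-aliased by 4×4 subpixel area
sampling; rendering is deterministic.

`thorax_phantom()` is an explicitly *synthetic* stand-in for the study's
segmented clinical slice (which would require a DICOM download): a body
ellipse, two iodine-filled lungs at 15 mg/mL, a spine disc and rib circles.
It preserves the things the beam-hardening experiment needs — large
tissue paths, disjoint material supports, realistic 492 mm field of view —
and claims no anatomical realism.

Consequently, passing tests show that the *method* behaves as published
under the stated geometry, spectrum class and noise model; they do not show
robustness to detector response, scatter, motion, or anatomical complexity,
none of which the generator emulates.

## Baselines and evaluation

`direct_decompose()` is the classical image-domain two-step: per-bin FBP
(flat-detector weighting, band-limited Ram-Lak with Hann apodization by
default, the filter being unstated in the study) followed by a per-pixel
inverse of the bin-mean attenuation matrix at zero coefficients —
deliberately without regularization or clamping, so its noise amplification
(the inverse matrix's row norms) and beam-hardening residual stay visible.
`osesart_run()` iterates the inner data-update sweeps alone and exhibits
the classical semi-convergence on noisy data. `monochromatic_image()`
synthesizes virtual monochromatic images $\sum_k \mu_k(E)\, b_k$ used by
the beam-hardening experiment.

RMSE/PSNR/SSIM follow the study's metric set. The study never defines its
PSNR peak or SSIM constants; this package fixes peak = ground-truth dynamic
range per material and the standard SSIM constants (11×11 Gaussian window,
σ = 1.5, K₁ = 0.01, K₂ = 0.03; verified against scikit-image to 10⁻⁶ in the
test suite), and the choice is echoed in every report. Exact reproduction of
the published table is therefore not promised — orderings and regimes are.

## Problem sizes used by tests and the acceptance script

The full published sampling is 256² pixels, 360 views, 512 detector
elements, OS = 90, 100 iterations. The package's acceptance test runs the
noise-free convergence experiment at exactly that scale, with two inner
sweeps per resolvent: at the full grid the per-sweep contraction of the
slowest image modes is weaker than at reduced grids, and the deep-error
regime within 100 outer iterations requires the extra resolvent accuracy
(the inner pass count is a resolvent-accuracy dial, not part of the model). The noisy
three-method comparison in the acceptance script runs at 128²/360
views/256 detectors (same field of view, same noise per ray, same OS and
iteration counts) — the published comparison's quantities are
resolution-dependent only weakly, and this scale keeps the full three-method
rerun to a few minutes on one CPU. The test suite's ordering checks use
64² for the same reason; the thorax beam-hardening experiment runs at 256².

## Known limitations

* No detector response model, scatter, pile-up, or cross-bin covariance;
  the spectrum is a parametric bremsstrahlung, so absolute published numbers
  are matched in regime, not digit by digit.
* The dual total-variation variable converges on the slow timescale
  $1/(\gamma\lambda)$; the dual optimality residual $d_2$ is bounded but not
  driven to zero within 100 iterations (the primal residual $d_1$ is — the
  test suite checks both behaviors).
* Fan-beam, flat detector, 2-D only; full 360° scans (no short-scan
  weighting).
* The NcADMM comparison method of the original study is a third paper's
  algorithm with unstated internals and is not implemented.
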