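---
title: "Hybrid swarm-genetic wavelength selection for Vis-NIR regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid swarm-genetic wavelength selection for Vis-NIR regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Visible/near-infrared (Vis-NIR) reflectance spectra of biological materials
are wide and strongly collinear: a 400–1800 nm sweep at 4 nm resolution
yields 351 variables, most of which carry redundant or irrelevant
information about any one quality indicator (a spoilage marker such as
total volatile basic nitrogen, TVB-N, in mg/100 g, or the CIELAB colour
coordinates L\*, a\*, b\*). Regressing on all 351 wavelengths invites
overfitting and obscures which absorption features — overtones of O–H,
N–H and C–H vibrations, myoglobin bands in the visible region — actually
drive a prediction. Wavelength selection is therefore a combinatorial
optimization over $2^{351}$ subsets, scored by how well a regression model
built on the subset generalizes.

`specswarm` implements one full workflow around that problem:

1. **Partitioning** — SPXY (sample set partitioning based on joint x–y
   distance) splits samples into calibration and prediction sets.
2. **Preprocessing** — SNV, MSC, Savitzky–Golay smoothing and first/second
   derivatives, compared by a data-driven bake-off on a fixed split.
3. **Selection** — a hybrid particle-swarm/genetic-algorithm (the package's
   core) plus binary PSO, GA, grey wolf optimizer and CARS baselines, all
   sharing a cross-validated boosted-tree fitness.
4. **Modelling** — a grid-searched XGBoost regressor on the selected
   wavelengths, reported as R²c, RMSEC, R²p, RMSEP and RPD.
5. **Attribution** — interventional TreeSHAP values on the prediction set,
   ranking the selected wavelengths by their contribution.

## The hybrid selector

Each of $N$ particles holds a continuous position $x \in [0,1]^p$;
coordinate $j$ selects wavelength $j$ when $x_j > 0.5$ (an all-below-threshold
position rescues its largest coordinate, so masks are never empty). The
fitness of a mask is the mean 3-fold cross-validated MSE of a small
fixed-hyperparameter gradient-boosted-tree model restricted to the masked
columns of the calibration set; fold assignment is frozen per run and
results are memoized by bit pattern.

Per iteration:

* Particles are ranked by fitness and split into an **elite** share
  (interpolating linearly from 50 % at $t=0$ to 20 % at $t=T$) and an
  ordinary remainder.
* **Elites** perform canonical PSO updates
  $v \leftarrow w v + c_1 r_1 (p_{best}-x) + c_2 r_2 (g_{best}-x)$ with a
  *nonlinear decreasing inertia weight*
  $w(t) = w_{min} + (w_{max}-w_{min})(1-t/T)^2$ (convex: fast early decay
  hands exploration over to exploitation; an exponential schedule is
  available as `inertia_schedule = "exp"` for sensitivity checks).
  Velocities are clamped to $\pm v_{clamp}$ and positions clipped to
  $[0,1]$.
* **Ordinary** slots are refilled by genetic variation: parents drawn by
  k = 2 tournament from the whole swarm, uniform crossover (probability
  `p_crossover`, coordinates swapped independently at rate 0.5, child
  velocities reset), then polynomial mutation whose perturbation is
  amplified by $1 + |\ell_j|$ with $\ell$ a Lévy-flight step drawn by
  Mantegna's algorithm ($\beta = 1.5$). The heavy Lévy tail produces
  occasional long jumps that cross between distant bit patterns.
* The population is initialized from chaotic logistic-map orbits
  ($x_{k+1} = 4 x_k (1-x_k)$, fresh orbit per particle, 100-iterate
  burn-in, degenerate starting points rejected), whose invariant density
  spreads mass towards the interval ends — useful when positions are
  thresholded.

Equal-fitness global bests are resolved towards fewer selected wavelengths,
then the lexicographically lower bit pattern: parsimony first, determinism
always. A fixed seed reproduces a run bit for bit; each selector draws from
its own derived RNG stream, so adding a baseline never perturbs another's
results.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `pop_size` / `max_iter` | 50 / 100 | reference budget; desk-scale runs use 20/30 |
| `w_max`, `w_min` | 0.9, 0.4 | inertia bounds of the quadratic decay |
| `c1`, `c2` | 2, 2 | cognitive/social acceleration |
| `v_clamp` | 0.5 | velocity bound (half the position range) |
| `elite_share_start/end` | 0.5 → 0.2 | adaptive elite fraction |
| `p_crossover` | 0.9 | probability a mated pair recombines |
| `p_mutation` | 2/p | per-coordinate mutation probability |
| `eta_m` | 2 | polynomial-mutation index (small ⇒ wide deltas) |
| `levy_beta`, `levy_scale` | 1.5, 1.0 | Lévy tail exponent and scale |
| `cv_folds` | 3 | folds of the fitness CV |

The mutation block deserves a note. With threshold binarization, a
mutation only changes the *mask* when the perturbed coordinate crosses
0.5. Under the textbook polynomial-mutation index $\eta_m = 20$ the median
perturbation is a few hundredths — the genetic phase then almost never
flips a wavelength in or out, and during development the hybrid stalled
far from the exhaustive optimum on 12-variable problems (3/10 runs found
it) while the plain bit-flip GA found it every time. We therefore
calibrated the mutation to be flip-capable ($\eta_m = 2$, rate $2/p$,
Lévy scale 1.0, crossover 0.9) on small development instances, after
which the hybrid reaches the enumerated optimum in 9–10 of 10 runs at
the same budget. These constants are the package's own: the hybrid's
published description leaves them unspecified.

### The inner fitness model

The fitness model is deliberately modest: 30 trees, depth 3, learning rate
0.3, histogram trees with 16 bins, single-threaded with a fixed seed. The
fitness only has to *rank* masks, not produce publishable accuracy — the
final reported model is grid-searched separately — and a small model keeps
the tens of thousands of fitness evaluations in a selector comparison
tractable. Column restriction is enforced through per-tree column sampling
with zero feature weights outside the mask, which lets every mask share
quantized per-fold matrices instead of rebuilding them; we verified the
trees use only masked features and that results are bit-reproducible.

## Baselines

* **PSO** — canonical global-best PSO, uniform random initialization,
  linear inertia decrease, the same binarization and fitness.
* **GA** — binary chromosomes, k = 2 tournament, uniform crossover,
  bit-flip mutation at rate $1/p$, elitism of one.
* **GWO** — grey wolf optimizer with α/β/δ leaders and control coefficient
  decreasing linearly 2 → 0, positions thresholded through the shared
  binarization.
* **CARS** — competitive adaptive reweighted sampling: per run, a PLS
  model on a Monte-Carlo 80 % row subset ranks retained variables by
  |coefficient|; an exponentially decreasing schedule $r_i = A e^{-k i}$
  calibrated to $r_1 = 1$, $r_{runs} = 2/p$ fixes the forced-retention
  count; adaptive reweighted sampling then draws variables with
  probability proportional to |coefficient|; the run whose variable set
  minimizes cross-validated PLS RMSE wins. PLS components (≤ 10) are
  chosen by the same CV. CARS is excluded from convergence-curve
  comparisons: its screening mechanism has no iterative fitness
  trajectory comparable to the evolutionary methods.

## Final models and metrics

The reported model is an XGBoost regressor grid-searched over
`n_estimators` ∈ {100,…,500}, `learning_rate` ∈ {0.01,…,0.3} and
`max_depth` ∈ {3,…,8} (3-fold CV RMSE; ties prefer fewer trees, then
shallower, then slower), with `gamma = 0`, `reg_lambda = 0`,
`reg_alpha = 1` fixed. All `n_estimators` candidates for a given learning
rate and depth are scored from one incremental fit per fold. Metrics follow
the chemometric conventions: R² on each set, RMSE in target units, and
RPD = SD(prediction-set reference values, n−1 denominator) / RMSEP. We
bind RPD to the prediction set because it is reported next to RMSEP; the
convention is stated because the quantity is sometimes computed on the
calibration SD instead.

## Attribution

`tree_shapley()` computes *interventional* TreeSHAP values: the worth of a
coalition S is the expected model output when features in S take the
explained sample's values and the rest are drawn from a background dataset
(default: the calibration set the model was fitted on). For a single
background row, every leaf reachable by mixing the two samples defines an
indicator game whose Shapley value is closed-form; summing over leaves,
trees and background rows (a pruned recursion, implemented in C++) gives
exact attributions in double precision. Local accuracy
(base value + Σ attributions = prediction) holds to ~1e-12 against the
package's own double-precision tree evaluation (the booster's float32
accumulation differs from it by ~1e-6 on deep ensembles, which is why the
attribution object carries its own `predictions`). The interventional
value function was chosen over the path-dependent variant because it
satisfies the dummy axiom exactly: a feature no tree splits on receives
zero attribution. `exact_shapley()` — full $2^p$ enumeration with
combinatorial weights, refusing p > 12 — serves as an independent oracle.

## The synthetic benchmark

Real beef spectra are not distributable, so the package ships a generator
whose defaults emulate the study geometry: 420 samples, 400–1800 nm at
4 nm, five Gaussian absorption bands at chemically plausible centres
(576, 728, 1080, 1236, 1450 nm), per-sample band amplitudes
U(0.5, 1.5) × base depth, a gentle linear baseline, multiplicative/additive
per-sample scatter (slope SD 0.02, offset SD 0.01), white spectral noise
(SD 0.003), and a TVB-N-like target: an affine map of the summed
informative-band amplitudes onto 6.65–66.05 mg/100 g plus noise with SD
2 % of the range (`target_noise_frac`, set 0 for an exactly affine
response). `storage_series()` adds monotone amplitude drift across storage
days, with per-slot base amplitudes shared across days so per-day mean
targets are strictly monotone by construction.

Band widths (σ of 12–18 nm) and near-equal amplitudes were fixed so the
generator meets its own recoverability contract: a univariate correlation
screen ranks every planted centre above the 90th percentile. Two effects
break that contract if ignored. In noise-free data, correlation is
scale-invariant, so a band's entire neighbourhood ties with its centre and
wide bands flood the top decile; a little noise makes |cor| peak at the
centres, where signal-to-noise is highest. And strong multiplicative
scatter delocalizes the signal — after SNV, the row mean and SD themselves
encode the summed amplitudes, so even flat spectral regions predict the
target. That second effect is worth remembering when interpreting selected
wavelengths on real scatter-corrected data: scatter correction can smear
band information across the spectrum, and the generator's mild scatter
deliberately keeps the planted problem localized.

What passing on this generator does **not** show: real tissue spectra have
correlated baselines, temperature-sensitive band shapes, and reference
noise that is neither Gaussian nor homoscedastic. The benchmark
demonstrates that the machinery finds planted, localized signal under mild
scatter — not that it reproduces any published accuracy on beef.

## Numerical choices and degenerate inputs

* SPXY distances are normalized by their maxima; an all-identical dataset
  is rejected. Distance ties break towards the lowest sample index, making
  the split fully deterministic.
* Savitzky–Golay edges use the asymmetric rows of the projection matrix (a
  polynomial fit to the first/last window), so any polynomial row up to
  the filter order is reproduced exactly at every position — mirror or
  zero padding would break that identity at the edges. Derivatives are
  divided by `step_nm^deriv` and reported per nm.
* SNV rejects zero-variance spectra by sample name; MSC rejects a
  regression slope below 1e-12 (a spectrum orthogonal to the centred
  reference carries no scatter information to invert).
* Constant targets give zero fitness for every mask (trees predict the
  mean exactly); R² is refused when SS_tot = 0, and RPD when RMSEP = 0.
* All xgboost fits are single-threaded with fixed seeds; split conditions
  are evaluated in float32 to match the booster's routing, which the
  attribution walker reproduces.

## Problem sizes used in the shipped checks

The test suite runs the comparative benchmark at the generator's full
420 × 351 geometry but a reduced selector budget (N = 20, T = 30, ten
paired seeds for the hybrid, PSO and GA) and a lighter inner fitness
(15 trees, learning rate 0.45, identical for all three algorithms so the
paired comparison stays fair), the oracle-equivalence check at
p = 12 with N = 30, T = 50 against a full 4095-mask enumeration, and CARS
at 20–30 variable problems. The acceptance script repeats the pipeline at
the same reduced budget with one grid-searched final model per mask. These
sizes are the package's chosen desk-scale study conditions; the selector
interfaces accept the full reference budget (N = 50, T = 100) unchanged.

## Known limitations

* The hybrid's constants are calibrated substitutes (see above), not a
  reconstruction of any published appendix.
* On the planted-band benchmark the hybrid consistently outperforms binary
  PSO, but a well-implemented elitist bit-flip GA is a strong competitor:
  in the shipped comparative check the GA's final cross-validated fitness
  is typically slightly lower than the hybrid's at equal population and
  iteration budget. On small problems (12 wavelengths) hybrid and GA both
  reach the exhaustively enumerated optimum. Interpreting the hybrid as
  uniformly dominant over a GA on every landscape would overstate what
  this implementation shows; its reliable advantage here is over PSO.
* The preprocessing bake-off fits one model per method on a single split;
  with near-tied methods the canonical order (RAW < SG < SNV < MSC <
  SG1D < SG2D) decides, which is a reporting convention, not a claim of
  superiority.
* CARS uses PLS coefficients (its canonical form), so its notion of
  variable importance differs from the tree-based fitness used by the
  evolutionary selectors; comparing their masks is meaningful, comparing
  their fitness values is not.
* `exact_shapley` is an oracle, not a tool: it enumerates $2^p$ coalitions
  and refuses more than 12 features.
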