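---
title: "Training coarse-grained neural-network potentials by inverse Monte Carlo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training coarse-grained neural-network potentials by inverse Monte Carlo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Bottom-up coarse-graining replaces an atomistic system by far fewer
interaction sites (here: a single site type, e.g. one site per solute
molecule with the solvent implicit) and asks for an effective interaction
that reproduces chosen structural observables of the fine-grained reference.
The canonical observable is the radial distribution function (RDF)
$g(r)$. Classic structure-matching methods — iterative Boltzmann inversion
and inverse Monte Carlo (IMC) — parameterize a *tabulated pair potential*
and iterate sampling/update cycles until the sampled RDF matches the
reference. A single pair table, however, is tied to the state point it was
fit at: effective CG interactions carry the solvent and density dependence
of the environment, and transfer poorly.

This package replaces the pair table by a Behler–Parrinello-style
neural-network potential on radial symmetry functions and trains it so that
Metropolis Monte Carlo sampling under the network reproduces one *or
several* reference RDFs. Because the network's site energies are nonlinear
functions of a site's whole radial environment, the model carries
many-body (density-sensing) terms that a pair table cannot express, which
is what buys transferability across state points.

## Model

**Descriptors.** For site $n$, descriptor $i$ of the set
$\{(\eta_i, r_{s,i})\}$ with shared cutoff $r_c$ is
$$G^2_{n,i} = \sum_{k \ne n} e^{-\eta_i (r_{nk} - r_{s,i})^2} f_c(r_{nk}),
\qquad
f_c(r) = \tfrac12\left[\cos(\pi r / r_c) + 1\right] \; (r \le r_c),$$
with minimum-image distances in an orthorhombic box. Two built-in sets are
provided (`builtinDescriptorSet()`): Set 1 (8 functions: one wide Gaussian
at $r_s = 0$, $\eta = 0.125\,$Å$^{-2}$, seven with $\eta = 4$ on 3–6 Å) and
Set 2 (24 functions, adding a wider one at 0 Å, nine narrow ones on 3–5 Å
and six of intermediate width on 3–8 Å). The exact centers of the
additional Set 2 groups are chosen uniformly spaced here; the wide
function at zero acts as a smooth local-density counter and is essential
for convergence in the core region.

**Network.** A bias-free feed-forward network maps each site's $G^2$
vector to a site energy (ReLU hidden layers, identity output); the total
energy is the sum over sites, $E = \sum_n E_n$. Without hidden layers the
model is linear, $E = \sum_n \sum_i \omega_i G^2_{n,i}$, and each weight
has the meaning of an effective pair potential evaluated at its Gaussian
center; with indicator (bin) descriptors this reduces *exactly* to the IMC
energy $\sum_\alpha \omega_\alpha S_\alpha$, where $S_\alpha$ is the pair
distance histogram — the package ships this as a test-only descriptor type
and verifies the identity.

**Units.** Coordinates are Å throughout. Energies (and hence weights and
learning rates) are in Kelvin, $E/k_B$, so $\beta = 1/T$. Only $\beta E$
ever enters the sampling and the gradients, so this choice is a pure
convention; it keeps potentials readable against $T$.

## Training

The sampled RDF is not a differentiable output of the network — it is an
ensemble average over a Markov chain. The loss
$L = \sum_\alpha (\langle g_\alpha\rangle^{NN} - g_\alpha^{ref})^2$
is differentiated with the statistical-mechanical fluctuation identity used
by IMC:
$$\frac{\partial \langle g_\alpha \rangle}{\partial \omega_i}
 = -\beta \left( \left\langle g_\alpha \frac{\partial E}{\partial \omega_i}
 \right\rangle - \langle g_\alpha \rangle \left\langle \frac{\partial
 E}{\partial \omega_i} \right\rangle \right),$$
whose three averages are accumulated during sampling
(`runSampling(collect_grad = TRUE)`); $\partial E / \partial \omega$ is an
ordinary reverse-mode pass through the site networks. One training
iteration = (per system) MC sampling → loss + gradient, gradients summed
over systems (the total loss is defined as the sum), one AMSGrad step.
For several reference state points the systems are sampled with
independent derived RNG streams, so results are independent of execution
order (sampling is single-process; the per-system streams also make the
results independent of any parallel scheduling). Because the sampled loss
is a noisy estimate, `trainModel(select = "best")` can return the weights
whose sampled loss was lowest rather than the final iterate — the same
model-selection rule the nonlinear reference protocol uses when further
training stops improving the loss. Runs checkpoint cleanly: the optimizer
state and weights returned by one call resume bit-exactly via
`opt_state` / `first_iteration`.

**Pretraining.** Starting from weights uniform in $[-1, 1]$ the sampler
would wander far from the reference ensemble. The potential of mean force
$V(r) = -k_B T \ln g^{ref}(r)$ (with a linear repulsive extrapolation
through the zero-RDF core, continuous at the first nonzero bin) provides
approximate configuration energies; pretraining repeatedly picks a
reference frame, displaces one site, and minimizes
$(\Delta E^{NN} - \Delta E^{PMF})^2$ by AMSGrad, averaging gradients over
systems. Only sites whose descriptor rows change contribute to
$\Delta E^{NN}$ and its gradient, so a step is $O(N K)$ with cached
descriptor matrices. The reference protocol uses 50,000 such steps.

**Optimizer.** AMSGrad with $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$, bias-corrected first moment and an element-wise
running maximum of the (bias-corrected) second moment. Learning rates are
energy-valued because the weights are; the defaults are $0.01\,k_BT$
(pretraining) and $0.005\,k_BT$ (training), i.e. `0.01 * T` and
`0.005 * T` Kelvin. These were fixed on the Lennard-Jones case to follow
the expected loss trajectory (a sharp drop over the first five iterations,
then a slow approach to the sampling-noise floor) and are exposed as
arguments.

## Monte Carlo details

Single-particle displacement moves, uniform in a cube of half-width
`max_disp`, Metropolis acceptance $\min(1, e^{-\beta \Delta E})$. The step
size adapts multiplicatively every 1000 steps *during equilibration only*
toward the target acceptance ratio (default 0.5) and is frozen for
production — adapting during production would violate detailed balance.
$\Delta E$ is computed incrementally (for networks: only descriptor rows
within $r_c$ of the moved site change) and is verified in tests against
full recomputation. Observables are collected every `output_freq`
production steps (default 1000); each training iteration restarts from a
randomly chosen reference frame. Non-finite energy changes reject the move
with a warning.

The RDF estimator histograms minimum-image pair distances into uniform
bins and normalizes by the ideal-gas expectation
$\tfrac{N(N-1)}{2}\, 4\pi r_\alpha^2 \Delta r / V$ with the shell volume
evaluated at the bin center (an `exact_shell` switch uses exact shell
volumes; the bin-center form is the common practice at the bin widths used
here, 0.025–0.05 Å). Sampler and analysis share one estimator.

## Reference generation

`ljReference()` / `stateSeries()` replace an external atomistic reference
with a self-contained Lennard-Jones fluid: Metropolis MC under the exact
truncated (unshifted) LJ potential at a configurable state point, returning
the reference RDF and 200 evenly spaced equilibrium frames. The default
state point is liquid argon, $N = 512$, $T = 95\,$K,
$\rho = 1374\,$kg/m³, with the standard argon parameters
$\sigma = 3.405\,$Å, $\epsilon/k_B = 119.8\,$K (configurable; these
particular values are the field's standard choice for LJ argon). The
default desk-scale budget is $2\times10^7$ steps ($10^6$ equilibration);
the RDF noise floor at any budget can be measured with `noiseFloor()`.

A *density series* with per-state scaling of the LJ well depth emulates a
concentration series: because the underlying pair interaction then varies
with the state point, no single pair table fits the whole family — the
same problem shape that makes effective CG potentials state-dependent.
The series used in the shipped transferability experiment couples a deeper
well to a lower density (densities 1400/1300/1200/1100 kg/m³ with well
depths 0.70/0.85/1.00/1.15 times the argon value), mirroring how stronger
effective solute–solute attraction accompanies lower density in a real
solution series; all four states sit in the clear liquid region of the LJ
phase diagram (reduced temperatures 0.86–1.41 at reduced densities
0.65–0.83 — state points near freezing or inside the liquid–gas
coexistence region give two-phase, hysteretic references and must be
avoided). The generator emulates the problem shape only; it does not
reproduce any specific solution's absolute values. What the synthetic references do **not**
contain: molecular shape and orientation averaging, hydrogen-bond network
structure, or the strongly non-additive solvation effects of a real
mixture. Passing the recovery and transferability tests therefore
demonstrates the estimator/optimizer machinery, not chemical accuracy on
real systems.

## The IMC baseline

`imcRun()` implements classic inverse Monte Carlo on the same machinery:
the energy is $\sum_\alpha \omega_\alpha S_\alpha$, sampling accumulates
$\langle S \rangle$ and $\langle S S^T\rangle$, and the update solves
$\mathrm{Cov}(S)\, \Delta\omega = -(S^{ref} - \langle S\rangle)/\beta$,
scaled by a regularization factor (default schedule: five iterations at
0.5, then five at 1.0, starting from the PMF table). The covariance is
inverted by SVD pseudo-inverse with a relative cutoff of $10^{-10}$;
never-visited core bins have zero covariance rows, drop out of the
update, and keep their PMF-extrapolated values.

`linearNNIMCEquivalence()` documents the formal bridge: with indicator
descriptors the linear network's energies and fluctuation-gradient rows
equal the IMC quantities exactly (up to the per-site double counting,
$\sum_n G_{n\alpha} = 2 S_\alpha$); with narrow Gaussians at the bin
centers the correspondence is approximate, and the comparison rescales by
the basis mass ratio $\kappa = \Delta r \sqrt{\eta/\pi}$ and compensates
the cosine cutoff. Note that narrowing the Gaussians at *fixed* bin width
does not approach the indicator basis (a Gaussian narrows toward a delta,
and the per-pair response variance grows $\propto \sqrt{\eta}$); the
deviation shrinks under matched refinement, $\eta \propto 1/\Delta r^2$
with $\kappa$ fixed, which is how the package tests convergence.

## Structural observables

Besides the RDF: triplet angle distributions in the first coordination
shell (default 6.2 Å) — for each central site all unordered neighbor
pairs, the angle at the center, histogram over $[0°, 180°]$ normalized to
per-bin probability and multiplied by the number of bins so values are
binning-independent (the geometric $\sin\theta$ measure is *not* divided
out; reference and model curves use the identical convention, so
comparisons are self-consistent) — and the three-body energy decomposition
$\Delta E^{(3)}(p) = E(1,2,p) - E(1,2) - E(2,p) - E(1,p)$ on a planar grid
around a fixed pair (presets 3.4, 4.5, 6.3 Å). For any linear model
$\Delta E^{(3)} \equiv 0$; a nonzero map is exactly the many-body content
of a trained network.

## Numerical choices and degenerate inputs

* ReLU$'(0) := 0$; summation over sites in ascending index order; both fix
  bit-reproducibility under a seed.
* Gaussian descriptor terms with exponent $> 40$ are treated as zero
  (below $4\times10^{-18}$, far under all test tolerances).
* Overlapping sites ($r = 0$) are legal descriptor inputs ($f_c$ finite);
  NaN positions are rejected.
* `rdf_rmax` (and $r_c$) beyond half the box is refused unless explicitly
  overridden; the override exists for small scaled-down boxes.
* An all-zero RDF has no PMF; a PMF's interior zero-RDF gaps carry the
  last finite value; the core below the first nonzero bin is linear with
  slope $\Delta V = V(r_{\alpha_0}) - V(r_{\alpha_0 + 1})$ per bin.
* Finite-difference gradient checks compare at the gradient's own scale;
  component-wise relative comparison is meaningless at $h = 10^{-6}$
  round-off.
* The model file stores weights as 17-significant-digit decimal strings:
  lossless for IEEE doubles, still a plain text format.

## Problem sizes used in the shipped tests

The test-suite and acceptance-script runs are scaled-down versions of the
reference protocol, chosen as the smallest sizes at which each property is
cleanly resolvable: LJ references with $N = 48$–216 and $2\times10^5$ to
$2\times10^6$ steps; the end-to-end recovery at $N = 125$ (reference
$2\times10^6$ steps, 5000 pretraining steps, 15 iterations of
$4\times10^5$ steps); the reference-protocol milestone check at $N = 216$ on
the reference 400-bin/0.025 Å grid with the full 50,000 pretraining steps
and reduced per-iteration sampling; the transferability experiment at
$N = 64$ over four state points. The full reference protocol
($N = 512$, 50 iterations of $8\times10^6$ steps) runs through exactly the
same code path via `runConfig(steps = 8e6, equil_steps = 2e6)` and
`n_iterations = 50`.

## A note on dead networks

A bias-free ReLU network can die: if an optimizer step drives some hidden
layer's pre-activations non-positive for *every* input the network emits
exactly zero forever (there is no bias to resurrect a unit, and the
gradient is identically zero). The symptom is an acceptance ratio pinned
at 1.0 with a zero gradient; `trainModel()` warns when it sees this.
During PMF pretraining the core extrapolation produces energy-change
targets of thousands of Kelvin, so aggressive learning rates push the
first layer hard — nonlinear architectures should be pretrained with more
steps at a smaller rate (the shipped experiments use 0.005 kBT over
30,000 steps for the 3x20 architecture) rather than fewer steps at a
large one. Linear models cannot die and tolerate much larger rates.

## Known limitations

Single CG site type; radial ($G^2$) descriptors only — no angular
symmetry functions; orthorhombic boxes; NVT displacement sampling only
(no NPT, no collective moves); minimal extended-XYZ trajectory I/O; the
IMC baseline treats total sampled steps as its only budget parameter. The
fluctuation-gradient estimator inherits the usual covariance-estimator
noise: at small sampling budgets gradients are noisy and the loss floor is
set by the RDF sampling noise, which `noiseFloor()` quantifies.
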