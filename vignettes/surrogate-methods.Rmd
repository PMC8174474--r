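---
title: "Methods: an actively trained flow surrogate and its oracle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an actively trained flow surrogate and its oracle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vastra)
```

This vignette records the model, the numerical choices, and the
limitations of `vastra` — the things a maintainer or a reviewer would want
stated rather than excavated from the code.

## Governing problem

The domain is a tube of length 100 mm, 10 mm wide at both ends, with
half-width

$$h(x; r) = 5 + r\,\cos^2\!\big(\pi(x-50)/100\big)\ \text{mm},$$

both walls deforming symmetrically about the midline $y = 5$. Negative
$r$ narrows the vessel (a stenosis); $h$ is smooth, symmetric about
mid-tube, leaves the end widths exact for every $r$, and reduces to the
straight tube identically at $r = 0$. This specific wall function is a
package design choice: the family it parametrises (end-preserving,
single-lobe, cosine-squared bump) is the simplest smooth shape with those
properties. Quantities that depend on the exact wall shape of *stenosed*
tubes are therefore comparable only qualitatively with other
implementations; straight-tube quantities are exact benchmarks.

Steady incompressible flow obeys

$$\rho (\mathbf u \cdot \nabla)\mathbf u - \mu \nabla^2 \mathbf u =
-\nabla p, \qquad \nabla\cdot\mathbf u = 0,$$

with no-slip walls, a parabolic inflow $\mathbf u = (I_f(y), 0)$,
$I_f(y) = f\,y(10-y)/25$, at $x = 0$, and a natural ("do-nothing")
outflow at $x = 100$ that also fixes the pressure gauge. Units are g, mm,
s, so pressure is in Pa; the defaults $\rho = 0.00106$ g mm$^{-3}$,
$\mu = 0.004$ g mm$^{-1}$ s$^{-1}$ are blood-like. At the design-region
extremes the Reynolds number is of order 10: laminar, steady, and
Newton-friendly.

## The finite-element oracle

The oracle is a Taylor–Hood discretisation — quadratic velocity, linear
pressure, inf-sup stable — on a mapped structured triangulation of the
parametric strip $\xi \in [0, 100]$, $\eta \in [-1, 1]$,
$y = 5 + \eta\,h(\xi)$. Design choices:

* **Structured, not Delaunay.** Meshes are bit-reproducible functions of
  $(r, \texttt{target\_nodes})$, refinement is a single knob, and point
  location is O(1) via the inverse map.
* **Mirrored diagonals, even transverse cell count.** Cell diagonals in
  the upper half mirror the lower half, so the triangulation — and hence
  the discrete solution — is exactly symmetric under $y \to 10 - y$ for
  symmetric shapes. The midline-symmetry test asserts this at $10^{-6}$
  relative; with a one-directional diagonal split it would fail at
  $\sim10^{-4}$.
* **Straight-sided elements.** Midside nodes sit at straight-edge
  midpoints (affine elements); wall midside nodes deviate from the exact
  curve by $O(\Delta x^2)$, which is below mesh-convergence error at the
  sizes used.
* **Newton from Stokes.** The linear Stokes solution (exact for the
  straight tube, where Poiseuille flow lies in the P2/P1 space) seeds
  Newton; the convective term and its Jacobian are assembled with a
  degree-5 (7-point) rule, which integrates every product exactly for
  affine elements. Tolerance $10^{-10}$ (absolute, max-norm of the
  nonlinear residual), cap 25 iterations; 2–4 iterations suffice across
  the design region. Dirichlet rows are eliminated, so boundary values
  hold exactly at nodes.
* **Probes.** Pressure differences are reported between A = (5, 5) and
  B = (95, 5) mm. Under fully developed flow the closed form over that
  90 mm span is $\Delta p = 2\mu f \cdot 90/25$: 0.0432 Pa at $f = 1.5$,
  0.0576 Pa at $f = 2.0$, which the solver reproduces to all printed
  digits (0.043 / 0.058 Pa) — this doubles as a guard against the classic
  $p$ vs $p/\rho$ unit slip.

## The network and its derivatives

The surrogate is a fully connected tanh network with inputs
$(x, y, f, r)$ and outputs $(\tilde\psi, \tilde p)$. Velocity is the
rotated gradient of the stream function, so continuity is an identity,
and the momentum residual needs third derivatives of $\tilde\psi$ in
$(x, y)$. No automatic-differentiation framework is available in this
stack — and the derivative machinery is the heart of the method — so the
compiled kernel propagates ten derivative channels (value, first, second,
third order in $x, y$) through each layer via the Faà di Bruno expansion
of tanh, and the parameter gradient is the hand-derived exact adjoint of
that propagation. Tests hold every channel to central finite differences
(≤ $10^{-10}$ observed) and the parameter gradient to $\sim10^{-7}$
relative. Double precision throughout: third derivatives of tanh
networks are precision-sensitive.

Conditioning choices, fixed once and used everywhere:

* **Input normalisation.** Inputs are affinely mapped to order one
  (shifts 50, 5, 0, 0; scales 50, 5, 2, 2). Raw millimetre coordinates up
  to 100 would saturate first-layer tanh units at standard
  initialisation. The chain factors enter through the derivative-channel
  seeds, so all reported derivatives remain with respect to physical mm.
* **Output scaling.** Raw outputs are multiplied by 10 (stream function)
  and 0.1 (pressure): the largest stream-function amplitude in the region
  is the inflow flux $20f/3 \approx 13$ mm²/s at $f = 2$, and pressures
  are a few hundredths of a Pa. Without this the optimiser must grow
  output weights two orders of magnitude before fitting can start, which
  dominates short training budgets.
* **Initialisation.** Weights are truncated-normal, truncated at two
  generating standard deviations and rescaled by $1/0.8796$ so the
  post-truncation variance equals $2/(N_{in}+N_{out})$ per layer; biases
  start at zero. (Plain truncation without the rescale would undershoot
  the nominal variance by 22.6 %.)

## Loss and training

$$L = \alpha_u L_u + \alpha_{NS} L_{NS} + \alpha_p L_p +
\alpha_{BC} L_{BC}, \qquad \alpha = (1, 10^6, 10^2, 10^6),$$

with all components *unnormalised sums* of squares — the weights
compensate, and the printed form of the components is preserved exactly.
$L_{NS}$ is collocated at the training points themselves (the FEM nodes
retained for that parameter point); no extra collocation cloud is used.
Each sampled parameter point contributes one reference pressure, taken
from the FEM pressure interpolated at (95, 5) mm, to pin the per-$\theta$
pressure constant. Outflow nodes carry no Dirichlet velocity term.

Training is full-batch and two-stage: Adam (learning rate $10^{-4}$),
then L-BFGS-B. Two numerical points deserve emphasis:

* **Quasi-Newton memory.** The $\alpha$-weighted objective mixes
  curvature scales across six orders of magnitude. With the usual
  L-BFGS memory of 5 (or even 10) pairs the line search stalls on a
  stiff manifold and the data misfit stops improving; with memory 20 the
  same budget reduces the single-tube data misfit by an order of
  magnitude. The package fixes memory 20.
* **Divergence aborts.** A non-finite loss aborts training and names the
  offending component; the bounded activations mean this occurs only
  under pathological step sizes.

Training is deterministic given the starting state; all randomness
(initialisation, data subsampling, the random baseline) flows from one
experiment seed.

## The active-learning loop

The design region $[-2, 2]^2$ is discretised into a grid G (13 × 13 at
full scale). Data are seeded at the four corners and the centre — five
FEM solutions. Each iteration: train on everything gathered so far;
evaluate $L_{NS}$ at *every* grid point (spatially, at the vertex nodes
of a geometry-only mesh for that shape — no FEM solve); stop if the map
is everywhere strictly below the threshold or the grid is exhausted;
otherwise solve the oracle at the unsampled point with the largest
residual (ties break to the lowest row-major index, $r$ varying fastest)
and append. Appending — never replacing — is what prevents catastrophic
forgetting. The *random* baseline replaces the selection by a uniform
draw over unsampled points; the *uniform* baseline sweeps the coarse
sub-grid $f, r \in \{-2, -1, 0, 1, 2\}$ in row-major order, skipping
already-sampled points, and signals exhaustion after its 20 unseeded
points.

The termination threshold is an *absolute* operating criterion (100 at
full scale). The residual map scales with the node count and the network
amplitude, so the mini preset — smaller meshes, smaller network — lives
orders of magnitude below it; the mini threshold is set to $10^{-6}$ and
mini runs are in practice iteration-budget-limited. Threshold semantics
(strict inequality, everywhere on G) are identical in both presets.

## Error metrics

Per parameter point, fields are compared as piecewise-linear interpolants
on the vertex triangulation of the oracle's mesh, and the squared
difference — a quadratic per triangle — is integrated *exactly* (no Monte
Carlo). The aggregate error over the grid is

$$E = \sum_G \Big( \int (u_x - \tilde u_x)^2 + \int (u_y - \tilde u_y)^2
+ \int (p - \tilde p)^2 \Big)\, dA,$$

mixing velocity and pressure units as printed; it is used only for
relative comparisons across iterations and strategies. Boundary fidelity
is reported as the mean nodal Euclidean error against the *imposed*
boundary data (not the FEM field) on the wall and inflow segments. The
inverse-design sweep queries only the network: $\Delta\tilde p(r)$
between the probes over $r \in [0, -2]$ in steps of 0.025 (81
geometries), and the first $r$ whose value, rounded to 3 decimal places,
reaches the rounded target is reported (sweeping from 0 toward $-2$;
targets at or below baseline return the baseline).

## Preset scales

`paper_full` carries the full-scale settings: 13 × 13 grid, 4 × 80
network, 20000 Adam + up to 50000 L-BFGS iterations per training,
~1000-node meshes, full data retention ($c = 1$), threshold 100. A full
run at this scale is a multi-hour commitment and is not exercised by the
test suite.

`mini` is the package's verification scale, used by the tests and chosen
once: 5 × 5 grid, 2 × 32 network, 2000 + 500 iterations, ~300-node
meshes, and data retention $c = 0.25$ — a uniform random quarter of the
nodes per parameter point. The quarter-density choice follows the
partial-data ablation logic (the loop still functions with 25 % of the
nodal data) and keeps a ten-run strategy comparison within a desk-CPU
budget. At this scale the surrogate is deliberately *under-trained*: the
stiff $\alpha$-weighted objective at a 2500-iteration budget fits the
velocity field only partially. What mini-scale results do show: the loop
mechanics (selection, appending, termination) and a steady reduction of
E with iterations under every strategy. What they do not show: the
near-interpolation accuracy of the full-scale configuration, or anything
about real (3-D, pulsatile, turbulent, measured) hemodynamics — the
oracle itself is the ground truth here, and the synthetic family has
exactly two degrees of freedom.

One mini-scale finding deserves explicit statement. Residual-based
acquisition presumes that the momentum residual is a usable proxy for
solution error, which holds for a surrogate trained to near-convergence
at each iteration. At the mini budget the opposite occurs: in regions of
parameter space the under-trained network effectively ignores, its
output is smooth and the residual is *small* exactly where the error is
large (measured rank correlation between the residual map and the true
squared error is mildly negative, around $-0.2$). The active strategy
then concentrates samples where the network already has structure, and
over five seeds its mean error E after eight iterations trails the
random baseline (both improve markedly; active is also noticeably
higher-variance across seeds). The full-scale ordering — active ahead of
random — should therefore be expected only when the per-iteration
training budget is large enough for the residual map to become
informative; verifying it is outside a desk-scale budget.

## Known limitations

* The wall-shape family is a package choice; stenosed-tube pressure
  values are not comparable digit-for-digit with implementations using a
  different (unpublished) wall function.
* 2-D, steady, laminar only; stabilised equal-order elements, curved
  elements, and 3-D are out of scope.
* The acquisition map prices every grid point with a geometry-only mesh
  of the same nominal size as the training meshes; at very coarse sizes
  the map inherits that mesh's sampling of the residual field.
* `find_r_for_target` assumes the swept quantity is monotone in practice
  near the crossing; it reports neighbours so a non-monotone table is
  visible to the caller.
* The uniform baseline has no continuation rule once its sub-grid is
  exhausted (none is defined); it stops and says so.
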