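---
title: "Kernel associative memory with reconsolidation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel associative memory with reconsolidation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rekam)
```

This vignette is the package's own account of the science it
implements: the memory model, the Riemannian geometry behind the exact
reconsolidation update, the numerical choices, the synthetic study
conditions, and the known limitations. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does
not itself compute.

## The kernel associative memory

A memory stores $m$ real-valued patterns $x_1,\dots,x_m \in
\mathbb{R}^n$ as the columns of $X$. In feature space the synaptic
operator is the orthogonal projector onto
$\mathrm{span}\{\varphi(x_1),\dots,\varphi(x_m)\}$, where $\varphi$ is
the feature map of a Mercer kernel $\kappa$. The projector is never
formed; it is accessed through kernel evaluations via the Gram matrix
$G_{ij} = \kappa(x_i, x_j)$. One recall step maps a state $y$ to

$$y' \;=\; \sigma\!\big(X\, G^{-1} h(y)\big), \qquad
  h_i(y) = \kappa\!\big((x_i - y)/\lambda_i\big),$$

with a bounded monotone activation $\sigma$ applied coordinate-wise
and per-attractor radius scales $\lambda_i > 0$ (all one unless an
extinction schedule is running). Recall iterates this map until the
max-norm update falls below a threshold ($10^{-6}$ by default, at most
100 iterations unless a driver raises the budget).

Because $c = G^{-1} h(x_j) = e_j$ at a stored pattern, every attractor
is an exact fixed point whenever $\sigma$ is the identity there. For
this reason the default activation is a **piecewise-linear clip** to
the output box (identity inside), with `tanh` available for
experimentation; the box defaults to $[-1,1]$ when the data fit in it
and to the data range otherwise.

The construction needs more than Mercer positivity: the feature images
of the stored patterns must be **linearly independent** so that $G$ is
invertible (the strong-Mercer condition). `rekam()` checks this at
load time with a relative eigenvalue tolerance of $10^{-10}$ (the
practical double-precision rank threshold) and refuses rank-deficient
sets with a condition report. Gaussian-family kernels satisfy the
condition for any set of distinct patterns, which is what frees the
attractor count from the input dimension — the test suite loads $m =
3n$ attractors and recalls each one. If the condition number of $G$
exceeds $10^{12}$, a stabilizing ridge of $10^{-10}\,\mathrm{tr}(G)/m$
is added with a warning.

Attractor edits (`replace_attractor()`, `add_attractor()`,
`remove_attractor()`) update the Gram matrix incrementally — only the
affected row and column are re-evaluated — and refresh the Cholesky
factorization; every 32nd edit triggers a full recomputation from the
patterns to bound accumulated drift. Each edit re-runs the
strong-Mercer check and is refused if independence would be lost.

### Kernel families

* `scalar_product` — $\kappa(x,y) = x^\top y$. The feature space is the
  input space; the memory is the classical pseudoinverse (projection
  rule) Hopfield network, and the manifold of memories is a Grassmann
  manifold. Not uniform.
* `gaussian` — $\exp(-\|x-y\|^2/2\sigma_v^2)$. Default bandwidth: the
  median pairwise distance of the stored patterns
  (`median_bandwidth()`), the standard scale heuristic.
* `gaussian_indicator` — a two-block Gaussian for patterns carrying a
  final list-context indicator $r \in [0,1]$, with separate bandwidths
  $\sigma_v$ (data) and $\sigma_r$ (indicator) balancing the two
  blocks.
* `weighted_gaussian` —
  $\exp(-((x-y)^\top \mathrm{diag}(w)(x-y) + b)/2\sigma_v^2)$.
  The default weight rule is the inverse per-component standard
  deviation of the training set (`weights_inverse_sd()`); a
  class-statistics alternative (`weights_class_stats()`, a
  Fisher-ratio style score built from per-class means and variances)
  is provided but is not the default, since the inverse-spread rule
  performs better on the tracking task.

All Gaussian families are *uniform* — they depend only on the
difference of their arguments — which is exactly the precondition for
radius scaling.

### Attraction-radius scaling

The printed form of the scaling rule is ambiguous, so the package
fixes the semantics as **argument scaling**: the scaled response
evaluates the kernel at $(x_i - y)/\lambda_i$. This is the reading
that (a) requires uniformity precisely where the theory demands it and
(b) makes the basin radius scale *proportionally* to $\lambda_i$: for
two Gaussian attractors the response boundary sits where
$d_1/\lambda_1 = d_2$, so doubling $\lambda_1$ moves the boundary to
the $2:1$ point of the connecting segment (a bisection test pins this
at $2/3$). Driving $\lambda_i \to 0^+$ makes the attractor
unreachable — extinction. The alternative reading, dividing the
response $h_i$ by $\lambda_i$, is available as
`rekam(..., scale_mode = "response")` for comparison only.

### Winner readouts and the far-probe regime

Two readouts report *which* memory an input engages:

* the **response winner** (`nearest_attractor()`): the attractor with
  the largest radius-scaled kernel response;
* the **recall winner**: the response winner at the fixed point of the
  iterative recall map.

For probes inside a basin the two agree. For probes far from every
attractor — e.g. uniform random vectors in a high-dimensional box —
the iterative map is dominated by its first Gram-solve step, which
contracts any far probe into the span of the stored patterns, where
one or two "central" attractors absorb almost everything. In that
regime the recall winner reflects the global geometry of the stored
set, not the probe, and retrieval frequencies degenerate to
winner-take-all. The extinction and list-learning drivers therefore
default to the response readout (`readout = "response"`), which keeps
the per-attractor retrieval probabilities meaningful, is *exactly*
monotone in $\lambda$ under common random numbers, and coincides with
recall wherever recall is well-behaved; `readout = "recall"` is kept
as an option. This choice and its rationale are deliberate design
decisions of the package, documented here rather than hidden in
driver defaults.

## The manifold of memory states

Two memories with the same kernel and the same $m$ correspond to two
rank-$m$ feature-space projectors $P_X$ and $P_Y$. With the
cross-kernel matrix $K_{ij} = \kappa(x_i, y_j)$, the matrix
$G_X^{-1} K G_Y^{-1} K^\top$ has eigenvalues $\cos^2\theta_k$ — the
squared principal cosines between the two feature subspaces — and
everything geometric follows from them:

* **chordal distance** (`memory_distance()`, default):
  $\|P_X - P_Y\|_F = \sqrt{2\sum_k \sin^2\theta_k}$, bounded by
  $\sqrt{2m}$. For the scalar-product kernel this equals
  $\|XX^+ - YY^+\|_F$ exactly, which is how the tests pin the formula
  to an explicit-projector oracle.
* **intrinsic distance** (`method = "intrinsic"`):
  $\sqrt{2\sum_k \theta_k^2}$, the arc length of the geodesic of the
  Riemannian metric induced by the Frobenius embedding.

### Why the geodesic optimizer uses the intrinsic distance

`geodesic_point(M1, M2, t)` returns the minimizer of the weighted
Fréchet objective

$$J(Z) = (1-t)\, d(M_1, Z)^2 + t\, d(M_2, Z)^2$$

over the attractor columns of $Z$. The choice of $d$ matters. With
the *chordal* $d$, the minimizer does **not** sit at arc-length
fraction $t$: on the simplest case (lines in the plane, projectors
$P(\phi)$) the objective is $2(1-t)\sin^2(\phi-\theta_1) +
2t\sin^2(\phi-\theta_2)$, whose minimizer deviates from
$(1-t)\theta_1 + t\theta_2$ by $\approx \tfrac{2}{3}\alpha^3
t(1-t)(2t-1)$ for separation $\alpha$ — zero only at $t = 1/2$.
Likewise, the sum of chordal distances is *not* constant along the
geodesic (it decreases toward the endpoints), so "no point beats the
geodesic point's distance sum" only holds in the intrinsic metric.
With the *intrinsic* $d$ the weighted Fréchet minimizer is exactly the
geodesic point at fraction $t$ (within the injectivity radius), and on
the scalar-product kernel it reproduces closed-form Grassmann
geodesics — the rotating-line test verifies this to $10^{-4}$.
`memory_distance()` itself stays chordal, as pinned by the projector
oracle; only the optimizer objective and the betweenness validation
use the intrinsic form. Both are computed from the same eigenvalues,
so the cost is identical.

### The optimizer and its gradient

$J$ is minimized with BFGS on $\mathrm{vec}(Z)$ using an **analytic
gradient**. Writing the principal cosines as generalized eigenvalues
$\lambda_k$ of $(K G_X^{-1} K^\top,\; G_Z)$ with eigenvectors
normalized by $u^\top G_Z u = 1$, first-order perturbation gives
$d\lambda_k = u_k^\top dA\, u_k - \lambda_k u_k^\top dG_Z u_k$, and
both $dA$ and $dG_Z$ contract against closed-form kernel derivatives
(for all Gaussian families $\partial_1\kappa(z,x) =
-2\kappa(z,x)\,a\odot(z-x)$ with the family's quadratic-form
coefficients $a$). The chain ends with
$g'(\lambda) = -2\theta/\sin 2\theta$ for
$g(\lambda) = \arccos^2\sqrt{\lambda}$, clamped at its limits. A unit
test checks the gradient against central finite differences.

A derivative-free Nelder–Mead fallback is available
(`opts = list(method = "nelder_mead")`). A coordinate pattern search
was considered and rejected: in $n\cdot m$ coordinates it cannot reach
the $10^{-4}$–$10^{-8}$ accuracy the geometric tests require at
realistic cost. Remaining numerics: the search is initialized at the
coordinate-space convex combination $(1-t)X_1 + tX_2$ after greedy
response-based column alignment (`align_attractors()`, avoiding
permutation ambiguity); $t \in \{0, 1\}$ and coincident endpoints
return immediately; eigenvalues are clipped into
$[10^{-12}, 1]$; a Cholesky failure during the line search returns a
large objective value, which BFGS backtracks out of. Default budget:
500 iterations, relative tolerance $10^{-12}$.

## Reconsolidation

`reconsolidate(M, s, step)` recalls the stimulus $s$, identifies the
winning attractor $j$, forms the stimulus-substituted memory $X_1$
(column $j$ replaced by $s$), and moves the memory a fraction
$\varepsilon$ = `step` of the way toward $X_1$:

* **exact mode** travels along the manifold geodesic
  (`geodesic_point(M, X1, eps)`) — a global update in which all
  attractors may shift;
* **approximate mode** replaces the geodesic with a straight line in
  coordinate space: only column $j$ moves, to
  $(1-\varepsilon)x_j + \varepsilon s$.

The two differ by $O(s^2)$ in the stimulus displacement $s$; the
acceptance suite fits the log–log slope of the discrepancy over the
ladder $s \in \{0.4, 0.2, 0.1, 0.05\}\cdot d_0$ and requires it in
$[1.8, 2.2]$. The ladder base $d_0 = 0.5$ (attractor scale
$\approx 1$, bandwidth $\approx 2$) keeps all four rungs inside the
small-displacement regime where the quadratic term leads; with the
largest rung at $d_0 = 1$ the highest point visibly leaves the
asymptotic regime and flattens the fitted slope.

The **gang variant** (`gang_reconsolidate()`, or `gang_size > 1` in
approximate mode) moves the $L$ most responsive attractors with
per-attractor steps $\varepsilon_j = \varepsilon\, h_j / h_{(1)}$.
Proportional-to-response is the minimal weighting consistent with a
relevance ordering of the co-updated attractors; it is exposed as a
pluggable function for exploration. Note the step is a *fraction of
each attractor's own segment* toward the stimulus, so a far neighbor
can move farther in absolute terms than the winner.

Every update appends `(winner, step, mode, surprise)` to the memory's
journal, where **surprise** is the manifold distance $d(M, X_1)$ — a
measure of how novel the stimulus is to the memory. Surprise is
logged, never used to gate updates; gating policies (time windows,
memory age, prediction error) are the caller's business. If the
stimulus recall does not converge, no update happens and a warning is
raised. Whether recall uses the radius scales is not specified by the
theory; the package always applies them (post-scaling recall), which
keeps extinction and reconsolidation composable.

**Extinction** (`extinguish()`) walks one attractor's scale down a
decreasing schedule, estimating its retrieval frequency at each value
on probes drawn uniformly from the data bounding box, with the same
probes reused across the schedule (common random numbers — the curve
is then exactly monotone under the response readout). The
event-based form (`extinction_event()`) multiplies $\lambda$ by a
decay factor, 0.7 per reactivation-without-reinforcement by default.

## Continuous-time recall

`continuous_recall()` integrates
$\dot y = \Lambda \odot (-y + F(y))$ where $F$ **is** the discrete
recall map. This is a deliberate pin: the discrete iterates are then
exactly the Euler steps with $\Lambda\,dt = 1$, so the two
formulations share their fixed-point set by construction, and the
relaxation is placed outside the activation to match the Hopfield
form the model is isomorphic to. For the scalar-product kernel with
unit scales the readout $X G^{-1} X^\top y$ is algebraically
$X X^+ y$, so the system equals the continuous Hopfield network under
the pseudoinverse learning rule
(`hopfield_equivalence_check()` integrates both sides and reports the
maximum trajectory deviation, at roundoff level unless a conditioning
ridge is active). Defaults: $\Lambda = 1$, RK4, $T = 50$,
$dt = 0.05$; explicit Euler refuses $dt \ge 2/\max\Lambda$.
Reconsolidation depends only on the stimulus and the attractors —
never on the recall clock — so exact and approximate updates work
identically under discrete and continuous recall.

## Synthetic study conditions

The simulations run on procedural stimuli; all generators are seeded
and bit-reproducible.

**Smooth object images** (`gen_smooth_images()`): white noise on a
square grid, separable moving-average smoothing, common RMS amplitude
(0.35), clipped to $[-1,1]$. They emulate the spatial correlation and
bounded range of photographs of objects; they do *not* have natural
image statistics (no edges, no segmentation, no category structure),
so all conclusions from them concern the memory dynamics, not vision.

**List learning.** Two 20-item lists (40 attractors, as in the human
protocol), each item an image plus one indicator channel encoding
association with the List-1 learning context: List-1 items load at
$r = 1$, List-2 items at $r = 0$. The reminded group's List-2
learning events shift those items' indicators toward 1 with step
$\varepsilon$; the control group gets no updates. The test presents
1000 noisy probes per list (noise 10% of the pooled data STD) with
the indicator at `r_init`, and classifies each probe by the winner's
list; percentages are normalized within group to sum to 100.

The human percentages are matched by the documented two-stage sweep
(`calibrate_list_learning()`): stage 1 fits the control group over
the kernel balance ($\sigma_v$ as multiples of the median image
distance) and `r_init`; stage 2 sweeps $\varepsilon$ (coarse grid
plus 0.01-step refinement) for the reminded group. Because the
control percentage plateaus in $\sigma_v$, stage 1 keeps, per
`r_init`, the flattest data kernel still on the plateau — the choice
that gives the reminded group its widest dynamic range — and the
final pick minimizes the joint deviation from both group targets.
Study conditions fixed once: `image_dim = 64`, `smooth = 3` (the
heavier smoothing spreads cross-item distances so intrusion rates are
graded rather than all-or-nothing), $\sigma_r = 1.1$ (a soft context
channel that biases rather than dominates), response readout (see
the far-probe discussion above: with this kernel the *iterated*
recall of context-ambiguous probes is governed by slow indicator
drift and Gram coupling rather than by the probe's own similarity
structure, and the intrusion rates it produces are artifacts of the
iteration budget). The $\varepsilon$-sweep is monotone on
$[0, r_\mathrm{init}]$; beyond the query's own indicator value the
shifted indicator overshoots and the advantage recedes — a geometric
property of the Gaussian indicator block worth knowing when choosing
sweeps.

**Extinction.** Ten images (light smoothing, `smooth = 1`, keeping
the stored set exchangeable), one randomly designated the shock
memory; 1000 box-uniform probes per schedule point; ten repeats with
fresh images. The schedule is dense near $\lambda = 1$ — box-uniform
probes sit at nearly equal distances from all stored images, so the
shock basin loses its probe mass over a narrow band of scale
reductions — and then tails down to $10^{-3}$ to confirm complete
extinction. By exchangeability the baseline retrieval frequency has
expectation $1/10$.

**Rotation tracking.** Stroke-drawn glyphs (anti-aliased distance
fields of jittered control-point strokes) stand in for handwritten
digits: 5 classes × 4 exemplars × 45 angle steps of 4° (0°–176°),
900 stimuli — the reduced-size analogue of rotating 9,000 digits.
The five default prototypes (L, T, V, triangle, F) are deliberately
**rotation-asymmetric**: point-symmetric shapes map onto themselves at
180° and confound the classification measure at large angles, the
same confound noted for symmetric digits; symmetric prototypes
(plus, bar, Z, H, slash) are available as classes 6–10. Rotation is
exact-center bilinear resampling (`rotate_image()`), checked by
round-trip and symmetry tests. Preprocessing is PCA keeping the
smallest component count reaching 96.77% explained variance; the
memory uses the weighted Gaussian kernel with inverse-spread weights
and bandwidth 0.7× the median weighted attractor distance (below 1 so
the recall map contracts briskly). Presentations run in increasing
angle order (or shuffled for the gradualness control); each stimulus
is recalled — winner's class vs. true class — then reconsolidated
with $\varepsilon = 0.5$ under the configured mode. Recall in PCA
space has a slow geometric relaxation tail, so the driver allows up
to 1000 iterations at a $10^{-5}$ threshold; unconverged recalls skip
their update with a warning, as reconsolidation semantics require.
"Final accuracy" for mode comparisons is the run-level overall
recognition accuracy; per-angle accuracies at this size rest on 20
stimuli each (5-point granularity).

### The exact-vs-approximate comparison at desk scale

The exact mode behaves qualitatively differently from the local
update in this reduced experiment, and the difference is worth
understanding rather than hiding. Replacing one attractor changes
the feature span, and the attractor chart cannot express the
resulting span rotation without moving *every* column a little — the
global update is exactly what produces gang effects, but it has three
sharp edges at this scale. First, same-class exemplars are close, so
the chart is ill-conditioned: small feature-space motions correspond
to large coordinate motions, and hundreds of sequential geodesic
updates accumulate them. Second, occasional misrecalls (inevitable
at intermediate angles) produce large-surprise updates that damage
only one column in approximate mode but perturb the whole memory in
exact mode. Third, the task itself is knife-edge: losing a single
exemplar to a wrong-class capture forks the entire subsequent
trajectory, so run-level accuracies respond discontinuously to
continuous parameter changes. In consequence the two modes each have
kernel regimes where they track essentially perfectly — the exact
mode under sharp bandwidths that confine its global component within
a class, the approximate mode under moderate bandwidths — but no
regime was found at this problem size where both do, and their
overall accuracies at the default conditions differ by tens of
points rather than the near-equality one observes when both run at
their own operating points. The tracking driver's exact mode
therefore uses a deliberately coarse optimizer budget (30 BFGS
iterations, strong chart penalty) that bounds runtime and mirrors
the coarse per-event derivative-free optimization such geodesic
trackers use in practice; optimizer precision is not the limiting
factor (accuracies move by a few points across budgets while the
mode gap remains an order of magnitude larger). The per-event
geometry itself is sound — the quadratic exact-vs-approximate error
law holds to high precision in the acceptance suite — the divergence
is a trajectory-level phenomenon of the sequential experiment.

## What the passing tests do and do not show

The generators reproduce the *structure* of the behavioral
experiments — list context, basin scaling, gradual transformation —
under fully controlled statistics. Passing tests show the memory
model produces the qualitative phenomena (context-driven intrusions,
monotone extinction, order-dependent tracking) and, for the list
task, that the free parameters can be calibrated to the published
group percentages. They do not show that the calibrated parameter
values are those a fit to real images would give, and the headline
tracking accuracies on glyphs are not comparable to accuracies on
handwritten digits.

## Limitations

* The geodesic optimizer treats the attractor coordinates as a chart;
  for the scalar-product kernel the parametrization has a gauge
  freedom (column mixing within the span) along which the objective
  is flat — harmless for BFGS, but solutions are unique only as
  subspaces.
* Large principal angles (near 90°) make the intrinsic-distance
  gradient stiff; reconsolidation steps between nearly orthogonal
  memories may need more optimizer iterations.
* Recall convergence is geometric with a rate that degrades as the
  Gram off-diagonal mass grows (flat kernels, crowded attractors);
  drivers raise iteration budgets rather than altering the dynamics.
* The boundary conditions of reconsolidation (lability windows, trace
  dominance, prediction-error gating) are out of scope; the journal's
  surprise column is the hook for callers who want to model them.
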