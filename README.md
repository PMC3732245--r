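# rekam — a reconsolidating kernel associative memory

Memory reconsolidation is the finding that a recalled memory becomes
temporarily labile: it can be strengthened, weakened, updated toward
new information, or extinguished before it restabilizes. `rekam`
implements an attractor-network model of this process for
computational neuroscientists and machine-learning researchers who
want attractor memories that are *updatable*, hold real-valued,
high-dimensional patterns, and are not capacity-limited by the input
dimension.

## The model

Patterns $x_1,\dots,x_m \in \mathbb{R}^n$ (columns of $X$) are stored
as attractors of a **kernel associative memory**: the synaptic
operator is the orthogonal projector onto the span of the patterns'
feature images under a Mercer kernel $\kappa$, represented implicitly
by the Gram matrix $G_{ij} = \kappa(x_i,x_j)$. Recall iterates

$$y \;\leftarrow\; \sigma\!\big(X\,G^{-1}h(y)\big),\qquad
  h_i(y)=\kappa\!\big((x_i-y)/\lambda_i\big)$$

to a fixed point; every stored pattern is one, for any number of
patterns whose feature images stay linearly independent (the
strong-Mercer condition, checked at load). The per-attractor scales
$\lambda_i$ set each basin's radius — driving $\lambda_i \to 0$
extinguishes the memory.

Memories with a common kernel form a Riemannian manifold of
feature-space projectors, with distances computed purely through
kernel evaluations. **Reconsolidation** moves the memory a fraction
$\varepsilon$ of the way toward the state in which the recalled
attractor is replaced by the new stimulus — exactly, along the
manifold geodesic (a global update), or approximately, along a
straight line in coordinate space (a local update). The two differ
by $O(s^2)$ in the stimulus displacement $s$. A continuous-time
recall $\dot y = \Lambda\odot(-y + F(y))$ is included and, for the
scalar-product kernel, equals the continuous Hopfield network under
the pseudoinverse learning rule.

Three behavioral simulations ship with the package: list-learning
intrusions under a reminded context, fear extinction by basin
shrinking, and incremental tracking of gradually rotating images.
See the methods vignette (`vignettes/rekam-methods.Rmd`) for the full
account of the model, the geometry, and the synthetic study
conditions.

## A worked example

```r
library(rekam)

set.seed(1)
X <- matrix(runif(8 * 5, -1, 1), 8, 5)   # five 8-dimensional patterns
M <- rekam(X)                            # gaussian kernel, median bandwidth
r <- recall(M, X[, 3] + rnorm(8, sd = 0.05))
print(r)
#> Recall: converged after 32 iteration(s); winner = attractor 3
```

The noisy probe falls back into the basin of the pattern it was made
from. Reconsolidating toward a new stimulus moves that attractor —
`reconsolidate(M, stim, step = 0.5)` — and logs the winner and the
"surprise" (the manifold distance to the stimulus-substituted
memory) in `M$journal`.

The list-learning simulation calibrates its free parameters (kernel
balance, query context value, reminded step) against the human group
percentages by a documented grid sweep:

```r
cal <- calibrate_list_learning()
print(cal)
#> List-learning calibration
#>   sigma_v = 4.304, sigma_r = 1.100, r_init = 0.41, eps = 0.18
#>   group A List-1 %: 60.40 (target 60.399)
#>   group B List-1 %: 90.00 (target 90.180)
```

Group A (reminded) shows List-2 items intruding into List-1 recall at
the human rate; group B (no reminder) does not. `run_extinction()`
and `run_tracking()` drive the other two simulations and return
plottable report objects.

A thin command-line wrapper is installed at
`system.file("scripts", "rekam", package = "rekam")` with `load`,
`recall`, `distance`, `update` and `extinguish` subcommands over
plain-text memory files.

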