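---
title: "Random-turn games and nonlocal PDEs on weighted graphs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-turn games and nonlocal PDEs on weighted graphs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphtow)
```

## The model

All computations in **graphtow** live on a finite, simple, undirected graph
$\mathcal G = (\mathcal V, \mathcal E, w)$ with strictly positive symmetric
edge weights and neighborhoods $I(x) = \{y : w(x,y) > 0\}$. A signal
$u : \mathcal V \to \mathbb R^C$ carries the data (pixel intensities, point
colors, feature values); channels are always processed independently.

The package is organized around one family of first-order nonlocal
operators. The upwind gradients keep only one-sided, $\sqrt{w}$-scaled
differences,
$$\|\nabla_w^\pm u(x)\|_\infty = \max_{y \in I(x)}
  \sqrt{w(x,y)}\,\big(u(y)-u(x)\big)^\pm, \qquad
  \|\nabla_w^\pm u(x)\|_p = \Big[\sum_{y\in I(x)} w(x,y)^{p/2}
  \big((u(y)-u(x))^\pm\big)^p\Big]^{1/p},$$
with $a^+ = \max(a, 0)$ and $a^- = \max(-a, 0)$. From these we form the
weighted-mean Laplacian $\Delta_{w,2}$, the graph $\infty$-Laplacian
$\Delta_{w,\infty} = \tfrac12(\|\nabla^+\|_\infty - \|\nabla^-\|_\infty)$,
the game $p$-Laplacian
$\Delta^G_{w,p} = \tfrac{p-2}{p}\Delta_{w,\infty} + \tfrac2p \Delta_{w,2}$,
and the morphological trio
$$\mathrm{NLD}(u) = u + \|\nabla^+ u\|_\infty,\quad
  \mathrm{NLE}(u) = u - \|\nabla^- u\|_\infty,\quad
  \mathrm{NLM}(u) = u + \Delta_{w,2} u .$$

A two-player random-turn game ties these together. At an interior vertex
the token moves to the maximizing player's choice with probability
$\alpha/2$, to the minimizing player's choice with probability $\beta/2$,
and to a random neighbor with probability $\gamma$, under the simplex
constraint $(\alpha+\beta)/2 + \gamma = 1$. One step of the expected-value
recursion is the nonlocal average
$$\mathrm{NLA}(u) = \tfrac\alpha2 \mathrm{NLD}(u)
  + \tfrac\beta2 \mathrm{NLE}(u) + \gamma\,\mathrm{NLM}(u),$$
and the associated game operator is
$\Delta_{\alpha,\beta,\gamma} u = \mathrm{NLA}(u) - u$. Special parameter
choices recover the named operators: $(1,1,0)$ the $\infty$-Laplacian,
$(0,0,1)$ the mean Laplacian, $\big(\tfrac{p-2}p,\tfrac{p-2}p,\tfrac2p\big)$
the game $p$-Laplacian. The dictionary's eikonal row $(0,1,0)$ is *formal*:
it breaks the simplex constraint, and
$\Delta_{0,1,0}u = -\tfrac12\|\nabla^- u\|_\infty$ carries the $\beta/2$
prefactor, i.e. half the eikonal operator. `game_params(..., strict = FALSE)`
admits such rows for operator algebra; they define no probability
distribution and no convergent averaging iteration, which is why the
default is strict.

### A note on the finite-$p$ gradient

The $\mathcal L_p$ norm above carries the exponent $p$ on the signed
difference inside the sum. Some statements of the formula omit that
exponent; we adopt the exponent-$p$ reading because it is the only one
whose $p \to \infty$ limit reproduces the max form and whose $p = 2$ local
eikonal solve reduces to the Osher–Sethian update.

## Interpolation problems

Inpainting and colorization are Dirichlet problems: a set $A$ of vertices
with missing data, boundary data $g$ on $\partial A$, and
$-\Delta_{\alpha,\beta,\gamma} u = h$ in $A$ (source $h$ enters as
$u - \mathrm{NLA}(u) = h$, so the iteration adds $+h$). `solve_dirichlet()`
iterates the synchronous (Jacobi-style) averaging step
$u_{n+1} = \mathrm{NLA}(u_n) + h$ on $A$, $u_{n+1} = g$ on $\partial A$ —
exactly the explicit Euler scheme for the parabolic flow
$\partial_t u = \Delta_{\alpha,\beta,\gamma}u + h$ with $\Delta t = 1$.
For $\Delta t \in (0,1]$ (`evolve_parabolic()`) the update is a convex
combination of $u_n$ and $\mathrm{NLA}(u_n)+h$, hence monotone and
nonexpansive; smaller steps change the transient, not the fixed point.

Because NLA is an averaging operator — it fixes constants, commutes with
translations and positive scalings, and is monotone — iterates obey the
maximum principle for $h = 0$ (values remain inside the boundary range
per channel) and a comparison principle in the data. Two caveats worth
stating:

* *Monotonicity of NLD/NLE needs $w \le 1$.* Writing
  $\mathrm{NLD}(u)(x) = \max\big(u(x), \max_y (1-\sqrt{w})u(x) +
  \sqrt{w}\,u(y)\big)$ shows the coefficient $1-\sqrt{w(x,y)}$ must be
  nonnegative. Every weight the package constructs is a similarity in
  $(0,1]$, so this holds by design; user-supplied edge lists with $w > 1$
  keep all algebraic identities but may lose comparison.
* *Negative homogeneity swaps dilation and erosion*:
  $\mathrm{NLD}(tu) = t\,\mathrm{NLE}(u)$ for $t < 0$, the duality
  $\mathrm{NLE}(u) = -\mathrm{NLD}(-u)$ in disguise. The test suite checks
  the axiom in this duality-corrected form.

Defaults: tolerance $10^{-6}$ on the sup-norm update with the true residual
$\|u - \mathrm{NLA}(u) - h\|_\infty$ also reported, iteration cap $10^5$,
initial guess $0$ on $A$ (the mean scribble color for colorization, the
known image for inpainting). Non-convergence is a reported flag, not an
error. For images the boundary is *all* known pixels, not just the hole's
rim: same fixed point on $A$, better-conditioned iteration. Patches that
overlap the hole are computed after filling the hole with the mean known
intensity — a deterministic choice that only perturbs weights, never the
boundary data.

## The eikonal equation and label propagation

Fronts, distance maps, superpixels and semi-supervised classification all
reduce to the graph eikonal equation
$\|\nabla_w^- u(x)\|_p = h(x)$ off a seed set, $u = $ seed values on it,
with $h > 0$. `solve_eikonal()` is a monotone label-setting
(Dijkstra-like) sweep: vertices settle in nondecreasing value order, and
each settlement triggers the explicit local solve at unsettled neighbors.
For $p = \infty$ the local solution is the closed form
$\min_i (a_i + k_i C)$ with $k_i = 1/\sqrt{w(x,y_i)}$ and $C = h(x)$; for
finite $p$ it is the unique root of
$\sum_i k_i^{-p}\big((x - a_i)^+\big)^p = C^p$, found by the standard
incremental scheme (sort the known values, add terms while the candidate
exceeds the next one; quadratic formula at $p = 2$, closed form at
$p = 1$, safeguarded root-finding otherwise). Unreachable vertices come
back as $+\infty$ rather than an error so disconnected k-NN graphs degrade
gracefully.

Multi-label propagation (`propagate_labels()`) is a single multi-source
sweep in which every vertex takes the label of the first-arriving front;
fronts stop where they meet. Exact ties are broken to the smaller label
index, then the smaller vertex index — a documented, deterministic rule
enforced through the priority queue's lexicographic key.
`superpixels()` dilates a regular seed lattice with $h \equiv 1$ on a
photometrically weighted 4-adjacency grid; `classify_semi_supervised()`
propagates a stratified 10% of labels (default) over a k-NN feature graph
with $p \in \{1, 2\}$.

## The game engine as a stochastic oracle

`value_iteration()` iterates the dynamic-programming operator
$u \mapsto \mathrm{NLA}(u) + h$ (boundary clamped) — the same fixed point
as `solve_dirichlet`, which the tests assert to $10^{-9}$.
`simulate_game()` plays the game forward: greedy strategies read from a
value function, the random move samples neighbors proportionally to edge
weight (so its expectation is exactly NLM, the choice forced by requiring
the playout expectation to match the averaging operator on weighted
graphs), and players choose from $I(x) \cup \{x\}$ because the one-sided
clamps let a player effectively stay when no neighbor improves their
objective. With $\alpha = \beta = 1$ and non-unit weights the pairwise
rule applies: the token moves to the maximizer's pick $y$ against the
minimizer's pick $z$ with probability
$P(x,y,z) = \sqrt{w(x,y)}\big/(\sqrt{w(x,y)}+\sqrt{w(x,z)})$.

On unit-weight graphs the per-step expectation of the playout equals
$\mathrm{NLA}$, so the Monte-Carlo mean is an unbiased estimate of the
deterministic value; the suite checks agreement within three standard
errors at $2\times 10^4$ playouts over 25 (graph, parameter) combinations.
For general weights with $\gamma > 0$ no single playout rule reproduces
the dilation/erosion terms exactly; the simulator is then exploratory and
the DPP remains the ground truth — a documented limitation, not a bug.
Episodes are capped at $10^5$ steps, counted and excluded from the mean
(the cap is never hit in the shipped configurations), and every estimate
is bit-reproducible from the spec's seed.

## Graph construction choices

* **k-NN symmetrization** is by union — an edge exists if either endpoint
  selects the other — the simplest undirected completion; mutual-k-NN is
  available via `mutual = TRUE`.
* **Patches** use replicate padding at borders and row-major window order
  (channels innermost); both choices are arbitrary but fixed for
  reproducibility, and pairwise distances are order-invariant anyway.
* **The similarity scale.** With the exponential map
  $s = \exp(-d/\sigma^2)$, leaving $\sigma$ unset estimates
  $\sigma^2$ as the mean nonzero distance among candidate edges, so a
  typical edge gets weight $e^{-1}$. (Estimating $\sigma$ itself as the
  mean distance would square the scale and collapse all weights for data
  whose distances are far from 1.)
* **Weight pruning** below $10^{-12}$ keeps $I(x)$ well defined; a pruned
  edge is a non-edge, so strongly contrasted regions can legitimately
  disconnect — solvers validate connectivity/solvability up front and
  eikonal sweeps report unreachable vertices as $+\infty$.
* **Vertices are 1-based**, with pixel $(r, c)$ of an $H \times W$ image
  mapped to vertex $(r-1) W + c$; file interfaces (edge lists, seed CSVs)
  use the same convention.

## What the synthetic fixtures emulate — and what they do not

The generators (`generate_test_image`, `generate_point_cloud`,
`generate_blob_features`) are first-class, seeded, bit-reproducible code.
They emulate the *structure* of the motivating applications: piecewise
constant and textured rasters with missing regions (restoration),
two-primitive colored point clouds with one scribble per primitive
(scribble colorization), and a four-class isotropic Gaussian feature table
with 400 samples, 10 descriptors and minimum centroid separation six
within-class standard deviations — a desk-scale stand-in for a cytological
feature table of cell-morphology descriptors. The separation default was
chosen once as "clearly clustered but overlapping tails", the regime where
label propagation is informative yet not trivial.

They do **not** emulate heavy-tailed noise, class imbalance, correlated
descriptors, textured natural images, or acquisition artifacts. Passing
tests therefore demonstrate correctness of the operators and solvers and
qualitative behavior of the pipelines, not expected accuracy on real
cytology slides or heritage imagery; published headline accuracies on
clinical databases are tied to data this package does not ship.

## Problem sizes and numerics

The shipped tests and the acceptance script use deliberately small
instances — random graphs up to 60 vertices, grids up to $24^2$, 400-sample
feature tables, $2\times10^4$ playouts — sizes at which the independent
oracles (dense linear solves, exhaustive relaxation, brute-force
enumeration, naive fast marching) are exact and fast, so every solver is
checked against an implementation that shares none of its code path. The
solvers themselves scale to much larger graphs; runtime grows linearly in
edges per iteration for the averaging solvers and
$O(|\mathcal E|\log|\mathcal V|)$ for the eikonal sweep.

Numerical conventions worth knowing: the simplex constraint is enforced to
$10^{-10}$; settlement monotonicity is asserted during every eikonal
sweep; strict improvement by more than $10^{-15}$ is required to re-queue
a vertex; and `local_update` treats already-larger neighbor values through
the $(\cdot)^+$ clamp, so label-setting with settled-only neighbors and
full relaxation have the same fixed point.

## Known limitations

* No directed graphs, no dynamic graph mutation during solves, no
  anisotropic metrics.
* The Monte-Carlo engine is an oracle only on unit-weight graphs (see
  above).
* Gauss–Seidel sweeps can converge faster than the synchronous update but
  are not the default, matching the averaging-filter formulation exactly.
* Binary PLY files are not parsed; ASCII PLY and XYZRGB text are.
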