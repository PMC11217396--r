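---
title: "Evolving bow-tie architecture in layered signaling networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving bow-tie architecture in layered signaling networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bowtieevo)
```

## The model

Signaling cascades and gene-regulatory hierarchies are modeled here as
layered feedforward linear networks: `L + 1` node layers of `M` nodes each,
with the links from layer `l` to layer `l + 1` collected in a nonnegative
matrix `A^(l)`. The network's input-output behavior is the composed matrix

    A = A^(L) A^(L-1) ... A^(1),

and selection acts on the distance to a fixed target in-out relation, the
*goal matrix* `G`:

    F = -||A - G||_F^2.

A *bow-tie* (hourglass) is a network whose information flow funnels through
a narrow middle layer. Activity of a middle node is judged by deleting it
(zeroing its incoming row and outgoing column) and asking whether its share
of the total fitness drop, `P_i^l = |dF_i| / sum_j |dF_j|`, exceeds a
threshold (0.001). The *waist* is the middle layer with the fewest active
nodes; the network is a bow-tie when the waist is narrower than `M`.

Two alternative activity readouts are provided: the node's share of the
squared change of the composed matrix upon deletion (threshold 0.001), and
the node's largest incident link relative to the layer (threshold 0.05).
The headline phenomena are robust to the choice; the fitness-drop readout
is the recording default. A note on the fitness-drop formula: two natural
forms exist, the raw ratio of drops and the ratio of squared drops. They
disagree materially for full-rank goals near convergence — squaring lets a
dominant flow component collapse the active count to one node even when
the remaining nodes carry the full-rank residual — and only the raw ratio
classifies a converged full-rank network as full-waisted, so the raw ratio
is used.

## The genetic algorithm

Each generation the population of `N = 100` networks is duplicated to
`2N`; 20% of the pool (40 individuals) each receive one *product-rule*
mutation `A_ij -> A_ij * xi`, `xi ~ N(1, 0.1)`, resampled if nonpositive so
links stay positive; all `2N` are evaluated; and `N` survivors are chosen
by tournament selection with group size 4 (elite selection is available and
gives the same phenomenology). A run is converged when the population mean
fitness reaches `-0.01`. Mutation is applied across the whole duplicated
pool by default; a flag restricts it to the copies (either bookkeeping is
compatible with the model definition). The initial population consists of `N`
independently drawn uniform(0,1) stacks, each rescaled by a common
per-layer factor so the composed norm equals the initial intensity `A0` —
whether individuals start as clones is likewise unspecified, and
independent draws were chosen as the more generic population state.

The multiplicative mutation is the scientific crux: links grow or shrink
in proportion to their current size, so small links are slow and large
links fast. Starting from `A0 << ||G||_F`, all links must grow by orders of
magnitude, and the multiplicative amplification of initial differences
concentrates the flow through one (or a few) middle nodes — a bow-tie —
*regardless of the goal's rank*. The goal rank then decides whether the
transient bow-tie persists (rank-deficient goals) or relaxes back to a full
waist (full-rank goals). Starting from `A0 ~ ||G||_F` no growth phase is
needed and no bow-tie forms.

Key tunables (all in `evolution_config()`): `N` (100), `mutate_fraction`
(0.2 of the 2N pool), `xi_var` (0.1; 0.5 with sign flips allowed in the
nonlinear variant), `tournament_size` (4), `convergence_fitness` (-0.01),
`max_generations` (150000, the per-epoch budget of the fluctuation
protocols), optional L1/L2 link-cost terms with weight `reg_lambda`
(default 0; no reference value exists, so it is exposed rather than fixed).

## Goal matrices

`generate_goal(M, rank, norm)` builds a rank-`r` goal as a sum of `r` outer
products of positive random vectors (uniform components shifted away from
zero), rescaled to the requested Frobenius norm (60 in the figure-level
protocols). Positive entries keep a perfect fit reachable by positive link
stacks; the generating distribution under the rank constraint is otherwise
a free choice and is flagged in the configuration. Declared rank is
verified by SVD (singular values above `1e-9` of the largest) and the draw
is repeated on the measure-zero event of rank collapse.

`normalize_variance_norm(G, D)` applies the affine element-wise
normalization `Z = (G - <G>)/sd(G) + sqrt(D/N^2 - 1)`, which makes the
element variance exactly 1 and the squared norm exactly `D`; it removes the
rank-dependent variance bias of the raw generator. The additive shift
introduces a rank-one component, so the output's rank is re-measured
rather than inherited. Both raw-norm and variance-normalized modes are
supported; the sweep protocols use either depending on whether the
rank-dependent variance bias should be controlled.

`goal_schedule()` builds fluctuation protocols (a fresh goal every 1000
generations, optionally after an adaptation phase, with per-epoch child
seeds), and `expand_goal()` grows a rank-1 goal to a larger dimension
keeping the original block and extending the generating vectors with
positive random components scaled to the existing components' mean
magnitude — the expanded norm then exceeds the old one, which is the
mechanism that re-opens the bow-tie window. When a scheduled goal is larger
than the current networks, every individual is padded with near-zero
uniform entries (`pad_scale`, default 0.01: small against evolved links of
order 1-10, but large enough for multiplicative growth to act on).

## The gradient-flow model

The continuous counterpart of the GA is the multiplicative gradient flow

    dA_ij^(l)/dt = eta A_ij^(l) dF/dA_ij^(l),  eta = 1e-4,

integrated with fixed-step classical RK4 (`integrate_ode()`; the scheme is
the package's choice — step-halving self-consistency is checked in the
tests, and the default `dt = 0.1` keeps `eta dt ||G||^2` well below one for
the norm-60 protocols). Zeros are absorbing, the goal is a fixed point, and
an entry cap (default `1e6`) guards against divergence with a status flag
instead of an error. The general-`L` gradient used by the integrator is the
analytic extension of the two-layer form and is validated against central
finite differences rather than assumed.

In the early phase (`A << G`, two layers, two nodes, uniform rank-1 goal
with element `g`) the summed input and output intensities `I_k`, `R_k` of
middle node `k` obey `dI/dt = dR/dt = 2 eta g R I`, so `R - I` is
conserved and

    R(t) = R0 (R0 - I0) / (R0 - I0 exp(2 eta g (R0 - I0) t)),

which blows up at `t* = (ln R0 - ln I0) / (2 eta g (R0 - I0))` (limit
`1/(2 eta g R0)` for `R0 = I0`, implemented analytically, not by
cancellation). The middle node whose column group blows up first becomes
the waist. `reduced_dynamics()` integrates the reduced pair with deSolve's
fixed-step RK4; `reduced_blowup_time()` is a small bespoke stepping loop
because the finite-time blow-up needs a divergence guard that a generic
integrator does not provide. Because the two reduced derivatives are the
same expression evaluated at the same state, the RK4 increments of `R` and
`I` are identical in floating point and the conservation of `R - I` holds
to rounding error, not merely to truncation order.

## The nonlinear variant

A five-layer tanh network (`u = f(A4 f(A3 f(A2 f(A1 v))))` with
`f(x) = (1 + tanh x)/2`, `A1` of shape 6 x 64) is evolved with the same GA
to classify 8 x 8 digit images of "2", "4", "6", "8" into six redundant
groups (two classes activate two output bits each; the exact published
grouping is not printed, so the class-to-group table is configurable).
Weights are signed: initialization is uniform(-1, 1) rescaled so the
composed linear product has norm `A0`, and the mutation multiplier widens
to `xi ~ N(1, 0.5)` *without* resampling, so sign flips occur. Fitness is
the summed squared error against the 6-bit group code, mirroring the
linear model's Frobenius objective (a configurable choice; cross-entropy
is deliberately not used so the two models stay parallel).

The bundled digit images are synthetic: fixed 8 x 8 glyph templates with
intensity jitter, one-pixel shifts and Gaussian pixel noise. They emulate
the size, value range, class structure and redundancy of the scanned-digit
task but not its stroke variability, so passing tests demonstrate the
A0-dependence of the evolved architecture on a task of this shape, not
benchmark accuracy on real handwriting.

## Reduced desk-scale protocol sizes

The full figure-level protocols use 100 replicates per condition and up to
150,000 generations per goal epoch. The package's experiment drivers
default to 20 replicates, and the test suite exercises the protocols at 10
seeded replicates per condition with these problem sizes, chosen as the
smallest at which the contrasts are unambiguous:

* waist-vs-rank end states: rank 1 at a 50,000-generation cap, rank 6 at
  300,000 (full-rank fine-tuning converges around 300,000 generations
  here);
* transients: 30,000-generation caps (the transient waist minimum occurs
  within the first few thousand generations);
* fluctuation: a 20,000-generation adaptation phase followed by 1000-
  generation epochs, and 10,000 generations for fluctuation from scratch;
* expansion: 10 x 10 to 20 x 20 at generation 1000, 60,000-generation cap;
* nonlinear: 1500 generations, N = 50, 300 images;
* the A0 sweep for the bow-tie window uses the gradient-flow surrogate,
  which reproduces the GA's A0 dependence at a fraction of the cost.

## Numerical and design notes

* Middle node layers are `2..L`: input and output layers are never
  deleted, and every layer between them — including the one feeding the
  output layer — is a candidate waist.
* Waist ties break toward the lowest layer index, making reports
  deterministic.
* A layer whose deletions are all exactly neutral reports every node
  inactive (the 0/0 ratio is defined as 0).
* Deletion sets links to exactly 0, the boundary of the "positive links"
  constraint; mutation cannot resurrect an exact zero (multiplicative
  updates preserve zeros), which is the intended absorbing behavior.
* Importance is always computed from the plain fitness, even when a
  regularized fitness drives selection: activity is meant as a structural
  readout of the evolved network.
* All randomness (R and compiled code) flows through R's RNG, so any run
  is bit-reproducible from `set.seed()`; experiment grids derive one child
  seed per (condition, replicate).
* Elite selection of `N` from the duplicated `2N` pool necessarily returns
  the top half twice when no mutation occurs; "no-op evolution" therefore
  preserves genotypes and the best individual, not the literal population
  multiset.

## Known limitations

Feedback loops, recombination, variable population sizes and
metabolic-style (material-flow) bow-ties are out of scope.

The *location* of the sharp transition of the end-state waist-1
probability is sensitive to details of the evolutionary protocol that the
model definition does not pin down. In this implementation the 0.5
crossing for rank-1 norm-60 goals sits near `A0 ~ 0.1`, and it stays
there under every variant of the free choices (clone vs independent
initial populations, elite vs tournament selection and its group size,
mutating copies only vs the whole pool, reading the waist at convergence
vs much later); implementations differing in such details can place it an
order of magnitude higher. The qualitative structure — waist-1 below a
sharp threshold, bow-tie (waist < M) throughout the small-`A0` window,
no bow-tie at `A0 ~ ||G||_F` — is robust. The reduced
two-node analysis describes only the early phase; after the first column
diverges the approximation `G - A ~ G` fails and the full flow must be
integrated. Waist trajectories are recorded at a configurable stride, so
`instantaneous_min_waist()` is the minimum over recorded generations; with
the default stride of 10 the multi-thousand-generation transients are
resolved comfortably.
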