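---
title: "Selecting the top k of a Cartesian sum with layer-ordered heap product trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting the top k of a Cartesian sum with layer-ordered heap product trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lohtree)
```

## The selection problem

Let X₁, …, X_m be numeric arrays of length n. Their Cartesian sum holds nᵐ
values, yet applications usually need only the k most extreme of them: the
k most probable isotopologues of a molecule, the k best terms of a
max-convolution, the k best joint assignments of independent discrete
variables whose scores add. `lohtree` computes exactly those k values while
generating only O(k) candidates per pairwise combination, by organizing all
intermediate results as *layer-ordered heaps* and combining arrays through
a balanced binary tree of lazy pairwise selections.

This vignette explains the data structure, the selection procedure, the two
tree modes, the tunable parameters, the numerical conventions, and what the
package's synthetic benchmarks do and do not establish.

## Layer-ordered heaps

A layer-ordered heap (LOH) of rank α > 1 partitions an array into layers
L₁, L₂, … such that

* |L₁| = 1 and |L_{i+1}| = ⌈α·|L_i|⌉ (the final layer truncated to fit),
* max(L_i) ≤ min(L_{i+1}) — the *layer-ordering property*,
* values inside a layer are unordered.

`lohify()` builds one by rank-selecting at the cumulative layer boundaries
from the largest boundary down; each pass touches a geometrically shrinking
prefix, so total work is expected linear. The rank selection itself
(`select_rank_k()`) is base R's partial sort, a C-level quickselect.
At α = 1 every layer would have size one — a full sort — which is why the
constructor rejects α ≤ 1.

The ceiling in the size recurrence matters near α = 1: while layers are
small, ⌈α·s⌉ = s + 1, so early layers grow arithmetically before the
geometric regime takes over, and the layer count for α = 1.1 exceeds the
idealized geometric-series prediction log_α(n(α−1)+1) by a sizable constant.
The recurrence was fixed (rather than made pluggable) because every
downstream guarantee depends only on |L₁| = 1, monotone growth and the
ratio converging to α — all of which the ceiling rule provides for any
α > 1. The tests assert the convergent-ratio form of the growth property.

## Pairwise selection on A + B

`select_pairwise()` selects the k smallest values of A + B in four phases.
Phase 0 LOHifies the inputs. Phase 1 explores *layer products*
A⁽ᵘ⁾ + B⁽ᵛ⁾ through two constant-space summaries: the min tuple
⌊(u,v)⌋ = (min A⁽ᵘ⁾ + min B⁽ᵛ⁾, (u,v), false) and the max tuple
⌈(u,v)⌉ = (max A⁽ᵘ⁾ + max B⁽ᵛ⁾, (u,v), true). Tuples pop from a priority
structure in lexicographic (value, is_max, u, v) order — min before max at
equal value, then smallest indices, so pop traces are deterministic even on
all-equal inputs. Popping ⌊(u,v)⌋ pushes ⌈(u,v)⌉ and the in-bounds
neighbors ⌊(u+1,v)⌋, ⌊(u,v+1)⌋ (a seen-set prevents duplicate insertion);
popping ⌈(u,v)⌉ adds |A⁽ᵘ⁾|·|B⁽ᵛ⁾| to an accumulator s and commits (u,v)
to a list q. When s ≥ k, the values covered by committed max tuples alone
already include k sums no unexplored layer product can beat: any
ungenerated value is at least the last popped value. Phases 2–3 commit the
max tuples still in the frontier, generate the committed layer products,
and cut to exactly k with one linear rank selection. The number of values
generated is O(α²·k).

The seed of the frontier is ⌊(1,1)⌋, the global minimum layer product. An
oversized k is clamped to |A|·|B| with a warning (`strict_k = TRUE` turns
this into an error), and `direction = "max"` negates inputs and outputs.

## The product tree

`build_tree()` arranges the m arrays as leaves of a balanced binary tree of
height ⌈log₂ m⌉, pairing X₁+X₂, X₃+X₄, … level by level; with an odd count
the unpaired node is promoted unchanged. Leaves LOHify their arrays at
construction; internal nodes start empty. Asking a node for its next LOH
layer (`generate_next_layer()`) resumes the node's *persistent* frontier —
heap contents, the accumulator s, and a buffer of generated-but-unemitted
candidates all survive between requests — and pops tuples until s reaches
the node's cumulative emitted count plus the next scheduled layer size.
Keeping s cumulative (rather than resetting per layer) is what makes the
persistent frontier consistent: each popped max tuple's product is counted
once, against all layers it helps cover.

Inside tree nodes the neighbor-insertion scheme is deliberately different
from the standalone pairwise module: popping ⌊(u,v)⌋ always inserts
⌈(u,v)⌉ and ⌊(u,v+1)⌋, and inserts ⌊(u+1,v)⌋ only when v = 1. Under this
scheme every index pair has a unique predecessor, so no deduplication set
is needed at all. A cross-check test asserts both schemes select identical
multisets. When a min tuple refers to a child layer that does not exist
yet, the child is asked to generate it recursively; if the child's full
Cartesian product is exhausted the tuple is skipped permanently. Values of
a popped min tuple's layer product are generated eagerly into the node's
buffer; buffer leftovers above a layer's cut are retained for later layers
(dropping them would lose values that belong to deeper layers).

Emission differs by mode:

* **standard** — exactly the scheduled layer size, the smallest buffered
  values (an order-based selection, so provenance indices travel with
  their values);
* **wobbly** — every buffered value ≤ the last popped max-tuple value, a
  pure value partition (`partition_by_value()` semantics). Layers are then
  at least scheduled size, and on adversarial homogeneous inputs grow
  super-exponentially: with k = 2 and arrays of two equal values, every
  level-1 node emits all 2² = 4 sums in its first layer and the root pool
  reaches 2ᵐ values. The package reproduces this exactly (`root_pool_size()`
  on the homogeneous tree returns 2ᵐ for m = 2…5); it is the price paid for
  skipping all internal rank selections, and it is favorable precisely when
  m is small.

`select_topk()` asks the root for layers until their cumulative size
reaches k. The layer-ordering property means earlier layers are part of the
answer verbatim; only the last layer needs a rank selection — and in wobbly
mode this root cut is the only exact selection in the entire computation.
Floating-point sums are formed left-associatively along the fixed tree
shape, so results are bit-reproducible run to run; integer inputs are exact
in doubles well beyond the 0–10,000 range used in the benchmarks.

## Parameters

* `alpha` (default **1.1**, must be > 1) — the LOH rank, the single
  speed/over-generation dial. Small α means many thin layers: more frontier
  pops (Ω(k log k) as α → 1) but few wasted values. Large α means few
  coarse layers: cheap frontier traffic but up to α²-fold over-generation
  per selection. 1.1 balances the two in practice; the asymptotic exponent
  in the runtime O(n·m + k·m^(log₂ α²)) is log₂(1.1²) ≈ 0.2750.
* `mode` — `"standard"` unless m is small; `top_isotopologues()` defaults
  to `"wobbly"` because formulas rarely have more than a handful of
  elements.
* `direction` — `"min"`/`"max"`; max negates inputs and outputs.
* `provenance` — per-value leaf index tracking (needed to reconstitute
  isotopologues); costs one integer matrix alongside every buffer.
* `strict_k` — turn the k-clamping warning into an error.
* `keep`/`cap` (isotopologue module) — per-element truncation of the
  combination list and an enumeration guard (default cap 10⁶ combinations
  per element). Truncation can in principle drop mass from the true top-k;
  a warning reports the probability mass retained per leaf.

## The isotopologue application

An isotopologue assigns each atom to an isotope of its element. Its
probability is a product of per-element multinomial terms: for an element
with abundances p₁…p_i and c atoms split as (c₁,…,c_i), the term is
c!/(c₁!⋯c_i!)·∏pⱼ^cⱼ. `element_combinations()` enumerates all
C(c+i−1, i−1) splits (stars and bars) and evaluates the term in log space
via `lgamma`, so hemoglobin-scale counts (thousands of atoms) neither
underflow nor overflow. Maximizing ∏ over elements is minimizing
∑ −log p, so `top_isotopologues()` builds one leaf per element holding
−log probabilities, selects with provenance, and reconstitutes each
species' probability, exact mass, and per-isotope atom counts. Ties in
probability are broken by ascending mass, deterministically. The embedded
isotope table carries standard terrestrial abundances for 16 elements and
can be replaced by any file with `element, isotope_mass_Da, abundance`
lines (validated: abundances sum to 1 within 10⁻⁹, masses strictly
increasing).

## Synthetic data and what the tests show

`generate_fixture()` draws arrays of uniform random integers on
[0, 10,000], the distributional setup of all empirical checks in the test
suite. The oracle for every equivalence test is `brute_force_topk()`:
enumerate, sort, truncate. Problem sizes were chosen so the full suite runs
in well under a minute: 500 random instances with m ≤ 6, nᵢ ≤ 12,
k ≤ 2,000 for oracle equivalence of both modes and the standalone pairwise
variant; 500 random arrays for LOH verification; 50 instances of m = 8,
n = 256 with k = 64…4096 for the candidate-count doubling ratio (median
ratio ≈ 1.8, comfortably below the 2.5 bound implied by linear growth in
k); and exhaustively enumerable formulas (H₂O, S₈, ATP) for the
isotopologue module.

Uniform integer arrays are a deliberately structureless benchmark — the
frontier's behavior does not depend on the values' distribution, only on
their order, and the all-equal adversarial case is tested separately. What
these tests do **not** exercise: very long arrays (n ≫ 10³ per leaf appear
only through the isotopologue leaves, up to ~3.5·10⁵ combinations for
hemoglobin's oxygen), floating-point inputs with near-tie pathologies
beyond what random integers produce, and k beyond ~10⁶.

## Degenerate inputs and edge behavior

Empty array lists, empty member arrays and NA values are rejected up
front. m = 1 collapses the tree to a single leaf and `select_topk()` to a
plain rank selection. k larger than the full product clamps with a
warning. All-equal arrays pop tuples purely in index order. A node whose
frontier empties has generated its entire product; remaining buffered
values are emitted in scheduled slices (standard) or at once (wobbly).

## Known limitations

* The frontier is a linear-scan priority structure; profiling shows it is
  not the bottleneck at the package's scales (frontiers hold one entry per
  live layer product), but a binary heap would serve k ≫ 10⁶ better.
* Wobbly mode with large m can explode memory by design; the package
  reproduces, rather than guards against, this regime — callers with
  m ≫ 5 should use standard mode.
* Per-element truncation (`keep`) trades exactness for memory without a
  bound on the lost probability mass beyond the reported retained mass.
* The LOH construction meets the linear-time contract via iterated partial
  sorts; it is not the constant-factor-optimal construction described in
  the LOH literature.
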