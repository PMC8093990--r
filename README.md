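# lohtree

Top-k selection on Cartesian sums via layer-ordered heap product trees.

## The problem

Given m numeric arrays X₁, X₂, …, X_m of length n, many problems in
proteomics, metabolomics and probabilistic inference need the k smallest (or
largest) values of the Cartesian sum

    X₁ + X₂ + ⋯ + X_m = { x₁ + x₂ + ⋯ + x_m : xᵢ ∈ Xᵢ },

a set of nᵐ values that is far too large to enumerate. The motivating
application is isotope fine structure: the probability of an isotopologue of
a molecule factorizes over its elements, so the k most probable
isotopologues of hemoglobin (C₂₉₅₂H₄₆₆₄O₈₃₂N₈₁₂S₈Fe₄) are the k smallest
values of C + H + O + N + S + Fe, where each leaf array holds the −log
probabilities of one element's isotope combinations (a multinomial per
element). The same selection appears in max-convolution and max-product
Bayesian inference over sums of discrete random variables.

## The method

Each input array is partitioned in linear time into a **layer-ordered heap**
(LOH) of rank α > 1: layers L₁, L₂, … with |L₁| = 1, |L_{i+1}| =
⌈α·|L_i|⌉, and max(L_i) ≤ min(L_{i+1}); values inside a layer stay unsorted.
Two LOHs A and B are combined by **pairwise selection**: a binary heap of
layer-product tuples — min tuple ⌊(u,v)⌋ = (min A⁽ᵘ⁾ + min B⁽ᵛ⁾, (u,v)) and
max tuple ⌈(u,v)⌉ — is popped in ascending order; popped max tuples
accumulate their product sizes into a counter s, and as soon as s ≥ k the
generated layer products are guaranteed to contain the k smallest sums,
after a final linear-time rank selection. Only O(α²·k) values are ever
generated.

For m arrays, the package builds a balanced binary tree of such pairwise
selections (height ⌈log₂ m⌉). Every internal node lazily generates its own
LOH one layer at a time, requesting child layers only on demand, with a
persistent frontier per node. Two modes are available:

* **standard** — every internal layer is cut to its exact scheduled size by
  a rank selection;
* **wobbly** — internal cuts are value partitions at the last popped
  max-tuple value. Layers can then grow super-exponentially (for
  homogeneous inputs and k = 2 the root pool reaches 2ᵐ values), but all
  exact selection work is deferred to the root, which pays off when m is
  small — exactly the isotopologue regime.

Both modes return the same multiset, the true top k, with overall runtime
O(n·m + k·m^(log₂ α²)); at the default α = 1.1 the exponent is 0.2750.

## Worked example

```r
library(lohtree)

arrays <- generate_fixture(m = 4, n = 6, seed = 42)  # uniform integers 0..10000
tree <- build_tree(arrays, alpha = 1.1, mode = "standard")
select_topk(tree, 5)
#> [1] 3997 4219 4893 5115 6010
total_candidates(tree)
#> [1] 66
```

The five smallest of the 6⁴ = 1,296 possible four-way sums were found after
generating only 66 candidate values across the tree's internal nodes.

The flagship application, the five most probable isotopologues of
hemoglobin (a selection over 6 leaves whose full product has ~10¹⁴
species, ~2 s on a laptop):

```r
hb <- top_isotopologues("C2952H4664O832N812S8Fe4", k = 5)
hb[, c("probability", "mass", "C12", "C13", "H1", "H2", "Fe56", "Fe57")]
#>   probability    mass  C12 C13   H1 H2 Fe56 Fe57
#> 1 0.001008526 65317.4 2921  31 4664  0    4    0
#> 2 0.000995691 65318.4 2920  32 4664  0    4    0
#> 3 0.000994800 65318.4 2921  31 4664  0    4    0
#> 4 0.000989265 65316.4 2922  30 4664  0    4    0
#> 5 0.000982140 65319.4 2920  32 4664  0    4    0
```

Each row is one isotope fine-structure variant: its exact probability, its
exact mass in Da, and how many atoms of each element sit on each isotope
(the most probable species carries 31 ¹³C atoms; no species with ²H or
⁵⁴Fe makes the top five). The same computations are available from a shell:

```sh
Rscript -e 'quit(status = lohtree::cli_main())' select --input arrays.tsv --k 4
Rscript -e 'quit(status = lohtree::cli_main())' isotopologue --formula H2O --k 3
```

(or via the installed wrapper script `inst/cli/lohtree`).

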