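Package: lohtree
Title: Top-k Selection on Cartesian Sums via Layer-Ordered Heap Product Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects the k smallest (or largest) values of the Cartesian sum
    X1 + X2 + ... + Xm of m numeric arrays without enumerating the full
    product. Arrays are partitioned into layer-ordered heaps (LOHs) of rank
    alpha and combined through a balanced binary tree of pairwise A+B
    selections whose internal LOHs are generated lazily, one layer at a time,
    in a standard (exact layer sizes) and a "wobbly" (value-partition) mode.
    Includes an optimal standalone A+B selection, a linear-time rank-k
    selection kernel, and an isotopologue calculator that returns the k most
    probable isotope fine-structure variants of a molecular formula by
    running the tree on per-element multinomial -log probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
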