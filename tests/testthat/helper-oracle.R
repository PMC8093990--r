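# Shared fixtures: random instances in the study's distributional setup
# (uniform integers on [0, 10000]) and the exhaustive sum oracle.

rand_instance <- function(m_max = 6, n_max = 12, k_max = 2000) {
  m <- sample.int(m_max, 1L)
  ns <- sample.int(n_max, m, replace = TRUE)
  arrays <- generate_fixture(m, ns)
  k <- sample.int(min(k_max, prod(ns)), 1L)
  list(arrays = arrays, k = k)
}

all_sums <- function(arrays) {
  Reduce(function(a, b) as.vector(outer(a, b, "+")), arrays)
}

expect_same_multiset <- function(got, want) {
  expect_identical(sort(as.numeric(got)), sort(as.numeric(want)))
}
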