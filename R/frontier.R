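# Frontier of layer-product tuples.
#
# A layer product A^(u) + B^(v) is summarized by two tuples that never
# require materializing its values:
#   min tuple: (min(A^(u)) + min(B^(v)), (u, v), is_max = 0)
#   max tuple: (max(A^(u)) + max(B^(v)), (u, v), is_max = 1)
# Tuples pop in lexicographic order of (value, is_max, u, v), so a min tuple
# precedes a max tuple of equal value and pop traces are reproducible.
#
# The frontier also carries the two accumulators of the selection loop:
# `s`, the running total of Cartesian-product sizes of popped max tuples,
# and `last_max`, the value of the most recently popped max tuple (the
# wobbly partition threshold). Stored as parallel vectors in an environment;
# frontiers stay small (one entry per live layer product), so an O(size) pop
# is cheaper in R than maintaining a binary heap.

new_frontier <- function() {
  f <- new.env(parent = emptyenv())
  f$val <- numeric(0)
  f$mx <- integer(0)
  f$u <- integer(0)
  f$v <- integer(0)
  f$s <- 0
  f$last_max <- NA_real_
  f
}

frontier_size <- function(f) length(f$val)

frontier_push <- function(f, val, mx, u, v) {
  f$val <- c(f$val, val)
  f$mx <- c(f$mx, as.integer(mx))
  f$u <- c(f$u, as.integer(u))
  f$v <- c(f$v, as.integer(v))
  invisible(f)
}

frontier_pop <- function(f) {
  i <- which(f$val == min(f$val))
  if (length(i) > 1L) i <- i[f$mx[i] == min(f$mx[i])]
  if (length(i) > 1L) i <- i[f$u[i] == min(f$u[i])]
  if (length(i) > 1L) i <- i[f$v[i] == min(f$v[i])]
  i <- i[1L]
  out <- list(val = f$val[i], mx = f$mx[i], u = f$u[i], v = f$v[i])
  keep <- seq_along(f$val) != i
  f$val <- f$val[keep]
  f$mx <- f$mx[keep]
  f$u <- f$u[keep]
  f$v <- f$v[keep]
  out
}
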