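test_that("tree_height is the exact ceiling of log2", {
  expect_identical(tree_height(1), 0L)
  expect_identical(tree_height(5), 3L)
  expect_identical(tree_height(1024), 10L)
  expect_identical(tree_height(1025), 11L)
  expect_error(tree_height(0), ">= 1")
  for (m in 1:64) expect_identical(tree_height(m), as.integer(ceiling(log2(m))))
})

test_that("build_tree shapes the balanced tree and stays lazy", {
  tr1 <- build_tree(list(c(3, 1, 2)))
  expect_identical(tr1$root$kind, "leaf")

  tr8 <- build_tree(generate_fixture(8, 4, seed = 11))
  st <- tree_stats(tr8)
  expect_identical(sum(st$kind == "pair"), 7L)
  expect_identical(max(st$depth), 3L)
  expect_identical(sum(st$generated), 0)   # nothing generated before selection
  expect_identical(sum(st$emitted), 0)

  expect_error(build_tree(list()), "non-empty")
  expect_error(build_tree(list(1:3, numeric(0))), "array 2")
})

test_that("select_topk equals the exhaustive oracle on random instances", {
  expect_identical(select_topk(build_tree(list(c(3, 1, 2))), 2), c(1, 2))
  set.seed(401)
  for (i in 1:150) {
    inst <- rand_instance()
    oracle <- brute_force_topk(inst$arrays, inst$k)
    for (mode in c("standard", "wobbly")) {
      got <- select_topk(build_tree(inst$arrays, mode = mode), inst$k)
      expect_identical(sort(got), oracle)
    }
  }
})

test_that("for two arrays the tree agrees with the standalone pairwise selection", {
  set.seed(402)
  for (i in 1:50) {
    a <- sample(0:10000, sample.int(30, 1L), replace = TRUE)
    b <- sample(0:10000, sample.int(30, 1L), replace = TRUE)
    k <- sample.int(length(a) * length(b), 1L)
    tree_out <- select_topk(build_tree(list(a, b)), k)
    pair_out <- select_pairwise(a, b, k)
    expect_same_multiset(tree_out, pair_out)
  }
})

test_that("standard-mode layers respect schedule sizes and global ordering", {
  set.seed(403)
  arrays <- generate_fixture(4, 10)
  tr <- build_tree(arrays, mode = "standard")
  root <- tr$root
  sizes <- integer(0)
  repeat {
    lay <- generate_next_layer(root)
    if (is.null(lay)) break
    sizes <- c(sizes, length(lay))
  }
  expect_identical(sizes, layer_schedule(prod(lengths(arrays)), tr$alpha))
  # emitted layers, concatenated, are the fully sorted Cartesian product
  vals <- unlist(lapply(seq_along(sizes), function(j) root$layers[[j]]))
  expect_identical(length(vals), as.integer(prod(lengths(arrays))))
  for (j in seq_len(length(sizes) - 1L)) {
    expect_lte(max(root$layers[[j]]), min(root$layers[[j + 1L]]))
  }
  expect_identical(sort(vals), sort(all_sums(arrays)))
})

test_that("modes return the same multiset instance by instance", {
  set.seed(404)
  for (i in 1:40) {
    inst <- rand_instance(m_max = 5, n_max = 10)
    s <- select_topk(build_tree(inst$arrays, mode = "standard"), inst$k)
    w <- select_topk(build_tree(inst$arrays, mode = "wobbly"), inst$k)
    expect_same_multiset(s, w)
  }
})

test_that("wobbly homogeneous pathology: root pool is exactly 2^m", {
  for (m in 2:5) {
    tr <- build_tree(rep(list(c(0, 0)), m), mode = "wobbly")
    got <- select_topk(tr, 2)
    expect_identical(got, c(0, 0))
    expect_identical(root_pool_size(tr), 2^m)
  }
  # each level-1 node has emitted all 2^2 = 4 of its values after two layer
  # requests (the second request returns the exhausted signal)
  tr <- build_tree(rep(list(c(0, 0)), 4), mode = "wobbly")
  invisible(select_topk(tr, 2))
  lvl1 <- tr$root$left
  expect_null(generate_next_layer(lvl1))
  expect_identical(lvl1$emitted, 4)
})

test_that("small k leaves deep nodes nearly untouched", {
  arrays <- generate_fixture(8, 64, seed = 12)
  tr <- build_tree(arrays)
  invisible(select_topk(tr, 1))
  st <- tree_stats(tr)
  expect_true(all(st$emitted[st$kind == "pair"] <= 16))
  expect_true(all(st$layers <= 5))
})

test_that("per-node generated work stays proportional to emitted values", {
  set.seed(405)
  arrays <- generate_fixture(6, 128)
  tr <- build_tree(arrays)
  invisible(select_topk(tr, 500))
  st <- tree_stats(tr)
  pair <- st[st$kind == "pair", ]
  expect_true(all(pair$generated <= 10 * pair$emitted + 50))
})

test_that("provenance names the leaf elements that sum to each output", {
  set.seed(406)
  for (mode in c("standard", "wobbly")) {
    arrays <- generate_fixture(5, 6)
    tr <- build_tree(arrays, mode = mode, provenance = TRUE)
    res <- select_topk(tr, 20)
    expect_s3_class(res, "tbl_df")
    recon <- rep(0, nrow(res))
    for (j in seq_along(arrays)) {
      recon <- recon + arrays[[j]][res[[paste0("i", j)]]]
    }
    expect_identical(recon, res$value)
    expect_same_multiset(res$value, brute_force_topk(arrays, 20))
  }
})

test_that("max direction mirrors min on negated inputs", {
  set.seed(407)
  arrays <- generate_fixture(3, 8)
  k <- 10
  mx <- select_topk(build_tree(arrays, direction = "max"), k)
  want <- -brute_force_topk(lapply(arrays, function(x) -x), k)
  expect_same_multiset(mx, want)
})

test_that("generate_next_layer signals exhaustion and rejects leaves", {
  tr <- build_tree(list(c(1, 2), c(3, 4)))
  n <- 0L
  while (!is.null(generate_next_layer(tr))) n <- n + 1L
  expect_identical(n, length(layer_schedule(4, tr$alpha)))
  expect_null(generate_next_layer(tr)) # stays exhausted
  expect_error(generate_next_layer(build_tree(list(1:3))), "leaf")
})
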