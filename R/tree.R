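# Cartesian product tree.
#
# Nodes are environments so that per-node state (emitted LOH layers, the
# persistent frontier, the candidate buffer) survives across layer
# generations. Leaves wrap LOHified input arrays and "generate" a layer by
# exposing the next slice; pairwise nodes run a bounded A+B selection over
# their children's LOHs each time a new layer is requested.
#
# Inside tree nodes the frontier uses a unique-predecessor insertion scheme:
# when a min tuple (u, v) is popped, the max tuple (u, v) and the min tuple
# (u, v + 1) are always inserted, and (u + 1, v) only when v = 1. Each index
# pair then has exactly one predecessor, so no dedup set is needed (unlike
# the standalone pairwise selection, which uses the richer neighbor scheme
# plus a seen-set).

new_leaf <- function(x, alpha, provenance) {
  e <- new.env(parent = emptyenv())
  e$kind <- "leaf"
  if (provenance) {
    # full sort so every layer slice can be mapped back to original indices;
    # a sorted array trivially satisfies the layer-ordering property
    ord <- order(x)
    h <- lohify(as.numeric(x)[ord], alpha)
    e$index <- ord
  } else {
    h <- lohify(x, alpha)
    e$index <- NULL
  }
  lay <- loh_layers(h)
  e$values <- h$values
  e$sizes <- h$sizes
  e$starts <- h$layer_starts
  e$lay <- lay
  e$lmins <- vapply(lay, min, numeric(1))
  e$lmaxs <- vapply(lay, max, numeric(1))
  e$nlay_total <- length(h$sizes)
  e$exposed <- 0L
  e$capacity <- as.numeric(length(x))
  e$nleaves <- 1L
  e$generated <- 0
  e
}

new_pair <- function(left, right, alpha, mode, provenance) {
  e <- new.env(parent = emptyenv())
  e$kind <- "pair"
  e$left <- left
  e$right <- right
  e$alpha <- alpha
  e$mode <- mode
  e$prov <- provenance
  e$capacity <- left$capacity * right$capacity
  e$nleaves <- left$nleaves + right$nleaves
  e$layers <- list()
  e$layerprov <- list()
  e$lmins <- numeric(0)
  e$lmaxs <- numeric(0)
  e$emitted <- 0
  e$next_size <- 1
  e$f <- new_frontier()
  e$seeded <- FALSE
  e$buf <- numeric(0)
  e$bufprov <- NULL
  e$generated <- 0
  e$exhausted <- FALSE
  e
}

# ---- uniform node accessors -------------------------------------------------

node_nlayers <- function(nd) {
  if (nd$kind == "leaf") nd$exposed else length(nd$layers)
}

node_exhausted <- function(nd) {
  if (nd$kind == "leaf") nd$exposed >= nd$nlay_total else nd$exhausted
}

# make layer j available, generating child layers recursively as needed;
# FALSE when the node can never produce layer j (capacity reached)
node_ensure_layer <- function(nd, j) {
  if (nd$kind == "leaf") {
    if (j > nd$nlay_total) return(FALSE)
    if (nd$exposed < j) nd$exposed <- as.integer(j)
    return(TRUE)
  }
  while (length(nd$layers) < j && !nd$exhausted) pair_gen_layer(nd)
  length(nd$layers) >= j
}

node_layer_vals <- function(nd, j) {
  if (nd$kind == "leaf") nd$lay[[j]] else nd$layers[[j]]
}

node_layer_size <- function(nd, j) {
  if (nd$kind == "leaf") nd$sizes[j] else length(nd$layers[[j]])
}

node_layer_min <- function(nd, j) nd$lmins[j]
node_layer_max <- function(nd, j) nd$lmaxs[j]

node_layer_prov <- function(nd, j) {
  if (nd$kind == "leaf") {
    st <- nd$starts[j]
    matrix(nd$index[st:(st + nd$sizes[j] - 1L)], ncol = 1L)
  } else {
    nd$layerprov[[j]]
  }
}

node_emitted <- function(nd) {
  if (nd$kind == "leaf") {
    if (nd$exposed == 0L) 0 else sum(nd$sizes[seq_len(nd$exposed)])
  } else {
    nd$emitted
  }
}

# ---- layer generation at a pairwise node ------------------------------------

try_push_min <- function(nd, u, v) {
  if (!node_ensure_layer(nd$left, u)) return(FALSE)
  if (!node_ensure_layer(nd$right, v)) return(FALSE)
  frontier_push(nd$f,
                node_layer_min(nd$left, u) + node_layer_min(nd$right, v),
                0L, u, v)
  TRUE
}

pair_gen_layer <- function(nd) {
  if (nd$exhausted) return(NULL)
  if (!nd$seeded) {
    try_push_min(nd, 1L, 1L) # layer 1 exists for every non-empty child
    nd$seeded <- TRUE
  }
  f <- nd$f
  size_sched <- min(nd$next_size, nd$capacity - nd$emitted)
  target <- nd$emitted + size_sched

  while (f$s < target && frontier_size(f) > 0L) {
    t <- frontier_pop(f)
    u <- t$u; v <- t$v
    if (t$mx == 0L) {
      va <- node_layer_vals(nd$left, u)
      vb <- node_layer_vals(nd$right, v)
      prod <- as.vector(outer(va, vb, "+"))
      nd$buf <- c(nd$buf, prod)
      nd$generated <- nd$generated + length(prod)
      if (nd$prov) {
        pa <- node_layer_prov(nd$left, u)
        pb <- node_layer_prov(nd$right, v)
        na <- length(va); nb <- length(vb)
        pr <- cbind(pa[rep(seq_len(na), times = nb), , drop = FALSE],
                    pb[rep(seq_len(nb), each = na), , drop = FALSE])
        nd$bufprov <- rbind(nd$bufprov, pr)
      }
      frontier_push(f, node_layer_max(nd$left, u) + node_layer_max(nd$right, v),
                    1L, u, v)
      try_push_min(nd, u, v + 1L)
      if (v == 1L) try_push_min(nd, u + 1L, 1L)
    } else {
      f$s <- f$s + node_layer_size(nd$left, u) * node_layer_size(nd$right, v)
      f$last_max <- t$val
    }
  }

  if (nd$mode == "standard") {
    sz <- as.integer(min(size_sched, length(nd$buf)))
    pick <- order(nd$buf)[seq_len(sz)]
  } else {
    # wobbly: cut at the last popped max-tuple value instead of an exact size
    thr <- if (frontier_size(f) == 0L) Inf else f$last_max
    pick <- which(nd$buf <= thr)
    pick <- pick[order(nd$buf[pick])]
  }

  layer <- nd$buf[pick]
  if (length(layer) == 0L) {
    stop("internal error: a pairwise node emitted an empty layer")
  }
  keep <- rep(TRUE, length(nd$buf))
  keep[pick] <- FALSE
  nd$buf <- nd$buf[keep]
  nd$layers <- c(nd$layers, list(layer))
  nd$lmins <- c(nd$lmins, min(layer))
  nd$lmaxs <- c(nd$lmaxs, max(layer))
  if (nd$prov) {
    nd$layerprov <- c(nd$layerprov, list(nd$bufprov[pick, , drop = FALSE]))
    nd$bufprov <- nd$bufprov[keep, , drop = FALSE]
  }
  nd$emitted <- nd$emitted + length(layer)
  nd$next_size <- ceiling(nd$alpha * nd$next_size)
  if (nd$emitted >= nd$capacity) nd$exhausted <- TRUE
  layer
}

#' Generate the next LOH layer of a pairwise tree node
#'
#' Resumes the node's persistent frontier, pops layer-product tuples until
#' the accumulator `s` covers the node's cumulative emitted count plus the
#' next scheduled layer size, and emits the new layer (exact scheduled size
#' in standard mode; every buffered value at or below the last popped
#' max-tuple value in wobbly mode). Child layers referenced by new min
#' tuples are generated recursively on demand; min tuples whose child layer
#' can never exist are skipped permanently.
#'
#' @param node a pairwise node of a [build_tree()] tree, or the tree itself
#'   (its root is used).
#' @return numeric vector with the new layer's values, or `NULL` (the
#'   exhausted signal) when the node has emitted its full Cartesian product.
#' @export
generate_next_layer <- function(node) {
  if (inherits(node, "product_tree")) node <- node$root
  if (!is.environment(node) || is.null(node$kind)) {
    stop("`node` must be a product tree or one of its nodes")
  }
  if (node$kind == "leaf") {
    stop("generate_next_layer() cannot be called on a leaf; ",
         "leaves expose layers of their LOHified input array directly")
  }
  pair_gen_layer(node)
}

# ---- tree construction and selection ----------------------------------------

#' Height of a balanced binary product tree
#'
#' `ceiling(log2(m))`, computed in exact integer arithmetic (no floating
#' point log).
#'
#' @param m number of leaves (positive integer).
#' @return integer tree height; 0 for a single leaf.
#' @examples
#' tree_height(5) # 3
#' @export
tree_height <- function(m) {
  if (length(m) != 1L || is.na(m) || !is.numeric(m) || m != floor(m) || m < 1) {
    stop("`m` must be a single integer >= 1")
  }
  h <- 0L
  p <- 1
  while (p < m) {
    p <- p * 2
    h <- h + 1L
  }
  h
}

#' Build a Cartesian product tree over m arrays
#'
#' Constructs a balanced binary tree with one leaf per input array, pairing
#' X1 + X2, X3 + X4, ... and then the results of those pairs, so the height
#' is `ceiling(log2(m))`. With odd counts at a level the unpaired node is
#' promoted unchanged. Leaves are LOHified on construction; internal nodes
#' generate no values until [select_topk()] (or [generate_next_layer()])
#' asks for them.
#'
#' @param arrays list of non-empty numeric vectors.
#' @param alpha LOH rank (> 1) used at every node; default 1.1.
#' @param mode `"standard"` cuts every internal layer to its exact scheduled
#'   size with a rank selection; `"wobbly"` replaces internal selections
#'   with a value partition at the last popped max-tuple value, which can
#'   grow layers super-exponentially but defers all exact selection work to
#'   the root (beneficial for small m, e.g. isotopologue calculations).
#' @param direction `"min"` selects smallest sums, `"max"` largest (inputs
#'   and outputs are negated internally).
#' @param provenance track, for every emitted value, which element of each
#'   input array it is a sum of; required by [top_isotopologues()].
#' @return object of class `"product_tree"`.
#' @examples
#' tr <- build_tree(list(c(1, 2), c(10, 20), c(100, 200)))
#' select_topk(tr, 3)
#' @export
build_tree <- function(arrays, alpha = 1.1, mode = c("standard", "wobbly"),
                       direction = c("min", "max"), provenance = FALSE) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  check_alpha(alpha)
  if (!is.list(arrays) || length(arrays) == 0L) {
    stop("`arrays` must be a non-empty list of numeric vectors")
  }
  bad <- which(!vapply(arrays, function(x) is.numeric(x) && length(x) > 0L && !anyNA(x),
                       logical(1)))
  if (length(bad)) {
    stop(sprintf("array %d is empty, non-numeric, or contains NA", bad[1L]))
  }
  m <- length(arrays)
  xs <- if (direction == "max") lapply(arrays, function(x) -as.numeric(x)) else arrays
  leaves <- lapply(xs, new_leaf, alpha = alpha, provenance = provenance)
  level <- leaves
  while (length(level) > 1L) {
    nxt <- list()
    i <- 1L
    while (i + 1L <= length(level)) {
      nxt[[length(nxt) + 1L]] <- new_pair(level[[i]], level[[i + 1L]],
                                          alpha, mode, provenance)
      i <- i + 2L
    }
    if (i == length(level)) nxt[[length(nxt) + 1L]] <- level[[i]]
    level <- nxt
  }
  structure(
    list(root = level[[1L]],
         leaves = leaves,
         m = m,
         alpha = alpha,
         mode = mode,
         direction = direction,
         provenance = provenance,
         capacity = prod(vapply(arrays, function(x) as.numeric(length(x)),
                                numeric(1)))),
    class = "product_tree"
  )
}

#' @export
print.product_tree <- function(x, ...) {
  cat(sprintf("Cartesian product tree: %d arrays, height %d, mode %s, alpha %g\n",
              x$m, tree_height(x$m), x$mode, x$alpha))
  cat(sprintf("full product size: %s; root values emitted so far: %s\n",
              format(x$capacity, big.mark = ","),
              format(node_emitted(x$root), big.mark = ",")))
  invisible(x)
}

#' Select the k extreme values of X1 + X2 + ... + Xm
#'
#' Asks the root of a product tree for LOH layers until their cumulative
#' size reaches `k`; all values in earlier layers are part of the answer
#' verbatim (by the layer-ordering property), and a single rank selection on
#' the last layer supplies the remainder. Both tree modes return the same
#' multiset; they differ only in internal layer bookkeeping.
#'
#' @param tree object from [build_tree()].
#' @param k number of values to select; clamped to the full product size
#'   with a warning unless `strict_k = TRUE`.
#' @param strict_k error instead of clamping an oversized `k`.
#' @return without provenance, a numeric vector of length `k` in
#'   non-decreasing order. With provenance (set at [build_tree()] time), a
#'   tibble with column `value` and integer columns `i1 ... im` giving, for
#'   each selected sum, the index of the contributing element in each input
#'   array.
#' @examples
#' arrays <- list(c(5, 1, 3), c(10, 20), c(0, 100))
#' select_topk(build_tree(arrays), 4)
#' @export
select_topk <- function(tree, k, strict_k = FALSE) {
  if (!inherits(tree, "product_tree")) stop("`tree` must be a product tree")
  k <- check_k(k, tree$capacity, strict_k)
  root <- tree$root

  repeat {
    nl <- node_nlayers(root)
    have <- node_emitted(root)
    if (have >= k) break
    if (!node_ensure_layer(root, nl + 1L)) break
  }

  take <- k
  vals <- numeric(0)
  prov <- NULL
  for (j in seq_len(node_nlayers(root))) {
    lv <- node_layer_vals(root, j)
    if (take >= length(lv)) {
      vals <- c(vals, lv)
      if (tree$provenance) prov <- rbind(prov, node_layer_prov(root, j))
      take <- take - length(lv)
    } else {
      if (tree$provenance) {
        pick <- order(lv)[seq_len(take)]
        vals <- c(vals, lv[pick])
        prov <- rbind(prov, node_layer_prov(root, j)[pick, , drop = FALSE])
      } else {
        vals <- c(vals, select_rank_k(lv, take))
      }
      take <- 0
    }
    if (take == 0) break
  }

  if (tree$direction == "max") vals <- -vals
  if (!tree$provenance) return(vals)
  colnames(prov) <- paste0("i", seq_len(ncol(prov)))
  out <- tibble::as_tibble(as.data.frame(prov))
  out <- tibble::add_column(out, value = vals, .before = 1L)
  out
}

# ---- instrumentation ---------------------------------------------------------

#' Per-node accounting of a product tree
#'
#' Walks the tree and reports, for every node, how many LOH layers and
#' values it has emitted, how many candidate values it has generated into
#' its buffer, and whether it is exhausted. Useful for inspecting laziness
#' (deep nodes should materialize few layers for small k) and the O(k)
#' candidate bound.
#'
#' @param tree object from [build_tree()].
#' @return tibble with one row per node: `node`, `depth`, `kind`,
#'   `capacity`, `layers`, `emitted`, `generated`, `exhausted`.
#' @export
tree_stats <- function(tree) {
  if (!inherits(tree, "product_tree")) stop("`tree` must be a product tree")
  rows <- list()
  id <- 0L
  walk <- function(nd, depth) {
    id <<- id + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      node = id,
      depth = depth,
      kind = nd$kind,
      capacity = nd$capacity,
      layers = node_nlayers(nd),
      emitted = node_emitted(nd),
      generated = nd$generated,
      exhausted = node_exhausted(nd),
      stringsAsFactors = FALSE
    )
    if (nd$kind == "pair") {
      walk(nd$left, depth + 1L)
      walk(nd$right, depth + 1L)
    }
  }
  walk(tree$root, 0L)
  tibble::as_tibble(do.call(rbind, rows))
}

#' Total candidate values generated by a tree's internal nodes
#'
#' @param tree object from [build_tree()].
#' @return single number: sum over pairwise nodes of values generated into
#'   their buffers (leaf values are inputs and are not counted).
#' @export
total_candidates <- function(tree) {
  st <- tree_stats(tree)
  sum(st$generated[st$kind == "pair"])
}

#' Size of the root candidate pool
#'
#' Number of values the root has emitted into its own LOH, i.e. the pool the
#' final rank selection of [select_topk()] draws from.
#'
#' @param tree object from [build_tree()].
#' @return single number.
#' @export
root_pool_size <- function(tree) {
  node_emitted(tree$root)
}
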