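#' Optimal selection of the k smallest values of A + B
#'
#' Standalone four-phase pairwise selection on the Cartesian sum of two
#' arrays. Phase 0 LOHifies the inputs (skipped when they already are LOHs).
#' Phase 1 walks a frontier of layer-product min/max tuples starting from the
#' (1, 1) layer product: popping a min tuple for layers (u, v) pushes its
#' corresponding max tuple and the neighboring min tuples (u + 1, v) and
#' (u, v + 1), bounds-checked and deduplicated with a seen-set; popping a max
#' tuple adds the layer product's size |A^(u)| * |B^(v)| to the accumulator
#' `s` and commits the index pair to the list `q`. The walk stops as soon as
#' `s >= k`, which certifies that the committed and still-frontiered layer
#' products contain the k smallest sums. Phases 2-3 append the indices of
#' all max tuples still in the frontier to `q`, generate the values of every
#' committed layer product, and cut them to exactly `k` with
#' [select_rank_k()]. The total number of values generated is O(k) for fixed
#' `alpha`.
#'
#' @param A,B numeric vectors, or `"loh"` objects built with [lohify()].
#' @param k number of smallest (or largest, see `direction`) sums to return.
#'   Values above `length(A) * length(B)` are clamped with a warning unless
#'   `strict_k = TRUE`.
#' @param alpha LOH rank used when `A` or `B` must be LOHified; > 1.
#' @param direction `"min"` (default) returns the k smallest sums, `"max"`
#'   negates inputs and outputs to return the k largest.
#' @param strict_k error instead of clamping an oversized `k`.
#' @return numeric vector of length `k`, the selected sums as a multiset (in
#'   unspecified order), with attribute `"n_candidates"` giving the number of
#'   candidate values generated before the final cut.
#' @examples
#' sort(select_pairwise(c(1, 2), c(10, 20), k = 3)) # 11 12 21
#' @seealso [select_topk()] for m > 2 arrays.
#' @export
select_pairwise <- function(A, B, k, alpha = 1.1,
                            direction = c("min", "max"), strict_k = FALSE) {
  direction <- match.arg(direction)
  if (direction == "max") {
    Av <- if (inherits(A, "loh")) A$values else A
    Bv <- if (inherits(B, "loh")) B$values else B
    out <- select_pairwise(-as.numeric(Av), -as.numeric(Bv), k = k,
                           alpha = alpha, direction = "min",
                           strict_k = strict_k)
    nc <- attr(out, "n_candidates")
    out <- -out
    attr(out, "n_candidates") <- nc
    return(out)
  }
  if (!inherits(A, "loh")) A <- lohify(A, alpha)
  if (!inherits(B, "loh")) B <- lohify(B, alpha)
  nA <- length(A$values)
  nB <- length(B$values)
  cap <- as.numeric(nA) * as.numeric(nB)
  k <- check_k(k, cap, strict_k)

  layA <- loh_layers(A)
  layB <- loh_layers(B)
  minA <- vapply(layA, min, numeric(1)); maxA <- vapply(layA, max, numeric(1))
  minB <- vapply(layB, min, numeric(1)); maxB <- vapply(layB, max, numeric(1))
  szA <- lengths(layA); szB <- lengths(layB)
  LA <- length(layA); LB <- length(layB)

  f <- new_frontier()
  seen <- matrix(FALSE, LA, LB)
  frontier_push(f, minA[1L] + minB[1L], 0L, 1L, 1L)
  seen[1L, 1L] <- TRUE
  q_u <- integer(0)
  q_v <- integer(0)

  while (f$s < k && frontier_size(f) > 0L) {
    t <- frontier_pop(f)
    u <- t$u; v <- t$v
    if (t$mx == 0L) {
      frontier_push(f, maxA[u] + maxB[v], 1L, u, v)
      if (u + 1L <= LA && !seen[u + 1L, v]) {
        frontier_push(f, minA[u + 1L] + minB[v], 0L, u + 1L, v)
        seen[u + 1L, v] <- TRUE
      }
      if (v + 1L <= LB && !seen[u, v + 1L]) {
        frontier_push(f, minA[u] + minB[v + 1L], 0L, u, v + 1L)
        seen[u, v + 1L] <- TRUE
      }
    } else {
      f$s <- f$s + as.numeric(szA[u]) * szB[v]
      q_u <- c(q_u, u)
      q_v <- c(q_v, v)
    }
  }
  rem <- which(f$mx == 1L)
  q_u <- c(q_u, f$u[rem])
  q_v <- c(q_v, f$v[rem])

  vals <- unlist(lapply(seq_along(q_u), function(i) {
    as.vector(outer(layA[[q_u[i]]], layB[[q_v[i]]], "+"))
  }), use.names = FALSE)

  out <- select_rank_k(vals, k)
  attr(out, "n_candidates") <- length(vals)
  out
}

# shared k validation/clamping
check_k <- function(k, cap, strict_k) {
  if (length(k) != 1L || !is.numeric(k) || is.na(k) || k != floor(k) || k < 1) {
    stop("`k` must be a single integer >= 1")
  }
  if (k > cap) {
    if (strict_k) {
      stop(sprintf("`k` = %s exceeds the Cartesian-product size %s",
                   format(k, scientific = FALSE),
                   format(cap, scientific = FALSE)))
    }
    warning(sprintf("`k` = %s exceeds the Cartesian-product size %s; clamping",
                    format(k, scientific = FALSE),
                    format(cap, scientific = FALSE)))
    k <- cap
  }
  k
}
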