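#' Layer size schedule for a layer-ordered heap
#'
#' Computes the sizes of the layers L1, L2, ... of a rank-`alpha` LOH over
#' `n` values: the first layer has size 1 and sizes grow by the recurrence
#' `s[i+1] = ceiling(alpha * s[i])`, with the final layer truncated so the
#' sizes sum to exactly `n`. The ratio of consecutive sizes approaches
#' `alpha` asymptotically. `alpha` must be strictly greater than 1: at
#' `alpha = 1` every layer has size one and the heap degenerates into a full
#' sort, which forfeits the linear-time construction.
#'
#' @param n number of values (positive integer).
#' @param alpha layer growth rank, `alpha > 1`. Default 1.1, a good balance
#'   between heap-pop overhead and over-generation in downstream selections.
#' @return integer vector of layer sizes summing to `n`; all entries >= 1 and
#'   the first entry is 1.
#' @examples
#' layer_schedule(15, 2)    # 1 2 4 8
#' layer_schedule(10, 1.1)  # 1 2 3 4
#' @export
layer_schedule <- function(n, alpha = 1.1) {
  check_alpha(alpha)
  if (length(n) != 1L || is.na(n) || !is.numeric(n) || n != floor(n) || n < 1) {
    stop("`n` must be a single integer >= 1")
  }
  n <- as.numeric(n)
  sizes <- integer(0)
  s <- 1
  total <- 0
  while (total < n) {
    take <- min(s, n - total)
    sizes <- c(sizes, as.integer(take))
    total <- total + take
    s <- ceiling(alpha * s)
  }
  sizes
}

check_alpha <- function(alpha) {
  if (length(alpha) != 1L || !is.numeric(alpha) || is.na(alpha) || alpha <= 1) {
    stop("`alpha` must be a single numeric value > 1 ",
         "(alpha = 1 degenerates to a full sort)")
  }
  invisible(alpha)
}

#' Build a layer-ordered heap
#'
#' Partitions `values` into layers L1, L2, ... following
#' [layer_schedule()] such that every value in layer i is <= every value in
#' layer i+1 (the layer-ordering property). Values within a layer are in
#' arbitrary order. Construction is a sequence of rank selections at the
#' cumulative layer boundaries, applied from the largest boundary down so the
#' total work is a geometric series, i.e. expected linear in `length(values)`.
#'
#' @param values non-empty numeric vector (unsorted is fine).
#' @param alpha layer growth rank, > 1.
#' @return an object of class `"loh"`: a list with `values` (the permuted
#'   input), `sizes` (layer sizes), `layer_starts` (1-based offsets of each
#'   layer) and `alpha`.
#' @examples
#' h <- lohify(c(9, 3, 7, 1, 5, 2, 8), alpha = 2)
#' loh_layers(h)
#' @seealso [verify_loh()], [loh_layers()]
#' @export
lohify <- function(values, alpha = 1.1) {
  if (!is.numeric(values)) stop("`values` must be a numeric vector")
  n <- length(values)
  if (n == 0L) stop("cannot LOHify an empty array")
  if (anyNA(values)) stop("`values` must not contain NA")
  check_alpha(alpha)
  sizes <- layer_schedule(n, alpha)
  bounds <- cumsum(sizes)
  x <- as.numeric(values)
  nb <- length(bounds)
  if (nb >= 2L) {
    # partition the prefix ending at each boundary, largest boundary first
    for (j in seq.int(nb - 1L, 1L)) {
      m <- bounds[j + 1L]
      x[seq_len(m)] <- sort(x[seq_len(m)], partial = bounds[j])
    }
  }
  structure(
    list(values = x,
         sizes = sizes,
         layer_starts = c(1L, bounds[-nb] + 1L),
         alpha = alpha),
    class = "loh"
  )
}

#' Extract the layers of a layer-ordered heap
#'
#' @param heap an object of class `"loh"`.
#' @return list of numeric vectors, one per layer.
#' @export
loh_layers <- function(heap) {
  stopifnot(inherits(heap, "loh"))
  mapply(function(st, sz) heap$values[st:(st + sz - 1L)],
         heap$layer_starts, heap$sizes, SIMPLIFY = FALSE)
}

#' @export
print.loh <- function(x, ...) {
  cat(sprintf("Layer-ordered heap: %d values in %d layers (alpha = %g)\n",
              length(x$values), length(x$sizes), x$alpha))
  cat("layer sizes:", paste(x$sizes, collapse = " "), "\n")
  invisible(x)
}

#' Verify the invariants of a layer-ordered heap
#'
#' Checks that (i) the first layer has size one, (ii) layer sizes follow
#' [layer_schedule()] for the heap's `alpha`, (iii) the layer-ordering
#' property `max(L_i) <= min(L_{i+1})` holds for every consecutive pair, and
#' (iv), when `reference` is supplied, that the heap's values are a
#' permutation (multiset equality) of the reference array.
#'
#' @param heap an object of class `"loh"`.
#' @param reference optional numeric vector the heap was built from.
#' @return an object of class `"loh_check"`: list with `ok` (logical),
#'   `first_violation` (index i of the first layer pair violating the
#'   ordering property, or `NA`) and `messages` (character diagnostics,
#'   empty when `ok`).
#' @export
verify_loh <- function(heap, reference = NULL) {
  msgs <- character(0)
  first_bad <- NA_integer_
  if (!inherits(heap, "loh")) {
    return(structure(list(ok = FALSE, first_violation = NA_integer_,
                          messages = "not an object of class 'loh'"),
                     class = "loh_check"))
  }
  n <- length(heap$values)
  L <- length(heap$sizes)
  if (heap$sizes[1L] != 1L) {
    msgs <- c(msgs, "first layer does not have size 1")
  }
  sched <- layer_schedule(n, heap$alpha)
  if (!identical(as.integer(heap$sizes), as.integer(sched))) {
    msgs <- c(msgs, "layer sizes do not follow the layer schedule")
  }
  if (sum(heap$sizes) != n) {
    msgs <- c(msgs, "layer sizes do not sum to the number of values")
  }
  lay <- loh_layers(heap)
  if (L >= 2L) {
    for (i in seq_len(L - 1L)) {
      if (max(lay[[i]]) > min(lay[[i + 1L]])) {
        first_bad <- i
        msgs <- c(msgs, sprintf(
          "layer-ordering property violated between layers %d and %d", i, i + 1L))
        break
      }
    }
  }
  if (!is.null(reference)) {
    if (!identical(sort(as.numeric(heap$values)), sort(as.numeric(reference)))) {
      msgs <- c(msgs, "heap values are not a permutation of the reference array")
    }
  }
  structure(list(ok = length(msgs) == 0L,
                 first_violation = first_bad,
                 messages = msgs),
            class = "loh_check")
}

#' @export
print.loh_check <- function(x, ...) {
  if (x$ok) cat("LOH check: ok\n")
  else cat("LOH check: FAILED\n ", paste(x$messages, collapse = "\n  "), "\n")
  invisible(x)
}
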