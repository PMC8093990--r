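#' Select the k smallest values of a numeric vector
#'
#' Linear-time rank selection: returns a multiset equal to the k smallest
#' elements of `values`, in unspecified order. This is the one-dimensional
#' selection kernel used throughout the package (LOH construction, the final
#' cut of a pairwise selection, and the last root layer of a product tree).
#'
#' The implementation rides on base R's partial sort (`sort(values,
#' partial = k)`), a C-level quickselect with expected linear running time.
#' Ties at the rank-k boundary are broken deterministically (exactly `k`
#' values are always returned).
#'
#' @param values numeric vector, no `NA`s.
#' @param k single integer, `1 <= k <= length(values)`.
#' @return numeric vector of length `k`: the k smallest values of `values`
#'   as a multiset (not necessarily sorted).
#' @examples
#' sort(select_rank_k(c(5, 1, 4, 2, 3), 2)) # 1 2
#' @seealso [partition_by_value()] for threshold-based partitions.
#' @export
select_rank_k <- function(values, k) {
  if (!is.numeric(values)) stop("`values` must be a numeric vector")
  n <- length(values)
  if (n == 0L) stop("`values` must be non-empty")
  if (anyNA(values)) stop("`values` must not contain NA")
  if (length(k) != 1L || is.na(k) || !is.numeric(k) || k != floor(k)) {
    stop("`k` must be a single integer")
  }
  if (k < 1 || k > n) {
    stop(sprintf("`k` must be between 1 and %d (= length(values)), got %s",
                 n, format(k)))
  }
  k <- as.integer(k)
  if (k == n) return(values)
  sort(values, partial = k)[seq_len(k)]
}

#' Keep all values at or below a threshold
#'
#' Value partition: returns every element of `values` that is `<= threshold`,
#' including all ties at the threshold. This is the cheap alternative to an
#' exact rank selection used by the wobbly product-tree mode, where internal
#' layers are cut at the value of the last popped max tuple instead of at an
#' exact size.
#'
#' @param values numeric vector.
#' @param threshold single numeric cut value.
#' @return numeric vector: the sub-multiset of `values` with `v <= threshold`.
#' @examples
#' partition_by_value(c(3, 7, 7, 9), 7) # 3 7 7
#' @export
partition_by_value <- function(values, threshold) {
  if (!is.numeric(values)) stop("`values` must be a numeric vector")
  if (length(threshold) != 1L || !is.numeric(threshold) || is.na(threshold)) {
    stop("`threshold` must be a single numeric value")
  }
  values[values <= threshold]
}
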