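#' Read numeric arrays from delimited text
#'
#' Two layouts are supported. `"rows"` (default): each non-empty line of a
#' single file is one array, fields separated by commas, tabs or spaces;
#' arrays may have different lengths. `"file"`: each path in `path` yields
#' one array made of all numeric tokens in that file.
#'
#' @param path file path (`"rows"`) or vector of file paths (`"file"`).
#' @param layout `"rows"` or `"file"`.
#' @return list of numeric vectors in file order.
#' @export
read_arrays <- function(path, layout = c("rows", "file")) {
  layout <- match.arg(layout)
  parse_tokens <- function(tokens, row) {
    vals <- suppressWarnings(as.numeric(tokens))
    bad <- which(is.na(vals))
    if (length(bad)) {
      stop(sprintf("non-numeric token '%s' at row %d, column %d",
                   tokens[bad[1L]], row, bad[1L]))
    }
    vals
  }
  if (layout == "rows") {
    if (length(path) != 1L) stop("layout 'rows' expects a single file path")
    lines <- readLines(path)
    if (length(lines) == 0L) stop("no arrays found in ", path)
    out <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      tokens <- strsplit(trimws(lines[i]), "[,\t ]+")[[1L]]
      if (length(tokens) == 0L || identical(tokens, "")) {
        stop(sprintf("array %d (row %d) is empty", i, i))
      }
      out[[i]] <- parse_tokens(tokens, i)
    }
    out
  } else {
    lapply(seq_along(path), function(i) {
      lines <- readLines(path[i])
      tokens <- unlist(strsplit(trimws(lines), "[,\t ]+"), use.names = FALSE)
      tokens <- tokens[nzchar(tokens)]
      if (length(tokens) == 0L) stop(sprintf("array %d ('%s') is empty", i, path[i]))
      parse_tokens(tokens, 1L)
    })
  }
}

#' Write numeric arrays as delimited text
#'
#' One array per line, space separated, 12 significant digits (integers
#' round-trip exactly).
#'
#' @param arrays list of numeric vectors.
#' @param path output file path.
#' @return `invisible(arrays)`.
#' @export
write_arrays <- function(arrays, path) {
  lines <- vapply(arrays, function(x) paste(sprintf("%.12g", x), collapse = " "),
                  character(1))
  writeLines(lines, path)
  invisible(arrays)
}

#' Generate synthetic input arrays
#'
#' Draws `m` arrays of uniform random integers on `[low, high]`, the
#' distributional setup used throughout the package's empirical checks
#' (defaults: integers between 0 and 10,000). Reproducible under `seed`;
#' the caller's RNG state is restored afterwards.
#'
#' @param m number of arrays.
#' @param n array length; a scalar, or a vector of `m` per-array lengths.
#' @param low,high inclusive integer bounds.
#' @param seed optional integer seed; `NULL` uses (and advances) the current
#'   RNG state.
#' @return list of `m` numeric vectors.
#' @examples
#' generate_fixture(2, 4, seed = 1)
#' @export
generate_fixture <- function(m, n, low = 0, high = 10000, seed = NULL) {
  if (length(m) != 1L || is.na(m) || m < 1 || m != floor(m)) {
    stop("`m` must be a single integer >= 1")
  }
  if (any(is.na(n)) || any(n < 1) || any(n != floor(n))) {
    stop("`n` must be integer(s) >= 1")
  }
  if (!(length(n) %in% c(1L, m))) stop("`n` must have length 1 or m")
  if (low > high) stop("`low` must be <= `high`")
  n <- rep(as.integer(n), length.out = m)
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  span <- high - low + 1
  lapply(seq_len(m), function(i) {
    as.numeric(low + sample.int(span, n[i], replace = TRUE) - 1)
  })
}

#' Brute-force top-k of a Cartesian sum
#'
#' Enumerates every value of X1 + X2 + ... + Xm, then returns the k smallest
#' in sorted order. This is the ground-truth oracle the package's
#' equivalence tests compare against; it is only feasible when the full
#' product fits in memory, hence the cap.
#'
#' @param arrays list of non-empty numeric vectors.
#' @param k number of values to return (clamped to the product size with a
#'   warning).
#' @param cap maximum allowed product size.
#' @return sorted numeric vector of length `k`.
#' @examples
#' brute_force_topk(list(c(1, 2), c(10, 20)), 2) # 11 12
#' @export
brute_force_topk <- function(arrays, k, cap = 1e7) {
  if (!is.list(arrays) || length(arrays) == 0L) {
    stop("`arrays` must be a non-empty list of numeric vectors")
  }
  if (any(lengths(arrays) == 0L)) stop("arrays must be non-empty")
  total <- prod(vapply(arrays, function(x) as.numeric(length(x)), numeric(1)))
  if (total > cap) {
    stop(sprintf("full product has %s values, above the enumeration cap %s",
                 format(total, big.mark = ","), format(cap, big.mark = ",")))
  }
  k <- check_k(k, total, strict_k = FALSE)
  vals <- Reduce(function(a, b) as.vector(outer(a, b, "+")),
                 lapply(arrays, as.numeric))
  sort(select_rank_k(vals, k))
}
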