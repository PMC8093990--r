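#' Parse a molecular formula
#'
#' Parses strings like `"H2O"` or `"C2952H4664O832N812S8Fe4"` into a named
#' vector of atom counts. An element symbol with no trailing count means one
#' atom. Repeated symbols are summed. Every symbol must be present in the
#' isotope table.
#'
#' @param formula single string of `Element(Count?)` groups.
#' @param table isotope table (see [isotope_table()]); used to reject
#'   unknown element symbols.
#' @return named integer vector of atom counts, in first-appearance order.
#' @examples
#' parse_formula("H2O")
#' @export
parse_formula <- function(formula, table = isotope_table()) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula)) {
    stop("`formula` must be a single non-empty string")
  }
  g <- gregexpr("[A-Z][a-z]?[0-9]*", formula)
  m <- g[[1L]]
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  if (starts[1L] == -1L) {
    stop(sprintf("malformed formula at position 1: '%s'", formula))
  }
  expect <- 1L
  for (i in seq_along(starts)) {
    if (starts[i] != expect) {
      stop(sprintf("malformed formula at position %d: '%s'", expect, formula))
    }
    expect <- starts[i] + lens[i]
  }
  if (expect != nchar(formula) + 1L) {
    stop(sprintf("malformed formula at position %d: '%s'", expect, formula))
  }
  tokens <- regmatches(formula, g)[[1L]]
  sym <- sub("[0-9]*$", "", tokens)
  cnt_str <- sub("^[A-Za-z]+", "", tokens)
  cnt <- ifelse(cnt_str == "", 1L, suppressWarnings(as.integer(cnt_str)))
  zero <- which(cnt < 1L)
  if (length(zero)) {
    stop(sprintf("atom count must be >= 1 at position %d: '%s'",
                 starts[zero[1L]], formula))
  }
  known <- unique(table$element)
  unknown <- which(!(sym %in% known))
  if (length(unknown)) {
    stop(sprintf("unknown element '%s' at position %d",
                 sym[unknown[1L]], starts[unknown[1L]]))
  }
  out <- tapply(cnt, factor(sym, levels = unique(sym)), sum)
  stats::setNames(as.integer(out), names(out))
}

# all non-negative integer vectors of length `parts` summing to `n`
# (stars and bars); rows ordered lexicographically by the first coordinates
compositions <- function(n, parts) {
  if (parts == 1L) return(matrix(n, nrow = 1L, ncol = 1L))
  do.call(rbind, lapply(0:n, function(j) {
    cbind(j, compositions(n - j, parts - 1L), deparse.level = 0)
  }))
}

#' Isotope combinations of one element
#'
#' Enumerates every way `count` atoms of an element can be distributed over
#' its isotopes (stars-and-bars: `choose(count + i - 1, i - 1)` multisets
#' for `i` isotopes) and computes each combination's probability under the
#' multinomial model with the table abundances, entirely in log space
#' (log-gamma factorials) so proteome-scale atom counts do not underflow.
#'
#' @param element element symbol present in `table`.
#' @param count number of atoms (>= 1).
#' @param table isotope table; see [isotope_table()].
#' @param keep retain only the `keep` most probable combinations (default
#'   all). Truncation can in principle exclude members of the true top-k of
#'   a full molecule; a warning reports the retained probability mass.
#' @param cap guard on the enumeration size; exceeding it is an error.
#' @return tibble sorted by `neg_log_prob` ascending (ties: mass ascending)
#'   with columns `neg_log_prob`, `prob`, `mass`, and a `counts` matrix
#'   column whose columns are labeled by isotope (e.g. `C12`, `C13`).
#' @examples
#' element_combinations("S", 8) # 165 combinations, probabilities sum to 1
#' @export
element_combinations <- function(element, count, table = isotope_table(),
                                 keep = Inf, cap = 1e6) {
  if (length(count) != 1L || is.na(count) || count != floor(count) || count < 1) {
    stop("`count` must be a single integer >= 1")
  }
  if (length(keep) != 1L || is.na(keep) || keep < 1) {
    stop("`keep` must be a single value >= 1")
  }
  validate_isotope_table(table)
  d <- table[table$element == element, ]
  if (nrow(d) == 0L) stop(sprintf("unknown element '%s'", element))
  d <- d[order(d$mass), ]
  ni <- nrow(d)
  ncomb <- choose(count + ni - 1, ni - 1)
  if (ncomb > cap) {
    stop(sprintf(
      "element %s with %d atoms has %s isotope combinations, above the cap of %s",
      element, count, format(ncomb, big.mark = ","), format(cap, big.mark = ",")))
  }
  cm <- compositions(as.integer(count), ni)
  logp <- lgamma(count + 1) - rowSums(lgamma(cm + 1)) +
    as.vector(cm %*% log(d$abundance))
  nlp <- -logp
  mass <- as.vector(cm %*% d$mass)
  ord <- order(nlp, mass)
  cm <- cm[ord, , drop = FALSE]
  colnames(cm) <- paste0(element, d$mass_number)
  out <- tibble::tibble(neg_log_prob = nlp[ord],
                        prob = exp(logp[ord]),
                        mass = mass[ord])
  out$counts <- cm
  if (is.finite(keep) && keep < nrow(out)) {
    retained <- sum(out$prob[seq_len(keep)])
    warning(sprintf(
      "keeping %d of %d combinations for %s%d; retained probability mass %.6g",
      as.integer(keep), nrow(out), element, count, retained))
    out <- out[seq_len(keep), ]
  }
  out
}

#' The k most probable isotopologues of a molecular formula
#'
#' An isotopologue assigns each atom of a molecule to one of its element's
#' isotopes; its probability is the product of independent per-element
#' multinomial terms and its exact mass is the sum of the per-element
#' masses. Maximizing a product of probabilities is minimizing a sum of
#' -log probabilities, so the k most probable species are the k smallest
#' values of a Cartesian sum with one leaf array per element - precisely
#' the selection [build_tree()] performs. The tree runs with provenance so
#' each selected value can be reconstituted into its per-element isotope
#' counts.
#'
#' @param formula molecular formula string, e.g. `"C2952H4664O832N812S8Fe4"`.
#' @param k number of species to return; clamped (with a warning) to the
#'   total number of isotopologues.
#' @param alpha LOH rank of the tree; default 1.1.
#' @param mode tree mode; `"wobbly"` by default, which is the favorable
#'   regime here because formulas have few distinct elements (small m).
#' @param keep optional per-element truncation passed to
#'   [element_combinations()].
#' @param table isotope table; see [isotope_table()] and
#'   [read_isotope_table()].
#' @param cap per-element enumeration guard.
#' @return tibble sorted by probability descending (ties: mass ascending)
#'   with columns `probability`, `mass`, `neg_log_prob`, and one integer
#'   count column per isotope (e.g. `H1`, `H2`, `O16`, `O17`, `O18`).
#' @examples
#' top_isotopologues("H2O", k = 3)
#' @export
top_isotopologues <- function(formula, k, alpha = 1.1,
                              mode = c("wobbly", "standard"), keep = Inf,
                              table = isotope_table(), cap = 1e6) {
  mode <- match.arg(mode)
  counts <- parse_formula(formula, table)
  els <- names(counts)
  combos <- lapply(els, function(el) {
    element_combinations(el, counts[[el]], table = table, keep = keep, cap = cap)
  })
  leaves <- lapply(combos, function(cb) cb$neg_log_prob)
  tree <- build_tree(leaves, alpha = alpha, mode = mode, direction = "min",
                     provenance = TRUE)
  sel <- select_topk(tree, k)
  idx <- as.matrix(sel[paste0("i", seq_along(els))])

  prob <- rep(1, nrow(sel))
  mass <- rep(0, nrow(sel))
  nlp <- rep(0, nrow(sel))
  cnt_blocks <- vector("list", length(els))
  for (j in seq_along(els)) {
    cb <- combos[[j]]
    rows <- idx[, j]
    prob <- prob * cb$prob[rows]
    mass <- mass + cb$mass[rows]
    nlp <- nlp + cb$neg_log_prob[rows]
    cnt_blocks[[j]] <- cb$counts[rows, , drop = FALSE]
  }
  cnts <- do.call(cbind, cnt_blocks)
  ord <- order(nlp, mass) # prob descending == -log prob ascending; underflow-safe
  out <- cbind(data.frame(probability = prob[ord],
                          mass = mass[ord],
                          neg_log_prob = nlp[ord]),
               as.data.frame(cnts[ord, , drop = FALSE]))
  tibble::as_tibble(out)
}

#' Write isotopologues to delimited text
#'
#' Tab-separated output with the columns of [top_isotopologues()]; floating
#' point values are written with 12 significant digits.
#'
#' @param x tibble from [top_isotopologues()].
#' @param path output file path (or `""` for stdout).
#' @return `invisible(x)`.
#' @export
write_isotopologues <- function(x, path) {
  fmt <- x
  for (nm in names(fmt)) {
    if (is.double(fmt[[nm]])) fmt[[nm]] <- sprintf("%.12g", fmt[[nm]])
  }
  utils::write.table(fmt, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}
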