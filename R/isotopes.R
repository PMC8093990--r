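# Embedded isotope masses (Da) and standard terrestrial abundances.
# Masses within each element are listed in strictly increasing order and
# abundances sum to 1. Overridable at call sites via read_isotope_table().
.iso_data <- list(
  H  = list(mass = c(1.00782503207, 2.0141017778),
            abundance = c(0.999885, 0.000115)),
  C  = list(mass = c(12.0, 13.0033548378),
            abundance = c(0.9893, 0.0107)),
  N  = list(mass = c(14.0030740048, 15.0001088982),
            abundance = c(0.99636, 0.00364)),
  O  = list(mass = c(15.9949146196, 16.9991317, 17.999161),
            abundance = c(0.99757, 0.00038, 0.00205)),
  F  = list(mass = 18.99840322, abundance = 1),
  Na = list(mass = 22.9897692809, abundance = 1),
  Mg = list(mass = c(23.9850417, 24.98583692, 25.982592929),
            abundance = c(0.7899, 0.1000, 0.1101)),
  Si = list(mass = c(27.9769265325, 28.9764947, 29.97377017),
            abundance = c(0.92223, 0.04685, 0.03092)),
  P  = list(mass = 30.97376163, abundance = 1),
  S  = list(mass = c(31.972071, 32.97145876, 33.9678669, 35.96708076),
            abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  Cl = list(mass = c(34.96885268, 36.96590259),
            abundance = c(0.7576, 0.2424)),
  K  = list(mass = c(38.96370668, 39.96399848, 40.96182576),
            abundance = c(0.932581, 0.000117, 0.067302)),
  Ca = list(mass = c(39.96259098, 41.95861801, 42.9587666, 43.9554818,
                     45.9536926, 47.952534),
            abundance = c(0.96941, 0.00647, 0.00135, 0.02086, 0.00004, 0.00187)),
  Fe = list(mass = c(53.9396105, 55.9349375, 56.935394, 57.9332756),
            abundance = c(0.05845, 0.91754, 0.02119, 0.00282)),
  Br = list(mass = c(78.9183371, 80.9162906),
            abundance = c(0.5069, 0.4931)),
  I  = list(mass = 126.904473, abundance = 1)
)

#' Embedded isotope mass and abundance table
#'
#' Standard terrestrial isotope masses (Da) and abundances for the elements
#' supported out of the box. No download is required; an alternative table
#' can be loaded with [read_isotope_table()] and passed to the isotopologue
#' functions.
#'
#' @return tibble with columns `element`, `mass_number` (nearest integer
#'   mass, used to label isotopes, e.g. C12/C13), `mass` (Da) and
#'   `abundance` (per-element probabilities summing to 1).
#' @examples
#' subset(isotope_table(), element == "S")
#' @export
isotope_table <- function() {
  rows <- lapply(names(.iso_data), function(el) {
    d <- .iso_data[[el]]
    data.frame(element = el,
               mass_number = as.integer(round(d$mass)),
               mass = d$mass,
               abundance = d$abundance,
               stringsAsFactors = FALSE)
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Load an isotope table from a delimited text file
#'
#' Expects one isotope per line with fields `element, isotope_mass_Da,
#' abundance` (comma, tab or whitespace separated; lines starting with `#`
#' are ignored). The table is validated: per-element abundances must sum to
#' 1 within 1e-9 and masses must be strictly increasing within an element.
#'
#' @param path path to the file.
#' @return tibble in the same shape as [isotope_table()].
#' @export
read_isotope_table <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("isotope table file is empty: ", path)
  parts <- strsplit(lines, "[,\t ]+")
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    stop(sprintf("isotope table line %d does not have 3 fields", bad[1L]))
  }
  mat <- do.call(rbind, parts)
  mass <- suppressWarnings(as.numeric(mat[, 2L]))
  ab <- suppressWarnings(as.numeric(mat[, 3L]))
  if (anyNA(mass) || anyNA(ab)) {
    stop("isotope table contains non-numeric mass or abundance values")
  }
  tab <- tibble::tibble(element = mat[, 1L],
                        mass_number = as.integer(round(mass)),
                        mass = mass,
                        abundance = ab)
  validate_isotope_table(tab)
  tab
}

validate_isotope_table <- function(tab) {
  need <- c("element", "mass", "abundance")
  if (!all(need %in% names(tab))) {
    stop("isotope table must have columns element, mass, abundance")
  }
  for (el in unique(tab$element)) {
    d <- tab[tab$element == el, ]
    d <- d[order(d$mass), ]
    if (any(d$abundance <= 0)) {
      stop(sprintf("element %s has a non-positive abundance", el))
    }
    if (abs(sum(d$abundance) - 1) > 1e-9) {
      stop(sprintf("abundances for element %s sum to %.12f, not 1",
                   el, sum(d$abundance)))
    }
    if (nrow(d) > 1L && any(diff(d$mass) <= 0)) {
      stop(sprintf("isotope masses for element %s are not strictly increasing", el))
    }
  }
  invisible(tab)
}
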