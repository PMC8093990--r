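test_that("parse_formula handles implicit counts, repeats and big formulas", {
  expect_identical(parse_formula("H2O"), c(H = 2L, O = 1L))
  expect_identical(parse_formula("C"), c(C = 1L))
  expect_identical(parse_formula("CH3COOH"), c(C = 2L, H = 4L, O = 2L))
  expect_identical(
    parse_formula("C2952H4664O832N812S8Fe4"),
    c(C = 2952L, H = 4664L, O = 832L, N = 812L, S = 8L, Fe = 4L))
})

test_that("parse_formula reports the offending position", {
  expect_error(parse_formula("H2O)"), "position 4")
  expect_error(parse_formula("2HO"), "position 1")
  expect_error(parse_formula("H0O"), ">= 1")
  expect_error(parse_formula("ZzO2"), "unknown element 'Zz' at position 1")
  expect_error(parse_formula(""), "non-empty")
})

test_that("embedded isotope table is internally consistent", {
  tab <- isotope_table()
  for (el in unique(tab$element)) {
    d <- tab[tab$element == el, ]
    expect_lt(abs(sum(d$abundance) - 1), 1e-9)
    if (nrow(d) > 1L) expect_true(all(diff(d$mass) > 0))
  }
})

test_that("element_combinations enumerates complete multinomial supports", {
  one <- element_combinations("P", 17)
  expect_identical(nrow(one), 1L)
  expect_identical(one$neg_log_prob, 0)

  # two isotopes, two atoms: binomial expansion p^2, 2pq, q^2
  two <- element_combinations("C", 2)
  p <- 0.9893; q <- 0.0107
  expect_identical(nrow(two), 3L)
  expect_equal(sort(two$prob), sort(c(p^2, 2 * p * q, q^2)))
  expect_lt(abs(sum(two$prob) - 1), 1e-9)

  # four isotopes, eight atoms: stars and bars gives C(11, 3) = 165
  s8 <- element_combinations("S", 8)
  expect_identical(nrow(s8), 165L)
  expect_lt(abs(sum(s8$prob) - 1), 1e-9)
  expect_true(all(diff(s8$neg_log_prob) >= 0))
  expect_true(all(rowSums(s8$counts) == 8))
})

test_that("element_combinations guards and truncation behave", {
  expect_error(element_combinations("Q", 2), "unknown element")
  expect_error(element_combinations("S", 1000, cap = 1000), "above the cap")
  expect_warning(top3 <- element_combinations("S", 8, keep = 3),
                 "retained probability mass")
  expect_identical(nrow(top3), 3L)
})

test_that("top_isotopologues matches exhaustive enumeration", {
  # mode of independent multinomials: all atoms on the dominant isotope
  w <- top_isotopologues("H2O", 1)
  expect_equal(w$probability, 0.999885^2 * 0.99757)
  expect_equal(w$mass, 2 * 1.00782503207 + 15.9949146196)

  # full product: probabilities are a complete distribution
  full <- suppressWarnings(top_isotopologues("H2O", 100))
  expect_identical(nrow(full), 9L)
  expect_lt(abs(sum(full$probability) - 1), 1e-9)
  expect_true(all(diff(full$probability) <= 0))

  # S8: tree output equals brute-force enumeration, both modes
  cb <- element_combinations("S", 8)
  for (mode in c("wobbly", "standard")) {
    got <- top_isotopologues("S8", 10, mode = mode)
    expect_equal(got$probability, sort(cb$prob, decreasing = TRUE)[1:10])
    expect_equal(got$neg_log_prob, sort(cb$neg_log_prob)[1:10])
  }
})

test_that("probabilities recompute from per-element terms and masses are order-invariant", {
  res <- top_isotopologues("C6H12O6", 15)
  tab <- isotope_table()
  for (r in seq_len(nrow(res))) {
    p <- 1
    for (el in c("C", "H", "O")) {
      d <- tab[tab$element == el, ]
      cols <- paste0(el, d$mass_number)
      cnt <- as.integer(unlist(res[r, cols]))
      p <- p * exp(lgamma(sum(cnt) + 1) - sum(lgamma(cnt + 1)) +
                     sum(cnt * log(d$abundance)))
    }
    expect_equal(res$probability[r], p)
  }
  swapped <- top_isotopologues("O6C6H12", 15)
  expect_equal(sort(res$mass), sort(swapped$mass))
  expect_equal(res$probability, swapped$probability)
})

test_that("isotope table override round-trips through a text file", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("# toy two-isotope element",
               "Xx, 1.0, 0.75",
               "Xx, 2.0, 0.25"), f)
  tab <- read_isotope_table(f)
  expect_identical(nrow(tab), 2L)
  res <- top_isotopologues("Xx2", 3, table = tab)
  expect_equal(res$probability, c(0.5625, 0.375, 0.0625))
  expect_equal(res$mass, c(2, 3, 4))

  bad <- tempfile()
  writeLines("Xx, 1.0, 0.5", bad)
  expect_error(read_isotope_table(bad), "sum to")
})
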