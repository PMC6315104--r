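test_that("known reverse-complement palindromes are found exactly", {
  h <- find_palindromes("GTTACGTACGTAAC", min_len = 14)
  expect_equal(nrow(h), 1)
  expect_equal(c(h$start, h$end), c(1L, 14L))
  expect_true(h$perfect)
  expect_equal(nrow(find_palindromes("AAAAAAAAAAAAAA", min_len = 14)), 0)
  # near-palindrome with one mismatched pair: absent at 0, present at 1
  s <- paste0(random_dna(30, 4), "GTTACGAACGTAAC", random_dna(30, 5))
  expect_equal(nrow(find_palindromes(s, 14, max_mismatch = 0)), 0)
  h1 <- find_palindromes(s, 14, max_mismatch = 1)
  expect_true(any(h1$mismatches == 1 & h1$start <= 31 & h1$end >= 44))
  expect_error(find_palindromes("ACGT", min_len = 13), "even")
})

test_that("palindrome search equals the brute-force enumeration oracle", {
  cases <- list(list(len = 200, seed = 11, min_len = 6, k = 0),
                list(len = 300, seed = 12, min_len = 6, k = 1),
                list(len = 400, seed = 13, min_len = 8, k = 1),
                list(len = 250, seed = 14, min_len = 10, k = 2))
  for (cs in cases) {
    s <- random_dna(cs$len, cs$seed)
    got <- find_palindromes(s, cs$min_len, cs$k)
    exp <- oracle_palindromes(s, cs$min_len, cs$k)
    expect_identical(data.frame(start = as.integer(got$start),
                                end = as.integer(got$end)),
                     data.frame(start = as.integer(exp$start),
                                end = as.integer(exp$end)),
                     info = sprintf("len=%d seed=%d", cs$len, cs$seed))
  }
  # planted long palindrome inside a random background
  s <- paste0(random_dna(80, 21), "GTTACCGCGGTAAC", random_dna(80, 22))
  got <- find_palindromes(s, 14, 0)
  exp <- oracle_palindromes(s, 14, 0)
  expect_equal(got$start, exp$start)
  expect_equal(got$end, exp$end)
})

test_that("circular search finds palindromes spanning the origin", {
  pal <- "GTTACCGCGGTAAC"
  base <- paste0(random_dna(60, 31), pal, random_dna(60, 32))
  # rotate so the palindrome straddles position 1
  rot <- 67  # palindrome occupies 61..74; shift start beyond it
  s2 <- paste0(substr(base, rot + 1, nchar(base)), substr(base, 1, rot))
  lin <- find_palindromes(s2, 14, 0, circular = FALSE)
  circ <- find_palindromes(s2, 14, 0, circular = TRUE)
  expect_false(any(grepl(pal, lin$sequence, fixed = TRUE)))
  spanning <- circ[grepl(pal, circ$sequence, fixed = TRUE), ]
  expect_equal(nrow(spanning), 1)
  expect_true(spanning$start <= nchar(s2) && spanning$end > nchar(s2))
})
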