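test_that("one-focus fraction matches the age-distribution prediction", {
  # F = 2(1 - 2^-a_d); tolerance 3 binomial SEs
  for (a_d in c(0.19, 0.5, 0.8)) {
    spec <- population_spec(n_cells = 10000,
                            loci = list(locus_program("L", a_d,
                                                      post_positions = c(0.15, 0.85))),
                            seed = 42)
    pop <- generate_population(spec)
    nf <- vapply(pop$cells, function(c) nrow(c$foci$L), integer(1))
    F_hat <- mean(nf == 1)
    F_exp <- 2 * (1 - 2^(-a_d))
    expect_lt(abs(F_hat - F_exp), 3 * sqrt(F_exp * (1 - F_exp) / 10000))
  }
})

test_that("degenerate duplication ages give all-1 or all-2 focus populations", {
  mk <- function(a_d) {
    pop <- generate_population(population_spec(
      n_cells = 200, loci = list(locus_program("L", a_d)), seed = 1))
    vapply(pop$cells, function(c) nrow(c$foci$L), integer(1))
  }
  expect_true(all(mk(0) == 2))
  expect_true(all(mk(1) == 1))
})

test_that("cell length interpolates linearly between birth and division", {
  spec <- population_spec(n_cells = 500, length_at_birth_um = 1.7,
                          length_at_division_um = 3.4, seed = 3)
  pop <- generate_population(spec)
  df <- as.data.frame(pop)
  expect_true(all(df$length_um >= 1.7 & df$length_um <= 3.4))
  expect_equal(df$length_um, 1.7 + df$age * 1.7, tolerance = 1e-12)
})

test_that("population generation is reproducible and validates its spec", {
  spec <- population_spec(n_cells = 50,
                          loci = list(locus_program("L", 0.3)), seed = 9)
  expect_identical(as.data.frame(generate_population(spec)),
                   as.data.frame(generate_population(spec)))
  expect_error(population_spec(0), "n_cells")
  expect_error(population_spec(10, length_at_birth_um = 3,
                               length_at_division_um = 2), "birth")
  expect_error(locus_program("L", 1.2), "duplication_age")
  expect_error(locus_program("L", 0.5, pre_positions = 1.5), "positions")
})

test_that("septal ring program renders flat-then-constricting diameters", {
  spec <- population_spec(
    n_cells = 2000, seed = 11,
    ring_program = list(onset_age = 0.5, plateau_um = 0.6,
                        constriction_length_um = 3.0, final_um = 0.1))
  pop <- generate_population(spec)
  ring_cells <- Filter(function(c) !is.null(c$ring), pop$cells)
  ages <- vapply(ring_cells, `[[`, numeric(1), "age")
  expect_true(all(ages >= 0.5))
  len <- vapply(ring_cells, `[[`, numeric(1), "length_um")
  dia <- vapply(ring_cells, function(c) c$ring$diameter_um, numeric(1))
  expect_true(all(dia[len <= 3.0] == 0.6))
  post <- len > 3.05
  expect_true(all(dia[post] < 0.6))
  expect_lt(cor(len[post], dia[post]), -0.99)
})
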