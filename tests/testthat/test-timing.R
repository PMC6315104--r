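test_that("the age map evaluates and round-trips the closed form", {
  expect_equal(age_at_duplication(0), 0)
  expect_equal(age_at_duplication(1), 1)
  expect_equal(age_at_duplication(0.35), 0.27754, tolerance = 1e-4)
  # strictly increasing, and inverse relation F = 2(1 - 2^-a)
  F <- seq(0, 1, by = 0.01)
  a <- age_at_duplication(F)
  expect_true(all(diff(a) > 0))
  expect_equal(2 * (1 - 2^(-a)), F, tolerance = 1e-12)
  expect_error(age_at_duplication(1.2), "\\[0, 1\\]")
  expect_equal(time_at_duplication(0.5, 150), 75)
  expect_error(time_at_duplication(0.5, 0), "T_min")
})

test_that("focus-count tabulation excludes undefined cells and uses Wilson", {
  cells <- c(lapply(1:25, function(i) make_cell(0.5, id = i)),
             lapply(1:75, function(i) make_cell(c(0.2, 0.8), id = i)),
             list(cell_observation("none", 2, 1,
                                   foci = list(ch1 = data.frame(
                                     frac = numeric(), lateral_um = numeric(),
                                     intensity = numeric())))))
  fr <- fraction_one_focus(cells, "ch1")
  expect_equal(fr$F, 0.25)
  expect_equal(fr$n_excluded, 1)
  # Wilson interval cross-checked against prop.test without correction
  pt <- prop.test(25, 100, correct = FALSE)$conf.int
  expect_equal(unname(fr$ci), as.numeric(pt), tolerance = 1e-9)
  # degenerate splits
  expect_equal(estimate_duplication(counts = c(0, 100))$t_d_min, 0)
  expect_equal(estimate_duplication(counts = c(100, 0), T_min = 150)$t_d_min,
               150)
})

test_that("duplication ages are recovered from simulated populations", {
  spec <- population_spec(n_cells = 10000,
                          loci = list(locus_program("L", 0.28)), seed = 6)
  pop <- generate_population(spec)
  est <- estimate_duplication(pop$cells, channel = "L", T_min = 150)
  expect_equal(est$t_d_min, 42, tolerance = 2 / 42)
  expect_true(est$ci_t_d[1] <= est$t_d_min && est$t_d_min <= est$ci_t_d[2])
  # late (terminus-like) duplication
  spec2 <- population_spec(n_cells = 10000,
                           loci = list(locus_program("L", 0.97)), seed = 7)
  est2 <- estimate_duplication(generate_population(spec2)$cells,
                               channel = "L", T_min = 150)
  expect_lte(abs(est2$t_d_min - 145.5), 3)
})

test_that("estimate accessors expose coefficients and intervals", {
  est <- estimate_duplication(counts = c(35, 65), T_min = 150, locus = "X")
  expect_equal(unname(coef(est)["F"]), 0.35)
  expect_equal(unname(coef(est)["t_d_min"]), est$t_d_min)
  ci <- confint(est, "t_d_min")
  expect_true(ci[1] < est$t_d_min && est$t_d_min < ci[2])
  # monotone transform: interval endpoints are the Wilson bounds of F
  # mapped through the age formula, not a delta-method approximation
  wilson <- as.numeric(prop.test(35, 100, correct = FALSE)$conf.int)
  expect_equal(ci, time_at_duplication(age_at_duplication(wilson), 150),
               tolerance = 1e-9)
})

test_that("segregation reports order loci and difference Ori/Ter pairs", {
  ests <- list(est_at_td("OriC2", 42), est_at_td("Ter2", 129),
               est_at_td("OriC1", 28.5), est_at_td("Ter1", 146))
  rep <- segregation_report(ests)
  expect_equal(rep$table$locus, c("OriC1", "OriC2", "Ter2", "Ter1"))
  iv <- rep$intervals
  expect_equal(iv$interval_min[iv$replicon == "2"], 87)
  expect_equal(iv$interval_min[iv$replicon == "1"], 117.5)
  # single estimate: a one-row table, no intervals, with a warning
  expect_warning(one <- segregation_report(list(est_at_td("OriC1", 30))),
                 "incomplete")
  expect_equal(nrow(one$table), 1)
  expect_null(one$intervals)
})
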