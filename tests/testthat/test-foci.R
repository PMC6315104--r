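spec0 <- image_spec(noise_sd = 0)

test_that("planted foci are recovered to subpixel accuracy", {
  px <- spec0$pixel_size_um
  for (fr in list(0.15, c(0.15, 0.85), c(0.3, 0.7))) {
    cell <- make_cell(fr, length_um = 3,
                      intensity = seq(420, 380, length.out = length(fr)))
    r <- render_cell_image(cell, spec0, channel = "ch1")
    det <- detect_foci(r$image, r$mask, pixel_size_um = px)
    expect_equal(nrow(det), length(fr))
    # strongest first
    expect_true(all(diff(det$intensity) <= 0))
    x_true <- (r$x0_px - 0.5) * px + fr * 3
    err_px <- abs(sort(det$x_um) - sort(x_true)) / px
    expect_true(all(err_px < 0.5))
    expect_true(all(abs(det$y_um - (r$y0_px - 0.5) * px) / px < 0.5))
  }
})

test_that("noise-only cells yield no detections at the default threshold", {
  sp <- image_spec(noise_sd = 6)
  cell <- cell_observation("n", length_um = 2.5, width_um = 1)
  hits <- vapply(1:50, function(s) {
    r <- render_cell_image(cell, sp, seed = s)
    nrow(detect_foci(r$image, r$mask, pixel_size_um = sp$pixel_size_um))
  }, integer(1))
  expect_gte(mean(hits == 0), 0.99)
})

test_that("detections never exceed max_foci and stay inside the mask", {
  set.seed(99)
  for (i in 1:20) {
    n_true <- sample(1:3, 1)
    fr <- sort(runif(n_true, 0.1, 0.9))
    cell <- make_cell(fr, length_um = runif(1, 2, 3.4))
    r <- render_cell_image(cell, spec0, channel = "ch1")
    det <- detect_foci(r$image, r$mask, max_foci = 2,
                       pixel_size_um = spec0$pixel_size_um)
    expect_lte(nrow(det), 2)
    for (j in seq_len(nrow(det))) {
      expect_true(r$mask[round(det$y_px[j]), round(det$x_px[j])])
    }
  }
})

test_that("interfocal distance follows the planted geometry", {
  cell <- make_cell(c(0.15, 0.85), length_um = 3)
  expect_equal(interfocal_distance(cell, "ch1"), 0.7 * 3, tolerance = 1e-9)
  expect_equal(interfocal_distance(make_cell(c(0.4, 0.4)), "ch1"), 0)
  # not defined for 1-focus cells
  expect_true(is.na(interfocal_distance(make_cell(0.5), "ch1")))
  # axial flag ignores the lateral offset
  c2 <- cell_observation("c", 3, 1, foci = list(ch1 = data.frame(
    frac = c(0.2, 0.8), lateral_um = c(-0.2, 0.2), intensity = 1)))
  expect_equal(interfocal_distance(c2, "ch1", method = "axial"), 1.8)
  expect_gt(interfocal_distance(c2, "ch1"), 1.8)
})

test_that("population mean IFD agrees with the generator expectation", {
  spec <- population_spec(n_cells = 3000,
                          loci = list(locus_program("L", 0.3,
                                                    post_positions = c(0.15, 0.85),
                                                    position_noise_sd = 0.02)),
                          seed = 21)
  pop <- generate_population(spec)
  two <- Filter(function(c) nrow(c$foci$L) == 2, pop$cells)
  ifd <- vapply(two, interfocal_distance, numeric(1), channel = "L")
  expected <- mean(vapply(two, `[[`, numeric(1), "length_um")) * 0.7
  se <- sd(ifd) / sqrt(length(ifd))
  expect_lt(abs(mean(ifd) - expected), 3 * se + 0.01)
})

test_that("colocalization matches trivially and respects the threshold", {
  A <- data.frame(x_um = c(0.5, 2.0), y_um = c(0.5, 0.5))
  res <- colocalize(A, A, threshold_um = 0.2)
  expect_equal(nrow(res$pairs), 2)
  expect_equal(res$pairs$distance_um, c(0, 0))
  B <- data.frame(x_um = c(1.5), y_um = c(0.5))
  far <- colocalize(A[1, ], B, threshold_um = 0.2)
  expect_equal(nrow(far$pairs), 0)
  expect_equal(far$unmatched_a, 1)
  expect_equal(far$unmatched_b, 1)
})

test_that("optimal matching beats greedy on the blocking configuration", {
  # the pair (0.5, 0.6) is closest but pairing it starves the second focus
  A <- cbind(c(0.5, 1.0), c(0, 0))
  B <- cbind(c(0.6, 0.0), c(0, 0))
  opt <- colocalize(A, B, threshold_um = 0.5)
  expect_equal(nrow(opt$pairs), 2)
  greedy <- colocalize(A, B, threshold_um = 0.5, method = "greedy")
  expect_equal(nrow(greedy$pairs), 1)
})
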