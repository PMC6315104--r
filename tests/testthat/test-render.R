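spec0 <- image_spec(noise_sd = 0, cell_intensity = 0)

test_that("a noise-free focus renders at the medial-axis midpoint", {
  cell <- make_cell(0.5, length_um = 3)
  r <- render_cell_image(cell, spec0, channel = "ch1")
  amax <- which(r$image == max(r$image), arr.ind = TRUE)
  x_true <- (r$x0_px + r$x1_px) / 2
  expect_lte(abs(mean(amax[, 2]) - x_true), 1)
  expect_lte(abs(mean(amax[, 1]) - r$y0_px), 1)
})

test_that("zero foci and zero noise reproduce the flat background", {
  cell <- cell_observation("empty", length_um = 2.5, width_um = 1)
  r <- render_cell_image(cell, spec0)
  expect_true(all(r$image == spec0$background_level))
  expect_true(any(r$mask))  # the footprint is still defined
})

test_that("rendering conserves the planted focus photons within 1%", {
  for (frac in c(0.3, 0.5, 0.7)) {
    cell <- make_cell(frac, length_um = 3, intensity = 500)
    r <- render_cell_image(cell, spec0, channel = "ch1")
    total <- sum(r$image - spec0$background_level)
    sigma_px <- spec0$psf_sigma_um / spec0$pixel_size_um
    expect_equal(total, 500 * 2 * pi * sigma_px^2, tolerance = 0.01)
  }
})

test_that("rendering is bit-deterministic under a fixed seed", {
  sp <- image_spec(noise_sd = 8)
  cell <- make_cell(c(0.2, 0.8))
  r1 <- render_cell_image(cell, sp, channel = "ch1", seed = 5)
  r2 <- render_cell_image(cell, sp, channel = "ch1", seed = 5)
  expect_identical(r1$image, r2$image)
  s1 <- render_ring_zstack(0.5, sp, seed = 9)
  s2 <- render_ring_zstack(0.5, sp, seed = 9)
  expect_identical(s1$stack, s2$stack)
})

test_that("foci outside the cell body are rejected", {
  bad <- cell_observation("b", length_um = 2, width_um = 1,
                          foci = list(ch1 = data.frame(
                            frac = 0.5, lateral_um = 0.8, intensity = 100)))
  expect_error(render_cell_image(bad, spec0, channel = "ch1"), "outside")
})

test_that("ring stacks respect their geometric preconditions", {
  expect_error(render_ring_zstack(1.2, spec0), "cell width")
  shallow <- image_spec(noise_sd = 0, n_z = 3)
  expect_error(render_ring_zstack(0.8, shallow), "stack depth")
})

test_that("stacks round-trip through multi-page TIFF", {
  sp <- image_spec(noise_sd = 0)
  st <- render_ring_zstack(0.4, sp)
  path <- withr::local_tempfile(fileext = ".tiff")
  write_stack_tiff(st$stack, path)
  back <- read_stack_tiff(path)
  expect_length(back, sp$n_z)
  # 16-bit quantisation: agreement to within one grey level
  expect_lt(max(abs(back[[1]] - st$stack[, , 1])), 1.01)
})
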