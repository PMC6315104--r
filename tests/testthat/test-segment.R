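spec_cyto <- image_spec(noise_sd = 0)  # cytoplasmic signal on

test_that("segmentation recovers cell length within two pixels", {
  for (len in c(1.8, 2.5, 3.2)) {
    cell <- make_cell(0.4, length_um = len)
    r <- render_cell_image(cell, spec_cyto, channel = "ch1")
    regs <- segment_cells(r$image, spec_cyto$pixel_size_um)
    expect_length(regs, 1)
    expect_lte(abs(regs[[1]]$length_um - len), 2 * spec_cyto$pixel_size_um)
    expect_lte(abs(regs[[1]]$width_um - 1.0), 2 * spec_cyto$pixel_size_um)
    expect_false(regs[[1]]$ambiguous)
  }
})

test_that("blank and noise-only frames segment to an empty list", {
  flat <- matrix(100, 40, 60)
  expect_length(segment_cells(flat, 0.064), 0)
  set.seed(3)
  noise <- matrix(rnorm(40 * 60, 100, 5), 40, 60)
  expect_length(segment_cells(noise, 0.064), 0)
})

test_that("well-separated cells give one region each", {
  r1 <- render_cell_image(make_cell(0.5, length_um = 2), spec_cyto,
                          channel = "ch1")$image
  r2 <- render_cell_image(make_cell(0.5, length_um = 2.8), spec_cyto,
                          channel = "ch1")$image
  canvas <- matrix(spec_cyto$background_level, 60, 140)
  canvas[1:nrow(r1), 1:ncol(r1)] <-
    pmax(canvas[1:nrow(r1), 1:ncol(r1)], r1)
  canvas[(61 - nrow(r2)):60, (141 - ncol(r2)):140] <-
    pmax(canvas[(61 - nrow(r2)):60, (141 - ncol(r2)):140], r2)
  regs <- segment_cells(canvas, spec_cyto$pixel_size_um)
  expect_length(regs, 2)
  lens <- sort(vapply(regs, `[[`, numeric(1), "length_um"))
  expect_equal(lens, c(2, 2.8), tolerance = 0.1)
})

test_that("merged side-by-side cells are flagged ambiguous", {
  r1 <- render_cell_image(make_cell(0.5, length_um = 2.6), spec_cyto,
                          channel = "ch1")$image
  # overlay a vertical copy shifted by less than a cell width so the two
  # footprints fuse into one wide region
  shift <- 10
  canvas <- matrix(spec_cyto$background_level, nrow(r1) + shift, ncol(r1))
  canvas[1:nrow(r1), ] <- pmax(canvas[1:nrow(r1), ], r1)
  canvas[shift + 1:nrow(r1), ] <- pmax(canvas[shift + 1:nrow(r1), ], r1)
  regs <- segment_cells(canvas, spec_cyto$pixel_size_um)
  expect_length(regs, 1)
  expect_true(regs[[1]]$ambiguous)
})

test_that("relative_position projects onto the medial axis", {
  cell <- make_cell(0.3, length_um = 3)
  r <- render_cell_image(cell, spec_cyto, channel = "ch1")
  reg <- segment_cells(r$image, spec_cyto$pixel_size_um)[[1]]
  # geometric midcell
  mid <- relative_position(sum(range(which(colSums(r$mask) > 0))) / 2 *
                             spec_cyto$pixel_size_um,
                           r$y0_px * spec_cyto$pixel_size_um, reg)
  expect_lt(abs(mid - 0.5), 0.02)
  # a point outside the mask errors
  expect_error(relative_position(0.05, 0.05, reg), "outside")
})
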