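ring_mid <- list(frac = 0.5, diameter_um = 0.4)

test_that("FtsZ scheme follows the rule cascade", {
  ringed <- cell_observation("a", 3, 1, ring = ring_mid)
  expect_equal(classify_localization(ringed, "FtsZ"), "ring at midcell")
  septal <- make_cell(0.5)
  expect_equal(classify_localization(septal, "FtsZ"), "focus at midcell")
  polar <- make_cell(0.05)
  expect_equal(classify_localization(polar, "FtsZ"),
               "polar focus or moving toward midcell")
  moving <- make_cell(0.3)
  expect_equal(classify_localization(moving, "FtsZ"),
               "polar focus or moving toward midcell")
  blank <- cell_observation("b", 3, 1)
  expect_equal(classify_localization(blank, "FtsZ"), "no defined signal")
})

test_that("MipZ scheme distinguishes polar and septal combinations", {
  two_ring <- cell_observation("c", 3, 1,
                               foci = list(ch1 = data.frame(
                                 frac = c(0.05, 0.95), lateral_um = 0,
                                 intensity = 1)),
                               ring = ring_mid)
  expect_equal(classify_localization(two_ring, "MipZ"),
               "2 polar foci + septal ring")
  three <- make_cell(c(0.05, 0.95, 0.5))
  expect_equal(classify_localization(three, "MipZ"),
               "2 polar foci + septal focus")
  two <- make_cell(c(0.1, 0.9))
  expect_equal(classify_localization(two, "MipZ"), "2 foci at both poles")
  one <- make_cell(0.05)
  expect_equal(classify_localization(one, "MipZ"), "focus at one pole")
})

test_that("category fractions sum to one and ignore cell order", {
  set.seed(5)
  cells <- c(lapply(1:30, function(i) make_cell(0.05, id = i)),
             lapply(1:50, function(i) make_cell(c(0.05, 0.95), id = i)),
             lapply(1:20, function(i) cell_observation(i, 3, 1,
                                                       ring = ring_mid)))
  tab <- localization_table(cells, "MipZ")
  expect_equal(sum(tab$fraction), 1)
  shuffled <- localization_table(sample(cells), "MipZ")
  expect_identical(tab[order(tab$category), ],
                   shuffled[order(shuffled$category), ],
                   ignore_attr = TRUE)
})

test_that("planted category proportions are recovered within 3 SE", {
  set.seed(8)
  n <- 600
  p_true <- c(one_pole = 0.4, both_poles = 0.35, ring = 0.25)
  kind <- sample(names(p_true), n, replace = TRUE, prob = p_true)
  cells <- lapply(seq_len(n), function(i) {
    switch(kind[i],
           one_pole = make_cell(runif(1, 0, 0.15), id = i),
           both_poles = make_cell(c(runif(1, 0, 0.15), runif(1, 0.85, 1)),
                                  id = i),
           ring = cell_observation(i, 3, 1,
                                   foci = list(ch1 = data.frame(
                                     frac = c(0.05, 0.95), lateral_um = 0,
                                     intensity = 1)),
                                   ring = ring_mid))
  })
  tab <- localization_table(cells, "MipZ")
  get <- function(cat) tab$fraction[tab$category == cat]
  for (pair in list(c("focus at one pole", "one_pole"),
                    c("2 foci at both poles", "both_poles"),
                    c("2 polar foci + septal ring", "ring"))) {
    p <- p_true[[pair[2]]]
    expect_lt(abs(get(pair[1]) - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("OriC1 phases follow focus count and length bounds", {
  expect_equal(oric1_phase(1, 1.8), "relaxed-1-focus")
  expect_equal(oric1_phase(2, 2.0), "tight-polar-2-foci")
  expect_equal(oric1_phase(2, 3.0), "relaxed-2-foci")
  expect_equal(oric1_phase(2, 2.0, bounds = c(1.7, 1.9)), "relaxed-2-foci")
  expect_error(oric1_phase(1, 0), "length_um")
  expect_error(oric1_phase(3, 2), "n_foci")
})
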