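#' Positional program of a tagged locus or protein
#'
#' Describes how a fluorescently tagged locus behaves across the cell cycle:
#' before its duplication age it shows the `pre_positions` foci (usually one),
#' afterwards the two `post_positions` foci. Positions are relative axial
#' coordinates (fractions of cell length, 0 = one pole, 1 = the other).
#'
#' @param name channel/locus label, e.g. `"OriC1"`.
#' @param duplication_age cell-cycle fraction in `[0, 1]` at which the focus
#'   duplicates (the quantity the timing estimator recovers).
#' @param pre_positions axial fractions of the foci shown before duplication.
#' @param post_positions pair of axial fractions shown after duplication,
#'   e.g. `c(0.15, 0.85)` for sub-polar or `c(0.30, 0.70)` for quarter-cell
#'   positioning.
#' @param position_noise_sd Gaussian noise on positions, relative units.
#' @param intensity_adu mean focus intensity in ADU used when rendering.
#' @return object of class `locus_program`.
#' @export
locus_program <- function(name, duplication_age,
                          pre_positions = 0.5,
                          post_positions = c(0.25, 0.75),
                          position_noise_sd = 0.02,
                          intensity_adu = 400) {
  stopifnot(is.character(name), length(name) == 1L)
  if (duplication_age < 0 || duplication_age > 1) {
    stopf("duplication_age must be in [0, 1], got %g", duplication_age)
  }
  pos <- c(pre_positions, post_positions)
  if (any(pos < 0 | pos > 1)) stopf("all positions must be in [0, 1]")
  if (length(post_positions) != 2L) stopf("post_positions must be a pair")
  structure(list(name = name, duplication_age = duplication_age,
                 pre_positions = pre_positions,
                 post_positions = post_positions,
                 position_noise_sd = position_noise_sd,
                 intensity_adu = intensity_adu),
            class = "locus_program")
}

#' Specification of a synthetic cell population
#'
#' @param n_cells number of cells (>= 1).
#' @param generation_time_min generation time T in minutes (default 150).
#' @param length_at_birth_um,length_at_division_um cell length at birth and
#'   division, micrometres; length interpolates linearly with age.
#' @param width_um cell width, micrometres.
#' @param loci list of [locus_program()] objects.
#' @param ring_program optional list describing a septal ring: `onset_age`
#'   (ring present from this age fraction on), `plateau_um` (formation-phase
#'   diameter), `constriction_length_um` (cell length at which constriction
#'   starts), `final_um` (diameter at division), `position` (axial fraction)
#'   and `position_noise_sd`. Diameter follows a flat-then-linear decrease
#'   with cell length.
#' @param seed integer seed.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(n_cells,
                            generation_time_min = 150,
                            length_at_birth_um = 1.7,
                            length_at_division_um = 3.4,
                            width_um = 1.0,
                            loci = list(),
                            ring_program = NULL,
                            seed = 1L) {
  if (n_cells < 1) stopf("n_cells must be >= 1")
  if (generation_time_min <= 0) stopf("generation_time_min must be > 0")
  if (!(length_at_birth_um > 0 && length_at_birth_um < length_at_division_um)) {
    stopf("need 0 < length_at_birth_um < length_at_division_um")
  }
  stopifnot(all(vapply(loci, inherits, logical(1), "locus_program")))
  if (!is.null(ring_program)) {
    ring_program <- modifyList(list(onset_age = 0.6, plateau_um = 0.6,
                                    constriction_length_um = 3.0,
                                    final_um = 0.1, position = 0.5,
                                    position_noise_sd = 0.01),
                               ring_program)
  }
  structure(list(n_cells = as.integer(n_cells),
                 generation_time_min = generation_time_min,
                 length_at_birth_um = length_at_birth_um,
                 length_at_division_um = length_at_division_um,
                 width_um = width_um, loci = loci,
                 ring_program = ring_program, seed = as.integer(seed)),
            class = "population_spec")
}

#' Generate a synthetic cell population with ground truth
#'
#' Draws cell ages from the exponential-growth age distribution
#' ([sample_cell_ages()]), maps age to length by linear interpolation between
#' birth and division lengths, and places per-locus foci according to each
#' [locus_program()]: cells younger than the locus' duplication age carry the
#' pre-duplication foci, older cells the post-duplication pair, with Gaussian
#' positional noise clipped to `[0, 1]`. The fraction of one-focus cells for a
#' locus with duplication age \eqn{a_d} is therefore \eqn{2(1 - 2^{-a_d})} in
#' expectation — the quantity the timing estimator inverts.
#'
#' @param spec a [population_spec()].
#' @return object of class `cell_population`: a list with elements `cells`
#'   (list of `cell_observation`) and `spec`. `as.data.frame()` yields the
#'   ground-truth table (age, length, per-locus focus count and positions).
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  ages <- sample_cell_ages(spec$n_cells, seed = NULL)
  cells <- vector("list", spec$n_cells)
  for (i in seq_len(spec$n_cells)) {
    a <- ages[i]
    len <- spec$length_at_birth_um +
      a * (spec$length_at_division_um - spec$length_at_birth_um)
    foci <- list()
    for (lp in spec$loci) {
      base <- if (a < lp$duplication_age) lp$pre_positions else lp$post_positions
      frac <- pmin(1, pmax(0, base + rnorm(length(base), 0, lp$position_noise_sd)))
      foci[[lp$name]] <- data.frame(
        frac = frac,
        lateral_um = rep(0, length(frac)),
        intensity = lp$intensity_adu * exp(rnorm(length(frac), 0, 0.1))
      )
    }
    ring <- NULL
    rp <- spec$ring_program
    if (!is.null(rp) && a >= rp$onset_age) {
      d <- if (len <= rp$constriction_length_um) rp$plateau_um else {
        slope <- (rp$plateau_um - rp$final_um) /
          (spec$length_at_division_um - rp$constriction_length_um)
        max(rp$plateau_um - slope * (len - rp$constriction_length_um),
            rp$final_um)
      }
      ring <- list(frac = min(1, max(0, rp$position +
                                       rnorm(1, 0, rp$position_noise_sd))),
                   diameter_um = d)
    }
    cells[[i]] <- cell_observation(
      cell_id = sprintf("cell_%05d", i),
      length_um = len, width_um = spec$width_um,
      foci = foci, ring = ring, age = a
    )
  }
  structure(list(cells = cells, spec = spec), class = "cell_population")
}

#' A single observed (or simulated) cell
#'
#' Container for one segmented cell: geometry, per-channel foci and optional
#' septal ring. Positions are axial fractions of cell length in `[0, 1]`.
#'
#' @param cell_id label.
#' @param length_um,width_um cell geometry in micrometres.
#' @param foci named list (per channel) of data frames with columns `frac`,
#'   `lateral_um`, `intensity`.
#' @param ring optional list with `frac` (axial fraction) and `diameter_um`.
#' @param age optional ground-truth age fraction.
#' @return object of class `cell_observation`.
#' @export
cell_observation <- function(cell_id, length_um, width_um = 1.0,
                             foci = list(), ring = NULL, age = NA_real_) {
  if (length_um <= 0) stopf("length_um must be > 0")
  for (ch in names(foci)) {
    f <- foci[[ch]]$frac
    if (any(f < 0 | f > 1)) stopf("axial fractions must be in [0, 1]")
  }
  structure(list(cell_id = cell_id, length_um = length_um,
                 width_um = width_um, foci = foci, ring = ring, age = age),
            class = "cell_observation")
}

#' @export
print.cell_observation <- function(x, ...) {
  cat(sprintf("<cell %s>  length %.2f um, width %.2f um\n",
              x$cell_id, x$length_um, x$width_um))
  for (ch in names(x$foci)) {
    cat(sprintf("  %s: %d focus/foci at frac %s\n", ch, nrow(x$foci[[ch]]),
                paste(sprintf("%.2f", x$foci[[ch]]$frac), collapse = ", ")))
  }
  if (!is.null(x$ring)) {
    cat(sprintf("  ring at frac %.2f, diameter %.2f um\n",
                x$ring$frac, x$ring$diameter_um))
  }
  invisible(x)
}

#' @export
print.cell_population <- function(x, ...) {
  cat(sprintf("<cell_population> %d cells, %d locus channel(s): %s\n",
              length(x$cells), length(x$spec$loci),
              paste(vapply(x$spec$loci, `[[`, "", "name"), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.cell_population <- function(x, ...) {
  loci <- vapply(x$spec$loci, `[[`, "", "name")
  rows <- lapply(x$cells, function(cell) {
    row <- data.frame(cell_id = cell$cell_id, age = cell$age,
                      length_um = cell$length_um, width_um = cell$width_um,
                      stringsAsFactors = FALSE)
    for (ch in loci) {
      f <- cell$foci[[ch]]
      row[[paste0(ch, "_n_foci")]] <- nrow(f)
      row[[paste0(ch, "_pos1")]] <- f$frac[1]
      row[[paste0(ch, "_pos2")]] <- if (nrow(f) > 1) f$frac[2] else NA_real_
    }
    row
  })
  do.call(rbind, rows)
}
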