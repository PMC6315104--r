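#' Classify a cell's localization pattern (FtsZ / MipZ schemes)
#'
#' Deterministic rule cascade assigning exactly one category per cell,
#' using two configurable zones: polar (axial fraction `< polar` or
#' `> 1 - polar`) and midcell (`|fraction - 0.5| < midcell`).
#'
#' FtsZ scheme: `"ring at midcell"` (a ring whose centre lies in the
#' midcell zone), `"focus at midcell"` (late septation), `"polar focus or
#' moving toward midcell"` (any other focus), else `"no defined signal"`.
#'
#' MipZ scheme: with two polar foci, the cascade distinguishes an
#' additional septal ring (`"2 polar foci + septal ring"`), a septal focus
#' (`"2 polar foci + septal focus"`), or neither (`"2 foci at both
#' poles"`); a single polar focus gives `"focus at one pole"`; anything
#' else is `"no defined signal"`.
#'
#' @param cell a [cell_observation()].
#' @param scheme `"FtsZ"` or `"MipZ"`.
#' @param channel focus channel used (default: first).
#' @param polar polar-zone half width, fraction of cell length.
#' @param midcell midcell-zone half width, fraction of cell length.
#' @return category label (character scalar).
#' @export
classify_localization <- function(cell, scheme = c("FtsZ", "MipZ"),
                                  channel = NULL, polar = 0.2,
                                  midcell = 0.15) {
  scheme <- match.arg(scheme)
  f <- if (is.null(channel)) {
    if (length(cell$foci)) cell$foci[[1]] else NULL
  } else cell$foci[[channel]]
  frac <- if (is.null(f)) numeric() else f$frac
  has_ring_mid <- !is.null(cell$ring) && abs(cell$ring$frac - 0.5) < midcell
  at_mid <- abs(frac - 0.5) < midcell
  at_pole <- frac < polar | frac > 1 - polar
  if (scheme == "FtsZ") {
    if (has_ring_mid) return("ring at midcell")
    if (any(at_mid)) return("focus at midcell")
    if (length(frac)) return("polar focus or moving toward midcell")
    return("no defined signal")
  }
  n_polar <- sum(at_pole)
  if (n_polar >= 2) {
    if (has_ring_mid) return("2 polar foci + septal ring")
    if (any(at_mid)) return("2 polar foci + septal focus")
    return("2 foci at both poles")
  }
  if (n_polar == 1) return("focus at one pole")
  "no defined signal"
}

#' Category fractions over a population
#'
#' Applies [classify_localization()] to every cell and tabulates category
#' fractions (summing to 1, the residual "no defined signal" included).
#' The result is invariant to cell order.
#'
#' @inheritParams classify_localization
#' @param cells list of [cell_observation()] or a `cell_population`.
#' @return object of class `localization_table`: data frame with
#'   `category`, `n`, `fraction`.
#' @export
localization_table <- function(cells, scheme = c("FtsZ", "MipZ"),
                               channel = NULL, polar = 0.2, midcell = 0.15) {
  scheme <- match.arg(scheme)
  if (inherits(cells, "cell_population")) cells <- cells$cells
  labels <- vapply(cells, classify_localization, "", scheme = scheme,
                   channel = channel, polar = polar, midcell = midcell)
  tab <- table(labels)
  out <- data.frame(category = names(tab), n = as.integer(tab),
                    fraction = as.numeric(tab) / length(labels),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("localization_table", "data.frame")
  out
}

#' Phase of the OriC1 positional program
#'
#' OriC1 positioning runs through three phases: a single, loosely placed
#' focus in newly divided cells; tightly polar sister foci in small cells
#' (default 1.7-2.5 um); and relaxed positioning in longer cells, once the
#' division ring has assembled at midcell.
#'
#' @param n_foci focus count (1 or 2).
#' @param length_um cell length (> 0).
#' @param bounds length window of the tight-polar phase, micrometres.
#' @return `"relaxed-1-focus"`, `"tight-polar-2-foci"` or
#'   `"relaxed-2-foci"`.
#' @export
oric1_phase <- function(n_foci, length_um, bounds = c(1.7, 2.5)) {
  if (length_um <= 0) stopf("length_um must be > 0")
  if (n_foci == 1) return("relaxed-1-focus")
  if (n_foci == 2) {
    # cells below the lower bound with 2 foci are treated as tight-polar:
    # the upper bound is the biologically meaningful switch
    if (length_um <= bounds[2]) return("tight-polar-2-foci")
    return("relaxed-2-foci")
  }
  stopf("n_foci must be 1 or 2")
}
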