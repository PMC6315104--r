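#' Quantify one synthetic multi-channel frame set into a cell observation
#'
#' Runs the measurement chain on rendered frames of a single cell:
#' segments the first channel's frame, detects foci per channel inside the
#' segmented mask, converts them to axial fractions via the region's
#' medial axis, and looks for a septal ring. Returns `NULL` when
#' segmentation finds no single unambiguous cell.
#'
#' @param frames named list of numeric matrices, one per channel (same
#'   geometry).
#' @param pixel_size_um micrometres per pixel.
#' @param max_foci maximum foci per channel.
#' @param ring_channel optional channel name searched for a ring.
#' @param ring_k ring band threshold (see [detect_ring()]).
#' @param cell_id label.
#' @param ... passed to [detect_foci()].
#' @return a [cell_observation()] or `NULL`.
#' @export
quantify_frames <- function(frames, pixel_size_um, max_foci = 2,
                            ring_channel = NULL, ring_k = 1.5,
                            cell_id = "cell", ...) {
  stopifnot(length(frames) >= 1, !is.null(names(frames)))
  regions <- segment_cells(frames[[1]], pixel_size_um = pixel_size_um)
  regions <- Filter(function(r) !r$ambiguous, regions)
  if (length(regions) != 1) return(NULL)
  region <- regions[[1]]
  foci <- list()
  for (ch in names(frames)) {
    det <- detect_foci(frames[[ch]], region$mask, max_foci = max_foci,
                       pixel_size_um = pixel_size_um, ...)
    if (nrow(det)) {
      frac <- vapply(seq_len(nrow(det)), function(i) {
        tryCatch(relative_position(det$x_um[i], det$y_um[i], region),
                 error = function(e) NA_real_)
      }, numeric(1))
      keep <- !is.na(frac)
      foci[[ch]] <- data.frame(frac = frac[keep],
                               lateral_um = det$y_um[keep] -
                                 region$centroid_um[2],
                               intensity = det$intensity[keep])
    } else {
      foci[[ch]] <- data.frame(frac = numeric(), lateral_um = numeric(),
                               intensity = numeric())
    }
  }
  ring <- NULL
  if (!is.null(ring_channel) && ring_channel %in% names(frames)) {
    r <- detect_ring(frames[[ring_channel]], region$mask, k = ring_k)
    if (!is.null(r)) ring <- list(frac = r$frac, diameter_um = NA_real_)
  }
  cell_observation(cell_id = cell_id, length_um = region$length_um,
                   width_um = region$width_um, foci = foci, ring = ring)
}

#' Per-cell wide-format quantification table
#'
#' One row per cell with geometry and, per channel, focus count, the first
#' two axial fractions and the interfocal distance of 2-focus cells.
#'
#' @param cells list of [cell_observation()].
#' @return data frame.
#' @export
cells_to_table <- function(cells) {
  channels <- unique(unlist(lapply(cells, function(c) names(c$foci))))
  rows <- lapply(cells, function(cell) {
    row <- data.frame(cell_id = cell$cell_id, length_um = cell$length_um,
                      width_um = cell$width_um, stringsAsFactors = FALSE)
    for (ch in channels) {
      f <- cell$foci[[ch]]
      nf <- if (is.null(f)) 0L else nrow(f)
      row[[paste0(ch, "_n_foci")]] <- nf
      row[[paste0(ch, "_pos1")]] <- if (nf >= 1) f$frac[1] else NA_real_
      row[[paste0(ch, "_pos2")]] <- if (nf >= 2) f$frac[2] else NA_real_
      row[[paste0(ch, "_ifd_um")]] <- interfocal_distance(cell, ch)
    }
    row$ring_frac <- if (is.null(cell$ring)) NA_real_ else cell$ring$frac
    row$ring_diameter_um <- if (is.null(cell$ring)) NA_real_ else
      cell$ring$diameter_um
    row
  })
  do.call(rbind, rows)
}
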