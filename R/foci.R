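#' Detect diffraction-limited foci inside a cell mask
#'
#' Finds local intensity maxima inside the mask that exceed a noise-derived
#' threshold, suppresses maxima closer than `min_sep_px` (strongest first),
#' keeps at most `max_foci`, and refines each to subpixel precision by a
#' background-subtracted intensity centroid in a fixed window. The
#' threshold is `baseline + max(threshold_k * noise_sd, min_amplitude)`,
#' where the baseline is the median in-mask intensity (cytoplasm plus
#' camera background) and the noise is estimated as the MAD of the
#' out-of-mask pixels. Plateaus of saturated/equal pixels collapse to their
#' centroid and are flagged.
#'
#' @param image numeric matrix (rows = y).
#' @param mask logical matrix, same dimensions (from [segment_cells()] or a
#'   render's ground truth).
#' @param max_foci maximum number of foci reported, strongest first.
#' @param threshold_k multiples of the noise MAD above baseline.
#' @param min_amplitude absolute ADU floor above baseline (guards the
#'   noise-free case where the MAD is 0).
#' @param min_sep_px minimum separation between reported foci, pixels.
#' @param window_px centroid window size (odd; default 7).
#' @param pixel_size_um micrometres per pixel (positions also returned in um).
#' @return data frame with one row per focus: `x_px`, `y_px` (subpixel),
#'   `x_um`, `y_um`, `intensity` (peak ADU above baseline), `plateau`.
#' @export
detect_foci <- function(image, mask, max_foci = 2, threshold_k = 5,
                        min_amplitude = 20, min_sep_px = 3, window_px = 7,
                        pixel_size_um = 1) {
  stopifnot(is.matrix(image), identical(dim(image), dim(mask)))
  empty <- data.frame(x_px = numeric(), y_px = numeric(), x_um = numeric(),
                      y_um = numeric(), intensity = numeric(),
                      plateau = logical())
  if (!any(mask)) return(empty)
  outside <- image[!mask]
  noise <- if (length(outside) > 10) mad(outside) else 0
  baseline <- median(image[mask])
  thr <- baseline + max(threshold_k * noise, min_amplitude)
  ny <- nrow(image); nx <- ncol(image)
  cand <- which(mask & image > thr, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  # local maxima over the 8-neighbourhood (>=, so plateaus survive)
  is_max <- vapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; c <- cand[i, 2]
    nb <- image[max(1, r - 1):min(ny, r + 1), max(1, c - 1):min(nx, c + 1)]
    image[r, c] >= max(nb)
  }, logical(1))
  cand <- cand[is_max, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  vals <- image[cand]
  ord <- order(-vals)
  cand <- cand[ord, , drop = FALSE]
  vals <- vals[ord]
  keep <- integer()
  for (i in seq_len(nrow(cand))) {
    if (length(keep) >= max_foci) break
    if (all(vapply(keep, function(j) {
      sqrt(sum((cand[i, ] - cand[j, ])^2)) >= min_sep_px
    }, logical(1)))) {
      keep <- c(keep, i)
    }
  }
  cand <- cand[keep, , drop = FALSE]
  vals <- vals[keep]
  h <- (window_px - 1) %/% 2
  res <- lapply(seq_len(nrow(cand)), function(i) {
    r0 <- cand[i, 1]; c0 <- cand[i, 2]
    rr <- max(1, r0 - h):min(ny, r0 + h)
    cc <- max(1, c0 - h):min(nx, c0 + h)
    win <- image[rr, cc]
    # local floor from the window border keeps cytoplasm and neighbouring
    # signal out of the centroid
    border <- c(win[1, ], win[nrow(win), ], win[, 1], win[, ncol(win)])
    w <- pmax(win - median(border), 0)
    plateau <- sum(win == max(win)) > 1
    cx <- sum(t(t(w) * cc)) / sum(w)
    cy <- sum(w * rr) / sum(w)
    data.frame(x_px = cx, y_px = cy,
               x_um = (cx - 0.5) * pixel_size_um,
               y_um = (cy - 0.5) * pixel_size_um,
               intensity = vals[i] - baseline, plateau = plateau)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Distance between the two sister foci of a 2-focus cell
#'
#' @param cell a [cell_observation()] with exactly 2 foci in `channel`
#'   (otherwise `NA` is returned: the cell is undefined for this statistic
#'   and excluded from population means).
#' @param channel focus channel name.
#' @param method `"euclidean"` (default) or `"axial"` (distance along the
#'   medial axis only).
#' @return interfocal distance in micrometres, or `NA`.
#' @export
interfocal_distance <- function(cell, channel = NULL,
                                method = c("euclidean", "axial")) {
  method <- match.arg(method)
  f <- if (is.null(channel)) cell$foci[[1]] else cell$foci[[channel]]
  if (is.null(f) || nrow(f) != 2) return(NA_real_)
  dx <- diff(f$frac) * cell$length_um
  if (method == "axial") return(abs(dx))
  dy <- diff(f$lateral_um)
  sqrt(dx^2 + dy^2)
}

#' Match foci of two channels by proximity (colocalization)
#'
#' Pairs foci of channel A with foci of channel B so that matched pairs are
#' closer than `threshold_um`, each focus is used at most once, the number
#' of matches is maximal and, among maximal matchings, the total distance
#' is minimal. The default method enumerates all assignments (focus counts
#' per cell are tiny); `method = "greedy"` gives the cheaper nearest-pair
#' heuristic, which can mismatch when one close pair blocks two feasible
#' ones.
#'
#' @param foci_a,foci_b matrices or data frames with columns `x_um`, `y_um`
#'   (or two-column matrices of coordinates).
#' @param threshold_um maximum pairing distance, micrometres.
#' @param method `"optimal"` (default) or `"greedy"`.
#' @return list with `pairs` (data frame `i`, `j`, `distance_um`),
#'   `unmatched_a`, `unmatched_b` (integer indices).
#' @export
colocalize <- function(foci_a, foci_b, threshold_um,
                       method = c("optimal", "greedy")) {
  method <- match.arg(method)
  coords <- function(f) {
    if (is.data.frame(f)) as.matrix(f[, c("x_um", "y_um")]) else as.matrix(f)
  }
  A <- coords(foci_a); B <- coords(foci_b)
  na <- nrow(A); nb <- nrow(B)
  empty <- list(pairs = data.frame(i = integer(), j = integer(),
                                   distance_um = numeric()),
                unmatched_a = seq_len(na), unmatched_b = seq_len(nb))
  if (na == 0 || nb == 0) return(empty)
  D <- as.matrix(stats::dist(rbind(A, B)))[seq_len(na), na + seq_len(nb),
                                           drop = FALSE]
  if (method == "greedy") {
    pairs <- NULL
    used_a <- logical(na); used_b <- logical(nb)
    Dw <- D
    repeat {
      m <- which(Dw == min(Dw), arr.ind = TRUE)[1, , drop = TRUE]
      if (Dw[m[1], m[2]] > threshold_um) break
      pairs <- rbind(pairs, data.frame(i = m[1], j = m[2],
                                       distance_um = D[m[1], m[2]]))
      used_a[m[1]] <- TRUE; used_b[m[2]] <- TRUE
      Dw[m[1], ] <- Inf; Dw[, m[2]] <- Inf
      if (all(used_a) || all(used_b)) break
    }
  } else {
    best <- list(n = -1L, dist = Inf, assign = NULL)
    assign_b <- integer(na)  # 0 = unmatched
    recurse <- function(i, used_b) {
      if (i > na) {
        matched <- which(assign_b > 0L)
        n <- length(matched)
        d <- if (n) sum(D[cbind(matched, assign_b[matched])]) else 0
        if (n > best$n || (n == best$n && d < best$dist)) {
          best <<- list(n = n, dist = d, assign = assign_b)
        }
        return(invisible())
      }
      for (j in seq_len(nb)) {
        if (!used_b[j] && D[i, j] <= threshold_um) {
          assign_b[i] <<- j
          recurse(i + 1L, `[<-`(used_b, j, TRUE))
        }
      }
      assign_b[i] <<- 0L
      recurse(i + 1L, used_b)
    }
    recurse(1L, logical(nb))
    matched <- which(best$assign > 0L)
    pairs <- if (length(matched)) {
      data.frame(i = matched, j = best$assign[matched],
                 distance_um = D[cbind(matched, best$assign[matched])])
    } else NULL
  }
  if (is.null(pairs)) return(empty)
  list(pairs = pairs,
       unmatched_a = setdiff(seq_len(na), pairs$i),
       unmatched_b = setdiff(seq_len(nb), pairs$j))
}
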