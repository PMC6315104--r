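#' Cumulative GC skew of a replicon
#'
#' Per window of `window_bp` bases, GC skew is `(#G - #C) / (#G + #C)` (0
#' when the window has no G or C; `N` bases count in neither numerator nor
#' denominator). The cumulative profile is the running sum of window skews,
#' computed linearly from position 1 of the (possibly circular) sequence. On
#' genomes replicated bidirectionally from a single origin the cumulative
#' curve attains its global minimum at the origin and its global maximum at
#' the terminus.
#'
#' @param seq character string over `A,C,G,T,N` (case-insensitive).
#' @param window_bp window size in bp; 1 gives the per-base profile. The
#'   last window may be shorter.
#' @param replicon_id label carried into the profile.
#' @return object of class `skew_profile`: list with `positions` (window
#'   midpoints, 1-based bp), `skew` (per-window), `cumulative_skew`,
#'   `window_bp`, `length_bp`, `replicon_id`.
#' @examples
#' cumulative_gc_skew("GGCC")$cumulative_skew  # 1 2 1 0
#' @export
cumulative_gc_skew <- function(seq, window_bp = 1L, replicon_id = "replicon") {
  seq <- toupper(as.character(seq))
  L <- nchar(seq)
  if (L == 0) stopf("sequence must be non-empty")
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(v), c("A", "C", "G", "T", "N"))
  if (length(bad)) stopf("sequence contains invalid bases: %s",
                         paste(bad, collapse = ","))
  g <- as.integer(v == "G")
  c_ <- as.integer(v == "C")
  window_bp <- as.integer(window_bp)
  if (window_bp < 1) stopf("window_bp must be >= 1")
  win <- (seq_len(L) - 1L) %/% window_bp
  gs <- as.vector(tapply(g, win, sum))
  cs <- as.vector(tapply(c_, win, sum))
  denom <- gs + cs
  skew <- ifelse(denom == 0, 0, (gs - cs) / pmax(denom, 1L))
  n_win <- length(skew)
  starts <- (seq_len(n_win) - 1L) * window_bp + 1L
  ends <- pmin(starts + window_bp - 1L, L)
  structure(list(replicon_id = replicon_id,
                 positions = (starts + ends) / 2,
                 skew = skew,
                 cumulative_skew = cumsum(skew),
                 window_bp = window_bp, length_bp = L),
            class = "skew_profile")
}

#' Locate origin and terminus from a cumulative GC-skew profile
#'
#' The origin is reported at the global minimum of the cumulative skew and
#' the terminus at the global maximum, at window-midpoint resolution. Ties
#' are broken towards the smallest coordinate (recorded in the result).
#'
#' @param profile a [cumulative_gc_skew()] profile (length >= 2).
#' @return object of class `ori_ter`: list with `ori`, `ter` (bp), their
#'   profile indices, `no_extremum` flag (TRUE for a constant profile, in
#'   which case `ori`/`ter` are `NA`), and `tie_break = "smallest-coordinate"`.
#' @export
locate_ori_ter <- function(profile) {
  stopifnot(inherits(profile, "skew_profile"))
  cs <- profile$cumulative_skew
  if (length(cs) < 2) stopf("profile must have length >= 2")
  if (diff(range(cs)) == 0) {
    return(structure(list(ori = NA_real_, ter = NA_real_,
                          ori_index = NA_integer_, ter_index = NA_integer_,
                          no_extremum = TRUE,
                          tie_break = "smallest-coordinate",
                          replicon_id = profile$replicon_id),
                     class = "ori_ter"))
  }
  i_min <- which.min(cs)   # which.min/max return the first (smallest index)
  i_max <- which.max(cs)
  structure(list(ori = profile$positions[i_min], ter = profile$positions[i_max],
                 ori_index = i_min, ter_index = i_max,
                 no_extremum = FALSE, tie_break = "smallest-coordinate",
                 replicon_id = profile$replicon_id),
            class = "ori_ter")
}

#' @export
print.ori_ter <- function(x, ...) {
  if (x$no_extremum) {
    cat(sprintf("<ori_ter %s> no extremum (constant profile)\n", x$replicon_id))
  } else {
    cat(sprintf("<ori_ter %s> ori (skew minimum) at %.0f bp, ter (skew maximum) at %.0f bp\n",
                x$replicon_id, x$ori, x$ter))
  }
  invisible(x)
}

#' @export
print.skew_profile <- function(x, ...) {
  cat(sprintf("<skew_profile %s> %d windows of %d bp over %d bp; cumulative range [%.1f, %.1f]\n",
              x$replicon_id, length(x$skew), x$window_bp, x$length_bp,
              min(x$cumulative_skew), max(x$cumulative_skew)))
  invisible(x)
}

#' @export
plot.skew_profile <- function(x, ...) {
  plot(x$positions, x$cumulative_skew, type = "l",
       xlab = "position (bp)", ylab = "cumulative GC skew",
       main = x$replicon_id, ...)
  ot <- locate_ori_ter(x)
  if (!ot$no_extremum) {
    abline(v = c(ot$ori, ot$ter), lty = 2, col = c("blue", "red"))
    legend("topleft", legend = c("ori (min)", "ter (max)"), lty = 2,
           col = c("blue", "red"), bty = "n")
  }
  invisible(x)
}

#' Write a skew profile as two-column TSV (position, cumulative skew)
#'
#' @param profile a `skew_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_skew_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "skew_profile"))
  df <- data.frame(position = profile$positions,
                   cumulative_skew = profile$cumulative_skew)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
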