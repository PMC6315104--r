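#' Two-phase fit of ring diameter against cell length
#'
#' Division rings first hold a constant diameter while they assemble
#' (formation phase), then shrink as constriction proceeds. This fits a
#' continuous two-segment model — flat at level `mu` up to a changepoint
#' `c`, then linear with slope `b` — by exhaustive least squares over
#' candidate changepoints (every interior observed length with at least
#' `min_side` points on each side). For a candidate `c` the model is
#' `d = mu + b * max(length - c, 0)`, solved in closed form from the
#' normal equations; the changepoint minimising the residual sum of
#' squares wins (smallest candidate on ties). The exhaustive scan is the
#' method, not an approximation to it.
#'
#' @param lengths_um cell lengths, micrometres.
#' @param diameters_um ring diameters, micrometres (same length, >= 6
#'   pairs).
#' @param min_side minimum number of points on each side of a candidate
#'   changepoint.
#' @param min_drop_um fitted diameter decrease over the constriction
#'   segment (`|slope| * (max length - changepoint)`) below which the fit
#'   is flagged degenerate — effectively flat data with no constriction
#'   phase.
#' @return object of class `constriction_fit`: `changepoint_um`,
#'   `plateau_um` (mu), `slope` (b, um of diameter per um of length),
#'   `rss`, `degenerate` flag, `n`, and the data.
#' @export
constriction_phases <- function(lengths_um, diameters_um, min_side = 3,
                                min_drop_um = 0.1) {
  stopifnot(length(lengths_um) == length(diameters_um))
  n <- length(lengths_um)
  if (n < 6) stopf("need at least 6 (length, diameter) pairs, got %d", n)
  ord <- order(lengths_um)
  x <- lengths_um[ord]
  y <- diameters_um[ord]
  cands <- unique(x[seq(min_side, n - min_side)])
  best <- list(rss = Inf)
  for (cp in cands) {
    h <- pmax(x - cp, 0)
    fit <- two_segment_ls(h, y)
    if (fit$rss < best$rss - 1e-12) {
      best <- c(fit, list(changepoint = cp))
    }
  }
  drop <- abs(best$b) * (max(x) - best$changepoint)
  structure(list(changepoint_um = best$changepoint,
                 plateau_um = best$mu, slope = best$b, rss = best$rss,
                 degenerate = drop < min_drop_um,
                 n = n, lengths_um = x, diameters_um = y),
            class = "constriction_fit")
}

# closed-form least squares for d = mu + b * h (h = hinge term)
two_segment_ls <- function(h, y) {
  n <- length(y)
  sh <- sum(h); shh <- sum(h^2); sy <- sum(y); shy <- sum(h * y)
  det <- n * shh - sh^2
  if (det <= 0) {
    mu <- mean(y); b <- 0
  } else {
    mu <- (shh * sy - sh * shy) / det
    b <- (n * shy - sh * sy) / det
  }
  list(mu = mu, b = b, rss = sum((y - mu - b * h)^2))
}

#' @export
print.constriction_fit <- function(x, ...) {
  cat(sprintf("<constriction_fit> n = %d\n", x$n))
  cat(sprintf("  formation phase: diameter ~ %.3f um up to length %.2f um\n",
              x$plateau_um, x$changepoint_um))
  cat(sprintf("  constriction phase: slope %.3f um/um (rss %.4g)%s\n",
              x$slope, x$rss,
              if (x$degenerate) "  [degenerate: effectively flat]" else ""))
  invisible(x)
}

#' @export
plot.constriction_fit <- function(x, ...) {
  plot(x$lengths_um, x$diameters_um, xlab = "cell length (um)",
       ylab = "ring diameter (um)", ...)
  xs <- seq(min(x$lengths_um), max(x$lengths_um), length.out = 200)
  lines(xs, x$plateau_um + x$slope * pmax(xs - x$changepoint_um, 0),
        col = "red", lwd = 2)
  abline(v = x$changepoint_um, lty = 2)
  invisible(x)
}
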