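#' Fraction of cells with one focus, with Wilson interval
#'
#' In a snapshot of a steadily growing population, the fraction `F` of
#' cells showing a single focus of a locus estimates how long the locus
#' spends unduplicated. Only cells with exactly 1 or 2 foci in the channel
#' are eligible; others (0 or >2, e.g. cells without a defined signal) are
#' excluded and their count reported.
#'
#' @param cells list of [cell_observation()] (or a `cell_population`).
#' @param channel focus channel name (default: first channel).
#' @return list with `F`, `ci` (95% Wilson interval), `n_one`, `n_two`,
#'   `n_excluded`.
#' @export
fraction_one_focus <- function(cells, channel = NULL) {
  if (inherits(cells, "cell_population")) cells <- cells$cells
  counts <- vapply(cells, function(cell) {
    f <- if (is.null(channel)) cell$foci[[1]] else cell$foci[[channel]]
    if (is.null(f)) 0L else nrow(f)
  }, integer(1))
  n_one <- sum(counts == 1L)
  n_two <- sum(counts == 2L)
  n_exc <- length(counts) - n_one - n_two
  if (n_one + n_two == 0) stopf("no cells with 1 or 2 foci in this channel")
  list(F = n_one / (n_one + n_two),
       ci = wilson_interval(n_one, n_one + n_two),
       n_one = n_one, n_two = n_two, n_excluded = n_exc)
}

# Wilson 95% score interval for a binomial proportion.
wilson_interval <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

#' Cell age at focus duplication from the one-focus fraction
#'
#' Under the exponential-growth age distribution (density
#' \eqn{p(a) = 2\ln 2\, 2^{-a}}), a locus that duplicates at age \eqn{a_d}
#' is seen as a single focus in the fraction \eqn{F = 2(1 - 2^{-a_d})} of
#' cells. Inverting gives the estimator
#' \deqn{a = -\ln(1 - F/2)/\ln 2.}
#'
#' @param F fraction of cells with one focus, in `[0, 1]` (vectorised).
#' @return age fraction(s) in `[0, 1]`.
#' @examples
#' age_at_duplication(0.25)  # 0.1926
#' @export
age_at_duplication <- function(F) {
  if (any(is.na(F)) || any(F < 0 | F > 1)) {
    stopf("F must lie in [0, 1]")
  }
  -log(1 - F / 2) / log(2)
}

#' Duplication time in minutes
#'
#' Scales a duplication age (fraction of the cell cycle) by the generation
#' time.
#'
#' @param a age fraction(s).
#' @param T_min generation time in minutes (> 0), default 150.
#' @return time(s) in minutes.
#' @export
time_at_duplication <- function(a, T_min = 150) {
  if (T_min <= 0) stopf("T_min must be > 0")
  a * T_min
}

#' Estimate when a locus duplicates from snapshot focus counts
#'
#' Chains [fraction_one_focus()] -> [age_at_duplication()] ->
#' [time_at_duplication()]. The 95% interval on the duplication time is
#' obtained by transforming the Wilson bounds of `F` through the (strictly
#' monotone) age map — exact under monotonicity, no delta-method
#' approximation.
#'
#' @param cells list of [cell_observation()] or a `cell_population`; or
#'   use `counts = c(n_one, n_two)` to start from tabulated counts.
#' @param channel focus channel name.
#' @param T_min generation time in minutes.
#' @param counts optional integer pair overriding `cells`.
#' @param locus label for reporting (defaults to `channel`).
#' @return object of class `duplication_estimate` with fields `locus`, `F`,
#'   `a`, `t_d_min`, `ci_t_d` (minutes), `n`, `n_excluded`, `T_min`.
#' @examples
#' estimate_duplication(counts = c(25, 75), T_min = 150)  # t_d ~ 28.9 min
#' @export
estimate_duplication <- function(cells = NULL, channel = NULL, T_min = 150,
                                 counts = NULL, locus = NULL) {
  if (!is.null(counts)) {
    stopifnot(length(counts) == 2, all(counts >= 0), sum(counts) > 0)
    fr <- list(F = counts[1] / sum(counts),
               ci = wilson_interval(counts[1], sum(counts)),
               n_one = counts[1], n_two = counts[2], n_excluded = 0L)
  } else {
    fr <- fraction_one_focus(cells, channel)
  }
  a <- age_at_duplication(fr$F)
  t_d <- time_at_duplication(a, T_min)
  ci_a <- age_at_duplication(fr$ci)
  structure(list(locus = locus %||% channel %||% "locus",
                 F = fr$F, a = a, t_d_min = t_d,
                 ci_a = unname(ci_a),
                 ci_t_d = unname(time_at_duplication(ci_a, T_min)),
                 n = fr$n_one + fr$n_two, n_excluded = fr$n_excluded,
                 T_min = T_min),
            class = "duplication_estimate")
}

#' @export
print.duplication_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("<duplication_estimate %s>\n", x$locus))
  cat(sprintf("  one-focus fraction F = %.3f  (n = %d eligible, %d excluded)\n",
              x$F, x$n, x$n_excluded))
  cat(sprintf("  duplication age a = %.4f of the cycle\n", x$a))
  cat(sprintf("  duplication time t_d = %.1f min of a %.0f-min cycle  [95%% CI %.1f, %.1f]\n",
              x$t_d_min, x$T_min, x$ci_t_d[1], x$ci_t_d[2]))
  invisible(x)
}

#' @export
coef.duplication_estimate <- function(object, ...) {
  c(F = object$F, a = object$a, t_d_min = object$t_d_min)
}

#' @export
confint.duplication_estimate <- function(object, parm = "t_d_min",
                                         level = 0.95, ...) {
  if (level != 0.95) stopf("only the 95%% interval is carried")
  switch(parm,
         t_d_min = object$ci_t_d,
         a = object$ci_a,
         stopf("parm must be 't_d_min' or 'a'"))
}

#' Order locus duplication estimates and report Ori->Ter intervals
#'
#' Sorts duplication estimates by time and, for every replicon with both an
#' `Ori...` and a `Ter...` estimate (matched by the trailing replicon
#' identifier, e.g. `OriC1`/`Ter1`), reports the interval
#' `t_d(Ter) - t_d(Ori)` — the apparent time between origin and terminus
#' duplication.
#'
#' @param estimates list of `duplication_estimate` objects (>= 1).
#' @return object of class `segregation_report`: `table` (one row per
#'   locus, sorted by `t_d_min`) and `intervals` (one row per matched
#'   Ori/Ter pair). Unpaired Ori/Ter loci produce a warning and no row.
#' @export
segregation_report <- function(estimates) {
  stopifnot(length(estimates) >= 1,
            all(vapply(estimates, inherits, logical(1), "duplication_estimate")))
  tab <- do.call(rbind, lapply(estimates, function(e) {
    data.frame(locus = e$locus, F = e$F, a = e$a, t_d_min = e$t_d_min,
               ci_lower_min = e$ci_t_d[1], ci_upper_min = e$ci_t_d[2],
               n = e$n, stringsAsFactors = FALSE)
  }))
  tab <- tab[order(tab$t_d_min), , drop = FALSE]
  rownames(tab) <- NULL
  is_ori <- grepl("^ori", tab$locus, ignore.case = TRUE)
  is_ter <- grepl("^ter", tab$locus, ignore.case = TRUE)
  rep_id <- sub("^(ori[c]?|ter)", "", tolower(tab$locus))
  intervals <- NULL
  for (id in unique(rep_id[is_ori | is_ter])) {
    o <- which(is_ori & rep_id == id)
    t <- which(is_ter & rep_id == id)
    if (length(o) == 1 && length(t) == 1) {
      intervals <- rbind(intervals, data.frame(
        replicon = id, ori = tab$locus[o], ter = tab$locus[t],
        interval_min = tab$t_d_min[t] - tab$t_d_min[o],
        stringsAsFactors = FALSE))
    } else if (length(o) + length(t) >= 1) {
      warning(sprintf("replicon '%s': Ori/Ter pair incomplete, interval omitted", id),
              call. = FALSE)
    }
  }
  structure(list(table = tab, intervals = intervals),
            class = "segregation_report")
}

#' @export
print.segregation_report <- function(x, ...) {
  cat("<segregation_report>\n")
  print(x$table, digits = 4)
  if (!is.null(x$intervals)) {
    cat("Ori->Ter duplication intervals:\n")
    print(x$intervals, digits = 4)
  }
  invisible(x)
}
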