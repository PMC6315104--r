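# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately use a different computation path from the
# package implementation.

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# -- palindromes: enumerate every even-length substring, keep those whose
# reverse complement equals itself with <= k mismatched pairs and whose
# outermost pair is complementary, then drop substrings properly contained
# in another qualifying one.
oracle_palindromes <- function(seq, min_len, max_mismatch) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  v <- strsplit(toupper(seq), "")[[1]]
  L <- length(v)
  qual <- list()
  for (len in seq(min_len, L, by = 2)) {
    half <- len / 2
    for (s in seq_len(L - len + 1)) {
      w <- v[s:(s + len - 1)]
      left <- w[seq_len(half)]
      right <- w[len + 1 - seq_len(half)]
      match_pair <- unname(comp[left]) == right
      if (sum(!match_pair) <= max_mismatch && match_pair[1]) {
        qual[[length(qual) + 1L]] <- c(s, s + len - 1L)
      }
    }
  }
  if (!length(qual)) {
    return(data.frame(start = integer(), end = integer()))
  }
  m <- do.call(rbind, qual)
  keep <- vapply(seq_len(nrow(m)), function(i) {
    !any(m[, 1] <= m[i, 1] & m[, 2] >= m[i, 2] &
           (m[, 2] - m[, 1]) > (m[i, 2] - m[i, 1]))
  }, logical(1))
  out <- unique(data.frame(start = m[keep, 1], end = m[keep, 2]))
  out[order(out$start, out$end), , drop = FALSE]
}

# -- colocalization: exhaustive search over every injective assignment of
# channel-A foci to channel-B foci (including leaving any focus out),
# maximising matches then minimising total distance.
oracle_colocalize <- function(A, B, threshold) {
  na <- nrow(A); nb <- nrow(B)
  D <- as.matrix(stats::dist(rbind(A, B)))[seq_len(na), na + seq_len(nb),
                                           drop = FALSE]
  best_n <- 0L; best_d <- 0
  options_per_a <- lapply(seq_len(na), function(i) c(0L, seq_len(nb)))
  grid <- do.call(expand.grid, options_per_a)
  for (g in seq_len(nrow(grid))) {
    asg <- as.integer(grid[g, ])
    used <- asg[asg > 0L]
    if (anyDuplicated(used)) next
    ok <- all(vapply(seq_len(na), function(i) {
      asg[i] == 0L || D[i, asg[i]] <= threshold
    }, logical(1)))
    if (!ok) next
    n <- length(used)
    d <- if (n) sum(D[cbind(which(asg > 0L), asg[asg > 0L])]) else 0
    if (n > best_n || (n == best_n && d < best_d)) {
      best_n <- n; best_d <- d
    }
  }
  list(n = best_n, dist = best_d)
}

# -- exact two-sided binomial p-value by direct enumeration of the mass
# function (sum of P(X = j) over all j no more probable than the observed
# count).
oracle_binom_p <- function(x, n) {
  probs <- vapply(0:n, function(j) choose(n, j) * 0.5^n, numeric(1))
  sum(probs[probs <= probs[x + 1] * (1 + 1e-9)])
}

# -- two-segment changepoint fit via lm() at every candidate changepoint.
oracle_constriction <- function(x, y, min_side = 3) {
  ord <- order(x); x <- x[ord]; y <- y[ord]
  n <- length(x)
  cands <- unique(x[seq(min_side, n - min_side)])
  best <- NULL
  for (cp in cands) {
    h <- pmax(x - cp, 0)
    fit <- lm(y ~ h)
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(changepoint = cp, mu = unname(coef(fit)[1]),
                   b = unname(coef(fit)[2]), rss = rss)
    }
  }
  best
}

# duplication estimate at an exact duplication time, for report fixtures
est_at_td <- function(locus, td, T_min = 150) {
  a <- td / T_min
  F <- 2 * (1 - 2^(-a))
  structure(list(locus = locus, F = F, a = a, t_d_min = td,
                 ci_a = c(a, a), ci_t_d = c(td, td), n = 1000L,
                 n_excluded = 0L, T_min = T_min),
            class = "duplication_estimate")
}

# simple two-focus cell at stated fractions
make_cell <- function(fracs, length_um = 3, id = "c", lateral = 0,
                      intensity = 400, channel = "ch1", ring = NULL) {
  cell_observation(id, length_um = length_um, width_um = 1,
                   foci = stats::setNames(list(data.frame(
                     frac = fracs,
                     lateral_um = rep_len(lateral, length(fracs)),
                     intensity = rep_len(intensity, length(fracs)))), channel),
                   ring = ring)
}
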