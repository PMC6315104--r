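#' Find reverse-complement palindromes (parS-candidate search)
#'
#' Searches a replicon for maximal even-length substrings `w` that equal
#' their own reverse complement with at most `max_mismatch` mismatched base
#' pairs — the signature of centromere-like parS sites, which are inverted
#' repeats bound symmetrically by ParB dimers. A pair `(w[i], w[n+1-i])`
#' matches when the bases are Watson-Crick complementary; `N` never matches.
#' A hit is maximal when no longer qualifying palindrome properly contains
#' it. Reported hits always begin and end on a complementary pair —
#' mismatched pairs are interior, so hits never have frayed ends. Perfect
#' hits (0 mismatches) are flagged distinctly from nearly perfect ones.
#'
#' For circular replicons the search is extended across the origin; hits
#' that span it are reported with `start` normalised to `[1, L]` and
#' `end = start + width - 1`, which may exceed `L` (coordinates wrap).
#'
#' @param seq character string over `A,C,G,T,N`.
#' @param min_len minimum palindrome length in bp; must be even and >= 4
#'   (reverse-complement symmetry makes gapless palindromes even-length).
#' @param max_mismatch maximum number of mismatched pairs (default 0;
#'   "nearly perfect" parS candidates use small values such as 2).
#' @param circular extend the search across the origin of a circular
#'   replicon.
#' @param replicon_id label for the hits.
#' @return a `feature_hits` data frame with columns `replicon_id`, `start`,
#'   `end`, `strand` (always `"+"`; a palindrome is its own reverse
#'   complement), `kind = "palindrome"`, `mismatches`, `perfect`, `sequence`.
#' @examples
#' find_palindromes("GTTACGTACGTAAC", min_len = 14)   # one perfect hit
#' @export
find_palindromes <- function(seq, min_len = 14L, max_mismatch = 0L,
                             circular = FALSE, replicon_id = "replicon") {
  seq <- toupper(as.character(seq))
  L <- nchar(seq)
  min_len <- as.integer(min_len)
  if (min_len < 4L || min_len %% 2L != 0L) {
    stopf("min_len must be even and >= 4 (gapless palindromes are even-length)")
  }
  if (L < min_len) return(empty_feature_hits())
  work <- seq
  if (circular) {
    # extend so palindromes spanning the origin are visible; a maximal
    # palindrome can be long, so pad generously but boundedly
    pad <- min(L - 1L, max(4L * min_len, 200L))
    work <- paste0(seq, substr(seq, 1L, pad))
  }
  v <- strsplit(work, "", fixed = TRUE)[[1]]
  n <- length(v)
  # complement as integer lookup: A<->T, C<->G, N matches nothing
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 0L)
  x <- unname(code[v])
  if (anyNA(x)) stopf("sequence contains invalid bases")
  comp <- c(4L, 3L, 2L, 1L)  # complement codes for A,C,G,T
  hits <- list()
  k <- as.integer(max_mismatch)
  for (c0 in seq_len(n - 1L)) {
    # even palindrome centred between positions c0 and c0+1
    max_arm <- min(c0, n - c0)
    if (2L * max_arm < min_len) next
    mism <- 0L
    arm <- 0L
    best_arm <- 0L
    while (arm < max_arm) {
      l <- x[c0 - arm]
      r <- x[c0 + 1L + arm]
      ok <- l > 0L && r > 0L && comp[l] == r
      if (!ok) {
        mism <- mism + 1L
        if (mism > k) break
      }
      arm <- arm + 1L
      if (ok) best_arm <- arm   # trim trailing mismatched pairs
    }
    # longest palindrome at this centre ends on a matched pair
    if (2L * best_arm >= min_len) {
      start <- c0 - best_arm + 1L
      end <- c0 + best_arm
      hits[[length(hits) + 1L]] <- c(start, end)
    }
  }
  if (!length(hits)) return(empty_feature_hits())
  hm <- do.call(rbind, hits)
  # drop hits properly contained in another hit (maximality across centres)
  keep <- rep(TRUE, nrow(hm))
  for (i in seq_len(nrow(hm))) {
    contained <- hm[, 1] <= hm[i, 1] & hm[, 2] >= hm[i, 2] &
      (hm[, 2] - hm[, 1]) > (hm[i, 2] - hm[i, 1])
    if (any(contained)) keep[i] <- FALSE
  }
  hm <- hm[keep, , drop = FALSE]
  if (circular) {
    # keep hits whose normalised start lies in [1, L]; drop duplicates of
    # hits fully visible in the unextended sequence
    keep <- hm[, 1] <= L
    hm <- hm[keep, , drop = FALSE]
    dup <- duplicated(paste(((hm[, 1] - 1L) %% L) + 1L, hm[, 2] - hm[, 1]))
    hm <- hm[!dup, , drop = FALSE]
  }
  if (!nrow(hm)) return(empty_feature_hits())
  seqs <- substring(work, hm[, 1], hm[, 2])
  mm <- vapply(seqs, count_mismatched_pairs, integer(1), USE.NAMES = FALSE)
  out <- data.frame(replicon_id = replicon_id,
                    start = hm[, 1], end = hm[, 2], strand = "+",
                    kind = "palindrome", mismatches = mm,
                    perfect = mm == 0L, sequence = seqs,
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("feature_hits", "data.frame")
  out
}

# number of non-complementary pairs (i, n+1-i) of an even-length string
count_mismatched_pairs <- function(w) {
  v <- strsplit(w, "", fixed = TRUE)[[1]]
  n <- length(v)
  half <- n %/% 2L
  l <- v[seq_len(half)]
  r <- v[n + 1L - seq_len(half)]
  sum(!(unname(DNA_COMPLEMENT[l]) == r & l %in% c("A", "C", "G", "T")))
}

empty_feature_hits <- function() {
  out <- data.frame(replicon_id = character(), start = integer(),
                    end = integer(), strand = character(), kind = character(),
                    mismatches = integer(), perfect = logical(),
                    sequence = character(), stringsAsFactors = FALSE)
  class(out) <- c("feature_hits", "data.frame")
  out
}

#' @export
print.feature_hits <- function(x, ...) {
  cat(sprintf("<feature_hits> %d hit(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 20))
  invisible(x)
}
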