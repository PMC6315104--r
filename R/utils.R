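# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Circular distance between genomic coordinates
#'
#' Shortest distance between two 1-based positions on a circular replicon of
#' length `L`, in bp.
#'
#' @param a,b 1-based positions (vectors recycle).
#' @param L replicon length in bp.
#' @return integer vector of distances in `[0, floor(L/2)]`.
#' @export
circular_distance <- function(a, b, L) {
  d <- abs(((a - 1) %% L) - ((b - 1) %% L))
  pmin(d, L - d)
}

# Deterministic small hash of a string onto [0, 2^28); used to derive
# per-stage random substreams from one top-level seed.
hash_string <- function(x) {
  v <- utf8ToInt(x)
  h <- 0
  for (ch in v) h <- (h * 131 + ch) %% 268435456L
  as.integer(h)
}

#' Derive a per-stage seed from a top-level seed
#'
#' Hashes the stage name into an offset so that adding a pipeline stage never
#' perturbs the random draws of earlier stages.
#'
#' @param seed top-level integer seed.
#' @param stage stage name (character scalar).
#' @return integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + hash_string(stage)) %% 2147483647)
}

# 1-based inclusive <-> BED 0-based half-open conversion. The only place in
# the package where genomic coordinate conventions are converted.
to_bed_coords <- function(start1, end1) {
  data.frame(start = start1 - 1L, end = end1)
}

from_bed_coords <- function(start0, end0) {
  data.frame(start = start0 + 1L, end = end0)
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Reverse complement of a plain character string (ACGTN).
revcomp_chr <- function(seq) {
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  paste(rev(unname(DNA_COMPLEMENT[v])), collapse = "")
}
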