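#' Specification of a synthetic replichore-skewed genome
#'
#' Describes a circular replicon whose G/C composition is biased by
#' replichore, emulating the strand bias that makes cumulative GC skew peak
#' at the terminus and dip at the origin. On the leading strand from `ori_pos`
#' to `ter_pos` (increasing coordinate, wrapping), `P(G) = 0.25 +
#' skew_strength` and `P(C) = 0.25 - skew_strength`; the bias is reversed on
#' the other replichore. A and T are fixed at 0.25 — GC skew is the only
#' statistic consumed downstream.
#'
#' @param length_bp replicon length in bp.
#' @param ori_pos,ter_pos 1-based origin and terminus positions (distinct).
#' @param skew_strength per-base G/C probability bias in `(0, 0.5)`; 0 is
#'   allowed and gives an unbiased control sequence.
#' @param planted_motifs optional list of `list(sequence, position, strand)`
#'   with 1-based positions; motifs are written over the background
#'   (reverse-complemented when strand is `"-"`) and must not overlap.
#' @param replicon_id label used in FASTA/BED output.
#' @param seed integer seed.
#' @return object of class `genome_spec`.
#' @export
genome_spec <- function(length_bp, ori_pos, ter_pos, skew_strength = 0.15,
                        planted_motifs = list(), replicon_id = "synthetic",
                        seed = 1L) {
  if (length_bp < 2) stopf("length_bp must be >= 2")
  if (ori_pos < 1 || ori_pos > length_bp || ter_pos < 1 || ter_pos > length_bp) {
    stopf("ori_pos and ter_pos must lie in [1, length_bp]")
  }
  if (ori_pos == ter_pos) stopf("ori_pos and ter_pos must differ")
  if (skew_strength < 0 || skew_strength >= 0.5) {
    stopf("skew_strength must be in [0, 0.5)")
  }
  if (length(planted_motifs)) {
    iv <- t(vapply(planted_motifs, function(m) {
      s <- as.integer(m$position); c(s, s + nchar(m$sequence) - 1L)
    }, integer(2)))
    if (any(iv[, 1] < 1) || any(iv[, 2] > length_bp)) {
      stopf("planted motifs must lie within [1, length_bp]")
    }
    o <- order(iv[, 1])
    iv <- iv[o, , drop = FALSE]
    if (nrow(iv) > 1 && any(iv[-1, 1] <= iv[-nrow(iv), 2])) {
      stopf("planted motifs overlap")
    }
  }
  structure(list(length_bp = as.integer(length_bp),
                 ori_pos = as.integer(ori_pos), ter_pos = as.integer(ter_pos),
                 skew_strength = skew_strength,
                 planted_motifs = planted_motifs,
                 replicon_id = replicon_id, seed = as.integer(seed)),
            class = "genome_spec")
}

#' Generate a synthetic genome with replichore GC-skew bias
#'
#' Samples a circular sequence under the per-replichore base composition of
#' its [genome_spec()] and overwrites the planted motifs. In expectation the
#' cumulative GC skew (window 1, computed linearly from position 1) increases
#' by `2 * skew_strength` per base on the ori->ter replichore and decreases
#' at the same rate on the other, so its global maximum falls at the terminus
#' and its global minimum at the origin (circularly).
#'
#' @param spec a [genome_spec()].
#' @return single character string of length `length_bp` over ACGT, with the
#'   spec attached as attribute `"spec"` and class `synthetic_genome`.
#' @export
generate_skewed_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  L <- spec$length_bp
  s <- spec$skew_strength
  # replichore 1: positions ori..ter-1 moving forward (wrapping)
  idx <- seq_len(L)
  if (spec$ori_pos < spec$ter_pos) {
    on_rep1 <- idx >= spec$ori_pos & idx < spec$ter_pos
  } else {
    on_rep1 <- idx >= spec$ori_pos | idx < spec$ter_pos
  }
  p_rep1 <- c(A = 0.25, C = 0.25 - s, G = 0.25 + s, T = 0.25)
  p_rep2 <- c(A = 0.25, C = 0.25 + s, G = 0.25 - s, T = 0.25)
  bases <- character(L)
  n1 <- sum(on_rep1)
  bases[on_rep1] <- sample(names(p_rep1), n1, replace = TRUE, prob = p_rep1)
  bases[!on_rep1] <- sample(names(p_rep2), L - n1, replace = TRUE, prob = p_rep2)
  for (m in spec$planted_motifs) {
    motif <- toupper(m$sequence)
    if (identical(m$strand, "-")) motif <- revcomp_chr(motif)
    pos <- as.integer(m$position)
    bases[pos:(pos + nchar(motif) - 1L)] <- strsplit(motif, "")[[1]]
  }
  structure(paste(bases, collapse = ""), spec = spec,
            class = c("synthetic_genome", "character"))
}

#' @export
print.synthetic_genome <- function(x, ...) {
  sp <- attr(x, "spec")
  cat(sprintf("<synthetic_genome %s> %d bp, ori %d, ter %d, skew %.2f, %d planted motif(s)\n",
              sp$replicon_id, sp$length_bp, sp$ori_pos, sp$ter_pos,
              sp$skew_strength, length(sp$planted_motifs)))
  invisible(x)
}

#' Write replicon sequences to FASTA
#'
#' @param seqs named character vector or list of sequences (names become
#'   FASTA record ids).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- vapply(seqs, as.character, "")
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    names(seqs) <- paste0("replicon_", seq_along(seqs))
  }
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read replicon sequences from FASTA
#'
#' @param path FASTA file; multi-record files are multiple replicons.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
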