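#' Percent identity of two proteins by global alignment
#'
#' Aligns two protein sequences globally (Needleman-Wunsch with affine gap
#' penalties, via [Biostrings::pairwiseAlignment()]) and reports the percent
#' identity: identical aligned pairs divided by alignment columns, terminal
#' gap columns excluded, times 100. Used e.g. to quantify how closely a
#' candidate division regulator resembles a characterised homologue.
#'
#' @param seq_a,seq_b protein sequences (single characters strings over the
#'   20 amino-acid one-letter codes plus `X`).
#' @param substitution_matrix name of the substitution matrix (default
#'   `"BLOSUM62"`).
#' @param gap_opening,gap_extension affine gap penalties.
#' @return percent identity in `[0, 100]`, with the alignment attached as
#'   attribute `"alignment"`.
#' @examples
#' pairwise_identity("ACDE", "ACDF")  # 75
#' @export
pairwise_identity <- function(seq_a, seq_b,
                              substitution_matrix = "BLOSUM62",
                              gap_opening = 10, gap_extension = 0.5) {
  check_aa <- function(s, nm) {
    s <- toupper(as.character(s))
    if (nchar(s) == 0) stopf("%s must be non-empty", nm)
    ok <- "ACDEFGHIKLMNPQRSTVWYXBZU*"
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- setdiff(v, strsplit(ok, "")[[1]])
    if (length(bad)) stopf("%s contains non-amino-acid characters: %s",
                           nm, paste(bad, collapse = ","))
    s
  }
  seq_a <- check_aa(seq_a, "seq_a")
  seq_b <- check_aa(seq_b, "seq_b")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gap <- p == "-" | s == "-"
  # trim terminal gap runs (global alignment may open with/end in gaps)
  first <- 1L
  while (first <= length(gap) && gap[first]) first <- first + 1L
  last <- length(gap)
  while (last >= first && gap[last]) last <- last - 1L
  if (last < first) stopf("alignment is all terminal gaps")
  keep <- first:last
  ident <- 100 * sum(p[keep] == s[keep] & p[keep] != "-") / length(keep)
  attr(ident, "alignment") <- aln
  ident
}
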