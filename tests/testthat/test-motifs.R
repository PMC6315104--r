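test_that("degenerate consensus matching honours IUPAC wildcards", {
  h <- match_consensus("GTTAAAACGTTTTAAC", "GTTNNNNCGNNNNAAC",
                       both_strands = FALSE)
  expect_equal(nrow(h), 1)
  expect_equal(c(h$start, h$end), c(1L, 16L))
  expect_equal(h$strand, "+")
  expect_equal(nrow(match_consensus("GGAAGGG", "GGNAGGG")), 1)
  expect_equal(nrow(match_consensus("GGTAGGC", "GGNAGGG")), 0)
  # subject N never satisfies a literal pattern base, only wildcards
  expect_equal(nrow(match_consensus("GGNAGGG", "GGNAGGG")), 1)
  expect_equal(nrow(match_consensus("GGANGGG", "GGNAGGG")), 0)
  expect_error(match_consensus("ACGT", "GG!A"), "IUPAC")
})

test_that("minus-strand hits carry forward coordinates", {
  s <- paste0(random_dna(40, 6), "CCCTGCC", random_dna(40, 7))  # revcomp KOPS
  h <- match_consensus(s, "GGCAGGG", both_strands = TRUE)
  minus <- h[h$strand == "-", ]
  expect_true(nrow(minus) >= 1)
  expect_true(any(minus$start == 41 & minus$end == 47))
})

test_that("circular hit count is invariant under sequence rotation", {
  s <- paste0(random_dna(1000, 17), "GGCAGGG", random_dna(800, 18),
              "CCCTACC", random_dna(900, 19))
  n0 <- nrow(match_consensus(s, "GGNAGGG", circular = TRUE))
  expect_gte(n0, 2)  # at least the planted forward and reverse motifs
  for (rot in c(1, 7, 1234)) {
    s2 <- paste0(substr(s, rot + 1, nchar(s)), substr(s, 1, rot))
    expect_equal(nrow(match_consensus(s2, "GGNAGGG", circular = TRUE)), n0,
                 info = paste("rotation", rot))
  }
})

test_that("KOPS strand bias calls the inversion at the terminus", {
  mkhits <- function(n_plus1, n_minus1, n_plus2, n_minus2, L = 10000,
                     ori = 1, ter = 5001) {
    pos1 <- round(seq(ori + 100, ter - 100,
                      length.out = n_plus1 + n_minus1))
    pos2 <- round(seq(ter + 100, L - 100,
                      length.out = n_plus2 + n_minus2))
    data.frame(replicon_id = "r",
               start = c(pos1, pos2), end = c(pos1, pos2) + 6,
               strand = c(rep("+", n_plus1), rep("-", n_minus1),
                          rep("+", n_plus2), rep("-", n_minus2)),
               kind = "kops", mismatches = 0L)
  }
  b <- kops_strand_bias(mkhits(50, 0, 0, 50), ori = 1, ter = 5001, L = 10000)
  expect_identical(b$verdict, "inverted")
  expect_equal(unname(b$counts["arc1", ]), c(50, 0))
  expect_equal(unname(b$counts["arc2", ]), c(0, 50))
  # balanced strands: no inversion
  b2 <- kops_strand_bias(mkhits(25, 25, 25, 25), 1, 5001, 10000)
  expect_identical(b2$verdict, "not-inverted")
  # empty hit set: no verdict
  expect_identical(kops_strand_bias(mkhits(1, 0, 0, 1)[0, ],
                                    1, 5001, 10000)$verdict, "no-hits")
})

test_that("strand-bias p-values equal the enumerated exact binomial", {
  h <- local({
    pos1 <- round(seq(200, 4800, length.out = 50))
    pos2 <- round(seq(5200, 9800, length.out = 50))
    data.frame(replicon_id = "r", start = c(pos1, pos2),
               end = c(pos1, pos2) + 6,
               strand = c(rep("+", 30), rep("-", 20),
                          rep("+", 20), rep("-", 30)),
               kind = "kops", mismatches = 0L)
  })
  b <- kops_strand_bias(h, ori = 1, ter = 5001, L = 10000)
  expect_equal(unname(b$p_values["arc1"]), oracle_binom_p(30, 50),
               tolerance = 1e-10)
  expect_equal(unname(b$p_values["arc2"]), oracle_binom_p(20, 50),
               tolerance = 1e-10)
  # 30/20 per arc flips the majority but is not significant at 0.05
  expect_identical(b$verdict, "not-inverted")
})

test_that("replicon-unique filtering keeps only origin-proximal private hits", {
  pal <- "GTTACCGCGGTAAC"
  cand <- data.frame(replicon_id = "C2",
                     start = c(1000, 9000, 30000),
                     end = c(1013, 9013, 30013),
                     strand = "+", kind = "palindrome", mismatches = 0L,
                     perfect = TRUE,
                     sequence = c(pal, "ACGTAAGGCCTTAC", "GTTAGGCGCCTAAC"))
  other <- paste0(random_dna(5000, 41), "ACGTAAGGCCTTAC", random_dna(5000, 42))
  kept <- filter_replicon_unique(cand, list(other = other), ori = 500,
                                 L = 40000, ori_window_bp = 5000)
  # hit 1: unique and 500 bp from ori -> retained
  # hit 2: present verbatim on the other replicon -> removed
  # hit 3: ~29.5 kb from ori with a 5-kb window -> removed
  expect_equal(kept$start, 1000)
  # subset of input and idempotent
  again <- filter_replicon_unique(kept, list(other = other), ori = 500,
                                  L = 40000, ori_window_bp = 5000)
  expect_identical(again, kept)
  # reverse-complement occurrences on other replicons also disqualify
  other_rc <- paste0(random_dna(2000, 43),
                     as.character(Biostrings::reverseComplement(
                       Biostrings::DNAString("GTTAGGCGCCTAAC"))),
                     random_dna(2000, 44))
  kept2 <- filter_replicon_unique(cand, list(o = other_rc), ori = 30500,
                                  L = 40000, ori_window_bp = 5000)
  expect_false("GTTAGGCGCCTAAC" %in% kept2$sequence)
})

test_that("feature tables export to BED and GFF3 with converted coordinates", {
  hits <- find_palindromes("GTTACGTACGTAAC", 14)
  bed <- withr::local_tempfile(fileext = ".bed")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_features_bed(hits, bed)
  write_features_gff3(hits, gff)
  b <- read.table(bed, sep = "\t")
  expect_equal(b$V2, 0)    # BED is 0-based half-open
  expect_equal(b$V3, 14)
  g <- read.table(gff, sep = "\t", comment.char = "#")
  expect_equal(g$V4, 1)    # GFF3 stays 1-based inclusive
  expect_equal(g$V5, 14)
})
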