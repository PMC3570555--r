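# Internal consistency of the alignment statistics machinery: the
# range-based masked-identity computation must agree exactly with the
# string-walking reference, and scores must match an independent
# Smith-Waterman implementation.

test_that("range-based identity equals the string-walking reference", {
  withr::local_seed(8)
  scoring <- msatselect:::.align_scoring()
  for (k in 1:40) {
    n <- sample(80:250, 1)
    base <- rand_dna(n)
    mut <- mutate_seq(base, runif(1, 0, 0.15))
    # sprinkle indels
    if (runif(1) < 0.5) {
      at <- sample(nchar(mut) - 10, 1)
      mut <- paste0(substr(mut, 1, at), rand_dna(sample(1:4, 1)),
                    substr(mut, at + 1, nchar(mut)))
    }
    # random masks on both sequences, sometimes none
    mseq <- mut; bseq <- base
    if (runif(1) < 0.7) {
      a <- sample(nchar(mseq) - 20, 1)
      mseq <- mask_spans(mseq, a, a + sample(5:20, 1))
    }
    if (runif(1) < 0.7) {
      a <- sample(nchar(bseq) - 20, 1)
      bseq <- mask_spans(bseq, a, a + sample(5:20, 1))
    }
    pmask <- msatselect:::.mask_of(mseq)
    smask <- msatselect:::.mask_of(bseq)
    got <- msatselect:::.align_pairs_oriented(
      toupper(mseq), toupper(bseq), list(pmask), list(smask), scoring)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(toupper(mseq)),
      Biostrings::DNAString(toupper(bseq)), type = "local",
      substitutionMatrix = scoring$mat, gapOpening = scoring$gap_open,
      gapExtension = scoring$gap_ext)
    ref <- msatselect:::.alignment_identity(
      as.character(Biostrings::alignedPattern(pa)),
      as.character(Biostrings::alignedSubject(pa)),
      IRanges::start(Biostrings::pattern(pa)),
      IRanges::start(Biostrings::subject(pa)), pmask, smask)
    expect_equal(got$aln_len, unname(ref["cols"]))
    expect_equal(got$identity,
                 100 * unname(ref["matches"]) / max(1, unname(ref["cols"])))
  }
})

test_that("alignment scores match an independent Smith-Waterman", {
  withr::local_seed(9)
  scoring <- msatselect:::.align_scoring()
  for (k in 1:12) {
    a <- rand_dna(sample(40:120, 1))
    b <- if (runif(1) < 0.5) mutate_seq(a, 0.1) else rand_dna(sample(40:120, 1))
    got <- msatselect:::.align_pairs_oriented(a, b,
                                              list(rep(FALSE, nchar(a))),
                                              list(rep(FALSE, nchar(b))),
                                              scoring)
    expect_equal(got$score, oracle_sw(a, b))
  }
})

test_that("identical sequences align at identity 100 and unrelated do not", {
  withr::local_seed(10)
  s <- rand_dna(300)
  h <- all_vs_all(c(a = s, b = s), min_aln_len = 50)
  ab <- h[h$query_id == "a" & h$subject_id == "b", ]
  expect_equal(ab$identity, 100)
  expect_equal(ab$aln_len, 300L)
  # empirical null: random pairs essentially never reach the 80% floor
  hits <- 0L
  for (k in 1:200) {
    x <- rand_dna(300); y <- rand_dna(300)
    hh <- all_vs_all(c(q = x, s = y), min_identity_report = 80,
                     min_aln_len = 50)
    hits <- hits + sum(hh$query_id != hh$subject_id)
  }
  expect_lte(hits, 2L)
})

test_that("mismatches inside masked repeat spans do not reduce identity", {
  withr::local_seed(12)
  fl1 <- rand_dna(120); fl2 <- rand_dna(120)
  a <- paste0(fl1, strrep("ac", 10), fl2)   # masked lowercase
  b <- paste0(fl1, strrep("gt", 14), fl2)   # different masked repeat
  h <- all_vs_all(c(a = a, b = b), min_aln_len = 50)
  ab <- h[h$query_id == "a" & h$subject_id == "b", ]
  expect_equal(ab$identity, 100)
  expect_equal(ab$aln_len, 240L)
})

test_that("reverse-complement homologs are found and flagged", {
  withr::local_seed(14)
  s <- rand_dna(250)
  h <- all_vs_all(c(f = s, r = revcomp_chr(s)), min_aln_len = 50)
  fr <- h[h$query_id == "f" & h$subject_id == "r", ]
  expect_equal(fr$identity, 100)
  expect_equal(fr$orientation, "reverse")
})

test_that("the k-mer prefilter keeps every reportable pair", {
  withr::local_seed(15)
  seqs <- character(0)
  base <- rand_dna(300)
  seqs["t1a"] <- mutate_seq(base, 0.01)
  seqs["t1b"] <- mutate_seq(base, 0.01)
  seqs["h1"] <- mutate_seq(base, 0.15)
  seqs["rc"] <- revcomp_chr(mutate_seq(base, 0.02))
  for (k in 1:20) seqs[paste0("u", k)] <- rand_dna(300)
  full <- all_vs_all(seqs, min_aln_len = 50, prefilter = FALSE)
  fast <- all_vs_all(seqs, min_aln_len = 50, prefilter = TRUE)
  key <- function(h) sort(paste(h$query_id, h$subject_id, round(h$identity, 6)))
  expect_identical(key(fast), key(full))
})
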