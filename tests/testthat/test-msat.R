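test_that("textbook arrays are found with canonical motifs", {
  f <- find_perfect_repeats("ACACACACACAC")
  expect_equal(nrow(f), 1L)
  expect_equal(f$motif, "AC")
  expect_equal(f$units, 6L)
  expect_equal(c(f$start, f$end), c(0L, 12L))
  # four units stay below the five-unit reporting threshold
  expect_equal(nrow(find_perfect_repeats("ACACACAC")), 0L)
  # homopolymer runs are excluded by the primitivity rule
  expect_equal(nrow(find_perfect_repeats(strrep("G", 30))), 0L)
  # N interrupts an array
  expect_equal(nrow(find_perfect_repeats("ACACACACNACACACAC")), 0L)
})

test_that("canonicalisation is idempotent and strand-symmetric", {
  withr::local_seed(2)
  for (k in 1:200) {
    ml <- sample(2:6, 1)
    m <- rand_dna(ml)
    cm <- canonical_motif(m)
    expect_equal(canonical_motif(cm), cm)
    expect_equal(canonical_motif(revcomp_chr(m)), cm)
    # rotations canonicalise identically
    r <- sample(ml, 1)
    rot <- paste0(substr(m, r, ml), substr(m, 1, r - 1))
    expect_equal(canonical_motif(rot), cm)
  }
})

test_that("finder equals the substring-comparison oracle on random input", {
  withr::local_seed(3)
  for (k in 1:120) {
    n <- sample(30:400, 1)
    s <- rand_dna(n)
    # boost repeat density: splice in a random array half the time
    if (runif(1) < 0.5) {
      ml <- sample(2:6, 1)
      arr <- strrep(rand_dna(ml), sample(4:9, 1))
      at <- sample(n, 1)
      s <- paste0(substr(s, 1, at), arr, substr(s, at + 1, n))
    }
    got <- find_perfect_repeats(s)[, c("motif", "units", "start", "end")]
    rownames(got) <- NULL
    expect_equal(got, oracle_find_repeats(s), info = s)
  }
})

test_that("nested and adjacent motifs are reported per the perfect rule", {
  # (ACACAG)n contains AC runs of only 2 units: just the hexamer reported
  s <- strrep("ACACAG", 6)
  f <- find_perfect_repeats(s)
  expect_equal(nrow(f), 1L)
  expect_equal(f$units, 6L)
  expect_equal(nchar(f$motif_obs), 6L)
  # two arrays separated by one base stay distinct loci
  s2 <- paste0(strrep("AG", 6), "T", strrep("CT", 7))
  f2 <- find_perfect_repeats(s2)
  expect_equal(nrow(f2), 2L)
  expect_equal(f2$units, c(6L, 7L))
})

test_that("read classification respects the clip and marks targets", {
  withr::local_seed(5)
  arr <- strrep("AC", 8)
  rs <- make_reads(c(paste0(rand_dna(50), arr, rand_dna(50)),
                     rand_dna(80)))
  cl <- classify_reads(rs)
  expect_equal(cl$with_msat$id, "r1")
  expect_equal(cl$without$id, "r2")
  expect_true(all(cl$loci$target))
  # same read, but the clip excludes the repeat
  rs2 <- read_set("x", paste0(rand_dna(50), arr, rand_dna(50)),
                  list(rep(40L, 116)), clip = cbind(0L, 40L))
  cl2 <- classify_reads(rs2)
  expect_equal(length(cl2$with_msat), 0L)
  # empty input
  cl3 <- classify_reads(rs[integer(0)])
  expect_equal(length(cl3$with_msat), 0L)
  expect_equal(nrow(cl3$loci), 0L)
})

test_that("multi-locus reads target the array with the most units", {
  withr::local_seed(6)
  s <- paste0(rand_dna(40), strrep("AGT", 5), rand_dna(40),
              strrep("CT", 9), rand_dna(40))
  cl <- classify_reads(make_reads(s))
  tgt <- cl$loci[cl$loci$target, ]
  expect_equal(tgt$units, 9L)
  expect_equal(nrow(cl$loci), 2L)
})

test_that("soft-masking lowercases exactly the given spans", {
  expect_equal(mask_spans("ACGTACGT", 2, 5), "ACgtaCGT")
  expect_equal(mask_spans("ACGT", integer(0), integer(0)), "ACGT")
})
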