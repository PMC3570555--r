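test_that("identical reads group, unrelated reads stay singletons", {
  withr::local_seed(16)
  s <- rand_dna(300)
  seqs <- c(a = s, b = s, c = rand_dna(300))
  cls <- classify_redundancy(names(seqs), all_vs_all(seqs, min_aln_len = 50))
  v <- setNames(cls$verdicts$verdict, cls$verdicts$read_id)
  expect_equal(unname(v[c("a", "b")]), rep("contig_member", 2))
  expect_equal(unname(v["c"]), "singleton")
  expect_equal(cls$contigs$contig_0001, c("a", "b"))
})

test_that("partial homologs in the 80-95% band are eliminated", {
  withr::local_seed(17)
  base <- rand_dna(300)
  seqs <- c(a = base, b = mutate_seq(base, 0.10))
  h <- all_vs_all(seqs, min_aln_len = 50)
  ab <- h[h$query_id == "a" & h$subject_id == "b", ]
  expect_true(ab$identity >= 80 && ab$identity <= 95)
  cls <- classify_redundancy(names(seqs), h)
  expect_equal(sort(cls$verdicts$verdict), rep("eliminated", 2))
})

test_that("contig membership shields members from the elimination band", {
  withr::local_seed(18)
  base <- rand_dna(300)
  seqs <- c(a = base, b = mutate_seq(base, 0.01), c = mutate_seq(base, 0.10))
  cls <- classify_redundancy(names(seqs), all_vs_all(seqs, min_aln_len = 50))
  v <- setNames(cls$verdicts$verdict, cls$verdicts$read_id)
  expect_equal(unname(v[c("a", "b")]), rep("contig_member", 2))
  expect_equal(unname(v["c"]), "eliminated")
})

test_that("verdicts always partition the input", {
  withr::local_seed(19)
  for (k in 1:5) {
    n <- sample(5:15, 1)
    seqs <- setNames(replicate(n, rand_dna(200)), paste0("s", 1:n))
    if (n > 2) seqs[2] <- mutate_seq(seqs[1], 0.05)
    cls <- classify_redundancy(names(seqs),
                               all_vs_all(seqs, min_aln_len = 50))
    expect_setequal(cls$verdicts$read_id, names(seqs))
    expect_equal(nrow(cls$verdicts), n)
    in_contigs <- as.character(unlist(cls$contigs, use.names = FALSE))
    expect_equal(sort(in_contigs),
                 sort(cls$verdicts$read_id[cls$verdicts$verdict ==
                                           "contig_member"]))
  }
})

test_that("the 66% consensus rule resolves columns as specified", {
  # two of three members agree: 66.7% >= 66% -> base emitted
  expect_equal(consensus_from_alignment(c("A", "A", "G"))$consensus, "A")
  # one of two: 50% < 66% -> N
  expect_equal(consensus_from_alignment(c("A", "G"))$consensus, "N")
  # identical members reproduce the member
  expect_equal(consensus_from_alignment(rep("ACGT", 3))$consensus, "ACGT")
  # modal gap drops the column
  expect_equal(consensus_from_alignment(c("A-G", "A-G", "ACG"))$consensus,
               "AG")
})

test_that("consensus corrects isolated errors as depth grows", {
  withr::local_seed(20)
  tmpl <- rand_dna(300)
  for (depth in c(3, 5, 9)) {
    members <- vapply(seq_len(depth), function(i) mutate_seq(tmpl, 0.01), "")
    cons <- build_consensus(members)$consensus
    errs <- sum(strsplit(cons, "")[[1]] != strsplit(tmpl, "")[[1]])
    if (depth == 3) expect_lte(errs, 12) else expect_lte(errs, 3)
  }
  # and with depth 9 the consensus is essentially the template
  members <- vapply(1:9, function(i) mutate_seq(tmpl, 0.01), "")
  expect_equal(build_consensus(members)$consensus, tmpl)
})

test_that("reverse-complement members are flipped before alignment", {
  withr::local_seed(23)
  tmpl <- rand_dna(250)
  members <- c(tmpl, revcomp_chr(mutate_seq(tmpl, 0.005)), mutate_seq(tmpl, 0.005))
  cons <- build_consensus(members)$consensus
  mism <- sum(strsplit(cons, "")[[1]] != strsplit(tmpl, "")[[1]])
  expect_lte(mism, 3)
})

test_that("members without alignable overlap raise a hard error", {
  expect_error(build_consensus(c(strrep("A", 80), strrep("C", 80))),
               "overlap")
})
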