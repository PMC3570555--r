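test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_templates = 40, seed = 7)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_library(cfg, out_dir = d1)
  simulate_library(cfg, out_dir = d2)
  for (f in c("reads.fastq", "re_library.fasta", "truth_templates.tsv",
              "truth_reads.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
})

test_that("the no-noise limit reproduces templates exactly", {
  cfg <- sim_config(n_templates = 30, quality_start = 62, quality_end = 62,
                    quality_jitter = 0, homopolymer_indel_rate = 0,
                    mid_error_rate = 0, seed = 9)
  sim <- simulate_library(cfg)
  expect_true(all(sim$truth$reads$n_subs == 0))
  expect_true(all(sim$truth$reads$n_indels == 0))
  # every read is its template (or reverse complement) behind the MID
  tr <- sim$truth$reads
  tmpl_seq <- setNames(rep(NA_character_, nrow(sim$truth$templates)),
                       sim$truth$templates$template_id)
  for (i in seq_along(sim$reads$id)) {
    body <- substring(sim$reads$bases[i], 12)
    tid <- tr$template_id[i]
      if (tr$strand[i] == "-") body <- revcomp_chr(body)
    if (is.na(tmpl_seq[tid])) tmpl_seq[tid] <- body
    expect_identical(body, unname(tmpl_seq[tid]))
  }
})

test_that("planted repeats are recovered exactly on error-free reads", {
  cfg <- sim_config(n_templates = 200, quality_start = 62, quality_end = 62,
                    quality_jitter = 0, homopolymer_indel_rate = 0,
                    mid_error_rate = 0, seed = 10)
  sim <- simulate_library(cfg)
  tt <- sim$truth$templates
  tr <- sim$truth$reads
  dm <- demultiplex(sim$reads, sim$mids, 0L)
  cl <- classify_reads(dm$assigned)
  got_tmpl <- sort(unique(tr$template_id[match(cl$with_msat$id,
                                               tr$read_id)]))
  want_tmpl <- sort(tt$template_id[!is.na(tt$msat_motif)])
  # mined fraction equals the planted truth fraction exactly
  expect_identical(got_tmpl, want_tmpl)
  # recovered motifs and unit counts match the truth per template
  for (i in seq_len(nrow(cl$loci))) {
    if (!cl$loci$target[i]) next
    tid <- tr$template_id[match(cl$loci$host_id[i], tr$read_id)]
    row <- tt[tt$template_id == tid, ]
    expect_equal(cl$loci$motif[i], row$msat_motif)
    expect_equal(cl$loci$units[i], row$msat_units)
  }
  # sub-threshold decoys exist in the truth and are never reported
  expect_gt(sum(!is.na(tt$decoy_motif)), 0)
})

test_that("stated Phred scores are calibrated against observed errors", {
  cfg <- sim_config(n_templates = 150, quality_start = 20, quality_end = 20,
                    quality_jitter = 0, homopolymer_indel_rate = 0, seed = 12)
  sim <- simulate_library(cfg)
  cal <- calibration_report(sim)
  tot_obs <- sum(cal$table$observed)
  tot_exp <- sum(cal$table$expected)
  # Q20 flat curve: overall error rate 0.01 within binomial tolerance
  expect_lt(abs(tot_obs - tot_exp) / tot_exp, 0.1)
  # error-free run reports zero everywhere
  cfg0 <- sim_config(n_templates = 30, quality_start = 62, quality_end = 62,
                     quality_jitter = 0, homopolymer_indel_rate = 0,
                     mid_error_rate = 0, seed = 13)
  cal0 <- calibration_report(simulate_library(cfg0))
  expect_equal(sum(cal0$table$observed), 0)
  # a decaying curve yields a higher error rate late in the read
  cfg1 <- sim_config(n_templates = 200, seed = 14)
  cal1 <- calibration_report(simulate_library(cfg1))
  tab <- cal1$table[cal1$table$n_reads > 50, ]
  third <- nrow(tab) %/% 3
  early <- sum(tab$observed[1:third]) / sum(tab$n_reads[1:third])
  late <- sum(tab$observed[(2 * third):nrow(tab)]) /
    sum(tab$n_reads[(2 * third):nrow(tab)])
  expect_gt(late, early)
})

test_that("enriched libraries oversample repeat-bearing templates", {
  s1 <- simulate_library(sim_config(n_templates = 300, seed = 15))
  s2 <- simulate_library(sim_config(n_templates = 300, mode = "enriched",
                                    seed = 15))
  f1 <- mean(!is.na(s1$truth$templates$msat_motif))
  f2 <- mean(!is.na(s2$truth$templates$msat_motif))
  expect_gt(f2, f1 + 0.15)
})

test_that("contradictory configurations are rejected", {
  expect_error(sim_config(unit_range = c(2, 4)))
  expect_error(sim_config(msat_fraction = 1.4))
  expect_error(sim_config(template_len = c(50, 60)))
})
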