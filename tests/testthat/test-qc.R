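test_that("presets carry the published parameter values", {
  h <- qc_preset("high")
  expect_equal(h$bracket_window, 10L)
  expect_equal(h$bracket_max_err, 0.003)
  expect_equal(unname(h$windows[1, ]), c(10, 0.003))
  expect_equal(h$global_max_err, 0.003)
  expect_equal(h$tail_max_err, 0.02)
  l <- qc_preset("low")
  expect_equal(l$bracket_max_err, 0.02)
  expect_equal(unname(l$windows[1, ]), c(50, 0.08))
  expect_equal(l$global_max_err, 0.025)
  expect_equal(l$tail_max_err, 0.02)
  expect_error(qc_preset("medium"), "high, low")
})

test_that("uniform-quality reads behave at the extremes", {
  good <- make_reads(rand_dna(200), list(rep(40L, 200)))
  out <- trim_reads(good, qc_preset("high"))
  expect_equal(unname(out$pass$clip[1, ]), c(0L, 200L))  # whole read kept
  bad <- make_reads(rand_dna(200), list(rep(10L, 200)))
  out2 <- trim_reads(bad, qc_preset("high"))
  expect_equal(length(out2$pass), 0L)
})

test_that("a low-quality 3' tail is trimmed under the low preset", {
  withr::local_seed(1)
  rs <- make_reads(rand_dna(400), list(c(rep(40L, 300), rep(5L, 100))))
  out <- trim_reads(rs, qc_preset("low"))
  clip <- out$pass$clip[1, ]
  expect_equal(unname(clip), c(0L, 300L))
})

test_that("trimming equals the exhaustive subinterval oracle", {
  withr::local_seed(7)
  presets <- list(high = qc_preset("high", min_len = 20),
                  low = qc_preset("low", min_len = 20))
  for (rep_i in 1:60) {
    n <- sample(40:200, 1)
    q <- random_qual_profile(n)
    p <- phred_to_error(q)
    for (ps in presets) {
      got <- msatselect:::.trim_interval(p, ps)
      want <- oracle_trim(p, ps)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_equal(got, c(want[1] - 1L, want[2]),
                     info = paste("n =", n))
      }
    }
  }
})

test_that("retained regions obey the global cap and preset nesting", {
  withr::local_seed(11)
  high <- qc_preset("high"); low <- qc_preset("low")
  sim <- simulate_library(sim_config(n_templates = 60, seed = 31))
  ph <- trim_reads(sim$reads, high)
  pl <- trim_reads(sim$reads, low)
  profs <- error_profiles(sim$reads)
  names(profs) <- sim$reads$id
  for (i in seq_along(ph$pass$id)) {
    cl <- ph$pass$clip[i, ]
    reg <- profs[[ph$pass$id[i]]][(cl[1] + 1):cl[2]]
    expect_lte(mean(reg), high$global_max_err)
  }
  # high-stringency region nests inside the low-stringency region
  common <- intersect(ph$pass$id, pl$pass$id)
  ih <- match(common, ph$pass$id); il <- match(common, pl$pass$id)
  expect_true(all(ph$pass$clip[ih, 1] >= pl$pass$clip[il, 1]))
  expect_true(all(ph$pass$clip[ih, 2] <= pl$pass$clip[il, 2]))
})

test_that("relaxing every threshold never shortens the retained region", {
  withr::local_seed(13)
  for (k in 1:25) {
    n <- sample(60:200, 1)
    p <- phred_to_error(random_qual_profile(n))
    tight <- qc_params(10, 0.003, cbind(10, 0.003), 0.003, 0.02,
                       min_len = 20)
    loose <- qc_params(10, 0.03, cbind(10, 0.03), 0.03, 0.2, min_len = 20)
    a <- msatselect:::.trim_interval(p, tight)
    b <- msatselect:::.trim_interval(p, loose)
    la <- if (is.null(a)) 0L else a[2] - a[1]
    lb <- if (is.null(b)) 0L else b[2] - b[1]
    expect_gte(lb, la)
  }
})

test_that("reads containing N fail windows that span the N", {
  bases <- paste0(strrep("A", 60), "N", strrep("A", 60))
  rs <- make_reads(bases, list(rep(40L, 121)))
  out <- trim_reads(rs, qc_preset("high", min_len = 30))
  clip <- out$pass$clip[1, ]
  expect_true(clip[2] <= 60 || clip[1] >= 61)  # region avoids the N
})
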