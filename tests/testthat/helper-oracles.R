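# Independent oracles used across the suite. Each reimplements the
# operation it checks through a different mechanism than the package:
# substring comparison instead of integer shift-compare for repeats, full
# matrix enumeration instead of pruned search for trimming, an R
# Smith-Waterman for alignment, and Biopython's melting-temperature
# module for thermodynamics.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

mutate_seq <- function(s, rate) {
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(b)) < rate)
  for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
  paste(b, collapse = "")
}

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# ---- repeat-finder oracle: substring-comparison brute force ----

oracle_primitive <- function(m) {
  k <- nchar(m)
  for (d in seq_len(k - 1)) {
    if (k %% d != 0) next
    if (paste(rep(substr(m, 1, d), k / d), collapse = "") == m) return(FALSE)
  }
  TRUE
}

oracle_canonical <- function(m) {
  k <- nchar(m)
  rot <- function(s) vapply(0:(k - 1), function(r)
    paste0(substr(s, r + 1, k), substr(s, 1, r)), "")
  min(c(rot(m), rot(revcomp_chr(m))))
}

oracle_find_repeats <- function(s, min_units = 5) {
  s <- toupper(s)
  n <- nchar(s)
  out <- NULL
  for (ml in 2:6) {
    if (n < ml * min_units) next
    starts <- 1:(n - ml * min_units + 1)
    # all min_units leading units equal, vectorised over starts
    ok <- rep(TRUE, length(starts))
    u1 <- substring(s, starts, starts + ml - 1)
    ok <- ok & !grepl("N", u1, fixed = TRUE)
    for (k in 1:(min_units - 1)) {
      uk <- substring(s, starts + k * ml, starts + (k + 1) * ml - 1)
      ok <- ok & u1 == uk
    }
    # left-maximality: preceding base must not extend the array in phase
    prev_ok <- starts == 1 |
      substring(s, starts - 1, starts - 1) !=
      substring(s, starts + ml - 1, starts + ml - 1)
    ok <- ok & prev_ok
    for (i in starts[ok]) {
      if (!oracle_primitive(u1[i - starts[1] + 1])) next
      # extend base by base to the maximal perfect extent
      e <- i + min_units * ml - 1
      while (e < n && substr(s, e + 1, e + 1) == substr(s, e + 1 - ml,
                                                        e + 1 - ml) &&
             substr(s, e + 1, e + 1) != "N")
        e <- e + 1
      total <- e - i + 1
      units <- total %/% ml
      out <- rbind(out, data.frame(
        motif = oracle_canonical(substr(s, i, i + ml - 1)),
        units = units, start = i - 1, end = i - 1 + units * ml,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    return(data.frame(motif = character(), units = integer(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  out <- out[order(out$start, out$end, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- quality-trimming oracle: full matrix enumeration ----

oracle_rollmean <- function(x, w) {
  if (length(x) < w) return(numeric(0))
  cs <- c(0, cumsum(x))
  (cs[(w + 1):(length(x) + 1)] - cs[1:(length(x) - w + 1)]) / w
}

oracle_trim <- function(p, params) {
  n <- length(p)
  if (!n) return(NULL)
  # step 1: bracket trimming (definitional)
  s <- 1; e <- n
  repeat {
    len <- e - s + 1
    if (len < 1) break
    w <- min(params$bracket_window, len)
    if (mean(p[s:(s + w - 1)]) > params$bracket_max_err) { s <- s + 1; next }
    if (mean(p[(e - w + 1):e]) > params$bracket_max_err) { e <- e - 1; next }
    break
  }
  if (s > e) return(NULL)
  q <- p[s:e]
  m <- length(q)
  cp <- c(0, cumsum(q))
  I <- row(matrix(0, m, m)); J <- col(matrix(0, m, m))
  L <- J - I + 1
  upper <- J >= I
  meanM <- matrix((cp[pmax(J, 1) + 1] - cp[pmax(I, 1)]), m, m) / L
  ok <- upper & meanM <= params$global_max_err
  bw <- params$bracket_window
  hw <- pmin(bw, L)
  headM <- matrix(cp[pmin(I + bw - 1, J) + 1] - cp[I], m, m) / hw
  tailM <- matrix(cp[J + 1] - cp[pmax(J - bw + 1, I)], m, m) / hw
  ok <- ok & headM <= params$tail_max_err & tailM <= params$tail_max_err
  for (k in seq_len(nrow(params$windows))) {
    w <- params$windows[k, 1]; t <- params$windows[k, 2]
    rm <- oracle_rollmean(q, w)
    bad0 <- c(0, cumsum(rm > t))
    long <- L >= w
    cnt <- matrix(bad0[pmax(pmin(J - w + 1, length(rm)), 0) + 1], m, m) -
           matrix(bad0[pmin(pmax(I - 1, 0), length(rm)) + 1], m, m)
    okk <- ifelse(long, cnt == 0, meanM <= t)
    ok <- ok & okk
  }
  if (!any(ok)) return(NULL)
  Lok <- ifelse(ok, L, -1)
  best_len <- max(Lok)
  if (best_len < params$min_len) return(NULL)
  cand <- which(Lok == best_len, arr.ind = TRUE)
  means <- meanM[cand]
  cand <- cand[order(means, cand[, 1]), , drop = FALSE]
  as.integer(c(s + cand[1, 1] - 1, s + cand[1, 2] - 1))  # 1-based inclusive
}

# random Phred profile with 3' decay, jitter and occasional bad patches
random_qual_profile <- function(n) {
  q0 <- sample(15:40, 1)
  q1 <- sample(2:30, 1)
  q <- q0 + (q1 - q0) * (seq_len(n) - 1) / max(1, n - 1) +
    rnorm(n, 0, 3)
  if (runif(1) < 0.3) {  # a random low-quality patch
    at <- sample(n, 1); w <- sample(3:15, 1)
    idx <- at:min(n, at + w)
    q[idx] <- q[idx] - sample(10:25, 1)
  }
  pmin(40L, pmax(2L, as.integer(round(q))))
}

# ---- Smith-Waterman oracle (match +1, mismatch -2, gap open 5, ext 2) ----

oracle_sw <- function(a, b, match = 1, mismatch = -2, gap_open = 5,
                      gap_ext = 2) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)  # best ending in match/mismatch or free
  E <- matrix(-Inf, n + 1, m + 1)  # gap in B (A consumed)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in A
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i - 1, j] - gap_open - gap_ext,
                     E[i - 1, j] - gap_ext)
      F[i, j] <- max(H[i, j - 1] - gap_open - gap_ext,
                     F[i, j - 1] - gap_ext)
      sub <- H[i - 1, j - 1] + if (A[i - 1] == B[j - 1]) match else mismatch
      H[i, j] <- max(0, sub, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# ---- Biopython melting-temperature oracle ----

biopython_tm <- function(oligos) {
  inf <- tempfile(); outf <- tempfile()
  writeLines(oligos, inf)
  script <- sprintf("
from Bio.SeqUtils import MeltingTemp as mt
with open('%s') as fh:
    seqs = [l.strip() for l in fh if l.strip()]
with open('%s', 'w') as out:
    for s in seqs:
        out.write('%%.6f\\n' %% mt.Tm_NN(s, nn_table=mt.DNA_NN3, Na=50,
                                         dnac1=25, dnac2=25, saltcorr=5))
", inf, outf)
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", sf, stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("python/Biopython oracle unavailable")
  as.numeric(readLines(outf))
}

# small read_set builder for tests
make_reads <- function(bases, quals = NULL, ids = NULL) {
  if (is.null(ids)) ids <- paste0("r", seq_along(bases))
  if (is.null(quals)) quals <- lapply(nchar(bases), function(n) rep(40L, n))
  read_set(ids, bases, quals)
}
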