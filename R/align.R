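# Pairwise local alignment on top of Biostrings, with identity computed
# over alignment columns and lowercase (soft-masked) positions excluded.
# Scoring follows a BLASTN-like scheme: match +1, mismatch -2, gap open 5,
# gap extend 2 (penalties positive as in Biostrings).
#
# Identity is computed without extracting aligned strings (which is by far
# the most expensive Biostrings accessor): the alignment path is
# reconstructed from the aligned ranges plus the insertion/deletion range
# lists, and mismatch columns come from mismatchTable(). A string-walking
# reference implementation (.alignment_identity) is kept for
# cross-checking in the test suite.

.align_scoring <- function(match = 1, mismatch = -2, gap_open = 5,
                           gap_ext = 2) {
  list(mat = Biostrings::nucleotideSubstitutionMatrix(
         match = match, mismatch = mismatch, baseOnly = FALSE),
       gap_open = gap_open, gap_ext = gap_ext)
}

# mask vector (logical per position) from a possibly lowercase string
.mask_of <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  chars %in% c("a", "c", "g", "t", "n")
}

.n_of <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  chars == "N"
}

# Reference implementation: walk one pairwise alignment given as gapped
# strings and compute identity over unmasked columns. Used by tests to
# validate the range-based path.
.alignment_identity <- function(ap, as_, pstart, sstart, pmask, smask) {
  pc <- strsplit(ap, "", fixed = TRUE)[[1]]
  sc <- strsplit(as_, "", fixed = TRUE)[[1]]
  pgap <- pc == "-"
  sgap <- sc == "-"
  ppos <- cumsum(!pgap) + pstart - 1L
  spos <- cumsum(!sgap) + sstart - 1L
  masked <- (!pgap & pmask[ppos]) | (!sgap & smask[spos])
  cols <- sum(!masked)
  matches <- sum(!masked & !pgap & !sgap & pc == sc &
                 pc %in% c("A", "C", "G", "T"))
  c(cols = cols, matches = matches)
}

# Alignment-column statistics from ranges only. ins/del are IRanges of
# gap runs relative to the aligned pattern/subject start; mm_p/mm_s are
# absolute mismatch positions.
.masked_aln_stats <- function(ps, pe, ss, se, ins, del, mm_p, mm_s,
                              pmask, smask, pN, sN) {
  ins_s <- ps - 1L + IRanges::start(ins); ins_w <- IRanges::width(ins)
  del_s <- ss - 1L + IRanges::start(del); del_w <- IRanges::width(del)
  pp <- ps; sp <- ss
  ii <- 1L; di <- 1L
  unmasked_diag <- 0L; unmasked_gap <- 0L; nn <- 0L
  check_nn <- any(pN) && any(sN)
  while (pp <= pe || sp <= se) {
    nxt_i <- if (ii <= length(ins_s)) ins_s[ii] else .Machine$integer.max
    nxt_d <- if (di <= length(del_s)) del_s[di] else .Machine$integer.max
    d <- min(nxt_i - pp, nxt_d - sp, pe - pp + 1L)
    if (d > 0L) {
      idx_p <- pp:(pp + d - 1L); idx_s <- sp:(sp + d - 1L)
      um <- !(pmask[idx_p] | smask[idx_s])
      unmasked_diag <- unmasked_diag + sum(um)
      if (check_nn) nn <- nn + sum(um & pN[idx_p] & sN[idx_s])
      pp <- pp + d; sp <- sp + d
    }
    if (ii <= length(ins_s) && ins_s[ii] == pp) {
      w <- ins_w[ii]
      unmasked_gap <- unmasked_gap + sum(!pmask[pp:(pp + w - 1L)])
      pp <- pp + w; ii <- ii + 1L
    } else if (di <= length(del_s) && del_s[di] == sp) {
      w <- del_w[di]
      unmasked_gap <- unmasked_gap + sum(!smask[sp:(sp + w - 1L)])
      sp <- sp + w; di <- di + 1L
    } else if (d <= 0L) break
  }
  um_mm <- if (length(mm_p)) sum(!(pmask[mm_p] | smask[mm_s])) else 0L
  cols <- unmasked_diag + unmasked_gap
  matches <- unmasked_diag - um_mm - nn
  c(cols = cols, matches = matches)
}

# Align a set of pattern sequences against one subject in the given
# orientation; returns a data.frame of per-pattern hit descriptions.
# patterns/subject are uppercase character; masks are logical lists/vector.
.align_batch <- function(patterns, subject, pmasks, smask, scoring,
                         type = "local") {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(patterns), Biostrings::DNAString(subject),
    type = type, substitutionMatrix = scoring$mat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext)
  ps <- IRanges::start(Biostrings::pattern(pa))
  pe <- IRanges::end(Biostrings::pattern(pa))
  ss <- IRanges::start(Biostrings::subject(pa))
  se <- IRanges::end(Biostrings::subject(pa))
  n <- length(patterns)
  s_has_mask <- any(smask)
  p_has_mask <- vapply(pmasks, any, TRUE)
  s_has_n <- grepl("N", subject, fixed = TRUE)
  p_has_n <- grepl("N", patterns, fixed = TRUE)
  plain <- !s_has_mask & !p_has_mask & !(s_has_n & p_has_n)
  cols <- integer(n); identity <- numeric(n)
  ins <- Biostrings::insertion(pa)
  del <- Biostrings::deletion(pa)
  gapcols <- sum(IRanges::width(ins)) + sum(IRanges::width(del))
  if (any(plain)) {
    nm <- Biostrings::nmatch(pa)
    ncols <- nm + Biostrings::nmismatch(pa) + gapcols
    cols[plain] <- ncols[plain]
    identity[plain] <- 100 * nm[plain] / pmax(1L, ncols[plain])
  }
  if (any(!plain)) {
    mt <- Biostrings::mismatchTable(pa)
    sN <- .n_of(subject)
    for (i in which(!plain)) {
      mm <- mt[mt$PatternId == i, , drop = FALSE]
      st <- .masked_aln_stats(ps[i], pe[i], ss[i], se[i], ins[[i]], del[[i]],
                              mm$PatternStart, mm$SubjectStart,
                              pmasks[[i]], smask,
                              if (p_has_n[i]) .n_of(patterns[i]) else
                                rep(FALSE, nchar(patterns[i])), sN)
      cols[i] <- st["cols"]
      identity[i] <- if (st["cols"] > 0) 100 * st["matches"] / st["cols"]
                     else 0
    }
  }
  data.frame(q_start = ps - 1L, q_end = pe,
             s_start = ss - 1L, s_end = se,
             score = Biostrings::score(pa),
             aln_len = cols,
             identity = identity)
}

# Elementwise alignment of sequence pairs (pattern[i] vs subject[i]) in
# one vectorised call; returns per-pair hit stats with masked identity.
.align_pairs_oriented <- function(pats, subs, pmasks, smasks, scoring,
                                  type = "local", min_score = NULL) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(pats), Biostrings::DNAStringSet(subs),
    type = type, substitutionMatrix = scoring$mat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext)
  ps <- IRanges::start(Biostrings::pattern(pa))
  pe <- IRanges::end(Biostrings::pattern(pa))
  ss <- IRanges::start(Biostrings::subject(pa))
  se <- IRanges::end(Biostrings::subject(pa))
  n <- length(pats)
  ins <- Biostrings::insertion(pa)
  del <- Biostrings::deletion(pa)
  p_has_mask <- vapply(pmasks, any, TRUE)
  s_has_mask <- vapply(smasks, any, TRUE)
  p_has_n <- grepl("N", pats, fixed = TRUE)
  s_has_n <- grepl("N", subs, fixed = TRUE)
  plain <- !p_has_mask & !s_has_mask & !(p_has_n & s_has_n)
  cols <- integer(n); identity <- numeric(n)
  # a qualifying hit (>= 80% identity over >= min_aln_len unmasked
  # columns) implies an alignment segment scoring well above this floor,
  # and every segment of an optimal local alignment scores at most the
  # total, so low-scoring alignments cannot hide a reportable hit
  sc <- Biostrings::score(pa)
  skip <- if (is.null(min_score)) rep(FALSE, n) else sc < min_score
  if (any(plain & !skip)) {
    nm <- Biostrings::nmatch(pa)
    ncols <- nm + Biostrings::nmismatch(pa) +
      sum(IRanges::width(ins)) + sum(IRanges::width(del))
    pl <- plain & !skip
    cols[pl] <- ncols[pl]
    identity[pl] <- 100 * nm[pl] / pmax(1L, ncols[pl])
  }
  if (any(!plain & !skip)) {
    mt <- Biostrings::mismatchTable(pa)
    for (i in which(!plain & !skip)) {
      mm <- mt[mt$PatternId == i, , drop = FALSE]
      st <- .masked_aln_stats(ps[i], pe[i], ss[i], se[i], ins[[i]], del[[i]],
                              mm$PatternStart, mm$SubjectStart,
                              pmasks[[i]], smasks[[i]],
                              if (p_has_n[i]) .n_of(pats[i]) else
                                rep(FALSE, nchar(pats[i])),
                              if (s_has_n[i]) .n_of(subs[i]) else
                                rep(FALSE, nchar(subs[i])))
      cols[i] <- st["cols"]
      identity[i] <- if (st["cols"] > 0) 100 * st["matches"] / st["cols"]
                     else 0
    }
  }
  data.frame(q_start = ps - 1L, q_end = pe, s_start = ss - 1L, s_end = se,
             score = sc, aln_len = cols,
             identity = identity)
}

# Best-orientation elementwise pair alignment.
.align_pairs <- function(pats, subs, pmasks, smasks,
                         scoring = .align_scoring(), min_score = NULL) {
  fwd <- .align_pairs_oriented(pats, subs, pmasks, smasks, scoring,
                               min_score = min_score)
  fwd$orientation <- "forward"
  rcsubs <- .revcomp(subs)
  rev_ <- .align_pairs_oriented(pats, rcsubs, pmasks, lapply(smasks, rev),
                                scoring, min_score = min_score)
  L <- nchar(subs)
  tmp <- rev_$s_start
  rev_$s_start <- L - rev_$s_end
  rev_$s_end <- L - tmp
  rev_$orientation <- "reverse"
  take_rev <- rev_$score > fwd$score
  out <- fwd
  out[take_rev, ] <- rev_[take_rev, ]
  out
}

# Best-orientation local alignment of pattern batches against a subject.
# Reverse-complement hits are mapped back to forward subject coordinates.
.align_batch_best <- function(patterns, subject, pmasks, smask, scoring) {
  fwd <- .align_batch(patterns, subject, pmasks, smask, scoring)
  fwd$orientation <- "forward"
  rcsub <- .revcomp(subject)
  rev_ <- .align_batch(patterns, rcsub, pmasks, rev(smask), scoring)
  L <- nchar(subject)
  tmp <- rev_$s_start
  rev_$s_start <- L - rev_$s_end
  rev_$s_end <- L - tmp
  rev_$orientation <- "reverse"
  take_rev <- rev_$score > fwd$score
  out <- fwd
  out[take_rev, ] <- rev_[take_rev, ]
  out
}

# Shared-k-mer candidate pair prefilter. Returns a 2-column matrix of
# sequence index pairs (i < j) sharing at least one unmasked k-mer in
# either orientation.
.kmer_pairs <- function(seqs, k = 16L) {
  grab <- function(s) {
    # k-mers from unmasked (uppercase) stretches only: repeat-derived
    # k-mers would link unrelated reads that merely share a motif
    segs <- regmatches(s, gregexpr("[ACGTN]+", s))[[1]]
    segs <- segs[nchar(segs) >= k]
    if (!length(segs)) return(character(0))
    kk <- unique(unlist(lapply(segs, function(g)
      substring(g, seq_len(nchar(g) - k + 1L),
                seq_len(nchar(g) - k + 1L) + k - 1L))))
    # drop periodic k-mers (period <= 6): error-truncated repeat remnants
    # below the masking threshold would otherwise pair unrelated reads
    per <- rep(FALSE, length(kk))
    for (p in 1:6)
      per <- per | substring(kk, 1L, k - p) == substring(kk, p + 1L, k)
    kk[!per]
  }
  n <- length(seqs)
  km <- lapply(seqs, grab)
  # k-mers of each sequence's reverse complement, so opposite-strand
  # homologs are caught without per-k-mer reverse complementation
  kmrc <- lapply(seqs, function(s) grab(.revcomp(toupper(s))))
  idx <- c(rep(seq_len(n), lengths(km)), rep(seq_len(n), lengths(kmrc)))
  keys <- c(unlist(km), unlist(kmrc))
  tab <- split(idx, keys)
  tab <- tab[lengths(tab) > 1L]
  if (!length(tab)) return(matrix(integer(0), ncol = 2L))
  prs <- lapply(tab, function(v) {
    u <- unique(v)
    if (length(u) < 2L) return(NULL)
    utils::combn(u, 2L)
  })
  prs <- prs[!vapply(prs, is.null, TRUE)]
  if (!length(prs)) return(matrix(integer(0), ncol = 2L))
  m <- do.call(cbind, prs)
  a <- pmin(m[1L, ], m[2L, ]); b <- pmax(m[1L, ], m[2L, ])
  keep <- !duplicated(a * (n + 1) + b)
  out <- cbind(a[keep], b[keep])
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}
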