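# SantaLucia (1998) unified nearest-neighbor parameters.
# Enthalpy in kcal/mol, entropy in cal/(mol K), 1 M NaCl reference.
.NN_H <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_S <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
.INIT_H <- c(G = 0.1, C = 0.1, A = 2.3, T = 2.3)
.INIT_S <- c(G = -2.8, C = -2.8, A = 4.1, T = 4.1)
.GAS_R <- 1.98717  # cal/(mol K)

.tm_from_HS <- function(dH, dS, n_pairs, na_molar, ct_molar) {
  dS <- dS + 0.368 * n_pairs * log(na_molar)
  1000 * dH / (dS + .GAS_R * log(ct_molar / 4)) - 273.15
}

#' Nearest-neighbor melting temperature of a primer
#'
#' Duplex melting temperature from the SantaLucia (1998) unified
#' nearest-neighbor model with the entropy-based salt correction
#' (`dS + 0.368 (N-1) ln[Na+]`) and the `CT/4` concentration term for
#' non-self-complementary duplexes. Defaults (50 mM monovalent salt, 50 nM
#' total oligo) reproduce the conventional primer Tm scale on which the
#' 57-63 degree design window is expressed.
#'
#' @param oligo DNA string, 10-36 bases, no `N`.
#' @param na_molar monovalent cation concentration (mol/L, default 0.05).
#' @param ct_molar total oligo concentration (mol/L, default 5e-8).
#' @return melting temperature in degrees Celsius.
#' @examples
#' melting_temp("AGCTTGCATGCCTGCAGGTC")
#' @export
melting_temp <- function(oligo, na_molar = 0.05, ct_molar = 5e-8) {
  oligo <- toupper(oligo)
  n <- nchar(oligo)
  if (n < 10L || n > 36L)
    stop("oligo length must be in [10, 36]", call. = FALSE)
  b <- strsplit(oligo, "", fixed = TRUE)[[1]]
  if (any(!b %in% c("A", "C", "G", "T")))
    stop("oligo contains non-ACGT characters", call. = FALSE)
  pairs <- paste0(b[-n], b[-1L])
  dH <- sum(.NN_H[pairs]) + .INIT_H[b[1L]] + .INIT_H[b[n]]
  dS <- sum(.NN_S[pairs]) + .INIT_S[b[1L]] + .INIT_S[b[n]]
  unname(.tm_from_HS(dH, dS, n - 1L, na_molar, ct_molar))
}

#' GC content of an oligo
#'
#' @param oligo DNA string (nonempty).
#' @return percent G+C in `[0, 100]`.
#' @examples
#' gc_content("ATGC")
#' @export
gc_content <- function(oligo) {
  vapply(toupper(oligo), function(s) {
    n <- nchar(s)
    if (!n) stop("empty oligo", call. = FALSE)
    100 * (nchar(gsub("[^GC]", "", s))) / n
  }, 1, USE.NAMES = FALSE)
}

#' Primer-design constraint set
#'
#' The default values are the microsatellite-marker design block: PCR
#' product 90-300 bp spanning the full repeat array, primer length
#' 18/20/27 (min/opt/max), Tm 57/60/63 with at most 1 degree difference
#' between the two primers, GC 20/50/80 with no GC clamp requirement, and
#' mononucleotide runs capped at 4 to avoid homopolymer miscalls at
#' priming sites.
#'
#' @param product_len length-2 numeric, admissible product size (bp).
#' @param primer_len length-3 numeric `(min, opt, max)`.
#' @param tm_celsius length-3 numeric `(min, opt, max)`.
#' @param max_tm_diff maximum |Tm(left) - Tm(right)|.
#' @param gc_percent length-3 numeric `(min, opt, max)`.
#' @param gc_clamp required 3' G/C bases (default 0: none).
#' @param max_polyx maximum mononucleotide run inside a primer.
#' @return object of class `primer_constraints`.
#' @export
primer_constraints <- function(product_len = c(90, 300),
                               primer_len = c(18, 20, 27),
                               tm_celsius = c(57, 60, 63),
                               max_tm_diff = 1.0,
                               gc_percent = c(20, 50, 80),
                               gc_clamp = 0L,
                               max_polyx = 4L) {
  stopifnot(product_len[1] <= product_len[2],
            primer_len[1] <= primer_len[2], primer_len[2] <= primer_len[3],
            tm_celsius[1] <= tm_celsius[2], tm_celsius[2] <= tm_celsius[3],
            gc_percent[1] <= gc_percent[2], gc_percent[2] <= gc_percent[3])
  structure(list(product_len = product_len, primer_len = primer_len,
                 tm_celsius = tm_celsius, max_tm_diff = max_tm_diff,
                 gc_percent = gc_percent, gc_clamp = as.integer(gc_clamp),
                 max_polyx = as.integer(max_polyx)),
            class = "primer_constraints")
}

# Precompute prefix arrays for O(1) evaluation of any substring:
# nearest-neighbor dH/dS sums, GC counts, N positions, and ends of
# mononucleotide runs exceeding the poly-X cap.
.template_index <- function(template, max_polyx) {
  b <- strsplit(toupper(template), "", fixed = TRUE)[[1]]
  n <- length(b)
  acgt <- b %in% c("A", "C", "G", "T")
  pairs <- if (n > 1L) paste0(b[-n], b[-1L]) else character(0)
  okpair <- acgt[-n] & acgt[-1L]
  ph <- cumsum(ifelse(okpair, .NN_H[pairs], 0))
  ps <- cumsum(ifelse(okpair, .NN_S[pairs], 0))
  gcc <- cumsum(b %in% c("G", "C"))
  ncnt <- cumsum(!acgt)
  run <- integer(n)
  run[1] <- 1L
  if (n > 1L) for (i in 2:n) run[i] <- if (b[i] == b[i - 1L]) run[i - 1L] + 1L else 1L
  badrun <- cumsum(run >= max_polyx + 1L)  # run of length > max_polyx ends here
  list(b = b, n = n, ph = c(0, ph), ps = c(0, ps), gcc = c(0, gcc),
       ncnt = c(0, ncnt), badrun = c(0, badrun), max_polyx = max_polyx)
}

# vectorised per-candidate stats; i, j are 1-based inclusive substring bounds
.candidate_stats <- function(ix, i, j, na_molar = 0.05, ct_molar = 5e-8) {
  len <- j - i + 1L
  has_n <- (ix$ncnt[j + 1L] - ix$ncnt[i]) > 0L
  gc <- 100 * (ix$gcc[j + 1L] - ix$gcc[i]) / len
  dH <- ix$ph[j] - ix$ph[i] + .INIT_H[ix$b[i]] + .INIT_H[ix$b[j]]
  dS <- ix$ps[j] - ix$ps[i] + .INIT_S[ix$b[i]] + .INIT_S[ix$b[j]]
  tm <- .tm_from_HS(dH, dS, len - 1L, na_molar, ct_molar)
  # a run longer than max_polyx fully inside [i, j] has an end position k
  # with run[k] > max_polyx and k - i + 1 > max_polyx (k >= i + max_polyx)
  lo <- pmin(i + ix$max_polyx, j + 1L)
  polyx_bad <- (ix$badrun[j + 1L] - ix$badrun[lo]) > 0L
  data.frame(len = len, has_n = has_n, gc = gc, tm = unname(tm),
             polyx_bad = polyx_bad)
}

#' Design primer pairs bracketing a microsatellite locus
#'
#' Enumerates every admissible left/right primer placement around the
#' repeat array (the product must contain the entire array), filters on
#' the constraint set (length, Tm window, GC window, poly-X cap, no `N`
#' inside a primer, Tm difference), and ranks the surviving pairs by a
#' penalty summing each primer's weighted deviations from the optimum:
#' 1/bp for length, 1/degree for Tm, 0.01/% for GC. Ties are broken by
#' leftmost left primer, then shortest product, so the ranking is total
#' and deterministic.
#'
#' @param template candidate sequence (singleton read or contig
#'   consensus); lowercase masking tolerated.
#' @param locus_start,locus_end 0-based half-open span of the repeat
#'   array within `template`.
#' @param constraints a [primer_constraints()] object.
#' @param top_k maximum number of pairs to return (default 3).
#' @return `data.frame` (possibly empty) with `rank`, `left_seq`,
#'   `left_start`, `left_len`, `left_tm`, `left_gc`, `right_seq`,
#'   `right_start`, `right_len`, `right_tm`, `right_gc`, `product_len`,
#'   `penalty`. `right_seq` is given 5'->3' on the reverse strand;
#'   `right_start` is the 0-based start of its binding site on the
#'   template.
#' @export
design_pairs <- function(template, locus_start, locus_end,
                         constraints = primer_constraints(), top_k = 3L) {
  empty <- data.frame(rank = integer(), left_seq = character(),
                      left_start = integer(), left_len = integer(),
                      left_tm = numeric(), left_gc = numeric(),
                      right_seq = character(), right_start = integer(),
                      right_len = integer(), right_tm = numeric(),
                      right_gc = numeric(), product_len = integer(),
                      penalty = numeric(), stringsAsFactors = FALSE)
  cn <- constraints
  L <- nchar(template)
  stopifnot(locus_start >= 0, locus_end <= L, locus_start < locus_end)
  lmin <- cn$primer_len[1]; lmax <- cn$primer_len[3]
  if (locus_start < lmin || L - locus_end < lmin) return(empty)
  ix <- .template_index(template, cn$max_polyx)

  enumerate <- function(starts, lens) {
    g <- expand.grid(start = starts, len = lens)
    g$end <- g$start + g$len - 1L
    g
  }
  # left primers: [ls, le] 1-based inclusive with le <= locus_start
  ls_min <- max(1L, locus_end + 1L + lmin - cn$product_len[2])
  lefts <- enumerate(ls_min:max(ls_min, locus_start - lmin + 1L),
                     lmin:lmax)
  lefts <- lefts[lefts$end <= locus_start, , drop = FALSE]
  # right binding sites: [rs, re] with rs >= locus_end + 1
  re_max <- min(L, locus_start + cn$product_len[2])
  rights <- enumerate((locus_end + 1L):max(locus_end + 1L, L - lmin + 1L),
                      lmin:lmax)
  rights <- rights[rights$end <= re_max & rights$end <= L, , drop = FALSE]
  if (!nrow(lefts) || !nrow(rights)) return(empty)

  gc_run <- function(pos3, dir) {  # gc_clamp G/C bases walking inward
    if (cn$gc_clamp == 0L) return(TRUE)
    vapply(pos3, function(p) {
      span <- p + dir * (seq_len(cn$gc_clamp) - 1L)
      all(ix$b[span] %in% c("G", "C"))
    }, TRUE)
  }
  filt <- function(g, side) {
    st <- .candidate_stats(ix, g$start, g$end)
    ok <- !st$has_n & !st$polyx_bad &
          st$tm >= cn$tm_celsius[1] & st$tm <= cn$tm_celsius[3] &
          st$gc >= cn$gc_percent[1] & st$gc <= cn$gc_percent[3]
    if (cn$gc_clamp > 0L)
      ok <- ok & (if (side == "left") gc_run(g$end, -1L)
                  else gc_run(g$start, +1L))
    cbind(g, st)[ok, , drop = FALSE]
  }
  lf <- filt(lefts, "left")
  rf <- filt(rights, "right")
  if (!nrow(lf) || !nrow(rf)) return(empty)
  lf$penalty <- abs(lf$len - cn$primer_len[2]) +
    abs(lf$tm - cn$tm_celsius[2]) + 0.01 * abs(lf$gc - cn$gc_percent[2])
  rf$penalty <- abs(rf$len - cn$primer_len[2]) +
    abs(rf$tm - cn$tm_celsius[2]) + 0.01 * abs(rf$gc - cn$gc_percent[2])

  nlf <- nrow(lf); nrf <- nrow(rf)
  li <- rep.int(seq_len(nlf), nrf)
  ri <- rep(seq_len(nrf), each = nlf)
  prod <- rf$end[ri] - lf$start[li] + 1L
  ok <- prod >= cn$product_len[1] & prod <= cn$product_len[2] &
        abs(lf$tm[li] - rf$tm[ri]) <= cn$max_tm_diff
  if (!any(ok)) return(empty)
  allp <- data.frame(li = li[ok], ri = ri[ok], product_len = prod[ok],
                     penalty = lf$penalty[li[ok]] + rf$penalty[ri[ok]])
  ord <- order(allp$penalty, lf$start[allp$li], allp$product_len)
  allp <- allp[ord[seq_len(min(top_k, nrow(allp)))], , drop = FALSE]
  up <- toupper(template)
  data.frame(
    rank = seq_len(nrow(allp)),
    left_seq = substring(up, lf$start[allp$li], lf$end[allp$li]),
    left_start = lf$start[allp$li] - 1L,
    left_len = lf$len[allp$li],
    left_tm = lf$tm[allp$li],
    left_gc = lf$gc[allp$li],
    right_seq = .revcomp(substring(up, rf$start[allp$ri], rf$end[allp$ri])),
    right_start = rf$start[allp$ri] - 1L,
    right_len = rf$len[allp$ri],
    right_tm = rf$tm[allp$ri],
    right_gc = rf$gc[allp$ri],
    product_len = allp$product_len,
    penalty = allp$penalty,
    stringsAsFactors = FALSE)
}
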