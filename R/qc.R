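#' Quality-trimming parameter sets
#'
#' Lucy-style three-step trimming parameters. `bracket` controls the
#' end-trimming step (window length in bp and its maximum average error
#' probability), `windows` the interior sliding-window check (one or more
#' `(length, max average error)` pairs), and `global_max_err` /
#' `tail_max_err` the final largest-region selection: the retained region
#' must have overall average error at most `global_max_err` and each of its
#' two terminal `bracket`-length windows at most `tail_max_err`.
#'
#' @param bracket_window integer window length (bp) for end trimming.
#' @param bracket_max_err maximum average error probability for terminal
#'   windows during end trimming.
#' @param windows numeric matrix-like, one row per sliding-window rule:
#'   `cbind(window_len, max_avg_err)`.
#' @param global_max_err maximum average error of the retained region.
#' @param tail_max_err maximum average error of the retained region's two
#'   terminal `bracket_window`-length windows.
#' @param min_len minimum retained length (bp); shorter reads are rejected.
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(bracket_window, bracket_max_err, windows,
                      global_max_err, tail_max_err, min_len = 100L) {
  windows <- matrix(as.numeric(windows), ncol = 2L,
                    dimnames = list(NULL, c("len", "max_err")))
  stopifnot(bracket_window >= 1, min_len >= 1,
            bracket_max_err > 0, bracket_max_err <= 1,
            all(windows[, 1] >= 1),
            all(windows[, 2] > 0), all(windows[, 2] <= 1),
            global_max_err > 0, global_max_err <= 1,
            tail_max_err > 0, tail_max_err <= 1)
  structure(list(bracket_window = as.integer(bracket_window),
                 bracket_max_err = bracket_max_err,
                 windows = windows,
                 global_max_err = global_max_err,
                 tail_max_err = tail_max_err,
                 min_len = as.integer(min_len)),
            class = "qc_params")
}

#' Built-in stringency presets
#'
#' `"high"` keeps only regions whose every 10 bp window has average error
#' probability at most 0.003 and whose overall average error is at most
#' 0.003; `"low"` relaxes the bracket to 0.02, the sliding window to 50 bp
#' at 0.08, and the overall average to 0.025. Both cap terminal-window
#' error at 0.02. The minimum retained length defaults to 100 bp, enough
#' room for a primer pair and the smallest admissible PCR product.
#'
#' @param name `"high"` or `"low"`.
#' @param min_len minimum retained length (bp).
#' @return A `qc_params` object.
#' @export
qc_preset <- function(name, min_len = 100L) {
  switch(name,
    high = qc_params(10L, 0.003, cbind(10, 0.003), 0.003, 0.02, min_len),
    low  = qc_params(10L, 0.02,  cbind(50, 0.08),  0.025, 0.02, min_len),
    stop("unknown preset '", name, "'; available presets: high, low",
         call. = FALSE))
}

# step-1 bracket trimming on a probability vector; returns c(s, e),
# 1-based inclusive, possibly s > e (everything trimmed)
.bracket_trim <- function(p, bw, bmax) {
  s <- 1L; e <- length(p)
  repeat {
    len <- e - s + 1L
    if (len < 1L) break
    w <- min(bw, len)
    if (mean(p[s:(s + w - 1L)]) > bmax) { s <- s + 1L; next }
    if (mean(p[(e - w + 1L):e]) > bmax) { e <- e - 1L; next }
    break
  }
  c(s, e)
}

# Select the best region inside p[s..e] (1-based inclusive bounds) under the
# step-2 sliding-window predicate and step-3 global/terminal caps.
# Returns c(start, end) 1-based inclusive or NULL.
.best_region <- function(p, s, e, params) {
  if (s > e) return(NULL)
  n <- length(p)
  cp <- c(0, cumsum(p))
  rmean <- function(i, j) (cp[j + 1L] - cp[i]) / (j - i + 1L)
  bw <- params$bracket_window
  gmax <- params$global_max_err
  tmax <- params$tail_max_err
  W <- params$windows

  # per window rule: logical "bad" flag for each full-window start position,
  # and its cumulative count for O(1) range queries
  cumbad <- vector("list", nrow(W))
  for (k in seq_len(nrow(W))) {
    w <- W[k, 1]
    nb <- n - w + 1L
    if (nb >= 1L) {
      means <- (cp[(w + 1L):(n + 1L)] - cp[1L:nb]) / w
      cumbad[[k]] <- cumsum(means > W[k, 2])
    } else cumbad[[k]] <- integer(0)
  }
  bad_count <- function(k, from, to) {  # bad full-window starts in [from, to]
    if (to < from) return(0L)
    cb <- cumbad[[k]]
    if (!length(cb)) return(0L)
    to <- min(to, length(cb))
    if (to < from) return(0L)
    cb[to] - if (from > 1L) cb[from - 1L] else 0L
  }
  region_ok <- function(i, j) {
    for (k in seq_len(nrow(W))) {
      w <- W[k, 1]
      if (j - i + 1L >= w) {
        if (bad_count(k, i, j - w + 1L) > 0L) return(FALSE)
      } else if (rmean(i, j) > W[k, 2]) return(FALSE)
    }
    if (rmean(i, j) > gmax) return(FALSE)
    hw <- min(bw, j - i + 1L)
    if (rmean(i, i + hw - 1L) > tmax) return(FALSE)
    if (rmean(j - hw + 1L, j) > tmax) return(FALSE)
    TRUE
  }

  # common fast path: the whole bracket-trimmed region qualifies
  if (region_ok(s, e)) return(c(s, e))

  best <- NULL; best_len <- 0L; best_mean <- Inf
  for (i in s:e) {
    if (e - i + 1L < best_len) break  # no longer region can start here
    js <- i:e
    len <- js - i + 1L
    means <- (cp[js + 1L] - cp[i]) / len
    ok <- means <= gmax
    # terminal windows (truncated windows use their actual length)
    hw <- pmin(bw, len)
    head_mean <- (cp[i + hw] - cp[i]) / hw
    tail_mean <- (cp[js + 1L] - cp[js + 1L - hw]) / hw
    ok <- ok & head_mean <= tmax & tail_mean <= tmax
    for (k in seq_len(nrow(W))) {
      w <- W[k, 1]
      long <- len >= w
      okk <- logical(length(js))
      if (any(long)) {
        jl <- js[long]
        cb <- cumbad[[k]]
        if (length(cb)) {
          upto <- pmin(jl - w + 1L, length(cb))
          base <- if (i > 1L) cb[min(i - 1L, length(cb))] else 0L
          cnt <- ifelse(upto >= i, cb[pmax(upto, 1L)] - base, 0L)
          okk[long] <- cnt == 0L
        } else okk[long] <- TRUE
      }
      if (any(!long)) okk[!long] <- means[!long] <= W[k, 2]
      ok <- ok & okk
    }
    if (any(ok)) {
      jbest <- max(js[ok])
      l <- jbest - i + 1L
      m <- rmean(i, jbest)
      if (l > best_len || (l == best_len && m < best_mean)) {
        best <- c(i, jbest); best_len <- l; best_mean <- m
      }
    }
  }
  best
}

# trim a single probability vector; returns 0-based half-open c(start, end)
# or NULL when rejected
.trim_interval <- function(p, params) {
  n <- length(p)
  if (!n) return(NULL)
  se <- .bracket_trim(p, params$bracket_window, params$bracket_max_err)
  reg <- .best_region(p, se[1], se[2], params)
  if (is.null(reg) || reg[2] - reg[1] + 1L < params$min_len) return(NULL)
  c(reg[1] - 1L, reg[2])
}

#' Quality-trim reads with the three-step sliding-window procedure
#'
#' For each read the procedure (1) strips low-quality bases from both ends
#' while the terminal bracket window exceeds its error cap, (2) requires
#' every interior sliding window of the retained region to satisfy its
#' average-error cap, and (3) selects the longest contiguous region
#' passing (2) whose overall average error does not exceed the global cap
#' and whose two terminal bracket windows stay under the tail cap. Ties on
#' length are broken by smaller average error, then by leftmost start, so
#' trimming is fully deterministic. Reads whose selected region is shorter
#' than `min_len` are rejected. All computations run on error
#' probabilities (see [phred_to_error()]); `N` bases count as probability
#' 1.
#'
#' @param rs a `read_set`; trimming operates on the current clip region.
#' @param params a `qc_params` object, e.g. from [qc_preset()].
#' @return list with `pass` (a `read_set` with narrowed clips) and
#'   `rejected` (a `read_set` of discarded reads).
#' @export
trim_reads <- function(rs, params) {
  if (!length(rs))
    return(list(pass = rs, rejected = rs))
  profs <- error_profiles(rs)
  keep <- logical(length(rs))
  newclip <- rs$clip
  for (i in seq_along(profs)) {
    iv <- .trim_interval(profs[[i]], params)
    if (!is.null(iv)) {
      keep[i] <- TRUE
      newclip[i, ] <- rs$clip[i, 1] + iv
    }
  }
  out <- rs
  out$clip <- newclip
  list(pass = out[keep], rejected = rs[!keep])
}

#' @rdname trim_reads
#' @details `trim_read()` is the single-read form; it returns the read with
#'   its clip narrowed, or `NULL` when the read is rejected.
#' @export
trim_read <- function(rs, params) {
  stopifnot(length(rs) == 1L)
  res <- trim_reads(rs, params)
  if (length(res$pass)) res$pass else NULL
}
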