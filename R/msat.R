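#' Canonical form of a repeat motif
#'
#' Tandem arrays can be read in either phase and on either strand, so a
#' motif is reported under the lexicographically smallest string among all
#' rotations of itself and of its reverse complement: `TG`, `GT`, `CA` and
#' `AC` all canonicalise to `AC`. Canonicalisation is idempotent and
#' strand-symmetric.
#'
#' @param motif DNA string (2-6 bp for microsatellite motifs, but any
#'   length is accepted).
#' @return canonical motif string.
#' @export
canonical_motif <- function(motif) {
  vapply(motif, function(m) {
    m <- toupper(m)
    rc <- .revcomp(m)
    k <- nchar(m)
    rots <- function(s) vapply(seq_len(k) - 1L, function(r)
      paste0(substring(s, r + 1L, k), substring(s, 1L, r)), "")
    min(c(rots(m), rots(rc)))
  }, "", USE.NAMES = FALSE)
}

.revcomp <- function(s) {
  vapply(s, function(x)
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                   collapse = "")), "", USE.NAMES = FALSE)
}

# is the motif primitive, i.e. not itself a tandem repetition of a shorter
# unit? "ACAC" -> FALSE (period 2), "AA" -> FALSE (period 1, homopolymer)
.is_primitive <- function(motif) {
  k <- nchar(motif)
  for (d in seq_len(k %/% 2)) {
    if (k %% d == 0L &&
        motif == strrep(substr(motif, 1L, d), k %/% d)) return(FALSE)
  }
  TRUE
}

#' Find perfect di- to hexanucleotide tandem repeats
#'
#' Detects every maximal perfect (uninterrupted) tandem array whose motif
#' length is in `motif_lens` and whose complete unit count is at least
#' `min_units`. Motifs are required to be primitive, which excludes
#' homopolymer runs (an `AA` motif reduces to `A`), and each array is
#' reported once under its canonical motif. Overlapping arrays with
#' different motifs are all reported. `N` never participates in a repeat.
#'
#' @param bases DNA string over `{A,C,G,T,N}` (lowercase tolerated).
#' @param min_units minimum number of complete units (default 5).
#' @param motif_lens motif lengths to consider (default `2:6`).
#' @return `data.frame` with one row per array: `motif` (canonical),
#'   `motif_obs` (as observed at the array start), `units`, `start`, `end`
#'   (0-based, half-open, spanning complete units only), `left_flank`,
#'   `right_flank` (bp outside the array).
#' @examples
#' find_perfect_repeats("TTTACACACACACACGGG")
#' @export
find_perfect_repeats <- function(bases, min_units = 5L, motif_lens = 2:6) {
  bases <- toupper(bases)
  n <- nchar(bases)
  empty <- data.frame(motif = character(), motif_obs = character(),
                      units = integer(), start = integer(), end = integer(),
                      left_flank = integer(), right_flank = integer(),
                      stringsAsFactors = FALSE)
  if (!n) return(empty)
  x <- utf8ToInt(bases)
  isN <- x == utf8ToInt("N")
  out <- list()
  for (ml in motif_lens) {
    if (n < ml * min_units) next
    m <- x[seq_len(n - ml)] == x[(ml + 1L):n]
    m <- m & !isN[seq_len(n - ml)] & !isN[(ml + 1L):n]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= ml * (min_units - 1L))
    for (h in hit) {
      st <- starts[h]                       # 1-based array start
      total <- r$lengths[h] + ml            # maximal array length in bases
      units <- total %/% ml
      if (units < min_units) next
      obs <- substr(bases, st, st + ml - 1L)
      if (!.is_primitive(obs)) next
      span <- units * ml                    # complete units only
      out[[length(out) + 1L]] <- data.frame(
        motif = canonical_motif(obs), motif_obs = obs, units = units,
        start = st - 1L, end = st - 1L + span,
        left_flank = st - 1L, right_flank = n - (st - 1L + span),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$start, res$end, res$motif), , drop = FALSE]
}

#' Partition reads by microsatellite content
#'
#' Runs [find_perfect_repeats()] on the clipped region of each read and
#' splits the set into repeat-bearing and repeat-free reads. When a read
#' carries several qualifying arrays the one with the most units (ties:
#' leftmost) is marked as the primer target (`target = TRUE`); the others
#' are retained as metadata.
#'
#' @param rs a `read_set` (normally quality-trimmed).
#' @param min_units minimum complete units (default 5).
#' @param motif_lens motif lengths (default `2:6`).
#' @return list with `with_msat` (a `read_set`), `loci` (`data.frame` of
#'   all arrays with `host_id` and `target` columns; coordinates are
#'   relative to the clipped region), and `without` (a `read_set`).
#' @export
classify_reads <- function(rs, min_units = 5L, motif_lens = 2:6) {
  seqs <- clipped_bases(rs)
  loci <- vector("list", length(rs))
  has <- logical(length(rs))
  for (i in seq_along(seqs)) {
    f <- find_perfect_repeats(seqs[i], min_units, motif_lens)
    if (nrow(f)) {
      f <- cbind(host_id = rs$id[i], f, stringsAsFactors = FALSE)
      tgt <- which(f$units == max(f$units))[1L]
      f$target <- seq_len(nrow(f)) == tgt
      loci[[i]] <- f
      has[i] <- TRUE
    }
  }
  loci <- if (any(has)) do.call(rbind, loci[has]) else
    data.frame(host_id = character(), motif = character(),
               motif_obs = character(), units = integer(), start = integer(),
               end = integer(), left_flank = integer(),
               right_flank = integer(), target = logical(),
               stringsAsFactors = FALSE)
  rownames(loci) <- NULL
  list(with_msat = rs[has], loci = loci, without = rs[!has])
}

#' Soft-mask microsatellite spans
#'
#' Lowercases the given spans of a sequence; the redundancy stage excludes
#' lowercase positions from identity computation so that similarity is
#' judged on the repeat-flanking regions only.
#'
#' @param seq sequence string.
#' @param starts,ends 0-based half-open span coordinates.
#' @return the masked sequence string.
#' @export
mask_spans <- function(seq, starts, ends) {
  for (k in seq_along(starts)) {
    s <- starts[k]; e <- ends[k]
    if (e > s)
      substr(seq, s + 1L, e) <- tolower(substr(seq, s + 1L, e))
  }
  seq
}
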