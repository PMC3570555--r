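#' Load a MID barcode table
#'
#' Pooled pyrosequencing libraries are tagged with Multiplex Identifier
#' (MID) adaptors; the table maps each sample to its MID (and, optionally,
#' the sequencing adaptor preceding it). Tables are validated at load time:
#' MIDs must be pairwise distinct, at least 4 bp, and no MID may be a prefix
#' of another (a prefix pair would make assignment ambiguous by
#' construction).
#'
#' @param path TSV file with columns `sample`, `mid`, `adaptor` (the
#'   `adaptor` column may be absent or empty).
#' @return A `data.frame` with columns `sample`, `mid`, `adaptor`.
#' @export
read_barcode_table <- function(path) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("sample", "mid") %in% names(tab)))
    stop("barcode table needs columns 'sample' and 'mid'", call. = FALSE)
  if (is.null(tab$adaptor)) tab$adaptor <- ""
  tab$adaptor[is.na(tab$adaptor)] <- ""
  barcode_table(tab$sample, tab$mid, tab$adaptor)
}

#' @rdname read_barcode_table
#' @param sample,mid,adaptor character vectors defining the table directly.
#' @export
barcode_table <- function(sample, mid, adaptor = "") {
  mid <- toupper(mid)
  tab <- data.frame(sample = as.character(sample), mid = mid,
                    adaptor = toupper(rep_len(adaptor, length(mid))),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(tab$mid)) stop("MID sequences must be distinct",
                                   call. = FALSE)
  if (any(nchar(tab$mid) < 4L)) stop("MIDs must be at least 4 bp",
                                     call. = FALSE)
  for (i in seq_len(nrow(tab)))
    for (j in seq_len(nrow(tab)))
      if (i != j && startsWith(tab$mid[j], tab$mid[i]))
        stop("MID '", tab$mid[i], "' is a prefix of '", tab$mid[j], "'",
             call. = FALSE)
  tab
}

# mismatches between the k-prefix of each string and a fixed tag
.prefix_mismatches <- function(bases, offset, tag) {
  k <- nchar(tag)
  pre <- substr(bases, offset + 1L, offset + k)
  tooshort <- nchar(pre) < k
  tagi <- utf8ToInt(tag)
  mm <- vapply(pre, function(s) {
    if (nchar(s) < k) return(k)
    sum(utf8ToInt(s) != tagi)
  }, 1L, USE.NAMES = FALSE)
  mm[tooshort] <- k
  mm
}

#' Split pooled reads by MID tag
#'
#' Each read is assigned to the unique sample whose MID matches the read
#' prefix with at most `max_mismatch` mismatches; when the table carries an
#' adaptor for a sample, an exact adaptor occurrence at the very start of
#' the read is skipped before the MID comparison. Reads matching no MID, or
#' matching two samples equally well, stay unassigned. Assigned reads have
#' the adaptor and MID removed from bases and qualities. The default
#' `max_mismatch = 0` reflects exact barcode splitting, under which barcode
#' sequencing errors surface as a small unassigned fraction.
#'
#' @param rs a `read_set`.
#' @param table barcode table from [read_barcode_table()] or
#'   [barcode_table()].
#' @param max_mismatch maximum MID mismatches (default 0).
#' @return list with `assigned` (a `read_set` with `sample` filled in and
#'   prefixes removed) and `unassigned` (a `read_set`).
#' @export
demultiplex <- function(rs, table, max_mismatch = 0L) {
  stopifnot(max_mismatch >= 0L)
  n <- length(rs)
  if (!n) return(list(assigned = rs, unassigned = rs))
  nmid <- nrow(table)
  mm <- matrix(0L, n, nmid)
  off <- matrix(0L, n, nmid)
  for (j in seq_len(nmid)) {
    o <- rep(0L, n)
    ad <- table$adaptor[j]
    if (nzchar(ad)) o[startsWith(rs$bases, ad)] <- nchar(ad)
    off[, j] <- o
    mm[, j] <- .prefix_mismatches(rs$bases, o, table$mid[j])
  }
  best <- apply(mm, 1L, which.min)
  bestmm <- mm[cbind(seq_len(n), best)]
  ties <- rowSums(mm == bestmm) > 1L
  hit <- bestmm <= max_mismatch & !ties
  assigned <- rs[hit]
  if (length(assigned)) {
    j <- best[hit]
    cut <- off[cbind(which(hit), j)] + nchar(table$mid[j])
    assigned$sample <- table$sample[j]
    assigned$bases <- substring(assigned$bases, cut + 1L)
    assigned$quals <- mapply(function(q, k) q[-seq_len(k)], assigned$quals,
                             cut, SIMPLIFY = FALSE)
    assigned$clip <- cbind(start = pmax(0L, assigned$clip[, 1] - cut),
                           end = pmax(0L, assigned$clip[, 2] - cut))
  }
  list(assigned = assigned, unassigned = rs[!hit])
}

#' Remove linker sequences from reads
#'
#' Exact linker occurrences at either end of the clipped region are cut
#' away; an interior occurrence truncates the read at the nearer end, i.e.
#' the longer linker-free side is kept. Applied repeatedly until no linker
#' remains in the clipped region.
#'
#' @param rs a `read_set`.
#' @param linkers character vector of linker sequences; empty means no-op.
#' @return the `read_set` with clips narrowed.
#' @export
strip_linkers <- function(rs, linkers) {
  linkers <- toupper(linkers[nzchar(linkers)])
  if (!length(linkers) || !length(rs)) return(rs)
  for (i in seq_along(rs$id)) {
    repeat {
      s <- rs$clip[i, 1]; e <- rs$clip[i, 2]
      if (e <= s) break
      region <- substr(rs$bases[i], s + 1L, e)
      hit <- NULL
      for (lk in linkers) {
        at <- gregexpr(lk, region, fixed = TRUE)[[1]]
        if (at[1] != -1L) { hit <- c(at[1] - 1L, nchar(lk)); break }
      }
      if (is.null(hit)) break
      pos <- hit[1]; w <- hit[2]; len <- e - s
      left_len <- pos
      right_len <- len - pos - w
      if (left_len >= right_len) {
        rs$clip[i, 2] <- s + left_len
      } else {
        rs$clip[i, 1] <- s + pos + w
      }
    }
  }
  rs
}
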