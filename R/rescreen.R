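#' Load a repetitive-element library
#'
#' Any FASTA of known repetitive elements (transposons, pseudogenes,
#' integrated viruses, ...) can serve as the screening library. An
#' optional `family` is parsed from headers of the form
#' `name<TAB>family` or `name#family`.
#'
#' @param path FASTA file.
#' @return named character vector of element sequences with a `family`
#'   attribute.
#' @export
read_re_library <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (!length(x)) stop("repetitive-element library '", path, "' is empty",
                       call. = FALSE)
  hdr <- names(x)
  nm <- sub("[#\t].*$", "", hdr)
  nm <- sub("\\s.*$", "", nm)
  fam <- ifelse(grepl("[#\t]", hdr), sub("^[^#\t]*[#\t]", "", hdr), "")
  if (anyDuplicated(nm)) stop("duplicate element names in RE library",
                              call. = FALSE)
  out <- toupper(as.character(x))
  names(out) <- nm
  attr(out, "family") <- fam
  out
}

#' Screen sequences against a repetitive-element library
#'
#' Each sequence is locally aligned (both orientations, same scoring as
#' [all_vs_all()]) against every library element; it is flagged as
#' repetitive-element-associated when some hit exceeds `min_identity`
#' percent identity over at least `min_hit_len` alignment columns.
#' Microsatellite soft-masking is deliberately *ignored* here — repetitive
#' elements frequently contain microsatellites, so the repeat span itself
#' is legitimate evidence. The best-scoring hit is reported per flagged
#' sequence. `clean` and `flagged` partition the input.
#'
#' @param seqs named character vector of query sequences.
#' @param library RE library from [read_re_library()] (or any named
#'   character vector). An empty library is a hard error; to skip
#'   screening, skip the call.
#' @param min_identity flagging threshold, strict `>` (default 65).
#' @param min_hit_len minimum alignment columns (default 50).
#' @param prefilter if `TRUE`, only query/element pairs sharing a 12-mer
#'   (either orientation) are aligned; a speed device for large runs.
#' @return list with `clean` (named character vector), `flagged` (named
#'   character vector), and `hits` (`data.frame`: `query_id`,
#'   `element_name`, `identity`, `aln_len`, `q_start`, `q_end`, `e_start`,
#'   `e_end`, `score`, `orientation` — best hit per flagged sequence).
#' @export
screen_repetitive <- function(seqs, library, min_identity = 65,
                              min_hit_len = 50L, prefilter = FALSE) {
  if (is.null(library) || !length(library))
    stop("RE screening requires a non-empty library", call. = FALSE)
  n <- length(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  up <- toupper(seqs)
  lup <- toupper(library)
  enames <- names(lup)
  scoring <- .align_scoring()
  nomask_q <- lapply(nchar(up), function(L) rep(FALSE, L))
  best <- data.frame(query_id = ids, element_name = NA_character_,
                     identity = 0, aln_len = 0L, q_start = NA_integer_,
                     q_end = NA_integer_, e_start = NA_integer_,
                     e_end = NA_integer_, score = -Inf,
                     orientation = NA_character_, stringsAsFactors = FALSE)
  cand <- if (prefilter) {
    both <- .kmer_pairs(c(up, lup), k = 12L)
    # keep only query-vs-element pairs
    qe <- both[both[, 1] <= n & both[, 2] > n, , drop = FALSE]
    split(qe[, 1], qe[, 2] - n)
  } else {
    setNames(rep(list(seq_len(n)), length(lup)), seq_along(lup))
  }
  for (jname in names(cand)) {
    j <- as.integer(jname)
    qs <- cand[[jname]]
    if (!length(qs)) next
    emask <- rep(FALSE, nchar(lup[j]))
    hit <- .align_batch_best(up[qs], lup[j], nomask_q[qs], emask, scoring)
    ok <- hit$identity > min_identity & hit$aln_len >= min_hit_len &
          hit$score > best$score[qs]
    if (any(ok)) {
      rows <- qs[ok]
      best$element_name[rows] <- enames[j]
      best$identity[rows] <- hit$identity[ok]
      best$aln_len[rows] <- hit$aln_len[ok]
      best$q_start[rows] <- hit$q_start[ok]
      best$q_end[rows] <- hit$q_end[ok]
      best$e_start[rows] <- hit$s_start[ok]
      best$e_end[rows] <- hit$s_end[ok]
      best$score[rows] <- hit$score[ok]
      best$orientation[rows] <- hit$orientation[ok]
    }
  }
  flagged_i <- !is.na(best$element_name)
  list(clean = seqs[!flagged_i],
       flagged = seqs[flagged_i],
       hits = best[flagged_i, , drop = FALSE])
}
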