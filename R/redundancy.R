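#' All-against-all similarity search over repeat-flanking regions
#'
#' Computes the best local alignment (match +1, mismatch -2, gap open 5,
#' gap extend 2) for every sequence pair in both orientations and reports
#' hits whose identity and alignment length over *unmasked* columns pass
#' the thresholds. Lowercase (soft-masked) positions — the microsatellite
#' arrays — are excluded from identity and length computation, so
#' similarity is judged along the whole repeat-flanking region. Output is
#' symmetric: if `(a,b)` is reported, so is `(b,a)`. Self-hits are
#' recorded (identity 100) but never drive classification.
#'
#' @param seqs named character vector; lowercase letters mark masked spans.
#' @param min_identity_report minimum percent identity to report
#'   (default 80).
#' @param min_aln_len minimum unmasked alignment columns (default 50;
#'   values below 20 are rejected as alignment noise).
#' @param prefilter if `TRUE`, only pairs sharing at least one unmasked
#'   16-mer (either orientation) are aligned. With the scoring scheme used
#'   here, pairs at or above the 80% reporting threshold over `min_aln_len`
#'   columns share 16-mers with overwhelming probability, so this is a
#'   speed device for large inputs; it is off by default.
#' @return `data.frame` with columns `query_id`, `subject_id`, `identity`,
#'   `aln_len`, `q_start`, `q_end`, `s_start`, `s_end` (0-based,
#'   half-open), `score`, `orientation`.
#' @export
all_vs_all <- function(seqs, min_identity_report = 80, min_aln_len = 50L,
                       prefilter = FALSE) {
  stopifnot(length(seqs) >= 1L, min_aln_len >= 20L)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  masks <- lapply(seqs, .mask_of)
  up <- toupper(seqs)
  scoring <- .align_scoring()
  n <- length(seqs)

  pairs <- if (prefilter) .kmer_pairs(seqs) else {
    if (n < 2L) matrix(integer(0), ncol = 2L) else t(utils::combn(n, 2L))
  }
  hits <- if (nrow(pairs)) {
    hit <- .align_pairs(up[pairs[, 1L]], up[pairs[, 2L]],
                        masks[pairs[, 1L]], masks[pairs[, 2L]], scoring,
                        min_score = floor(0.3 * min_aln_len))
    keep <- hit$identity >= min_identity_report & hit$aln_len >= min_aln_len
    h <- hit[keep, , drop = FALSE]
    h$query_id <- ids[pairs[keep, 1L]]
    h$subject_id <- ids[pairs[keep, 2L]]
    h
  } else NULL
  hits <- if (!is.null(hits) && nrow(hits)) hits else
    data.frame(q_start = integer(), q_end = integer(), s_start = integer(),
               s_end = integer(), score = numeric(), aln_len = integer(),
               identity = numeric(), orientation = character(),
               query_id = character(), subject_id = character(),
               stringsAsFactors = FALSE)
  # symmetrise and add self-hits
  if (nrow(hits)) {
    mirror <- hits
    mirror[, c("query_id", "subject_id")] <- hits[, c("subject_id", "query_id")]
    mirror[, c("q_start", "q_end", "s_start", "s_end")] <-
      hits[, c("s_start", "s_end", "q_start", "q_end")]
    hits <- rbind(hits, mirror)
  }
  unmasked_len <- vapply(masks, function(m) sum(!m), 1L)
  self <- data.frame(q_start = 0L, q_end = nchar(seqs), s_start = 0L,
                     s_end = nchar(seqs), score = unmasked_len,
                     aln_len = unmasked_len, identity = 100,
                     orientation = "forward", query_id = ids,
                     subject_id = ids, stringsAsFactors = FALSE)
  hits <- rbind(hits, self)
  hits <- hits[, c("query_id", "subject_id", "identity", "aln_len",
                   "q_start", "q_end", "s_start", "s_end", "score",
                   "orientation")]
  hits <- hits[order(hits$query_id, hits$subject_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Sort sequences into contigs, eliminated partial homologs, and singletons
#'
#' Single-linkage components over hits with identity strictly above
#' `contig_identity` become contigs (size at least 2). Contig membership is
#' decided first; any remaining sequence with a non-self hit inside the
#' elimination band (identity in `[elim_band[1], elim_band[2]]`) is
#' eliminated as a partial homolog — such sequences risk amplifying
#' multiple loci. Everything else, i.e. sequences with only self-hits, are
#' singletons. The partition is total and disjoint.
#'
#' @param ids character vector of all sequence ids under classification.
#' @param hits hit table from [all_vs_all()].
#' @param contig_identity grouping threshold, strict (default 95: a 95.0%
#'   hit does *not* group, it eliminates).
#' @param elim_band closed identity interval for elimination
#'   (default `c(80, 95)`).
#' @return list with `verdicts` (`data.frame`: `read_id`, `verdict` in
#'   `{contig_member, eliminated, singleton}`, `contig_id`) and `contigs`
#'   (named list of member id vectors).
#' @export
classify_redundancy <- function(ids, hits, contig_identity = 95,
                                elim_band = c(80, 95)) {
  nonself <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  strong <- nonself[nonself$identity > contig_identity, , drop = FALSE]
  contig_of <- setNames(rep(NA_character_, length(ids)), ids)
  contigs <- list()
  if (nrow(strong)) {
    g <- igraph::graph_from_data_frame(
      strong[, c("query_id", "subject_id")], directed = FALSE,
      vertices = data.frame(name = ids))
    comp <- igraph::components(g)
    sizes <- comp$csize
    big <- which(sizes >= 2L)
    # deterministic contig numbering: by smallest member position in `ids`
    first_at <- vapply(big, function(k)
      min(match(names(comp$membership)[comp$membership == k], ids)), 1L)
    big <- big[order(first_at)]
    for (k in seq_along(big)) {
      members <- names(comp$membership)[comp$membership == big[k]]
      members <- members[order(match(members, ids))]
      cid <- sprintf("contig_%04d", k)
      contigs[[cid]] <- members
      contig_of[members] <- cid
    }
  }
  in_contig <- !is.na(contig_of)
  band <- nonself$identity >= elim_band[1] & nonself$identity <= elim_band[2]
  banded_ids <- unique(c(nonself$query_id[band], nonself$subject_id[band]))
  # a >threshold hit to anything also means "not a clean singleton": such a
  # sequence is always inside a contig already, so only the band matters
  eliminated <- setdiff(intersect(ids, banded_ids), ids[in_contig])
  verdict <- ifelse(in_contig, "contig_member",
                    ifelse(ids %in% eliminated, "eliminated", "singleton"))
  list(verdicts = data.frame(read_id = ids, verdict = verdict,
                             contig_id = ifelse(in_contig, contig_of, ""),
                             stringsAsFactors = FALSE),
       contigs = contigs)
}

#' Majority-rule consensus from pre-aligned sequences
#'
#' Applies the 66% rule to an explicit alignment (equal-length gapped
#' strings): per column, a symbol shared by at least 66% of members is
#' emitted (a modal gap drops the column); columns without a 66% majority
#' become `N`.
#'
#' @param aligned character vector of equal-length gapped strings.
#' @param threshold majority fraction (default 0.66).
#' @return list with `consensus` (string) and `depth` (integer vector of
#'   non-gap coverage per emitted column).
#' @export
consensus_from_alignment <- function(aligned, threshold = 0.66) {
  stopifnot(length(aligned) >= 2L,
            length(unique(nchar(aligned))) == 1L)
  m <- do.call(rbind, strsplit(aligned, "", fixed = TRUE))
  nmem <- nrow(m)
  out <- character(0)
  depth <- integer(0)
  for (j in seq_len(ncol(m))) {
    tab <- table(m[, j])
    modal <- names(tab)[which.max(tab)]
    if (max(tab) / nmem >= threshold) {
      if (modal != "-") {
        out <- c(out, modal)
        depth <- c(depth, sum(m[, j] != "-"))
      }
      # modal gap: column dropped
    } else {
      out <- c(out, "N")
      depth <- c(depth, sum(m[, j] != "-"))
    }
  }
  list(consensus = paste(out, collapse = ""), depth = depth)
}

# center-star multiple alignment: globally (ends-free) align every member
# to the longest member and merge insertions into common columns
.center_star_msa <- function(seqs, scoring = .align_scoring()) {
  up <- toupper(seqs)
  ref_i <- which.max(nchar(up))[1L]
  ref <- up[ref_i]
  n_ref <- nchar(ref)
  others <- setdiff(seq_along(up), ref_i)

  # orient members relative to the reference (one batched call)
  if (length(others)) {
    f <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(c(up[others], .revcomp(up[others]))),
      Biostrings::DNAString(ref), type = "overlap",
      substitutionMatrix = scoring$mat, gapOpening = scoring$gap_open,
      gapExtension = scoring$gap_ext)
    sc <- Biostrings::score(f)
    m <- length(others)
    flip <- sc[m + seq_len(m)] > sc[seq_len(m)]
    up[others[flip]] <- .revcomp(up[others[flip]])
  }

  # per member: character at each reference position (or "-") plus
  # insertions after each reference position (0 = before first)
  chars <- matrix("-", nrow = length(up), ncol = n_ref)
  inserts <- vector("list", length(up))
  chars[ref_i, ] <- strsplit(ref, "", fixed = TRUE)[[1]]
  inserts[[ref_i]] <- list()
  if (length(others)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(up[others]), Biostrings::DNAString(ref),
      type = "overlap", substitutionMatrix = scoring$mat,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext)
    aps <- as.character(Biostrings::alignedPattern(pa))
    ass <- as.character(Biostrings::alignedSubject(pa))
    rstart <- IRanges::start(Biostrings::subject(pa)) - 1L
    # members sharing only an internal segment with the reference (e.g.
    # contigs chained through a common repetitive element) produce an
    # empty ends-free alignment; fall back to local alignment for those
    bad <- which(nchar(aps) == 0L)
    if (length(bad)) {
      pa2 <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(up[others[bad]]),
        Biostrings::DNAString(ref), type = "local",
        substitutionMatrix = scoring$mat, gapOpening = scoring$gap_open,
        gapExtension = scoring$gap_ext)
      aps[bad] <- as.character(Biostrings::alignedPattern(pa2))
      ass[bad] <- as.character(Biostrings::alignedSubject(pa2))
      rstart[bad] <- IRanges::start(Biostrings::subject(pa2)) - 1L
    }
    for (k in seq_along(others)) {
      i <- others[k]
      ap <- strsplit(aps[k], "", fixed = TRUE)[[1]]
      as_ <- strsplit(ass[k], "", fixed = TRUE)[[1]]
      rpos <- rstart[k]
      if (length(ap) == 0L || all(as_ == "-"))
        stop("contig members share no alignable overlap", call. = FALSE)
      ins <- list()
      for (c_ in seq_along(ap)) {
        if (as_[c_] != "-") {
          rpos <- rpos + 1L
          chars[i, rpos] <- ap[c_]
        } else if (ap[c_] != "-") {
          key <- as.character(rpos)
          ins[[key]] <- c(ins[[key]], ap[c_])
        }
      }
      inserts[[i]] <- ins
    }
  }

  # merge insertions: max insert length after each reference position
  ins_len <- integer(n_ref + 1L)  # index r+1 = after ref position r
  for (i in seq_along(up)) {
    for (key in names(inserts[[i]])) {
      r <- as.integer(key)
      ins_len[r + 1L] <- max(ins_len[r + 1L], length(inserts[[i]][[key]]))
    }
  }
  rows <- character(length(up))
  for (i in seq_along(up)) {
    parts <- character(0)
    for (r in 0:n_ref) {
      if (ins_len[r + 1L] > 0L) {
        v <- inserts[[i]][[as.character(r)]]
        if (is.null(v)) v <- character(0)
        parts <- c(parts, paste(c(v, rep("-", ins_len[r + 1L] - length(v))),
                                collapse = ""))
      }
      if (r < n_ref) parts <- c(parts, chars[i, r + 1L])
    }
    rows[i] <- paste(parts, collapse = "")
  }
  rows
}

#' Build a contig consensus from its member sequences
#'
#' Members (which the clustering stage guarantees to be highly similar)
#' are oriented and progressively aligned against the longest member
#' (center-star), and the majority-rule consensus of the resulting
#' alignment is returned. With as few as three members, a site where two
#' agree reaches the 66% rule, so moderate-depth contigs already correct
#' isolated base-calling errors.
#'
#' @param member_seqs character vector (length at least 2) of member
#'   sequences; lowercase masking is tolerated and ignored.
#' @param threshold majority fraction (default 0.66).
#' @return list with `consensus`, `depth`, and `alignment` (the gapped
#'   member strings).
#' @export
build_consensus <- function(member_seqs, threshold = 0.66) {
  stopifnot(length(member_seqs) >= 2L)
  aln <- .center_star_msa(member_seqs)
  res <- consensus_from_alignment(aln, threshold)
  res$alignment <- aln
  res
}
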