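#' @importFrom methods as is
#' @importFrom stats rbinom rnorm runif setNames
#' @importFrom utils head read.delim write.table
NULL

#' Construct a set of sequencing reads
#'
#' A `read_set` is the package's columnar container for single-end reads:
#' identifiers, sample labels, base strings over `{A,C,G,T,N}`, per-base
#' integer Phred scores, and a half-open clip interval `[start,end)`
#' (0-based) marking the currently valid region of each read. All pipeline
#' stages slice bases and qualities in lockstep through the clip, so raw
#' coordinates are never lost.
#'
#' @param id character vector of unique read identifiers.
#' @param bases character vector of DNA strings over `{A,C,G,T,N}`.
#' @param quals list of integer vectors, one per read, same lengths as
#'   `bases`; Phred scores in `[0, 62]`.
#' @param sample character vector of sample labels (recycled); reads not yet
#'   demultiplexed carry `"unassigned"`.
#' @param desc optional character vector of FASTQ header remainders.
#' @param clip integer matrix with columns `start`, `end` (0-based,
#'   half-open) or `NULL` for whole-read clips.
#' @return An object of class `read_set`.
#' @export
read_set <- function(id, bases, quals, sample = "unassigned", desc = "",
                     clip = NULL) {
  id <- as.character(id)
  bases <- toupper(as.character(bases))
  n <- length(id)
  stopifnot(length(bases) == n, length(quals) == n)
  quals <- lapply(quals, as.integer)
  widths <- nchar(bases)
  qlen <- lengths(quals)
  if (any(widths != qlen)) {
    bad <- which(widths != qlen)[1L]
    stop("read '", id[bad], "': ", widths[bad], " bases but ", qlen[bad],
         " quality values", call. = FALSE)
  }
  rng <- range(c(0L, unlist(quals, use.names = FALSE)))
  if (rng[1] < 0 || rng[2] > 62)
    stop("Phred scores must lie in [0, 62]; got range [", rng[1], ", ",
         rng[2], "] (Phred+64 input is not supported)", call. = FALSE)
  if (is.null(clip)) clip <- cbind(start = rep(0L, n), end = widths)
  clip <- matrix(as.integer(clip), ncol = 2L,
                 dimnames = list(NULL, c("start", "end")))
  if (any(clip[, 1] < 0 | clip[, 1] > clip[, 2] | clip[, 2] > widths))
    stop("invalid clip interval(s)", call. = FALSE)
  structure(list(id = id,
                 sample = rep_len(as.character(sample), n),
                 bases = bases, quals = quals,
                 desc = rep_len(as.character(desc), n),
                 clip = clip),
            class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$id)

#' @export
`[.read_set` <- function(x, i) {
  structure(list(id = x$id[i], sample = x$sample[i], bases = x$bases[i],
                 quals = x$quals[i], desc = x$desc[i],
                 clip = x$clip[i, , drop = FALSE]),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set with", length(x), "reads\n")
  if (length(x)) {
    k <- min(5L, length(x))
    for (i in seq_len(k))
      cat(sprintf("  %s [%s] %d bp, clip [%d,%d)\n", x$id[i], x$sample[i],
                  nchar(x$bases[i]), x$clip[i, 1], x$clip[i, 2]))
    if (length(x) > k) cat("  ...\n")
  }
  invisible(x)
}

#' Combine read sets
#' @param ... `read_set` objects.
#' @return A single `read_set`.
#' @export
c_read_sets <- function(...) {
  xs <- list(...)
  xs <- xs[vapply(xs, length, 1L) > 0]
  if (!length(xs)) return(read_set(character(), character(), list()))
  structure(list(id = unlist(lapply(xs, `[[`, "id")),
                 sample = unlist(lapply(xs, `[[`, "sample")),
                 bases = unlist(lapply(xs, `[[`, "bases")),
                 quals = do.call(c, lapply(xs, `[[`, "quals")),
                 desc = unlist(lapply(xs, `[[`, "desc")),
                 clip = do.call(rbind, lapply(xs, `[[`, "clip"))),
            class = "read_set")
}

#' Extract the clipped (currently valid) region of each read
#' @param rs a `read_set`.
#' @return `clipped_bases`: character vector; `clipped_quals`: list of
#'   integer vectors.
#' @export
clipped_bases <- function(rs) {
  substr(rs$bases, rs$clip[, 1] + 1L, rs$clip[, 2])
}

#' @rdname clipped_bases
#' @export
clipped_quals <- function(rs) {
  mapply(function(q, s, e) if (e > s) q[(s + 1L):e] else integer(0),
         rs$quals, rs$clip[, 1], rs$clip[, 2], SIMPLIFY = FALSE)
}

#' Convert Phred scores to error probabilities
#'
#' The standard Phred transform `p = 10^(-q/10)`: Q20 is 1 error in 100
#' calls, Q30 one in 1000. Quality thresholds throughout the pipeline are
#' expressed as probabilities of this kind.
#'
#' @param q numeric vector of Phred scores, all `>= 0`.
#' @return numeric vector of error probabilities in `(0, 1]`.
#' @examples
#' phred_to_error(c(0, 20, 30))
#' @export
phred_to_error <- function(q) {
  if (any(q < 0)) stop("negative Phred score", call. = FALSE)
  10^(-q / 10)
}

#' Per-base error probabilities of the clipped region
#'
#' `N` calls are explicit base-calling failures and get probability 1
#' regardless of their stated quality, so any quality window containing an
#' `N` fails thresholds below 1.
#'
#' @param rs a `read_set`.
#' @return list of numeric vectors.
#' @export
error_profiles <- function(rs) {
  b <- clipped_bases(rs)
  q <- clipped_quals(rs)
  lapply(seq_along(q), function(i) {
    p <- phred_to_error(q[[i]])
    if (nzchar(b[i])) {
      chars <- strsplit(b[i], "", fixed = TRUE)[[1]]
      p[chars == "N"] <- 1
    }
    p
  })
}

#' Read a 4-line FASTQ file (Phred+33)
#'
#' Strict reader for modern 4-line FASTQ. Record order is preserved;
#' duplicate identifiers get a deterministic numeric suffix (with a
#' warning); a bases/qualities length mismatch is a hard error naming the
#' record. An empty file yields an empty `read_set`. A header token of the
#' form `sample=<label>` is recognised and recorded (this is how pipeline
#' artifacts carry demultiplexed sample labels).
#'
#' @param path FASTQ file (gzip transparently supported).
#' @return A `read_set` with whole-read clips.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines)) return(read_set(character(), character(), list()))
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ: ", path, " has ", length(lines),
         " lines (not a multiple of 4)", call. = FALSE)
  hdr <- lines[seq(1L, length(lines), 4L)]
  seqs <- lines[seq(2L, length(lines), 4L)]
  plus <- lines[seq(3L, length(lines), 4L)]
  qstr <- lines[seq(4L, length(lines), 4L)]
  if (any(substr(hdr, 1L, 1L) != "@") || any(substr(plus, 1L, 1L) != "+"))
    stop("malformed FASTQ record near line ",
         4L * which(substr(hdr, 1L, 1L) != "@" |
                    substr(plus, 1L, 1L) != "+")[1L] - 3L, call. = FALSE)
  hdr <- substring(hdr, 2L)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  bad <- which(nchar(seqs) != nchar(qstr))
  if (length(bad))
    stop("malformed FASTQ record '", id[bad[1L]], "': ", nchar(seqs[bad[1L]]),
         " bases but ", nchar(qstr[bad[1L]]), " quality characters",
         call. = FALSE)
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    warning("duplicate read ids (", paste(head(dup, 3L), collapse = ", "),
            if (length(dup) > 3L) ", ..." else "",
            "); adding numeric suffixes", call. = FALSE)
    id <- make.unique(id, sep = ".")
  }
  quals <- lapply(qstr, function(s) utf8ToInt(s) - 33L)
  sample <- rep("unassigned", length(id))
  m <- regmatches(desc, regexpr("sample=\\S+", desc))
  has <- grepl("sample=", desc, fixed = TRUE)
  sample[has] <- sub("^sample=", "", m)
  read_set(id, seqs, quals, sample = sample, desc = desc)
}

#' Write a read set as 4-line FASTQ (Phred+33)
#'
#' @param rs a `read_set`.
#' @param path output file.
#' @param clipped write only the clipped region (default) or the full read.
#' @param with_sample if `TRUE`, write `sample=<label>` as the header
#'   description (used by pipeline artifacts); otherwise the original
#'   description is preserved, making read/write round trips byte-identical.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(rs, path, clipped = TRUE, with_sample = FALSE) {
  if (clipped) {
    b <- clipped_bases(rs)
    q <- clipped_quals(rs)
  } else {
    b <- rs$bases
    q <- rs$quals
  }
  qs <- vapply(q, function(v) if (length(v)) intToUtf8(v + 33L) else "", "")
  d <- if (with_sample) paste0("sample=", rs$sample) else rs$desc
  hdr <- paste0("@", rs$id, ifelse(nzchar(d), paste0(" ", d), ""))
  con <- file(path, "wb")  # binary: fixed "\n" endings for byte-stable output
  on.exit(close(con))
  if (length(rs))
    writeLines(as.vector(rbind(hdr, b, "+", qs)), con)
  invisible(path)
}

#' Write sequences as 80-column FASTA
#'
#' Lowercase letters (soft-masked microsatellite spans) are preserved.
#'
#' @param seqs named character vector of sequences (names must be unique).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (length(seqs) && (is.null(names(seqs)) || anyDuplicated(names(seqs))))
    stop("sequence names must be present and unique", call. = FALSE)
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' Case (soft-masking) is preserved. Names are the first whitespace token of
#' each header.
#'
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  if (file.exists(path) && file.size(path) == 0) return(character(0))
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
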