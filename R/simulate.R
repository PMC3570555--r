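#' Configuration for the 454-style read simulator
#'
#' The simulator emulates single-end pyrosequencing of genomic fragments:
#' templates carry planted perfect microsatellites (plus sub-threshold
#' 4-unit decoys), planted diverged copies of repetitive-element library
#' sequences, MID barcodes, 3' quality decay with substitution errors
#' calibrated to the stated Phred scores, and homopolymer-length indel
#' errors — the dominant pyrosequencing error mode. Every read is
#' traceable to its template through the returned truth tables.
#'
#' @param n_templates number of genomic fragment templates.
#' @param template_len length-2 integer range of template lengths (bp).
#' @param mode `"shotgun"` (templates sampled uniformly) or `"enriched"`
#'   (repeat-bearing fraction boosted, emulating hybridisation capture).
#' @param msat_fraction probability a template carries a planted repeat;
#'   `NULL` means 0.3 for shotgun and 0.6 for enriched libraries.
#' @param motif_weights named weights over motif lengths 2-6.
#' @param unit_range length-2 range of planted complete unit counts.
#' @param msat_min_flank minimum flank (bp) on each side of a planted
#'   array.
#' @param decoy_fraction probability a repeat-free template carries a
#'   4-unit decoy array (below the 5-unit reporting threshold).
#' @param re_fraction probability a template carries a repetitive-element
#'   segment.
#' @param re_divergence_range substitution divergence range of planted RE
#'   copies (fractions).
#' @param re_seg_len length-2 range of planted RE segment lengths (bp).
#' @param n_re_elements,re_elem_len size of the emitted RE library.
#' @param singleton_fraction fraction of templates sequenced once; the
#'   rest are sequenced `contig_depth` times.
#' @param contig_depth read depth for multi-read templates.
#' @param quality_start,quality_end,quality_jitter linear Phred decay from
#'   read start to read end with Gaussian jitter (sd in Phred units).
#' @param homopolymer_indel_rate probability of a +/-1 length miscall per
#'   mononucleotide run of length >= 3.
#' @param mids barcode table ([barcode_table()]); reads get MID prefixes.
#' @param mid_error_rate per-base substitution rate inside the MID
#'   (barcode sequencing errors produce unassignable reads).
#' @param seed integer; a fixed seed makes the output byte-identical.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_templates = 2000L,
                       template_len = c(300L, 600L),
                       mode = c("shotgun", "enriched"),
                       msat_fraction = NULL,
                       motif_weights = c(`2` = 0.45, `3` = 0.25, `4` = 0.15,
                                         `5` = 0.08, `6` = 0.07),
                       unit_range = c(5L, 14L),
                       msat_min_flank = 80L,
                       decoy_fraction = 0.05,
                       re_fraction = 0.10,
                       re_divergence_range = c(0, 0.30),
                       re_seg_len = c(150L, 300L),
                       n_re_elements = 12L,
                       re_elem_len = c(400L, 800L),
                       singleton_fraction = 0.7,
                       contig_depth = 3L,
                       quality_start = 40,
                       quality_end = 25,
                       quality_jitter = 2,
                       homopolymer_indel_rate = 0.005,
                       mids = NULL,
                       mid_error_rate = 0.002,
                       seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(msat_fraction))
    msat_fraction <- if (mode == "enriched") 0.6 else 0.3
  if (is.null(mids))
    mids <- barcode_table(paste0("s", 1:4),
                          c("ACGCGTCTAGT", "ACGAGTAGACT",
                            "ACACGTAGTAT", "ACGTACTGTGT"))
  cfg <- list(n_templates = as.integer(n_templates),
              template_len = as.integer(template_len), mode = mode,
              msat_fraction = msat_fraction, motif_weights = motif_weights,
              unit_range = as.integer(unit_range),
              msat_min_flank = as.integer(msat_min_flank),
              decoy_fraction = decoy_fraction, re_fraction = re_fraction,
              re_divergence_range = re_divergence_range,
              re_seg_len = as.integer(re_seg_len),
              n_re_elements = as.integer(n_re_elements),
              re_elem_len = as.integer(re_elem_len),
              singleton_fraction = singleton_fraction,
              contig_depth = as.integer(contig_depth),
              quality_start = quality_start, quality_end = quality_end,
              quality_jitter = quality_jitter,
              homopolymer_indel_rate = homopolymer_indel_rate,
              mids = mids, mid_error_rate = mid_error_rate,
              seed = as.integer(seed))
  probs <- c(cfg$msat_fraction, cfg$decoy_fraction, cfg$re_fraction,
             cfg$singleton_fraction, cfg$mid_error_rate,
             cfg$homopolymer_indel_rate, cfg$re_divergence_range)
  stopifnot(all(probs >= 0), all(probs <= 1),
            cfg$unit_range[1] >= 5L, cfg$unit_range[2] >= cfg$unit_range[1],
            cfg$template_len[1] >= 2L * cfg$msat_min_flank + 30L,
            cfg$contig_depth >= 2L)
  class(cfg) <- "sim_config"
  cfg
}

.DNA <- c("A", "C", "G", "T")

.rand_dna_chars <- function(n) sample(.DNA, n, replace = TRUE)

# draw one element from a vector (safe for length-1 vectors, where
# base::sample() would treat the value as a range)
.samp1 <- function(v) v[sample.int(length(v), 1L)]

# regex-based scan for qualifying perfect arrays (>= min_units complete
# units of a primitive 2-6 bp motif); used to keep random template
# backbones free of unplanted repeats
.accidental_repeats <- function(seq, min_units = 5L) {
  hits <- list()
  for (ml in 2:6) {
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", ml, min_units - 1L)
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    for (k in seq_along(m)) {
      motif <- substr(seq, m[k], m[k] + ml - 1L)
      if (!.is_primitive(motif)) next
      hits[[length(hits) + 1L]] <-
        c(start = m[k] - 1L,
          end = m[k] - 1L + ml * ((attr(m, "match.length")[k]) %/% ml))
    }
  }
  hits
}

.overlaps <- function(hits, span) {
  if (!length(hits)) return(logical(0))
  vapply(hits, function(h) h["start"] < span[2] && h["end"] > span[1], TRUE)
}

# plant `units` perfect copies of `motif` at 0-based `st0`, with guard
# bases preventing phase extension on either side
.plant_array <- function(chars, motif, units, st0) {
  mb <- strsplit(motif, "", fixed = TRUE)[[1]]
  ml <- length(mb)
  span <- st0 + c(0L, units * ml)
  chars[(span[1] + 1L):span[2]] <- rep(mb, units)
  if (span[1] >= 1L && chars[span[1]] == mb[ml])
    chars[span[1]] <- sample(setdiff(.DNA, mb[ml]), 1L)
  if (span[2] < length(chars) && chars[span[2] + 1L] == mb[1L])
    chars[span[2] + 1L] <- sample(setdiff(.DNA, mb[1L]), 1L)
  list(chars = chars, span = span)
}

#' Simulate a pyrosequencing library with full ground truth
#'
#' Deterministic under `config$seed`. Planted repeats are perfect in the
#' template; substitution errors are drawn per base from the stated Phred
#' score, so the emitted qualities are calibrated; homopolymer runs of
#' length 3 or more suffer +/-1 length miscalls at the configured rate.
#'
#' @param config a [sim_config()] object.
#' @param out_dir if non-`NULL`, write `reads.fastq`, `re_library.fasta`,
#'   `mids.tsv`, `truth_templates.tsv` and `truth_reads.tsv` there.
#' @return list with `reads` (a `read_set`), `truth` (list of
#'   `templates` and `reads` data frames), `re_library` (named character
#'   vector), `mids`, and `config`.
#' @export
simulate_library <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config

  # --- repetitive-element library (repeat-free by construction) ---
  re_lib <- character(cfg$n_re_elements)
  for (i in seq_len(cfg$n_re_elements)) {
    repeat {
      L <- .samp1(cfg$re_elem_len[1]:cfg$re_elem_len[2])
      s <- paste(.rand_dna_chars(L), collapse = "")
      if (!length(.accidental_repeats(s))) break
    }
    re_lib[i] <- s
  }
  names(re_lib) <- sprintf("RE_%02d", seq_len(cfg$n_re_elements))

  # --- templates ---
  nt <- cfg$n_templates
  t_id <- sprintf("t%05d", seq_len(nt))
  t_seq <- character(nt)
  t_len <- integer(nt)
  msat_motif <- rep(NA_character_, nt); msat_units <- rep(NA_integer_, nt)
  msat_start <- rep(NA_integer_, nt); msat_end <- rep(NA_integer_, nt)
  decoy_motif <- rep(NA_character_, nt)
  decoy_start <- rep(NA_integer_, nt); decoy_end <- rep(NA_integer_, nt)
  re_name <- rep(NA_character_, nt); re_div <- rep(NA_real_, nt)
  re_start <- rep(NA_integer_, nt); re_end <- rep(NA_integer_, nt)
  depth <- integer(nt)
  mlens <- as.integer(names(cfg$motif_weights))

  for (i in seq_len(nt)) {
    has_msat <- runif(1) < cfg$msat_fraction
    has_decoy <- !has_msat && runif(1) < cfg$decoy_fraction
    has_re <- runif(1) < cfg$re_fraction
    ok <- FALSE
    for (try in 1:100) {
      len <- .samp1(cfg$template_len[1]:cfg$template_len[2])
      plant_span <- NULL
      if (has_msat || has_decoy) {
        ml <- if (has_msat)
          sample(mlens, 1L, prob = cfg$motif_weights) else 2L
        repeat {
          motif <- paste(.rand_dna_chars(ml), collapse = "")
          if (.is_primitive(motif)) break
        }
        units <- if (has_msat)
          .samp1(cfg$unit_range[1]:cfg$unit_range[2]) else 4L
        replen <- ml * units
        lo <- cfg$msat_min_flank
        hi <- len - cfg$msat_min_flank - replen
        if (hi < lo) next
        st0 <- .samp1(lo:hi)
        chars <- .rand_dna_chars(len)
        pl <- .plant_array(chars, motif, units, st0)
        chars <- pl$chars; plant_span <- pl$span
      } else {
        chars <- .rand_dna_chars(len)
      }
      re_ok <- NULL
      if (has_re) {
        el <- sample.int(length(re_lib), 1L)
        seg_len <- .samp1(cfg$re_seg_len[1]:cfg$re_seg_len[2])
        seg_len <- min(seg_len, nchar(re_lib[el]))
        es <- sample.int(nchar(re_lib[el]) - seg_len + 1L, 1L)
        seg <- strsplit(substr(re_lib[el], es, es + seg_len - 1L), "",
                        fixed = TRUE)[[1]]
        d <- runif(1, cfg$re_divergence_range[1], cfg$re_divergence_range[2])
        nsub <- rbinom(1L, seg_len, d)
        if (nsub > 0L) {
          at <- sample(seg_len, nsub)
          seg[at] <- vapply(seg[at],
                            function(bb) sample(setdiff(.DNA, bb), 1L), "")
        }
        # admissible placements avoid the planted array and its guards
        cand <- if (!is.null(plant_span)) {
          c(if (plant_span[1] - 1L - seg_len >= 0L)
              list(c(0L, plant_span[1] - 1L - seg_len)),
            if (len - seg_len >= plant_span[2] + 1L)
              list(c(plant_span[2] + 1L, len - seg_len)))
        } else list(c(0L, len - seg_len))
        cand <- Filter(function(w) w[2] >= w[1], cand)
        if (length(cand)) {
          w <- cand[[sample(length(cand), 1L)]]
          p0 <- .samp1(w[1]:w[2])
          chars[(p0 + 1L):(p0 + seg_len)] <- seg
          re_ok <- list(name = names(re_lib)[el], div = nsub / seg_len,
                        span = c(p0, p0 + seg_len))
        }
      }
      seqstr <- paste(chars, collapse = "")
      acc <- .accidental_repeats(seqstr)
      if (!is.null(plant_span) && has_msat)
        acc <- acc[!.overlaps(acc, plant_span)]
      if (length(acc)) next
      # planting succeeded with a clean backbone
      t_seq[i] <- seqstr; t_len[i] <- len
      if (has_msat) {
        msat_motif[i] <- canonical_motif(motif); msat_units[i] <- units
        msat_start[i] <- plant_span[1]; msat_end[i] <- plant_span[2]
      } else if (has_decoy) {
        decoy_motif[i] <- canonical_motif(motif)
        decoy_start[i] <- plant_span[1]; decoy_end[i] <- plant_span[2]
      }
      if (!is.null(re_ok)) {
        re_name[i] <- re_ok$name; re_div[i] <- re_ok$div
        re_start[i] <- re_ok$span[1]; re_end[i] <- re_ok$span[2]
      }
      ok <- TRUE
      break
    }
    if (!ok) stop("failed to construct template ", i, call. = FALSE)
    depth[i] <- if (runif(1) < cfg$singleton_fraction) 1L else
      cfg$contig_depth
  }

  # --- reads ---
  total <- sum(depth)
  r_id <- character(total); r_tmpl <- character(total)
  r_sample <- character(total); r_strand <- character(total)
  r_nsub <- integer(total); r_subpos <- character(total)
  r_nindel <- integer(total); r_nmiderr <- integer(total)
  r_bases <- character(total); r_quals <- vector("list", total)
  k <- 0L
  for (i in seq_len(nt)) {
    tchars_f <- strsplit(t_seq[i], "", fixed = TRUE)[[1]]
    for (cp in seq_len(depth[i])) {
      k <- k + 1L
      strand <- sample(c("+", "-"), 1L)
      tchars <- if (strand == "+") tchars_f else
        rev(chartr("ACGT", "TGCA", tchars_f))
      L <- length(tchars)
      pos <- seq_len(L)
      q <- round(cfg$quality_start +
                 (cfg$quality_end - cfg$quality_start) * (pos - 1) /
                 max(1L, L - 1L) +
                 rnorm(L, 0, cfg$quality_jitter))
      q <- pmin(62L, pmax(2L, as.integer(q)))
      p <- 10^(-q / 10)
      hit <- which(runif(L) < p)
      if (length(hit))
        tchars[hit] <- vapply(tchars[hit],
                              function(bb) sample(setdiff(.DNA, bb), 1L), "")
      # homopolymer +/-1 length miscalls at runs >= 3
      r <- rle(tchars)
      nindel <- 0L
      if (any(r$lengths >= 3L)) {
        ends <- cumsum(r$lengths)
        runs <- which(r$lengths >= 3L)
        do <- runs[runif(length(runs)) < cfg$homopolymer_indel_rate]
        for (rr in rev(do)) {
          e <- ends[rr]
          if (runif(1) < 0.5) {   # insertion: one extra copy
            tchars <- append(tchars, r$values[rr], after = e)
            q <- append(q, q[e], after = e)
          } else {                # deletion: one copy fewer
            tchars <- tchars[-e]
            q <- q[-e]
          }
          nindel <- nindel + 1L
        }
      }
      mrow <- sample.int(nrow(cfg$mids), 1L)
      mid <- strsplit(cfg$mids$mid[mrow], "", fixed = TRUE)[[1]]
      miderr <- which(runif(length(mid)) < cfg$mid_error_rate)
      if (length(miderr))
        mid[miderr] <- vapply(mid[miderr],
                              function(bb) sample(setdiff(.DNA, bb), 1L), "")
      r_id[k] <- sprintf("read%06d", k)
      r_tmpl[k] <- t_id[i]
      r_sample[k] <- cfg$mids$sample[mrow]
      r_strand[k] <- strand
      r_nsub[k] <- length(hit)
      r_subpos[k] <- paste(hit, collapse = ",")
      r_nindel[k] <- nindel
      r_nmiderr[k] <- length(miderr)
      r_bases[k] <- paste(c(mid, tchars), collapse = "")
      r_quals[[k]] <- c(rep(40L, length(mid)), q)
    }
  }

  reads <- read_set(r_id, r_bases, r_quals)
  truth_templates <- data.frame(
    template_id = t_id, length = t_len, depth = depth,
    msat_motif = msat_motif, msat_units = msat_units,
    msat_start = msat_start, msat_end = msat_end,
    decoy_motif = decoy_motif, decoy_start = decoy_start,
    decoy_end = decoy_end,
    re_name = re_name, re_divergence = re_div,
    re_start = re_start, re_end = re_end,
    stringsAsFactors = FALSE)
  truth_reads <- data.frame(
    read_id = r_id, template_id = r_tmpl, sample = r_sample,
    strand = r_strand, n_subs = r_nsub, sub_pos = r_subpos,
    n_indels = r_nindel, n_mid_errors = r_nmiderr,
    stringsAsFactors = FALSE)

  out <- list(reads = reads,
              truth = list(templates = truth_templates, reads = truth_reads),
              re_library = re_lib, mids = cfg$mids, config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fastq(reads, file.path(out_dir, "reads.fastq"))
    write_fasta(re_lib, file.path(out_dir, "re_library.fasta"))
    write.table(cfg$mids, file.path(out_dir, "mids.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(truth_templates, file.path(out_dir, "truth_templates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(truth_reads, file.path(out_dir, "truth_reads.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Phred calibration report for a simulated library
#'
#' Compares, position by position along the template-derived part of each
#' read, the observed substitution rate with the rate implied by the
#' stated Phred scores. Reads carrying homopolymer indels are excluded
#' because their coordinates shift. Returns the per-position table and a
#' chi-squared calibration statistic over positions with adequate
#' expected counts.
#'
#' @param sim result of [simulate_library()].
#' @return list with `table` (`data.frame`: `position`, `n_reads`,
#'   `observed`, `expected`, `obs_rate`, `exp_rate`), `chisq`, `df`.
#' @export
calibration_report <- function(sim) {
  tr <- sim$truth$reads
  if (!identical(tr$read_id, sim$reads$id))
    stop("truth table does not match the read set", call. = FALSE)
  keep <- tr$n_indels == 0L
  if (!any(keep)) stop("no indel-free reads to calibrate on", call. = FALSE)
  midlen <- nchar(sim$config$mids$mid[match(tr$sample,
                                            sim$config$mids$sample)])
  quals <- sim$reads$quals[keep]
  midlen <- midlen[keep]
  subpos <- tr$sub_pos[keep]
  tlen <- lengths(quals) - midlen
  maxL <- max(tlen)
  nreads <- integer(maxL); expected <- numeric(maxL); observed <- integer(maxL)
  for (i in seq_along(quals)) {
    q <- quals[[i]][(midlen[i] + 1L):length(quals[[i]])]
    L <- length(q)
    nreads[1:L] <- nreads[1:L] + 1L
    expected[1:L] <- expected[1:L] + 10^(-q / 10)
    if (nzchar(subpos[i])) {
      at <- as.integer(strsplit(subpos[i], ",", fixed = TRUE)[[1]])
      observed[at] <- observed[at] + 1L
    }
  }
  tab <- data.frame(position = seq_len(maxL), n_reads = nreads,
                    observed = observed, expected = expected,
                    obs_rate = observed / pmax(1L, nreads),
                    exp_rate = expected / pmax(1L, nreads))
  use <- tab$expected >= 5
  chisq <- sum((tab$observed[use] - tab$expected[use])^2 /
               tab$expected[use])
  list(table = tab, chisq = chisq, df = sum(use))
}
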