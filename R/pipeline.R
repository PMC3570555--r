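#' Pipeline configuration
#'
#' Bundles the tunables of the two-track selection pipeline. Defaults are
#' the published microsatellite-selection settings: QC presets from
#' [qc_preset()], 5-unit minimum for di- to hexanucleotide repeats, >95%
#' identity contig grouping with the 80-95% elimination band, 66%
#' majority-rule consensus, >65% repetitive-element homology exclusion,
#' and the [primer_constraints()] block.
#'
#' @param qc_low,qc_high `qc_params` for the two stringency tracks.
#' @param min_units,motif_lens repeat mining parameters.
#' @param cluster_identity,elim_band,min_aln_len redundancy thresholds.
#' @param consensus_threshold majority fraction for contig consensus.
#' @param re_min_identity,re_min_hit_len repetitive-element screen
#'   thresholds.
#' @param constraints a [primer_constraints()] object.
#' @param top_k primer pairs reported per locus.
#' @param max_mismatch MID mismatches tolerated by demultiplexing.
#' @param prefilter use the shared-k-mer prefilter in the all-vs-all and
#'   RE-screen stages (a speed device; thresholds are unchanged).
#' @param dedup_cross_track report loci found by both tracks once,
#'   preferring the contig version.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(qc_low = qc_preset("low"),
                            qc_high = qc_preset("high"),
                            min_units = 5L, motif_lens = 2:6,
                            cluster_identity = 95, elim_band = c(80, 95),
                            min_aln_len = 50L,
                            consensus_threshold = 0.66,
                            re_min_identity = 65, re_min_hit_len = 50L,
                            constraints = primer_constraints(),
                            top_k = 3L, max_mismatch = 0L,
                            prefilter = TRUE, dedup_cross_track = TRUE) {
  structure(list(qc_low = qc_low, qc_high = qc_high,
                 min_units = as.integer(min_units), motif_lens = motif_lens,
                 cluster_identity = cluster_identity, elim_band = elim_band,
                 min_aln_len = as.integer(min_aln_len),
                 consensus_threshold = consensus_threshold,
                 re_min_identity = re_min_identity,
                 re_min_hit_len = as.integer(re_min_hit_len),
                 constraints = constraints, top_k = as.integer(top_k),
                 max_mismatch = as.integer(max_mismatch),
                 prefilter = prefilter,
                 dedup_cross_track = dedup_cross_track),
            class = "pipeline_config")
}

.loci_cols <- c("host_id", "motif", "motif_obs", "units", "start", "end",
                "left_flank", "right_flank", "target")

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

.art <- function(out_dir, name) if (is.null(out_dir)) NULL else
  file.path(out_dir, name)

# ---- stage: input (load + demultiplex) ----
.stage_input <- function(fastq, barcodes, config, out_dir) {
  rs <- if (inherits(fastq, "read_set")) fastq else read_fastq(fastq)
  if (!is.null(barcodes)) {
    tab <- if (is.character(barcodes)) read_barcode_table(barcodes) else
      barcodes
    dm <- demultiplex(rs, tab, config$max_mismatch)
    assigned <- dm$assigned
    unassigned <- dm$unassigned
  } else {
    assigned <- rs
    unassigned <- rs[integer(0)]
  }
  pre <- classify_reads(assigned, config$min_units, config$motif_lens)
  state <- list(
    reads = assigned,
    ledger = list(
      sequences_input = length(rs),
      sequences_unassigned = length(unassigned),
      before_qc = list(
        sequences = length(assigned),
        msats = length(pre$with_msat),
        pct_with_msats = if (length(assigned))
          round(100 * length(pre$with_msat) / length(assigned), 1) else 0)))
  if (!is.null(out_dir)) {
    write_fastq(assigned, .art(out_dir, "assigned.fastq"),
                clipped = FALSE, with_sample = TRUE)
    write_fastq(unassigned, .art(out_dir, "unassigned.fastq"),
                clipped = FALSE)
    .save_state(state, out_dir)
  }
  state
}

# ---- stage: quality trimming (both stringency tracks) ----
.stage_qc <- function(state, config, out_dir) {
  low <- trim_reads(state$reads, config$qc_low)
  high <- trim_reads(state$reads, config$qc_high)
  state$tracks <- list(
    low = list(label = "Low Stringency - consensus", pass = low$pass),
    high = list(label = "High Stringency - singletons", pass = high$pass))
  state$ledger$tracks <- list(
    low = list(sequences_after_qc = length(low$pass)),
    high = list(sequences_after_qc = length(high$pass)))
  if (!is.null(out_dir)) {
    write_fastq(low$pass, .art(out_dir, "qc_low.fastq"), with_sample = TRUE)
    write_fastq(high$pass, .art(out_dir, "qc_high.fastq"), with_sample = TRUE)
    .save_state(state, out_dir)
  }
  state
}

# ---- stage: microsatellite mining ----
.stage_mine <- function(state, config, out_dir) {
  for (t in c("low", "high")) {
    cl <- classify_reads(state$tracks[[t]]$pass, config$min_units,
                         config$motif_lens)
    seqs <- clipped_bases(cl$with_msat)
    names(seqs) <- cl$with_msat$id
    # soft-mask every qualifying array so similarity is flank-only
    for (i in seq_along(seqs)) {
      li <- cl$loci[cl$loci$host_id == names(seqs)[i], , drop = FALSE]
      seqs[i] <- mask_spans(seqs[i], li$start, li$end)
    }
    state$tracks[[t]]$msat_seqs <- seqs
    state$tracks[[t]]$loci <- cl$loci
    state$ledger$tracks[[t]]$msat_reads <- length(seqs)
  }
  if (!is.null(out_dir)) {
    for (t in c("low", "high")) {
      write_fasta(state$tracks[[t]]$msat_seqs,
                  .art(out_dir, paste0("msat_", t, ".fasta")))
      .write_tsv(state$tracks[[t]]$loci,
                 .art(out_dir, paste0("loci_", t, ".tsv")))
    }
    .save_state(state, out_dir)
  }
  state
}

# ---- stage: redundancy resolution + candidate construction ----
.stage_cluster <- function(state, config, out_dir) {
  for (t in c("low", "high")) {
    seqs <- state$tracks[[t]]$msat_seqs
    if (length(seqs) >= 2L) {
      hits <- all_vs_all(seqs, min_identity_report = config$elim_band[1],
                         min_aln_len = config$min_aln_len,
                         prefilter = config$prefilter)
      cls <- classify_redundancy(names(seqs), hits, config$cluster_identity,
                                 config$elim_band)
    } else {
      cls <- list(verdicts = data.frame(
        read_id = names(seqs),
        verdict = rep("singleton", length(seqs)),
        contig_id = rep("", length(seqs)), stringsAsFactors = FALSE),
        contigs = list())
    }
    state$tracks[[t]]$verdicts <- cls$verdicts
    if (t == "low") {
      # contig consensuses are the candidates
      cand <- character(0)
      cand_loci <- NULL
      for (cid in names(cls$contigs)) {
        members <- cls$contigs[[cid]]
        cons <- build_consensus(toupper(seqs[members]),
                                config$consensus_threshold)$consensus
        f <- find_perfect_repeats(cons, config$min_units, config$motif_lens)
        masked <- mask_spans(cons, f$start, f$end)
        cand[cid] <- masked
        if (nrow(f)) {
          f <- cbind(host_id = cid, f, stringsAsFactors = FALSE)
          tgt <- which(f$units == max(f$units))[1L]
          f$target <- seq_len(nrow(f)) == tgt
          cand_loci <- rbind(cand_loci, f)
        }
      }
      state$tracks$low$cand <- cand
      state$tracks$low$cand_loci <- if (is.null(cand_loci))
        state$tracks$low$loci[0, ] else cand_loci
      state$tracks$low$contigs <- cls$contigs
    } else {
      keep <- cls$verdicts$read_id[cls$verdicts$verdict == "singleton"]
      state$tracks$high$cand <- seqs[keep]
      state$tracks$high$cand_loci <-
        state$tracks$high$loci[state$tracks$high$loci$host_id %in% keep, ,
                               drop = FALSE]
    }
    state$ledger$tracks[[t]]$eliminated <-
      sum(cls$verdicts$verdict == "eliminated")
    state$ledger$tracks[[t]]$candidates <- length(state$tracks[[t]]$cand)
  }
  if (!is.null(out_dir)) {
    for (t in c("low", "high")) {
      write_fasta(state$tracks[[t]]$cand,
                  .art(out_dir, paste0("candidates_", t, ".fasta")))
      .write_tsv(state$tracks[[t]]$cand_loci,
                 .art(out_dir, paste0("candidates_", t, "_loci.tsv")))
      .write_tsv(state$tracks[[t]]$verdicts,
                 .art(out_dir, paste0("cluster_", t, ".tsv")))
    }
    .save_state(state, out_dir)
  }
  state
}

# ---- stage: repetitive-element screening ----
.stage_screen <- function(state, re_lib, config, out_dir) {
  lib <- if (is.null(re_lib)) NULL else {
    if (is.character(re_lib) && length(re_lib) == 1L && file.exists(re_lib))
      read_re_library(re_lib) else re_lib
  }
  for (t in c("low", "high")) {
    cand <- state$tracks[[t]]$cand
    if (is.null(lib) || !length(cand)) {
      if (is.null(lib) && length(cand))
        message("RE screening skipped for track '", t,
                "': no library given; all candidates kept")
      state$tracks[[t]]$clean <- cand
      state$tracks[[t]]$flagged <- data.frame()
    } else {
      # no prefilter here: at the 65% identity threshold, diverged element
      # copies can lack shared k-mers, and the screen is cheap (candidates
      # x elements, not all-vs-all)
      scr <- screen_repetitive(cand, lib, config$re_min_identity,
                               config$re_min_hit_len)
      state$tracks[[t]]$clean <- scr$clean
      state$tracks[[t]]$flagged <- scr$hits
    }
    state$ledger$tracks[[t]]$msat_without_re <-
      length(state$tracks[[t]]$clean)
  }
  if (!is.null(out_dir)) {
    for (t in c("low", "high")) {
      write_fasta(state$tracks[[t]]$clean,
                  .art(out_dir, paste0("clean_", t, ".fasta")))
      fl <- state$tracks[[t]]$flagged
      if (!nrow(fl)) fl <- data.frame(query_id = character(),
                                      element_name = character(),
                                      identity = numeric())
      .write_tsv(fl, .art(out_dir, paste0("flagged_", t, ".tsv")))
    }
    .save_state(state, out_dir)
  }
  state
}

# ---- stage: primer design + cross-track deduplication + ledger ----
.stage_primers <- function(state, config, out_dir) {
  for (t in c("low", "high")) {
    clean <- state$tracks[[t]]$clean
    loci <- state$tracks[[t]]$cand_loci
    rows <- list()
    for (id in names(clean)) {
      tgt <- loci[loci$host_id == id & loci$target, , drop = FALSE]
      if (!nrow(tgt)) next
      pp <- design_pairs(clean[[id]], tgt$start[1], tgt$end[1],
                         config$constraints, config$top_k)
      if (nrow(pp)) {
        pp <- cbind(locus_id = id, track = t, motif = tgt$motif[1],
                    units = tgt$units[1], pp, stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- pp
      }
    }
    prim <- if (length(rows)) do.call(rbind, rows) else
      data.frame(locus_id = character(), track = character(),
                 motif = character(), units = integer(), rank = integer(),
                 left_seq = character(), left_start = integer(),
                 left_len = integer(), left_tm = numeric(),
                 left_gc = numeric(), right_seq = character(),
                 right_start = integer(), right_len = integer(),
                 right_tm = numeric(), right_gc = numeric(),
                 product_len = integer(), penalty = numeric(),
                 stringsAsFactors = FALSE)
    state$tracks[[t]]$primers <- prim
    state$ledger$tracks[[t]]$primer_pairs <- length(unique(prim$locus_id))
  }

  # loci found by both tracks are reported once (contig version preferred)
  dropped <- character(0)
  lowp <- state$tracks$low$primers
  highp <- state$tracks$high$primers
  if (config$dedup_cross_track && nrow(lowp) && nrow(highp)) {
    low_ids <- unique(lowp$locus_id)
    high_ids <- unique(highp$locus_id)
    low_seqs <- state$tracks$low$clean[low_ids]
    high_seqs <- state$tracks$high$clean[high_ids]
    # candidate duplicate pairs must share flank k-mers; align only those
    pool <- c(low_seqs, high_seqs)
    pr <- .kmer_pairs(pool)
    nl <- length(low_seqs)
    cross <- pr[pr[, 1] <= nl & pr[, 2] > nl, , drop = FALSE]
    if (nrow(cross)) {
      pats <- high_seqs[cross[, 2] - nl]
      subs <- low_seqs[cross[, 1]]
      hit <- .align_pairs(toupper(pats), toupper(subs),
                          lapply(pats, .mask_of), lapply(subs, .mask_of))
      dup <- hit$identity >= config$cluster_identity &
             hit$aln_len >= config$min_aln_len
      dropped <- unique(names(pats)[dup])
    }
  }
  merged <- rbind(lowp, highp[!highp$locus_id %in% dropped, , drop = FALSE])
  rownames(merged) <- NULL
  state$primers <- merged
  lg <- state$ledger
  lg$total_primer_pairs <- lg$tracks$low$primer_pairs +
    lg$tracks$high$primer_pairs
  lg$cross_track_duplicates <- length(dropped)
  lg$unique_loci <- length(unique(merged$locus_id))
  state$ledger <- lg
  if (!is.null(out_dir)) {
    .write_tsv(state$tracks$low$primers, .art(out_dir, "primers_low.tsv"))
    .write_tsv(state$tracks$high$primers, .art(out_dir, "primers_high.tsv"))
    .write_tsv(merged, .art(out_dir, "primers.tsv"))
    jsonlite::write_json(lg, .art(out_dir, "ledger.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    writeLines(ledger_report(lg), .art(out_dir, "report.txt"))
    .save_state(state, out_dir)
  }
  state
}

.save_state <- function(state, out_dir) {
  jsonlite::write_json(state$ledger, file.path(out_dir, "state.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

# reconstruct pipeline state from the artifacts of completed stages
.load_state <- function(out_dir, upto, config) {
  lg <- jsonlite::read_json(file.path(out_dir, "state.json"),
                            simplifyVector = TRUE)
  state <- list(ledger = lg)
  if (upto == "input") {
    state$reads <- read_fastq(file.path(out_dir, "assigned.fastq"))
    return(state)
  }
  state$tracks <- list(
    low = list(label = "Low Stringency - consensus"),
    high = list(label = "High Stringency - singletons"))
  if (upto == "qc") {
    for (t in c("low", "high"))
      state$tracks[[t]]$pass <-
        read_fastq(file.path(out_dir, paste0("qc_", t, ".fastq")))
    return(state)
  }
  if (upto == "mine") {
    for (t in c("low", "high")) {
      state$tracks[[t]]$msat_seqs <-
        read_fasta(file.path(out_dir, paste0("msat_", t, ".fasta")))
      state$tracks[[t]]$loci <-
        .read_tsv(file.path(out_dir, paste0("loci_", t, ".tsv")))
    }
    return(state)
  }
  if (upto == "cluster") {
    for (t in c("low", "high")) {
      state$tracks[[t]]$cand <-
        read_fasta(file.path(out_dir, paste0("candidates_", t, ".fasta")))
      state$tracks[[t]]$cand_loci <-
        .read_tsv(file.path(out_dir, paste0("candidates_", t, "_loci.tsv")))
      state$tracks[[t]]$verdicts <-
        .read_tsv(file.path(out_dir, paste0("cluster_", t, ".tsv")))
    }
    return(state)
  }
  if (upto == "screen") {
    state <- .load_state(out_dir, "cluster", config)
    state$ledger <- lg
    for (t in c("low", "high")) {
      state$tracks[[t]]$clean <-
        read_fasta(file.path(out_dir, paste0("clean_", t, ".fasta")))
      state$tracks[[t]]$flagged <-
        .read_tsv(file.path(out_dir, paste0("flagged_", t, ".tsv")))
    }
    return(state)
  }
  stop("unknown stage '", upto, "'", call. = FALSE)
}

#' Run the two-track microsatellite selection pipeline
#'
#' Track A applies low-stringency quality trimming and takes only contig
#' consensuses forward; track B applies high-stringency trimming and
#' takes only singletons forward. Both tracks then pass the
#' repetitive-element screen and primer design. A locus recovered by both
#' tracks is reported once, preferring the contig version, whose
#' consensus averages out base-calling errors. All thresholds sit in
#' [pipeline_config()].
#'
#' @param fastq input FASTQ path or a `read_set`.
#' @param barcodes optional barcode table (path or data frame) for
#'   demultiplexing; reads failing assignment are set aside.
#' @param re_lib optional repetitive-element FASTA path (or named
#'   character vector). `NULL` skips the screen (logged loudly).
#' @param config a [pipeline_config()].
#' @param out_dir if non-`NULL`, every stage writes its artifacts here
#'   and the run can be resumed per stage.
#' @param resume_from `NULL` for a fresh run, or one of `"qc"`, `"mine"`,
#'   `"cluster"`, `"screen"`, `"primers"` to restart that stage from the
#'   artifacts already in `out_dir`.
#' @return list with `primers` (deduplicated pair table), `ledger`
#'   (summary counts), and `tracks` (per-track intermediate objects).
#' @export
run_pipeline <- function(fastq, barcodes = NULL, re_lib = NULL,
                         config = pipeline_config(), out_dir = NULL,
                         resume_from = NULL) {
  stages <- c("qc", "mine", "cluster", "screen", "primers")
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(resume_from)) {
    state <- .stage_input(fastq, barcodes, config, out_dir)
    todo <- stages
  } else {
    resume_from <- match.arg(resume_from, stages)
    if (is.null(out_dir)) stop("resume requires out_dir", call. = FALSE)
    prev <- c(qc = "input", mine = "qc", cluster = "mine",
              screen = "cluster", primers = "screen")[[resume_from]]
    state <- .load_state(out_dir, prev, config)
    todo <- stages[match(resume_from, stages):length(stages)]
  }
  for (st in todo) {
    state <- switch(st,
      qc = .stage_qc(state, config, out_dir),
      mine = .stage_mine(state, config, out_dir),
      cluster = .stage_cluster(state, config, out_dir),
      screen = .stage_screen(state, re_lib, config, out_dir),
      primers = .stage_primers(state, config, out_dir))
  }
  list(primers = state$primers, ledger = state$ledger,
       tracks = state$tracks)
}

#' Render the summary ledger as a fixed-width table
#'
#' Row labels follow the conventional marker-development summary:
#' sequence counts before and after quality control, microsatellite
#' candidates, candidates without repetitive elements, and designed
#' primer pairs per track, plus their total.
#'
#' @param ledger the `ledger` element of a [run_pipeline()] result.
#' @return character vector of report lines.
#' @export
ledger_report <- function(ledger) {
  num <- function(x) format(x, width = 10)
  mu <- "\u00b5sats"
  c("Before Quality Control",
    sprintf("  %-28s %s", "Sequences", num(ledger$before_qc$sequences)),
    sprintf("  %-28s %s", mu, num(ledger$before_qc$msats)),
    sprintf("  %-28s %s", paste("% with", mu),
            num(ledger$before_qc$pct_with_msats)),
    "After Quality Control",
    unlist(lapply(c("low", "high"), function(t) {
      tr <- ledger$tracks[[t]]
      lab <- if (t == "low") "Low Stringency - consensus" else
        "High Stringency - singletons"
      c(lab,
        sprintf("  %-28s %s", "Sequences", num(tr$sequences_after_qc)),
        sprintf("  %-28s %s", mu, num(tr$candidates)),
        sprintf("  %-28s %s", paste(mu, "without RE"),
                num(tr$msat_without_re)),
        sprintf("  %-28s %s", "Primer pairs", num(tr$primer_pairs)))
    })),
    sprintf("%-30s %s", "Total primer pairs",
            num(ledger$total_primer_pairs)))
}
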