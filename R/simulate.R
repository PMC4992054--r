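#' Configuration of the synthetic RACE experiment generator
#'
#' Defines the study conditions emulated by the simulator: a panel of
#' lowly characterized multi-exon loci whose annotation hides terminal
#' structure, gene-specific RACE priming with off-target background, long
#' reads (~600 bp platform) with substitution errors, non-templated polyA
#' tails on 3' products, RACE adapters, and CAGE/polyA evidence tracks
#' with jitter and drop-out.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A `sim_config` list with fields:
#' * `seed`: integer seed; a fixed seed gives byte-identical outputs.
#' * `n_loci` (50), `n_offtarget_loci` (25): targeted loci and decoy loci
#'   that source off-target amplification.
#' * `transcripts_per_locus` (1-2), `exons_per_transcript` (3-6),
#'   `exon_len` (150-400 nt), `intron_len` (300-1500 nt), `locus_gap`
#'   (2000-4000 nt), `gc` (0.55): genome/annotation geometry.
#' * `truncation` (0.6): probability that each end (5', 3') of a target
#'   locus is hidden in the truncated "pre-RACE" annotation, planting a
#'   known extension truth.
#' * `on_target_frac`: named vector `c(standard = 0.039, nested =
#'   0.364)`, the observed on-target read proportions of the two priming
#'   strategies.
#' * `reads_per_target` (200): total reads generated per targeted locus
#'   (on-target with probability `on_target_frac[mode]`).
#' * `error_rate` (0.005): substitution rate on insert bases.
#' * `read_full_frac` (0.8): probability a RACE product runs through to
#'   the true transcript end.
#' * `tail_frac` (0.9), `tail_len_range` (20-45 nt): polyA tails on
#'   full-length 3' products (error-free; 20-nt tails are planted as
#'   below-threshold negatives).
#' * `adapter5`, `adapter3`: RACE adapter sequences; `adapter_frac`
#'   (0.85) of reads carry them.
#' * `lowq_frac` (0.15): fraction of adapter-bearing reads whose trailing
#'   bases get low phred scores, exercising quality trimming.
#' * `multimap_frac` (0.02): reads emitted with a secondary alignment.
#' * `cage_jitter` (5), `polya_jitter` (10), `evidence_dropout` (0.1):
#'   evidence-track noise; wrong-strand distractor tags are always
#'   included.
#' @export
sim_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_loci = 50L,
    n_offtarget_loci = 25L,
    transcripts_per_locus = c(1L, 2L),
    exons_per_transcript = c(3L, 6L),
    exon_len = c(150L, 400L),
    intron_len = c(300L, 1500L),
    locus_gap = c(2000L, 4000L),
    gc = 0.55,
    truncation = 0.6,
    on_target_frac = c(standard = 0.039, nested = 0.364),
    reads_per_target = 200L,
    error_rate = 0.005,
    read_full_frac = 0.8,
    tail_frac = 0.9,
    tail_len_range = c(20L, 45L),
    adapter5 = "CTAATACGACTCACTATAGGGCAAGCAGTGGTATCAACGCAGAGTACT",
    adapter3 = "CTAATACGACTCACTATAGGGCAAGCAGTGGTATCAACGCAGAGTACGCGGG",
    adapter_frac = 0.85,
    lowq_frac = 0.15,
    multimap_frac = 0.02,
    cage_jitter = 5L,
    polya_jitter = 10L,
    evidence_dropout = 0.1
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) abort("unknown sim_config field(s): %s", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  fr <- c("gc", "truncation", "error_rate", "read_full_frac", "tail_frac",
          "adapter_frac", "lowq_frac", "multimap_frac", "evidence_dropout")
  for (f in fr) if (cfg[[f]] < 0 || cfg[[f]] > 1)
    abort("sim_config field %s must lie in [0,1]", f)
  if (any(cfg$on_target_frac < 0 | cfg$on_target_frac > 1))
    abort("on_target_frac values must lie in [0,1]")
  structure(cfg, class = "sim_config")
}

rand_dna <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

rint <- function(range) if (range[1] >= range[2]) range[1] else
  sample(range[1]:range[2], 1L)

#' Simulate a reference genome with truth and truncated annotations
#'
#' Generates a random genome carrying multi-exon loci (targets and
#' decoys) with canonical splice sites planted at every intron, the full
#' "truth" annotation, and a truncated annotation in which, per
#' `cfg$truncation`, the terminal (transcription-order first and/or
#' last) exon of target loci is hidden — the situation of a gene with
#' poorly defined boundaries awaiting RACE. The hidden structure defines
#' a known extension truth for every locus end.
#'
#' @param cfg A [sim_config()].
#' @return List: `genome` ([Biostrings::DNAStringSet]), `truth` and
#'   `annotated` ([race_annotation()]s; `annotated` is the truncated
#'   one), `target_ids` (gene ids of targeted loci), and `loci_truth`, a
#'   data frame per target locus end with the planted signed extension
#'   lengths (`ext5_signed` <= 0, `ext3_signed` >= 0; 0 = not truncated).
#' @export
simulate_reference <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  n_all <- cfg$n_loci + cfg$n_offtarget_loci
  per_chrom <- 10L
  chrom_of <- function(i) sprintf("chr%d", (i - 1L) %/% per_chrom + 1L)
  exon_rows <- list(); chrom_seqs <- list(); cursor <- list()
  loci_meta <- list()
  is_target <- rep(c(TRUE, FALSE), c(cfg$n_loci, cfg$n_offtarget_loci))
  is_target <- sample(is_target)  # interleave targets and decoys
  t_ct <- 0L; o_ct <- 0L
  for (i in seq_len(max(n_all, 0L))) {
    chrom <- chrom_of(i)
    if (is.null(cursor[[chrom]])) {
      cursor[[chrom]] <- 0L
      chrom_seqs[[chrom]] <- character()
    }
    gap <- rint(cfg$locus_gap)
    n_ex <- rint(cfg$exons_per_transcript)
    ex_len <- vapply(seq_len(n_ex), function(x) rint(cfg$exon_len), integer(1))
    in_len <- if (n_ex > 1)
      vapply(seq_len(n_ex - 1L), function(x) rint(cfg$intron_len), integer(1))
    else integer()
    strand <- sample(c("+", "-"), 1L)
    start <- cursor[[chrom]] + gap
    ex_start <- start + cumsum(c(0L, head(ex_len, -1L) + in_len))
    ex_end <- ex_start + ex_len
    locus_len <- max(ex_end) - start
    seq <- chars(rand_dna(gap + locus_len, cfg$gc))
    # plant canonical splice dinucleotides at intron boundaries
    if (n_ex > 1) {
      istart <- ex_end[-n_ex] - start + gap   # 1-based offsets into seq
      iend <- ex_start[-1] - start + gap
      for (j in seq_along(istart)) {
        if (strand == "+") {
          seq[istart[j] + 1:2] <- c("G", "T")
          seq[iend[j] - 1:0] <- c("G", "A")[2:1]
        } else {
          seq[istart[j] + 1:2] <- c("C", "T")
          seq[iend[j] - 1:0] <- c("C", "A")[2:1]
        }
      }
    }
    chrom_seqs[[chrom]] <- c(chrom_seqs[[chrom]], seq)
    cursor[[chrom]] <- cursor[[chrom]] + gap + locus_len
    if (is_target[i]) { t_ct <- t_ct + 1L; gid <- sprintf("TGT%04d", t_ct) }
    else { o_ct <- o_ct + 1L; gid <- sprintf("OFF%04d", o_ct) }
    loci_meta[[gid]] <- list(gene_id = gid, chrom = chrom, strand = strand,
                             ex_start = ex_start, ex_end = ex_end,
                             target = is_target[i])
  }
  if (!length(chrom_seqs)) {
    # no loci requested: still emit a genome so sequence-level code runs
    genome <- Biostrings::DNAStringSet(c(chr1 = rand_dna(5000L, cfg$gc)))
  } else {
    genome <- Biostrings::DNAStringSet(vapply(chrom_seqs, paste0,
                                              character(1), collapse = ""))
    names(genome) <- names(chrom_seqs)
  }
  truth_rows <- list(); trunc_rows <- list(); truth_tab <- list()
  for (gid in names(loci_meta)) {
    m <- loci_meta[[gid]]
    n_ex <- length(m$ex_start)
    n_tx <- rint(cfg$transcripts_per_locus)
    tx_defs <- list(seq_len(n_ex))
    if (n_tx > 1L && n_ex >= 3L) {
      skip <- rint(c(2L, n_ex - 1L))
      tx_defs[[2]] <- setdiff(seq_len(n_ex), skip)
    }
    trunc5 <- m$target && runif(1) < cfg$truncation
    trunc3 <- m$target && runif(1) < cfg$truncation
    # transcription-order first exon is the genomic last on '-'
    drop_idx <- integer()
    if (trunc5) drop_idx <- c(drop_idx, if (m$strand == "+") 1L else n_ex)
    if (trunc3) drop_idx <- c(drop_idx, if (m$strand == "+") n_ex else 1L)
    kept_idx <- list()
    for (ti in seq_along(tx_defs)) {
      keep <- tx_defs[[ti]]
      tid <- sprintf("%s.t%d", gid, ti)
      truth_rows[[tid]] <- data.frame(
        chrom = m$chrom, start = m$ex_start[keep], end = m$ex_end[keep],
        strand = m$strand, transcript_id = tid, gene_id = gid,
        stringsAsFactors = FALSE)
      keep2 <- setdiff(keep, drop_idx)
      # a transcript whose exons all fall in the hidden set keeps an
      # internal exon so the truncated annotation is never empty
      if (!length(keep2)) keep2 <- keep[ceiling(length(keep) / 2)]
      kept_idx[[ti]] <- keep2
      trunc_rows[[tid]] <- data.frame(
        chrom = m$chrom, start = m$ex_start[keep2], end = m$ex_end[keep2],
        strand = m$strand, transcript_id = tid, gene_id = gid,
        stringsAsFactors = FALSE)
    }
    if (m$target) {
      # planted truth from the exons *actually* kept, so the signed
      # extension is exactly (truth extreme - truncated extreme)
      keep_all <- sort(unique(unlist(kept_idx)))
      span5 <- if (m$strand == "+") min(m$ex_start) else max(m$ex_end) - 1L
      t5 <- if (m$strand == "+") min(m$ex_start[keep_all]) else
        max(m$ex_end[keep_all]) - 1L
      span3 <- if (m$strand == "+") max(m$ex_end) - 1L else min(m$ex_start)
      t3 <- if (m$strand == "+") max(m$ex_end[keep_all]) - 1L else
        min(m$ex_start[keep_all])
      real5 <- trunc5 && t5 != span5
      real3 <- trunc3 && t3 != span3
      truth_tab[[gid]] <- data.frame(
        gene_id = gid, chrom = m$chrom, strand = m$strand,
        truncated5 = real5, truncated3 = real3,
        ext5_signed = if (real5) -abs(span5 - t5) else 0L,
        ext3_signed = if (real3) abs(span3 - t3) else 0L,
        stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth_rows))
    validate_annotation(do.call(rbind, unname(truth_rows))) else
    race_annotation()
  annotated <- if (length(trunc_rows))
    validate_annotation(do.call(rbind, unname(trunc_rows))) else
    race_annotation()
  loci_truth <- do.call(rbind, unname(truth_tab)) %||%
    data.frame(gene_id = character(), chrom = character(),
               strand = character(), truncated5 = logical(),
               truncated3 = logical(), ext5_signed = integer(),
               ext3_signed = integer(), stringsAsFactors = FALSE)
  rownames(loci_truth) <- NULL
  list(genome = genome, truth = truth, annotated = annotated,
       target_ids = grep("^TGT", names(loci_meta), value = TRUE),
       loci_truth = loci_truth)
}

# pick primers for simulation: designed outer/nested where possible,
# otherwise a fallback annealing window so every target can be primed.
sim_primer_panel <- function(ref, cfg = sim_config(),
                             design_cfg = race_config()) {
  ann <- ref$annotated
  tt <- transcripts_table(ann)
  target_tx <- tt$transcript_id[grepl("^TGT", tt$gene_id) &
                                  grepl("\\.t1$", tt$transcript_id)]
  manifest <- design_race_primers(ann, ref$genome, target_ids = target_tx,
                                  cfg = design_cfg, mask = TRUE)
  seqs <- transcript_sequences(ann, ref$genome)
  rows <- list(manifest)
  for (tx in target_tx) {
    for (dir in c("5prime", "3prime")) {
      have <- manifest$target_transcript == tx & manifest$direction == dir
      if (any(have & manifest$role == "outer")) next
      # fallback: mid-transcript window, kept regardless of thermodynamics
      L <- nchar(seqs[[tx]])
      k <- design_cfg$primer_len_opt
      s <- max(0L, L %/% 2L - k %/% 2L)
      win <- substr(seqs[[tx]], s + 1L, s + k)
      oligo <- if (dir == "5prime") revcomp(win) else win
      rows[[length(rows) + 1L]] <- data.frame(
        primer_id = sprintf("%s_%s_fallback", tx, dir),
        target_transcript = tx, direction = dir, role = "outer",
        sequence = oligo, tm = melting_temperature(oligo),
        gc = gc_fraction(oligo), t_start = s, t_end = s + k,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# genomic blocks covered by transcript interval [a, b) (0-based spliced
# coordinates); returns data.frame(start, end) sorted genomically.
transcript_interval_to_blocks <- function(ex, a, b) {
  strand <- ex$strand[1]
  ord <- if (strand == "-") order(ex$start, decreasing = TRUE) else order(ex$start)
  lens <- (ex$end - ex$start)[ord]
  offs <- cumsum(c(0L, lens))
  out <- list()
  for (i in seq_along(ord)) {
    lo <- max(a, offs[i]); hi <- min(b, offs[i + 1L])
    if (lo >= hi) next
    e <- ord[i]
    if (strand == "+") {
      gs <- ex$start[e] + (lo - offs[i]); ge <- ex$start[e] + (hi - offs[i])
    } else {
      ge <- ex$end[e] - (lo - offs[i]); gs <- ex$end[e] - (hi - offs[i])
    }
    out[[length(out) + 1L]] <- c(gs, ge)
  }
  m <- do.call(rbind, out)
  m <- m[order(m[, 1]), , drop = FALSE]
  data.frame(start = m[, 1], end = m[, 2])
}

add_substitutions <- function(seq, rate) {
  if (rate <= 0 || !nchar(seq)) return(seq)
  b <- chars(seq)
  hit <- which(runif(length(b)) < rate)
  for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
  paste(b, collapse = "")
}

sam_cigar <- function(blocks, left_clip, right_clip) {
  parts <- character()
  if (left_clip > 0) parts <- c(parts, sprintf("%dS", left_clip))
  for (i in seq_len(nrow(blocks))) {
    if (i > 1) parts <- c(parts, sprintf("%dN", blocks$start[i] - blocks$end[i - 1L]))
    parts <- c(parts, sprintf("%dM", blocks$end[i] - blocks$start[i]))
  }
  if (right_clip > 0) parts <- c(parts, sprintf("%dS", right_clip))
  paste(parts, collapse = "")
}

#' Simulate RACE reads with alignments and a truth ledger
#'
#' Generates the read output of one RACE experiment (standard or nested
#' priming) against the simulated reference: each read is on-target with
#' probability `cfg$on_target_frac[mode]`; on-target reads start at their
#' originating primer and run toward the true transcript end (fully, with
#' probability `cfg$read_full_frac`); full 3' products carry non-templated
#' polyA tails followed by the 3' adapter; off-target reads are drawn
#' from decoy loci. Substitution errors are applied to insert bases.
#' Alongside the FASTQ, pre-computed spliced alignments of the
#' adapter-free reads are emitted as SAM (the simulator knows the true
#' placements, including soft clips for tails), keeping the downstream
#' pipeline free of external aligners.
#'
#' @param ref Output of [simulate_reference()].
#' @param primers Primer panel from [sim_primer_panel()] (or any manifest
#'   with genomic footprints resolvable against `ref$annotated`).
#' @param cfg A [sim_config()].
#' @param mode `"nested"` or `"standard"`.
#' @return List with `reads` (FASTQ-style data frame), `sam_lines`
#'   (character vector, header included) and `ledger` (one row per read:
#'   origin, locus, direction, tail and adapter truth).
#' @export
simulate_race_reads <- function(ref, primers, cfg = sim_config(),
                                mode = c("nested", "standard")) {
  mode <- match.arg(mode)
  set.seed(cfg$seed + if (mode == "nested") 101L else 202L)
  p_on <- unname(cfg$on_target_frac[mode])
  truth_tt <- transcripts_table(ref$truth)
  truth_seqs <- transcript_sequences(ref$truth, ref$genome)
  decoy_tx <- truth_tt$transcript_id[grepl("^OFF", truth_tt$gene_id)]
  role_wanted <- if (mode == "nested") "nested" else "outer"
  pick_primer <- function(tx, dir) {
    sel <- primers$target_transcript == tx & primers$direction == dir
    cand <- primers[sel & primers$role == role_wanted, , drop = FALSE]
    if (!nrow(cand)) cand <- primers[sel & primers$role == "outer", , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    cand[1, ]
  }
  n_max <- length(ref$target_ids) * cfg$reads_per_target
  v <- list(read_id = character(n_max), seq = character(n_max),
            qual = character(n_max), origin = character(n_max),
            gene_id = character(n_max), transcript_id = character(n_max),
            direction = character(n_max), on_target = logical(n_max),
            full_length = logical(n_max), insert_len = integer(n_max),
            tail_len = integer(n_max), adapter = logical(n_max),
            lowq_tail = logical(n_max), multimap = logical(n_max),
            clean_len = integer(n_max))
  sam <- character(2L * n_max); n_sam <- 0L
  qual_hi <- function(n) intToUtf8(sample(30:40, n, TRUE) + 33L)
  n_id <- 0L
  for (gid in ref$target_ids) {
    tx <- sprintf("%s.t1", gid)
    ex_tr <- ref$annotated[ref$annotated$transcript_id == tx, , drop = FALSE]
    ex_truth <- ref$truth[ref$truth$transcript_id == tx, , drop = FALSE]
    Lt <- sum(ex_truth$end - ex_truth$start)
    tseq <- truth_seqs[[tx]]
    # primer transcript coordinates on the *truth* transcript
    pcoord <- list()
    for (dir in c("5prime", "3prime")) {
      pr <- pick_primer(tx, dir)
      if (is.null(pr)) next
      g <- transcript_to_genomic(ex_tr, c(pr$t_start, pr$t_end - 1L))
      tc <- genomic_to_transcript(ex_truth, g)
      if (anyNA(tc)) next
      pcoord[[dir]] <- list(id = pr$primer_id, lo = min(tc), hi = max(tc) + 1L)
    }
    if (!length(pcoord)) next
    for (r in seq_len(cfg$reads_per_target)) {
      n_id <- n_id + 1L
      rid <- sprintf("%s_%s_%06d", mode, gid, n_id)
      on <- runif(1) < p_on
      if (on) {
        dir <- sample(names(pcoord), 1L)
        pc <- pcoord[[dir]]
        if (dir == "3prime") {
          Lp <- Lt - pc$lo
          full <- runif(1) < cfg$read_full_frac
          len <- if (full) Lp else max(100L, rint(c(100L, max(100L, Lp - 1L))))
          len <- min(len, Lp)
          full <- len == Lp
          a <- pc$lo; b <- pc$lo + len
        } else {
          Lp <- pc$hi
          full <- runif(1) < cfg$read_full_frac
          len <- if (full) Lp else max(100L, rint(c(100L, max(100L, Lp - 1L))))
          len <- min(len, Lp)
          full <- len == Lp
          a <- pc$hi - len; b <- pc$hi
        }
        insert <- add_substitutions(substr(tseq, a + 1L, b), cfg$error_rate)
        tail_len <- 0L
        if (dir == "3prime" && full && runif(1) < cfg$tail_frac)
          tail_len <- rint(cfg$tail_len_range)
        tail_seq <- strrep("A", tail_len)
        src_ex <- ex_truth; src_tx <- tx; src_gid <- gid
      } else {
        dir <- NA_character_
        src_tx <- sample(decoy_tx, 1L)
        src_ex <- ref$truth[ref$truth$transcript_id == src_tx, , drop = FALSE]
        src_gid <- src_ex$gene_id[1]
        Ls <- sum(src_ex$end - src_ex$start)
        len <- min(Ls, rint(c(150L, 600L)))
        a <- rint(c(0L, Ls - len)); b <- a + len
        insert <- add_substitutions(
          substr(truth_seqs[[src_tx]], a + 1L, b), cfg$error_rate)
        tail_len <- 0L; tail_seq <- ""; full <- FALSE
      }
      use_ad <- runif(1) < cfg$adapter_frac
      fastq_seq <- paste0(if (use_ad) cfg$adapter5 else "", insert, tail_seq,
                          if (use_ad) cfg$adapter3 else "")
      q <- qual_hi(nchar(fastq_seq))
      lowq <- use_ad && runif(1) < cfg$lowq_frac
      if (lowq) {
        nl <- rint(c(5L, 15L))
        q <- paste0(substr(q, 1L, nchar(q) - nl),
                    intToUtf8(sample(2:12, nl, TRUE) + 33L))
      }
      # SAM: adapter-free read (insert + tail), spliced over the source
      blocks <- transcript_interval_to_blocks(src_ex, a, b)
      strand <- src_ex$strand[1]
      aligned <- paste0(insert, tail_seq)
      if (strand == "-") {
        sam_seq <- revcomp(aligned)
        lclip <- tail_len; rclip <- 0L; flag <- 16L
      } else {
        sam_seq <- aligned
        lclip <- 0L; rclip <- tail_len; flag <- 0L
      }
      multi <- runif(1) < cfg$multimap_frac
      nh <- if (multi) 2L else 1L
      n_sam <- n_sam + 1L
      sam[n_sam] <- sprintf(
        "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tNH:i:%d",
        rid, flag, src_ex$chrom[1], blocks$start[1] + 1L,
        if (multi) 3L else 60L,
        sam_cigar(blocks, lclip, rclip), sam_seq, nh)
      if (multi) {
        # a decoy secondary alignment elsewhere, unspliced
        n_sam <- n_sam + 1L
        sam[n_sam] <- sprintf(
          "%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*\tNH:i:%d",
          rid, flag + 256L, src_ex$chrom[1],
          max(1L, blocks$start[1] - 5000L), 0L, nchar(aligned) - lclip - rclip,
          nh)
      }
      v$read_id[n_id] <- rid; v$seq[n_id] <- fastq_seq; v$qual[n_id] <- q
      v$origin[n_id] <- if (on) "target" else "offtarget"
      v$gene_id[n_id] <- src_gid; v$transcript_id[n_id] <- src_tx
      v$direction[n_id] <- if (on) dir else NA_character_
      v$on_target[n_id] <- on; v$full_length[n_id] <- full
      v$insert_len[n_id] <- nchar(insert); v$tail_len[n_id] <- tail_len
      v$adapter[n_id] <- use_ad; v$lowq_tail[n_id] <- lowq
      v$multimap[n_id] <- multi
      v$clean_len[n_id] <- nchar(insert) + tail_len
    }
  }
  keep <- seq_len(n_id)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(ref$genome),
                      Biostrings::width(ref$genome)))
  list(reads = data.frame(read_id = v$read_id[keep], seq = v$seq[keep],
                          qual = v$qual[keep], stringsAsFactors = FALSE),
       sam_lines = c(header, sam[seq_len(n_sam)]),
       ledger = data.frame(read_id = v$read_id[keep], mode = mode,
                           origin = v$origin[keep],
                           gene_id = v$gene_id[keep],
                           transcript_id = v$transcript_id[keep],
                           direction = v$direction[keep],
                           on_target = v$on_target[keep],
                           full_length = v$full_length[keep],
                           insert_len = v$insert_len[keep],
                           tail_len = v$tail_len[keep],
                           adapter = v$adapter[keep],
                           lowq_tail = v$lowq_tail[keep],
                           multimap = v$multimap[keep],
                           clean_len = v$clean_len[keep],
                           stringsAsFactors = FALSE))
}

#' Simulate CAGE and polyA evidence tracks
#'
#' Places tags at the true TSS (CAGE) and TTS (polyA) of targeted loci
#' with configurable jitter and drop-out, plus a wrong-strand distractor
#' tag per site so that stranded support rules are exercised.
#'
#' @param ref Output of [simulate_reference()].
#' @param cfg A [sim_config()].
#' @return List with `cage` and `polya` [point_features()] tables.
#' @export
simulate_evidence <- function(ref, cfg = sim_config()) {
  set.seed(cfg$seed + 303L)
  tt <- transcripts_table(ref$truth)
  tt <- tt[grepl("^TGT", tt$gene_id), , drop = FALSE]
  mk <- function(pos, jitter, label) {
    keep <- runif(nrow(tt)) >= cfg$evidence_dropout
    jit <- if (jitter > 0) sample(seq(-jitter, jitter), nrow(tt), TRUE) else
      rep(0L, nrow(tt))
    real <- point_features(tt$chrom[keep], pmax(0L, pos[keep] + jit[keep]),
                           tt$strand[keep], source = label)
    flip <- ifelse(tt$strand == "+", "-", "+")
    distract <- point_features(tt$chrom, pos + 500L, flip,
                               source = paste0(label, "_distractor"))
    rbind(real, distract)
  }
  list(cage = mk(tt$tss, cfg$cage_jitter, "CAGE"),
       polya = mk(tt$tts, cfg$polya_jitter, "polyA"))
}

#' Run the full simulator and write a fixture directory
#'
#' Produces `genome.fa`, `truth.gtf`, `annotated.gtf`, `primers.tsv`,
#' `reads.fastq`, `reads.sam`, `cage.bed`, `polya.bed`, `ledger.tsv` and
#' `loci_truth.tsv` under `dir`.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if missing).
#' @param mode Read-generation mode, `"nested"` or `"standard"`.
#' @return Invisibly, a list with all in-memory simulation objects and
#'   file paths.
#' @export
simulate_experiment <- function(cfg = sim_config(), dir = tempfile("racefix"),
                                mode = "nested") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulate_reference(cfg)
  primers <- sim_primer_panel(ref, cfg)
  rd <- simulate_race_reads(ref, primers, cfg, mode)
  ev <- simulate_evidence(ref, cfg)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    truth = file.path(dir, "truth.gtf"),
    annotated = file.path(dir, "annotated.gtf"),
    primers = file.path(dir, "primers.tsv"),
    fastq = file.path(dir, "reads.fastq"),
    sam = file.path(dir, "reads.sam"),
    cage = file.path(dir, "cage.bed"),
    polya = file.path(dir, "polya.bed"),
    ledger = file.path(dir, "ledger.tsv"),
    loci_truth = file.path(dir, "loci_truth.tsv"))
  Biostrings::writeXStringSet(ref$genome, paths$genome)
  write_gtf(ref$truth, paths$truth)
  write_gtf(ref$annotated, paths$annotated)
  write_primer_manifest(primers, paths$primers)
  write_fastq(rd$reads, paths$fastq)
  writeLines(rd$sam_lines, paths$sam)
  write_bed_points(ev$cage, paths$cage)
  write_bed_points(ev$polya, paths$polya)
  write.table(rd$ledger, paths$ledger, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(ref$loci_truth, paths$loci_truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(ref, list(primers = primers, reads = rd$reads,
                        sam_lines = rd$sam_lines, ledger = rd$ledger,
                        cage = ev$cage, polya = ev$polya, paths = paths,
                        mode = mode, cfg = cfg)))
}
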