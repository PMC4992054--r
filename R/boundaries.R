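# distance from a point to the nearest base of a footprint [start, end)
footprint_dist <- function(pos, start, end) {
  ifelse(pos >= start & pos <= end - 1L, 0L,
         pmin(abs(pos - start), abs(pos - (end - 1L))))
}

#' Assign the originating RACE direction to transcripts
#'
#' A transcript is labelled a 5' RACE product when it extends its
#' annotated locus further 5', or when its 3' end lies within
#' `cfg$primer_proximity` (50) bp of a 5' RACE primer footprint on the
#' opposite strand (5' RACE products are anchored at their originating
#' primer at the 3' end). The 3' rule is symmetric, with the primer on
#' the same strand. Transcripts firing both rules are `both`; neither,
#' `unassigned`.
#'
#' @param post_tt Per-transcript table ([transcripts_table()]) of the
#'   post-RACE transcript models, with `gene_id` naming the originating
#'   annotated locus.
#' @param pre_spans Locus spans ([locus_spans()]) of the pre-RACE
#'   annotation.
#' @param primer_sites Genomic primer footprints
#'   ([primer_genomic_sites()]).
#' @param cfg A [race_config()].
#' @return Data frame: `transcript_id`, `call` in
#'   `{five_prime_product, three_prime_product, both, unassigned}`.
#' @export
assign_race_direction <- function(post_tt, pre_spans, primer_sites,
                                  cfg = race_config()) {
  loc <- pre_spans[match(post_tt$gene_id, pre_spans$gene_id), , drop = FALSE]
  calls <- vapply(seq_len(nrow(post_tt)), function(i) {
    t <- post_tt[i, ]
    have_locus <- !is.na(loc$gene_id[i])
    if (have_locus &&
        (loc$chrom[i] != t$chrom || loc$strand[i] != t$strand))
      abort("transcript %s is not on its locus' chromosome/strand",
            t$transcript_id)
    ext5 <- have_locus && (
      if (t$strand == "+") t$tss < loc$start[i] else t$tss > loc$end[i] - 1L)
    ext3 <- have_locus && (
      if (t$strand == "+") t$tts > loc$end[i] - 1L else t$tts < loc$start[i])
    near <- function(pos, dir, opposite) {
      sel <- primer_sites$direction == dir & primer_sites$chrom == t$chrom &
        (if (opposite) primer_sites$strand != t$strand
         else primer_sites$strand == t$strand)
      if (!any(sel)) return(FALSE)
      any(footprint_dist(pos, primer_sites$start[sel],
                         primer_sites$end[sel]) <= cfg$primer_proximity)
    }
    five <- ext5 || near(t$tts, "5prime", opposite = TRUE)
    three <- ext3 || near(t$tss, "3prime", opposite = FALSE)
    if (five && three) "both"
    else if (five) "five_prime_product"
    else if (three) "three_prime_product"
    else "unassigned"
  }, character(1))
  data.frame(transcript_id = post_tt$transcript_id, call = calls,
             stringsAsFactors = FALSE)
}

#' Single-linkage clustering of transcript end sites
#'
#' Same-strand sites on one chromosome closer than the clustering gap
#' (51 bp for TSS, 151 bp for TTS; i.e. adjacent sorted sites merge when
#' their distance is strictly below the gap) join one cluster. The
#' representative is the 5'-most member on the transcription axis, a
#' conservative choice for downstream extension calls.
#'
#' @param sites A [point_features()] table of TSS or TTS positions.
#' @param site_type `"TSS"` or `"TTS"` (selects the gap from `cfg`).
#' @param cfg A [race_config()].
#' @param gap Override for the clustering gap.
#' @return Data frame of clusters: `site_type`, `chrom`, `strand`,
#'   `representative`, `n_members`, and `members` (list column of member
#'   positions, sorted).
#' @export
cluster_sites <- function(sites, site_type = c("TSS", "TTS"),
                          cfg = race_config(), gap = NULL) {
  site_type <- match.arg(site_type)
  gap <- gap %||% if (site_type == "TSS") cfg$tss_cluster_gap else
    cfg$tts_cluster_gap
  if (!nrow(sites)) {
    return(data.frame(site_type = character(), chrom = character(),
                      strand = character(), representative = integer(),
                      n_members = integer(), stringsAsFactors = FALSE))
  }
  sp <- split(seq_len(nrow(sites)), paste(sites$chrom, sites$strand, sep = "\r"))
  rows <- lapply(sp, function(idx) {
    pos <- sort(sites$position[idx])
    breaks <- which(diff(pos) >= gap)
    grp <- rep(seq_len(length(breaks) + 1L),
               diff(c(0L, breaks, length(pos))))
    strand <- sites$strand[idx[1]]
    members <- split(pos, grp)
    data.frame(site_type = site_type, chrom = sites$chrom[idx[1]],
               strand = strand,
               representative = vapply(members, function(m)
                 if (strand == "-") max(m) else min(m), numeric(1)),
               n_members = lengths(members),
               members = I(unname(members)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag clusters as novel relative to an annotated site set
#'
#' A cluster is novel when its representative lies farther than
#' `cfg$novelty_dist` (100) bp from every annotated site on the same
#' chromosome and strand; exactly 100 bp away is not novel.
#'
#' @param clusters Output of [cluster_sites()].
#' @param annotated A [point_features()] table of annotated sites (e.g.
#'   TSSs of the targeted pre-RACE transcripts).
#' @param cfg A [race_config()].
#' @return `clusters` with a logical `novel` column.
#' @export
classify_site_novelty <- function(clusters, annotated, cfg = race_config()) {
  clusters$novel <- vapply(seq_len(nrow(clusters)), function(i) {
    sel <- annotated$chrom == clusters$chrom[i] &
      annotated$strand == clusters$strand[i]
    if (!any(sel)) return(TRUE)
    min(abs(annotated$position[sel] - clusters$representative[i])) >
      cfg$novelty_dist
  }, logical(1))
  clusters
}

#' Tag clusters with evidence support
#'
#' A cluster is supported when an evidence tag lies within `window` bp of
#' the representative (inclusive on both sides) on the same strand.
#'
#' @param clusters Output of [cluster_sites()].
#' @param tags A [point_features()] table (CAGE tag 5' ends, polyA
#'   sites...).
#' @param window Support window in bp (50 for CAGE at TSS, 100 for polyA
#'   evidence at TTS).
#' @param same_strand Require matching strand (default `TRUE`).
#' @return `clusters` with a logical `supported` column.
#' @export
tag_support <- function(clusters, tags, window, same_strand = TRUE) {
  clusters$supported <- vapply(seq_len(nrow(clusters)), function(i) {
    sel <- tags$chrom == clusters$chrom[i] &
      (!same_strand | tags$strand == clusters$strand[i])
    any(abs(tags$position[sel] - clusters$representative[i]) <= window)
  }, logical(1))
  clusters
}

# longest tail run of `base` in an outward-oriented clip sequence,
# allowing cfg$tail_mismatch_frac mismatches and a start within
# cfg$tail_anchor_slop of the clip boundary. Returns 0 when none.
tail_run_length <- function(clip_outward, base, cfg) {
  b <- chars(toupper(clip_outward))
  n <- length(b)
  best <- 0L
  for (skip in 0:min(cfg$tail_anchor_slop, max(n - 1L, 0L))) {
    if (n - skip < cfg$tail_min_len) break
    sub <- b[(skip + 1L):n]
    mm <- cumsum(sub != base)
    L <- seq_along(sub)
    ok <- L >= cfg$tail_min_len & mm <= cfg$tail_mismatch_frac * L + 1e-9
    if (any(ok)) best <- max(best, max(L[ok]))
  }
  best
}

#' Infer polyA sites from non-templated read tails
#'
#' Mapped 3' RACE reads that run through a polyadenylation site carry a
#' non-templated stretch of As (or Ts, when the read was sequenced
#' antisense) in their terminal soft clip. A clip whose outward-facing
#' sequence starts (within `cfg$tail_anchor_slop` bases of the clip
#' boundary) with a run longer than 20 nt of >= 90% A (right clip; `+`
#' site at the last aligned base) or T (left clip; `-` site at the first
#' aligned base) yields a polyA site. Identical sites are merged with
#' read support summed.
#'
#' @param aln Alignments of 3' RACE reads (from [read_alignments()],
#'   unique-filtered).
#' @param cfg A [race_config()].
#' @return List with `sites` (deduplicated: `chrom`, `position`,
#'   `strand`, `supporting_reads`, `max_tail_length`) and `read_calls`
#'   (per-read detection table: `read_id`, `detected`, `tail_length`).
#' @export
infer_polya_sites <- function(aln, cfg = race_config()) {
  rows <- lapply(seq_len(nrow(aln)), function(i) {
    # right clip, A tail -> site on + at last aligned base
    lenA <- if (nzchar(aln$clip_right[i]))
      tail_run_length(aln$clip_right[i], "A", cfg) else 0L
    # left clip, T head -> site on - at first aligned base
    lenT <- if (nzchar(aln$clip_left[i]))
      tail_run_length(rev_string(aln$clip_left[i]), "T", cfg) else 0L
    if (lenA >= lenT && lenA > 0L) {
      data.frame(read_id = aln$read_id[i], chrom = aln$chrom[i],
                 position = max(aln$block_ends[[i]]) - 1L, strand = "+",
                 tail_length = lenA, stringsAsFactors = FALSE)
    } else if (lenT > 0L) {
      data.frame(read_id = aln$read_id[i], chrom = aln$chrom[i],
                 position = min(aln$block_starts[[i]]), strand = "-",
                 tail_length = lenT, stringsAsFactors = FALSE)
    } else {
      data.frame(read_id = aln$read_id[i], chrom = NA_character_,
                 position = NA_integer_, strand = NA_character_,
                 tail_length = 0L, stringsAsFactors = FALSE)
    }
  })
  calls <- do.call(rbind, rows)
  if (is.null(calls)) {
    calls <- data.frame(read_id = character(), chrom = character(),
                        position = integer(), strand = character(),
                        tail_length = integer(), stringsAsFactors = FALSE)
  }
  calls$detected <- calls$tail_length > 0L
  det <- calls[calls$detected, , drop = FALSE]
  if (nrow(det)) {
    key <- paste(det$chrom, det$position, det$strand, sep = "\r")
    sp <- split(seq_len(nrow(det)), key)
    sites <- do.call(rbind, lapply(sp, function(idx) {
      data.frame(chrom = det$chrom[idx[1]], position = det$position[idx[1]],
                 strand = det$strand[idx[1]], supporting_reads = length(idx),
                 max_tail_length = max(det$tail_length[idx]),
                 stringsAsFactors = FALSE)
    }))
    sites <- sites[order(sites$chrom, sites$position), , drop = FALSE]
    rownames(sites) <- NULL
  } else {
    sites <- data.frame(chrom = character(), position = integer(),
                        strand = character(), supporting_reads = integer(),
                        max_tail_length = integer(), stringsAsFactors = FALSE)
  }
  rownames(calls) <- NULL
  list(sites = sites, read_calls = calls)
}

#' Label locus extensions from post-RACE transcript ends
#'
#' For each annotated locus, the 5' ends of its 5' RACE product models
#' are compared with the locus' annotated 5' extreme, and the 3' ends of
#' its 3' RACE products with the 3' extreme. Signed lengths follow the
#' transcription axis: negative values are novel TSSs upstream of the
#' annotated locus, positive values novel TTSs downstream. A locus end
#' is `extending` when the new end lies strictly beyond the annotated
#' extreme.
#'
#' @param pre_spans Locus spans of the pre-RACE annotation.
#' @param post_tt [transcripts_table()] of post-RACE models with
#'   `gene_id` giving the originating locus.
#' @param direction_calls Output of [assign_race_direction()].
#' @return Data frame: `gene_id`, `end` (`five_prime`/`three_prime`),
#'   `signed_length` (NA when no product of that class exists) and
#'   `extending`.
#' @export
label_locus_extension <- function(pre_spans, post_tt, direction_calls) {
  post_tt$call <- direction_calls$call[match(post_tt$transcript_id,
                                             direction_calls$transcript_id)]
  rows <- lapply(seq_len(nrow(pre_spans)), function(i) {
    loc <- pre_spans[i, ]
    mine <- post_tt[!is.na(post_tt$gene_id) & post_tt$gene_id == loc$gene_id, ,
                    drop = FALSE]
    if (nrow(mine) && any(mine$chrom != loc$chrom | mine$strand != loc$strand))
      abort("locus %s has assigned transcripts on another chromosome/strand",
            loc$gene_id)
    old5 <- if (loc$strand == "+") loc$start else loc$end - 1L
    old3 <- if (loc$strand == "+") loc$end - 1L else loc$start
    p5 <- mine[mine$call %in% c("five_prime_product", "both"), , drop = FALSE]
    p3 <- mine[mine$call %in% c("three_prime_product", "both"), , drop = FALSE]
    sgn <- function(new, old) if (loc$strand == "+") new - old else old - new
    new5 <- if (nrow(p5)) {
      if (loc$strand == "+") min(p5$tss) else max(p5$tss)
    } else NA_integer_
    new3 <- if (nrow(p3)) {
      if (loc$strand == "+") max(p3$tts) else min(p3$tts)
    } else NA_integer_
    s5 <- if (is.na(new5)) NA_real_ else sgn(new5, old5)
    s3 <- if (is.na(new3)) NA_real_ else sgn(new3, old3)
    data.frame(gene_id = loc$gene_id,
               end = c("five_prime", "three_prime"),
               signed_length = c(s5, s3),
               extending = c(!is.na(s5) && s5 < 0, !is.na(s3) && s3 > 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Merge loci bridged by novel transcripts
#'
#' Annotated loci connected by a new transcript with same-strand exonic
#' overlap to two or more of them are unioned into a single locus
#' (transitively). New transcripts inherit the (possibly merged) locus
#' they overlap, or found a new locus of their own.
#'
#' @param ann Pre-RACE [race_annotation()].
#' @param new_tx [race_annotation()] of novel transcript models.
#' @return List with `annotation` (combined annotation with updated
#'   `gene_id`s) and `log`, a data frame mapping old locus ids to merged
#'   ids.
#' @export
merge_loci <- function(ann, new_tx) {
  uni <- exonic_union(ann, by = "gene_id")
  genes <- unique(ann$gene_id)
  parent <- seq_along(genes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  overlaps_of <- function(ex) {
    hit <- character(0)
    if (nrow(uni)) {
      for (j in seq_len(nrow(ex))) {
        sel <- uni$chrom == ex$chrom[j] & uni$strand == ex$strand[j] &
          uni$start < ex$end[j] & uni$end > ex$start[j]
        hit <- c(hit, uni$gene_id[sel])
      }
    }
    unique(hit)
  }
  tx_hits <- list()
  for (tx in unique(new_tx$transcript_id)) {
    ex <- new_tx[new_tx$transcript_id == tx, , drop = FALSE]
    hits <- overlaps_of(ex)
    tx_hits[[tx]] <- hits
    if (length(hits) >= 2L) {
      idx <- match(hits, genes)
      for (k in idx[-1]) {
        ra <- find(idx[1]); rb <- find(k)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_along(genes), find, numeric(1))
  merged_id <- vapply(seq_along(genes), function(i) {
    members <- sort(genes[roots == roots[i]])
    if (length(members) == 1L) genes[i] else paste(members, collapse = "+")
  }, character(1))
  names(merged_id) <- genes
  log <- data.frame(old_id = genes, new_id = unname(merged_id),
                    stringsAsFactors = FALSE)
  log <- log[log$old_id != log$new_id, , drop = FALSE]
  out_pre <- ann
  out_pre$gene_id <- unname(merged_id[ann$gene_id])
  out_new <- new_tx
  novel_counter <- 0L
  for (tx in unique(new_tx$transcript_id)) {
    hits <- tx_hits[[tx]]
    gid <- if (length(hits)) unname(merged_id[hits[1]]) else {
      novel_counter <- novel_counter + 1L
      sprintf("novel_locus_%04d", novel_counter)
    }
    out_new$gene_id[out_new$transcript_id == tx] <- gid
  }
  combined <- validate_annotation(rbind(as.data.frame(out_pre),
                                        as.data.frame(out_new)))
  list(annotation = combined, log = log)
}

#' Collapse aligned reads into transcript models
#'
#' Automated stand-in for manual curation: unique-filtered spliced reads
#' sharing an identical intron chain are collapsed into one model whose
#' terminal exons span the widest member; single-exon reads are collapsed
#' by overlap. Model strand is taken from the majority splice-motif
#' orientation of the chain (single-exon models are unstranded).
#'
#' @param aln Unique-filtered alignments.
#' @param genome Genome, for splice-motif strand assignment.
#' @param cfg A [race_config()].
#' @param obs Optional precomputed per-read junction table from
#'   [infer_introns()] (avoids recomputing it when the caller already
#'   has one).
#' @return A [race_annotation()] of models (placeholder `gene_id`s,
#'   replaced by locus assignment downstream), with the member read ids
#'   attached as attribute `"members"` (a named list).
#' @export
collapse_reads_to_models <- function(aln, genome, cfg = race_config(),
                                     obs = NULL) {
  if (!nrow(aln)) return(race_annotation())
  genome <- load_genome(genome)
  if (is.null(obs)) obs <- infer_introns(aln, genome, cfg)
  intron_chain <- setNames(rep("", nrow(aln)), aln$read_id)
  chain_strand <- character()
  if (nrow(obs)) {
    obs <- obs[order(obs$read_id, obs$start), , drop = FALSE]
    sp <- split(seq_len(nrow(obs)), obs$read_id)
    chains <- vapply(sp, function(idx) {
      paste(obs$chrom[idx[1]],
            paste(obs$start[idx], obs$end[idx], sep = "-", collapse = ","),
            sep = ":")
    }, character(1))
    intron_chain[names(chains)] <- chains
    # majority motif-orientation strand per chain
    for (ch in unique(chains)) {
      st <- obs$strand[unlist(sp[chains == ch], use.names = FALSE)]
      tb <- sort(table(st), decreasing = TRUE)
      chain_strand[ch] <- names(tb)[1]
    }
  }
  spliced <- aln[intron_chain[aln$read_id] != "", , drop = FALSE]
  single <- aln[intron_chain[aln$read_id] == "", , drop = FALSE]
  models <- list()
  members <- list()
  mk_id <- function() sprintf("model_%05d", length(models) + 1L)
  # multi-exon: group by chrom + intron chain
  if (nrow(spliced)) {
    grp <- split(seq_len(nrow(spliced)),
                 paste(spliced$chrom, intron_chain[spliced$read_id]))
    sp_start1 <- vapply(spliced$block_starts, min, numeric(1))
    sp_endN <- vapply(spliced$block_ends, max, numeric(1))
    for (idx in grp) {
      chrom <- spliced$chrom[idx[1]]
      chain <- intron_chain[spliced$read_id[idx[1]]]
      strand <- chain_strand[[chain]]
      span_start <- min(sp_start1[idx])
      span_end <- max(sp_endN[idx])
      introns <- do.call(rbind, lapply(
        strsplit(sub("^[^:]*:", "", chain), ",")[[1]],
        function(p) as.integer(strsplit(p, "-")[[1]])))
      introns <- introns[order(introns[, 1]), , drop = FALSE]
      ex_start <- c(span_start, introns[, 2])
      ex_end <- c(introns[, 1], span_end)
      id <- mk_id()
      models[[id]] <- data.frame(chrom = chrom, start = ex_start,
                                 end = ex_end, strand = strand,
                                 transcript_id = id, gene_id = id,
                                 stringsAsFactors = FALSE)
      members[[id]] <- spliced$read_id[idx]
    }
  }
  # single-exon: overlap clusters per chromosome
  if (nrow(single)) {
    for (chrom in unique(single$chrom)) {
      sel <- which(single$chrom == chrom)
      ir <- IRanges::IRanges(
        vapply(sel, function(i) min(single$block_starts[[i]]), numeric(1)) + 1L,
        vapply(sel, function(i) max(single$block_ends[[i]]), numeric(1)))
      red <- IRanges::reduce(ir)
      hit <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red))
      for (g in unique(hit)) {
        idx <- sel[hit == g]
        id <- mk_id()
        models[[id]] <- data.frame(
          chrom = chrom,
          start = IRanges::start(red)[g] - 1L, end = IRanges::end(red)[g],
          strand = "*", transcript_id = id, gene_id = id,
          stringsAsFactors = FALSE)
        members[[id]] <- single$read_id[idx]
      }
    }
  }
  out <- validate_annotation(do.call(rbind, unname(models)))
  attr(out, "members") <- members
  out
}

#' Assign transcript models to annotated loci
#'
#' Sets each model's `gene_id` to the annotated locus it overlaps
#' exonically on the same strand (the locus with the largest exonic
#' overlap wins when several match); models with no overlap keep
#' `"unassigned"`.
#'
#' @param models A [race_annotation()] of models.
#' @param ann The pre-RACE [race_annotation()].
#' @return `models` with updated `gene_id`.
#' @export
assign_models_to_loci <- function(models, ann) {
  uni <- exonic_union(ann, by = "gene_id")
  for (tx in unique(models$transcript_id)) {
    ex <- models[models$transcript_id == tx, , drop = FALSE]
    best <- NULL; best_ov <- 0
    for (g in unique(uni$gene_id)) {
      u <- uni[uni$gene_id == g, , drop = FALSE]
      if (u$chrom[1] != ex$chrom[1] || u$strand[1] != ex$strand[1]) next
      ov <- 0
      for (j in seq_len(nrow(ex))) {
        ov <- ov + sum(pmax(0, pmin(u$end, ex$end[j]) - pmax(u$start, ex$start[j])))
      }
      if (ov > best_ov) { best_ov <- ov; best <- g }
    }
    if (!is.null(best)) models$gene_id[models$transcript_id == tx] <- best
  }
  models
}
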