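#' Enumerate RACE primer candidates on a masked transcript sequence
#'
#' Scans every window of `cfg$primer_len_min` to `cfg$primer_len_max`
#' nucleotides lying entirely in unmasked sequence and keeps those whose
#' nearest-neighbour melting temperature and GC content fall within the
#' configured bounds (defaults 68-72 degrees C, 50-70% GC). A 3' RACE
#' primer is the sense-strand window itself (it primes the antisense cDNA
#' strand and extends toward the 3' end); a 5' RACE primer is the window's
#' reverse complement. Candidates are scored by weighted distance to the
#' optima (25 nt, 70 degrees C, 60% GC); lower is better.
#'
#' @param masked A masked sequence: either the list returned by
#'   [mask_nonspecific()] or a character scalar (possibly containing `N`).
#' @param direction `"5prime"` or `"3prime"`.
#' @param cfg A [race_config()].
#' @param transcript_id Optional identifier copied into the result.
#' @return Data frame of candidates: `target_transcript_id`, `direction`,
#'   `t_start`, `t_end` (0-based half-open transcript coordinates of the
#'   annealing site), `sequence` (oligo 5' to 3'), `tm`, `gc`, `score`.
#' @export
enumerate_primer_candidates <- function(masked, direction = c("3prime", "5prime"),
                                        cfg = race_config(),
                                        transcript_id = NA_character_) {
  direction <- match.arg(direction)
  seq <- if (is.list(masked)) masked$sequence else masked
  rows <- lapply(cfg$primer_len_min:cfg$primer_len_max, function(k) {
    w <- window_thermo(seq, k)
    ok <- !is.na(w$tm) &
      w$tm >= cfg$primer_tm_min & w$tm <= cfg$primer_tm_max &
      w$gc >= cfg$primer_gc_min & w$gc <= cfg$primer_gc_max
    w <- w[ok, , drop = FALSE]
    if (!nrow(w)) return(NULL)
    data.frame(start = w$start, len = k, tm = w$tm, gc = w$gc)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    return(data.frame(target_transcript_id = character(),
                      direction = character(), t_start = integer(),
                      t_end = integer(), sequence = character(),
                      tm = numeric(), gc = numeric(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  window <- substring(seq, rows$start + 1L, rows$start + rows$len)
  oligo <- if (direction == "5prime") revcomp(window) else window
  score <- abs(rows$len - cfg$primer_len_opt) +
    abs(rows$tm - cfg$primer_tm_opt) +
    abs(rows$gc - cfg$primer_gc_opt) * 25
  out <- data.frame(target_transcript_id = transcript_id,
                    direction = direction,
                    t_start = rows$start, t_end = rows$start + rows$len,
                    sequence = oligo, tm = rows$tm, gc = rows$gc,
                    score = score, stringsAsFactors = FALSE)
  out[order(out$score, out$t_start), , drop = FALSE]
}

#' Choose an outer and nested primer from scored candidates
#'
#' The outer primer is the best-scoring candidate whose predicted product
#' (annealing site to the targeted transcript end) falls within the
#' configured span range for the sequencing platform. The nested primer
#' is the candidate lying strictly downstream of the outer one (toward
#' the targeted end) that minimizes the downstream shift; it may be
#' absent.
#'
#' @param cands Candidate table from [enumerate_primer_candidates()].
#' @param direction `"5prime"` or `"3prime"`.
#' @param transcript_len Spliced transcript length (defines product span).
#' @param cfg A [race_config()].
#' @return List with `outer` and `nested` (single-row data frames or
#'   `NULL`) and `designable` flag.
#' @export
choose_primer_pair <- function(cands, direction = c("3prime", "5prime"),
                               transcript_len, cfg = race_config()) {
  direction <- match.arg(direction)
  if (!nrow(cands)) return(list(outer = NULL, nested = NULL, designable = FALSE))
  span <- if (direction == "3prime") transcript_len - cands$t_start else cands$t_end
  eligible <- span >= cfg$product_span_min & span <= cfg$product_span_max
  pool <- cands[eligible, , drop = FALSE]
  if (!nrow(pool)) return(list(outer = NULL, nested = NULL, designable = FALSE))
  outer <- pool[which.min(pool$score), , drop = FALSE]
  if (direction == "3prime") {
    down <- cands$t_start - outer$t_start
  } else {
    down <- outer$t_end - cands$t_end
  }
  nest_pool <- cands[down > 0, , drop = FALSE]
  nested <- NULL
  if (nrow(nest_pool)) {
    dist <- down[down > 0]
    best <- order(dist, nest_pool$score)[1]
    nested <- nest_pool[best, , drop = FALSE]
  }
  outer$role <- "outer"
  if (!is.null(nested)) nested$role <- "nested"
  list(outer = outer, nested = nested, designable = TRUE)
}

#' Design outer and nested RACE primers for a panel of targets
#'
#' Full design path for each target transcript: extract the spliced
#' sequence, hard-mask regions shared with transcripts of other loci,
#' enumerate candidates in both RACE directions and pick outer/nested
#' pairs.
#'
#' @param ann A [race_annotation()] containing the targets (and,
#'   typically, the rest of the transcriptome).
#' @param genome Genome as [Biostrings::DNAStringSet] or FASTA path.
#' @param target_ids Transcript identifiers to design against (default:
#'   all transcripts in `ann`).
#' @param cfg A [race_config()].
#' @param mask Logical; skip the specificity mask when `FALSE`.
#' @return A primer manifest data frame (`primer_id`, `target_transcript`,
#'   `direction`, `role`, `sequence`, `tm`, `gc`, `t_start`, `t_end`).
#'   Targets with no eligible outer primer in a direction are simply
#'   absent for that direction.
#' @export
design_race_primers <- function(ann, genome, target_ids = NULL,
                                cfg = race_config(), mask = TRUE) {
  seqs <- transcript_sequences(ann, genome)
  tt <- transcripts_table(ann)
  if (is.null(target_ids)) target_ids <- tt$transcript_id
  transcriptome <- data.frame(transcript_id = tt$transcript_id,
                              gene_id = tt$gene_id,
                              sequence = unname(seqs[tt$transcript_id]),
                              stringsAsFactors = FALSE)
  rows <- list()
  for (tx in target_ids) {
    own_locus <- tt$gene_id[tt$transcript_id == tx]
    if (mask) {
      ms <- mask_nonspecific(seqs[[tx]], own_locus, transcriptome, cfg)
    } else {
      ms <- list(sequence = seqs[[tx]])
    }
    for (dir in c("5prime", "3prime")) {
      cands <- enumerate_primer_candidates(ms, dir, cfg, transcript_id = tx)
      pair <- choose_primer_pair(cands, dir, nchar(seqs[[tx]]), cfg)
      for (role in c("outer", "nested")) {
        p <- pair[[role]]
        if (is.null(p)) next
        rows[[length(rows) + 1L]] <- data.frame(
          primer_id = sprintf("%s_%s_%s", tx, dir, role),
          target_transcript = tx, direction = dir, role = role,
          sequence = p$sequence, tm = p$tm, gc = p$gc,
          t_start = p$t_start, t_end = p$t_end, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(primer_id = character(), target_transcript = character(),
               direction = character(), role = character(),
               sequence = character(), tm = numeric(), gc = numeric(),
               t_start = integer(), t_end = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write / read a tab-separated primer manifest
#'
#' @param manifest Primer manifest from [design_race_primers()].
#' @param path File path.
#' @return `path` (writer) or the manifest data frame (reader).
#' @export
write_primer_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_primer_manifest
#' @export
read_primer_manifest <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Genomic annealing footprints of designed primers
#'
#' Projects each primer's transcript-coordinate annealing site onto the
#' genome. The genomic strand of the oligo is the transcript strand for
#' 3' RACE primers (sense oligos) and the opposite strand for 5' RACE
#' primers (antisense oligos).
#'
#' @param manifest Primer manifest.
#' @param ann A [race_annotation()] containing the target transcripts.
#' @return Data frame: `primer_id`, `chrom`, `start`, `end` (0-based
#'   half-open genomic footprint), `strand`, `direction`, `role`.
#' @export
primer_genomic_sites <- function(manifest, ann) {
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    ex <- ann[ann$transcript_id == manifest$target_transcript[i], , drop = FALSE]
    if (!nrow(ex)) abort("target transcript %s not in annotation",
                         manifest$target_transcript[i])
    g <- transcript_to_genomic(ex, c(manifest$t_start[i], manifest$t_end[i] - 1L))
    tx_strand <- ex$strand[1]
    oligo_strand <- if (manifest$direction[i] == "3prime") tx_strand else
      if (tx_strand == "+") "-" else "+"
    data.frame(primer_id = manifest$primer_id[i], chrom = ex$chrom[1],
               start = min(g), end = max(g) + 1L, strand = oligo_strand,
               direction = manifest$direction[i], role = manifest$role[i],
               target_transcript = manifest$target_transcript[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(primer_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      direction = character(), role = character(),
                      target_transcript = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
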