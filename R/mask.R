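# positions (1-based) of every k-mer in a sequence
kmer_index <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(list(kmers = character(), starts = integer()))
  starts <- seq_len(n - k + 1L)
  list(kmers = substring(s, starts, starts + k - 1L), starts = starts)
}

# greedy ungapped X-drop extension of a seed interval on one diagonal.
# m: logical match vector (candidate coordinates along the diagonal span),
# seed: c(lo, hi) indices into m. Returns extended c(lo, hi).
xdrop_extend <- function(m, seed, match_score = 1, mismatch_score = -3,
                         xdrop = 20) {
  lo <- seed[1]; hi <- seed[2]
  extend_dir <- function(from, idx) {
    best <- 0; score <- 0; best_i <- from
    for (i in idx) {
      score <- score + if (m[i]) match_score else mismatch_score
      if (score > best) { best <- score; best_i <- i }
      if (score < best - xdrop) break
    }
    best_i
  }
  if (hi < length(m)) hi <- max(hi, extend_dir(hi, (hi + 1L):length(m)))
  if (lo > 1L) lo <- min(lo, extend_dir(lo, (lo - 1L):1L))
  c(lo, hi)
}

#' Hard-mask regions similar to transcripts of other loci
#'
#' RACE primers placed in sequence shared between loci amplify off-target
#' products. This screen finds, for a candidate spliced transcript
#' sequence, every region participating in a sense-to-sense local
#' alignment of identity above `cfg$mask_identity_min` (over at least
#' `cfg$mask_min_align_len` aligned nucleotides) with any transcript of a
#' *different* locus, and replaces it with `N`. Alignments are seeded on
#' shared `cfg$mask_seed_len`-mers and extended ungapped with an X-drop
#' rule, so the criterion is deterministic and reproducible. Only the
#' sense strand is compared: antisense similarity does not interfere with
#' gene-specific priming of first-strand cDNA.
#'
#' @param seq Spliced sense-strand sequence of the candidate transcript.
#' @param own_locus Locus identifier of the candidate.
#' @param transcriptome Data frame with columns `transcript_id`,
#'   `gene_id`, `sequence` covering the transcripts to screen against
#'   (entries from `own_locus` are ignored).
#' @param cfg A [race_config()].
#' @return List with `sequence` (masked copy of `seq`) and
#'   `mask_segments`, a data frame of masked intervals in 0-based
#'   half-open transcript coordinates.
#' @export
mask_nonspecific <- function(seq, own_locus, transcriptome,
                             cfg = race_config()) {
  k <- cfg$mask_seed_len
  cb <- chars(toupper(seq))
  nc <- length(cb)
  masked <- logical(nc)
  foreign <- transcriptome[transcriptome$gene_id != own_locus, , drop = FALSE]
  cidx <- kmer_index(toupper(seq), k)
  if (length(cidx$kmers)) {
    cand_map <- split(cidx$starts, cidx$kmers)
    for (fi in seq_len(nrow(foreign))) {
      fseq <- toupper(foreign$sequence[fi])
      fb <- chars(fseq)
      nf <- length(fb)
      fidx <- kmer_index(fseq, k)
      shared <- intersect(names(cand_map), unique(fidx$kmers))
      if (!length(shared)) next
      fmap <- split(fidx$starts, fidx$kmers)
      seeds <- do.call(rbind, lapply(shared, function(km) {
        expand.grid(c = cand_map[[km]], f = fmap[[km]])
      }))
      seeds$diag <- seeds$c - seeds$f
      for (d in unique(seeds$diag)) {
        ci_lo <- max(1L, 1L + d); ci_hi <- min(nc, nf + d)
        if (ci_hi - ci_lo + 1L < k) next
        span <- ci_lo:ci_hi
        m <- cb[span] == fb[span - d]
        sd <- seeds[seeds$diag == d, , drop = FALSE]
        sd <- sd[order(sd$c), , drop = FALSE]
        done_hi <- 0L
        for (si in seq_len(nrow(sd))) {
          s_lo <- sd$c[si] - ci_lo + 1L
          s_hi <- s_lo + k - 1L
          if (s_lo <= done_hi) next  # inside a previous extension
          ext <- xdrop_extend(m, c(s_lo, s_hi))
          done_hi <- ext[2]
          span_len <- ext[2] - ext[1] + 1L
          ident <- mean(m[ext[1]:ext[2]])
          if (span_len >= cfg$mask_min_align_len &&
              ident > cfg$mask_identity_min) {
            masked[(ext[1]:ext[2]) + ci_lo - 1L] <- TRUE
          }
        }
      }
    }
  }
  out <- cb
  out[masked] <- "N"
  segs <- logical_to_segments(masked)
  list(sequence = paste(out, collapse = ""),
       mask_segments = segs)
}

# convert a logical mask vector to 0-based half-open segments
logical_to_segments <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}
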