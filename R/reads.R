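#' Read / write FASTQ (Sanger quality scale)
#'
#' Reads are held as a plain data frame with columns `read_id`, `seq` and
#' `qual` (phred+33 encoded string, same length as `seq`).
#'
#' @param path FASTQ file path.
#' @return Data frame of reads.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort("FASTQ file not found: %s", path)
  if (file.size(path) == 0)
    return(data.frame(read_id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  out <- tryCatch({
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    data.frame(read_id = sub("\\s.*$", "", names(x)),
               seq = as.character(x),
               qual = as.character(Biostrings::quality(x)),
               stringsAsFactors = FALSE)
  }, error = function(e) abort("malformed or truncated FASTQ record in %s",
                               path))
  if (any(nchar(out$seq) != nchar(out$qual)))
    abort("malformed or truncated FASTQ record in %s", path)
  out
}

#' @rdname read_fastq
#' @param reads Data frame of reads (`read_id`, `seq`, `qual`).
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    writeLines(paste0("@", reads$read_id, "\n", reads$seq, "\n+\n",
                      reads$qual), con)
  }
  invisible(path)
}

phred_ints <- function(qual) utf8ToInt(qual) - 33L
phred_chars <- function(ints) intToUtf8(ints + 33L)

#' Remove sequencing adapters from read ends
#'
#' Searches each read end for the best occurrence of any of the supplied
#' adapters, allowing partial overlap off the read end, with edit distance
#' at most `max_err_frac` of the aligned adapter length and at least
#' `min_overlap` aligned bases. The adapter and all bases distal to it
#' (toward the nearer read end) are removed; qualities are trimmed in
#' lockstep. Internal occurrences are honoured only when anchored within
#' the terminal 60% of the read, so genuine insert sequence resembling an
#' adapter in the middle of a long read is left alone.
#'
#' @param seq,qual Read sequence and phred+33 quality string.
#' @param adapters Character vector of adapter sequences (5' to 3').
#' @param min_overlap Minimum aligned adapter length.
#' @param max_err_frac Maximum error fraction of the aligned length.
#' @return List with `seq`, `qual`, `trimmed` (one of `"none"`,
#'   `"5prime"`, `"3prime"`, `"both"`) and `bases_removed`.
#' @export
trim_adapters <- function(seq, qual, adapters, min_overlap = 10L,
                          max_err_frac = 0.1) {
  if (!length(adapters)) abort("no adapters supplied")
  if (nchar(seq) != nchar(qual)) abort("sequence/quality length mismatch")
  trimmed5 <- FALSE; trimmed3 <- FALSE
  removed <- 0L
  repeat {
    n <- nchar(seq)
    if (n == 0L) break
    best <- NULL
    for (ad in toupper(adapters)) {
      # 3' (back) orientation: adapter prefix anchored toward the read end
      h <- .adapter_hit_back(toupper(seq), ad, as.integer(min_overlap),
                             max_err_frac)
      if (h[1] >= 0 && !trimmed3 && h[1] >= floor(0.4 * n)) {
        cand <- list(end = "3prime", from = h[1], score = h[4] - 4L * h[3])
        if (is.null(best) || cand$score > best$score) best <- cand
      }
      # 5' (front) orientation: mirrored search on the reversed strings
      hr <- .adapter_hit_back(rev_string(toupper(seq)), rev_string(ad),
                              as.integer(min_overlap), max_err_frac)
      if (hr[1] >= 0 && !trimmed5 && hr[1] >= floor(0.4 * n)) {
        cand <- list(end = "5prime", upto = n - hr[1],
                     score = hr[4] - 4L * hr[3])
        if (is.null(best) || cand$score > best$score) best <- cand
      }
    }
    if (is.null(best)) break
    if (best$end == "3prime") {
      removed <- removed + (nchar(seq) - best$from)
      seq <- substr(seq, 1L, best$from)
      qual <- substr(qual, 1L, best$from)
      trimmed3 <- TRUE
    } else {
      removed <- removed + best$upto
      seq <- substr(seq, best$upto + 1L, nchar(seq))
      qual <- substr(qual, best$upto + 1L, nchar(qual))
      trimmed5 <- TRUE
    }
    if (trimmed5 && trimmed3) break
  }
  trimmed <- if (trimmed5 && trimmed3) "both" else if (trimmed5) "5prime" else
    if (trimmed3) "3prime" else "none"
  list(seq = seq, qual = qual, trimmed = trimmed, bases_removed = removed)
}

rev_string <- function(x) paste(rev(chars(x)), collapse = "")

#' Progressive 3'-end quality trimming
#'
#' While the read is at least `cfg$qtrim_window` (3) bases long and the
#' mean phred score of its last `qtrim_window` bases is not greater than
#' `cfg$qtrim_mean_min` (20), the last base is removed. Reads shorter
#' than the window are returned unchanged (the rule is defined on the
#' last three nucleotides).
#'
#' @param seq,qual Read sequence and phred+33 quality string.
#' @param cfg A [race_config()].
#' @return List with `seq`, `qual` and `bases_removed`.
#' @export
quality_trim_3prime <- function(seq, qual, cfg = race_config()) {
  q <- phred_ints(qual)
  n <- length(q)
  w <- cfg$qtrim_window
  n0 <- n
  while (n >= w && mean(q[(n - w + 1L):n]) <= cfg$qtrim_mean_min) {
    n <- n - 1L
  }
  list(seq = substr(seq, 1L, n), qual = substr(qual, 1L, n),
       bases_removed = n0 - n)
}

#' Minimum-length read filter
#'
#' Reads shorter than `cfg$read_min_len` are removed; a read of exactly
#' the minimum length is retained.
#'
#' @param reads Data frame of reads.
#' @param cfg A [race_config()].
#' @return List with `reads` (retained) and `n_discarded`.
#' @export
length_filter <- function(reads, cfg = race_config()) {
  keep <- nchar(reads$seq) >= cfg$read_min_len
  list(reads = reads[keep, , drop = FALSE], n_discarded = sum(!keep))
}

#' Full read preprocessing: adapters, quality, length
#'
#' Applies, in order, adapter removal ([trim_adapters()]), 3' quality
#' trimming ([quality_trim_3prime()]) and the minimum-length filter
#' ([length_filter()]). The operation is idempotent: preprocessing its
#' own output changes nothing.
#'
#' @param reads Data frame of reads (`read_id`, `seq`, `qual`).
#' @param adapters Character vector of adapter sequences.
#' @param cfg A [race_config()].
#' @return List with `reads` (processed, retained reads with extra
#'   columns `adapter_trimmed` and `bases_quality_trimmed`) and `report`,
#'   a one-row data frame of totals.
#' @export
preprocess_reads <- function(reads, adapters, cfg = race_config()) {
  n_in <- nrow(reads)
  ad_flag <- character(n_in)
  ad_bases <- integer(n_in)
  q_bases <- integer(n_in)
  seqs <- reads$seq; quals <- reads$qual
  for (i in seq_len(n_in)) {
    tr <- trim_adapters(seqs[i], quals[i], adapters,
                        min_overlap = cfg$min_overlap,
                        max_err_frac = cfg$max_err_frac)
    qt <- quality_trim_3prime(tr$seq, tr$qual, cfg)
    seqs[i] <- qt$seq; quals[i] <- qt$qual
    ad_flag[i] <- tr$trimmed; ad_bases[i] <- tr$bases_removed
    q_bases[i] <- qt$bases_removed
  }
  out <- reads
  out$seq <- seqs; out$qual <- quals
  out$adapter_trimmed <- ad_flag
  out$bases_quality_trimmed <- q_bases
  lf <- length_filter(out, cfg)
  report <- data.frame(
    n_in = n_in, n_out = nrow(lf$reads), n_discarded_short = lf$n_discarded,
    n_adapter_trimmed = sum(ad_flag != "none"),
    bases_adapter_trimmed = sum(ad_bases),
    bases_quality_trimmed = sum(q_bases))
  list(reads = lf$reads, report = report)
}

#' Preprocess a FASTQ file to a FASTQ file
#'
#' Streamed composition of the preprocessing rules over a FASTQ file;
#' discarded reads are counted, not written.
#'
#' @param fastq_in,fastq_out Input and output FASTQ paths.
#' @param adapters Character vector of adapter sequences.
#' @param cfg A [race_config()].
#' @return The report data frame (see [preprocess_reads()]), invisibly
#'   returned with the retained reads attached as attribute `"reads"`.
#' @export
preprocess_fastq <- function(fastq_in, fastq_out, adapters,
                             cfg = race_config()) {
  reads <- read_fastq(fastq_in)
  res <- preprocess_reads(reads, adapters, cfg)
  write_fastq(res$reads, fastq_out)
  structure(res$report, reads = res$reads)
}
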