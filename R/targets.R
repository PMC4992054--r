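#' Reads per kilobase of exon per million mapped reads
#'
#' @param reads_in_exons Read count falling in the transcript's exons.
#' @param exonic_length Merged exonic length in nucleotides (> 0).
#' @param total_mapped Total mapped reads in the sample (> 0).
#' @return RPKM values, `1e9 * reads / (length * total)`. All arguments
#'   recycle to a common length.
#' @examples
#' compute_rpkm(100, 1000, 1e6)  # 100
#' @export
compute_rpkm <- function(reads_in_exons, exonic_length, total_mapped) {
  if (any(exonic_length <= 0)) abort("exonic_length must be > 0")
  if (any(total_mapped <= 0)) abort("total_mapped must be > 0")
  if (any(reads_in_exons < 0)) abort("read counts must be >= 0")
  1e9 * reads_in_exons / (exonic_length * total_mapped)
}

#' Select lowly characterized, expressed target transcripts
#'
#' Keeps transcripts expressed above an RPKM floor in at least one sample
#' (strictly greater than `cfg$rpkm_min`) whose annotated TSS has no
#' same-strand CAGE/PET tag within `cfg$cage_window`, ranks the survivors
#' by mean RPKM across samples (decreasing) and truncates the list to
#' `cfg$n_targets`.
#'
#' @param rpkm Numeric matrix of RPKM values, transcripts in rows (row
#'   names are transcript identifiers), samples in columns.
#' @param ann A [race_annotation()] providing each transcript's TSS.
#' @param cage_tags A [point_features()] table of CAGE/PET 5' tags (may be
#'   empty).
#' @param cfg A [race_config()].
#' @return Data frame of selected targets (`transcript_id`, `gene_id`,
#'   `mean_rpkm`, `max_rpkm`), sorted by decreasing mean RPKM.
#' @export
select_targets <- function(rpkm, ann, cage_tags = point_features(),
                           cfg = race_config()) {
  if (is.null(rownames(rpkm))) abort("rpkm matrix needs transcript row names")
  tss <- transcript_tss(ann)
  tss <- tss[match(rownames(rpkm), tss$transcript_id), , drop = FALSE]
  if (anyNA(tss$transcript_id))
    abort("rpkm matrix contains transcripts absent from the annotation")
  expressed <- apply(rpkm, 1, max) > cfg$rpkm_min
  cage_near <- vapply(seq_len(nrow(tss)), function(i) {
    sel <- cage_tags$chrom == tss$chrom[i] & cage_tags$strand == tss$strand[i]
    any(abs(cage_tags$position[sel] - tss$position[i]) <= cfg$cage_window)
  }, logical(1))
  keep <- expressed & !cage_near
  out <- data.frame(transcript_id = rownames(rpkm)[keep],
                    gene_id = tss$transcript_id[keep],  # replaced below
                    mean_rpkm = rowMeans(rpkm)[keep],
                    max_rpkm = apply(rpkm, 1, max)[keep],
                    stringsAsFactors = FALSE)
  tt <- transcripts_table(ann)
  out$gene_id <- tt$gene_id[match(out$transcript_id, tt$transcript_id)]
  out <- out[order(-out$mean_rpkm, out$transcript_id), , drop = FALSE]
  out <- head(out, cfg$n_targets)
  rownames(out) <- NULL
  out
}
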