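#' Classify aligned reads as on- or off-target
#'
#' A read is on-target when at least one aligned block overlaps at least
#' one base of the merged exonic regions of any targeted locus. Intronic
#' overlap alone does not count.
#'
#' @param aln An alignment table from [read_alignments()] (ideally after
#'   [filter_unique()]).
#' @param targets A [race_annotation()] of the targeted loci.
#' @return List with `on_count`, `off_count` and `per_locus`, a data frame
#'   of read tallies per targeted locus (each read counted once per locus).
#' @export
classify_on_target <- function(aln, targets) {
  uni <- exonic_union(targets, by = "gene_id")
  if (!nrow(aln)) {
    return(list(on_count = 0L, off_count = 0L,
                per_locus = data.frame(gene_id = unique(uni$gene_id),
                                       reads = 0L, stringsAsFactors = FALSE)))
  }
  blocks <- alignment_blocks(aln)
  if (!nrow(uni)) {
    return(list(on_count = 0L, off_count = nrow(aln),
                per_locus = data.frame(gene_id = character(), reads = integer(),
                                       stringsAsFactors = FALSE)))
  }
  bgr <- GenomicRanges::GRanges(blocks$chrom,
                                IRanges::IRanges(blocks$start + 1L, blocks$end))
  tgr <- GenomicRanges::GRanges(uni$chrom,
                                IRanges::IRanges(uni$start + 1L, uni$end))
  ov <- GenomicRanges::findOverlaps(bgr, tgr, ignore.strand = TRUE)
  hit_reads <- blocks$read_id[S4Vectors::queryHits(ov)]
  hit_genes <- uni$gene_id[S4Vectors::subjectHits(ov)]
  pairs <- unique(data.frame(read_id = hit_reads, gene_id = hit_genes,
                             stringsAsFactors = FALSE))
  on_ids <- unique(pairs$read_id)
  tallies <- table(factor(pairs$gene_id, levels = unique(uni$gene_id)))
  per_locus <- data.frame(gene_id = names(tallies),
                          reads = as.integer(tallies),
                          stringsAsFactors = FALSE)
  list(on_count = length(on_ids),
       off_count = nrow(aln) - length(on_ids),
       per_locus = per_locus)
}

#' On-target enrichment fold
#'
#' The enrichment achieved by a targeted experiment is the ratio `R/E`,
#' where `R` is the proportion of mapped targeted-experiment reads
#' overlapping target exons and `E` the corresponding proportion expected
#' in an untargeted experiment. When several tissues are available, the
#' proportions are unweighted means across tissues.
#'
#' @param R,E Proportions in `[0,1]` (scalars or per-tissue vectors, which
#'   are averaged).
#' @return The dimensionless fold `mean(R)/mean(E)`; `NA` with a warning
#'   when `E` is zero.
#' @export
enrichment_fold <- function(R, E) {
  if (any(R < 0 | R > 1) || any(E < 0 | E > 1))
    abort("R and E must be proportions in [0,1]")
  Rm <- mean(R); Em <- mean(E)
  if (Em == 0) {
    warning("expected on-target proportion is zero; enrichment undefined")
    return(NA_real_)
  }
  Rm / Em
}

#' Detect amplified targets and off-target loci
#'
#' A locus "produces reads" when its read tally reaches `min_reads`
#' (default 1). Tallies should be computed against the full annotation so
#' that non-targeted amplified loci can be counted too.
#'
#' @param per_locus Data frame with `gene_id` and `reads` (e.g. the
#'   `per_locus` component of [classify_on_target()] run on the full
#'   annotation).
#' @param target_ids Character vector of targeted locus identifiers.
#' @param min_reads Minimum read tally for a locus to count as positive.
#' @return List with `positive_targets` (character vector),
#'   `n_positive_targets`, and `n_offtarget_loci` (non-targeted loci with
#'   reads).
#' @export
detect_amplified_targets <- function(per_locus, target_ids, min_reads = 1L) {
  pos <- per_locus$gene_id[per_locus$reads >= min_reads]
  list(positive_targets = intersect(pos, target_ids),
       n_positive_targets = length(intersect(pos, target_ids)),
       n_offtarget_loci = length(setdiff(pos, target_ids)))
}

#' Basic annotation statistics
#'
#' Reproduces the usual before/after summary of a (re-)annotation round:
#' locus, transcript and exon counts, unique exons (distinct genomic
#' coordinates), derived per-locus and per-transcript ratios rounded half
#' up to one decimal, and the median spliced transcript length.
#'
#' @param ann A [race_annotation()].
#' @param reference Optional second annotation; when given, exons of `ann`
#'   absent (by coordinates) from `reference` are counted as novel.
#' @return List of class `annotation_summary`.
#' @export
annotation_summary <- function(ann, reference = NULL) {
  tt <- transcripts_table(ann)
  key <- unique(paste(ann$chrom, ann$start, ann$end, ann$strand))
  novel <- NA_integer_
  if (!is.null(reference)) {
    rkey <- unique(paste(reference$chrom, reference$start, reference$end,
                         reference$strand))
    novel <- sum(!key %in% rkey)
  }
  junc <- annotation_introns(ann)
  jkey <- unique(paste(junc$chrom, junc$start, junc$end, junc$strand))
  structure(list(
    n_loci = length(unique(ann$gene_id)),
    n_transcripts = nrow(tt),
    transcripts_per_locus = transcripts_per_locus(nrow(tt),
                                                  length(unique(ann$gene_id))),
    n_exons_all = nrow(ann),
    n_exons_unique = length(key),
    n_exons_novel_unique = novel,
    exons_per_transcript = exons_per_transcript(nrow(ann), nrow(tt)),
    n_unique_junctions = length(jkey),
    median_transcript_length = if (nrow(tt)) median(tt$spliced_len) else NA_real_
  ), class = "annotation_summary")
}

#' @export
print.annotation_summary <- function(x, ...) {
  cat("Annotation summary:\n")
  for (n in names(x)) cat(sprintf("  %-26s %s\n", n, format(x[[n]])))
  invisible(x)
}

#' Derived per-locus and per-transcript ratios
#'
#' Quotients of printed integer counts, rounded half up to one decimal as
#' in standard annotation summary tables.
#'
#' @param n_transcripts,n_loci,n_exons Integer counts.
#' @return Numeric scalar with one decimal.
#' @export
transcripts_per_locus <- function(n_transcripts, n_loci) {
  if (n_loci <= 0) return(NA_real_)
  round_half_up(n_transcripts / n_loci, 1)
}

#' @rdname transcripts_per_locus
#' @export
exons_per_transcript <- function(n_exons, n_transcripts) {
  if (n_transcripts <= 0) return(NA_real_)
  round_half_up(n_exons / n_transcripts, 1)
}

#' Support-rate table
#'
#' Turns rows of (total sites, supported sites) into the integer
#' percentage layout used by evidence-support tables, with percentages
#' rounded half up.
#'
#' @param labels Character vector of row labels.
#' @param total,supported Integer vectors, `supported <= total`.
#' @return Data frame with columns `set_label`, `total_sites`,
#'   `supported_count`, `supported_pct`.
#' @export
support_rate_table <- function(labels, total, supported) {
  if (any(supported > total)) abort("supported count exceeds total")
  if (any(total < 0) || any(supported < 0)) abort("counts must be >= 0")
  pct <- ifelse(total == 0, 0,
                round_half_up(100 * supported / pmax(total, 1L), 0))
  data.frame(set_label = labels, total_sites = as.integer(total),
             supported_count = as.integer(supported),
             supported_pct = as.integer(pct), stringsAsFactors = FALSE)
}

#' Ratio statistics for prose-style comparisons
#'
#' @param a,b Numerator and reference quantities (`b > 0`).
#' @param mode One of `"fold_1dp"` (fold change, one decimal),
#'   `"pct_excess"` / `"pct_increase"` (integer percent change relative to
#'   `b`; two names for the same formula, matching how shrinking and
#'   growing quantities are usually phrased).
#' @return Numeric scalar.
#' @export
ratio_stats <- function(a, b, mode = c("fold_1dp", "pct_excess", "pct_increase")) {
  mode <- match.arg(mode)
  if (b <= 0) abort("reference quantity must be > 0")
  switch(mode,
         fold_1dp = round_half_up(a / b, 1),
         pct_excess = ,
         pct_increase = round_half_up(100 * (a - b) / b, 0))
}
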