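#' Analysis thresholds for the RACE workflow
#'
#' Central registry of every numeric constant used by the workflow, so that
#' window and boundary rules are defined in exactly one place. Defaults
#' follow the published protocol this package implements:
#'
#' * `mask_identity_min`: primer regions with greater than this identity to
#'   a transcript of a *different* locus are hard-masked (default 0.80).
#' * `read_min_len`: reads shorter than this many nucleotides are discarded
#'   after trimming (default 100; exactly 100 nt is retained).
#' * `qtrim_window`, `qtrim_mean_min`: 3'-quality trimming removes bases
#'   while the mean phred of the last `qtrim_window` (3) bases is not
#'   greater than `qtrim_mean_min` (20, Sanger scale).
#' * `tss_cluster_gap` / `tts_cluster_gap`: same-strand sites closer than
#'   51 / 151 bp are merged into one cluster.
#' * `novelty_dist`: a clustered site is novel when farther than 100 bp
#'   from any annotated site of the targeted transcripts.
#' * `cage_window` / `polya_window`: a site is supported when a CAGE /
#'   polyA-site tag lies within 50 / 100 bp on the same strand.
#' * `primer_proximity`: a transcript end within 50 bp of a RACE primer
#'   (correct relative strand) marks the originating RACE direction.
#' * `tail_min_len`, `tail_mismatch_frac`: non-templated tails must run
#'   longer than 20 nt (i.e. >= 21) with at most 10% mismatches.
#' * `target_flank`: junction comparisons are restricted to target locus
#'   spans extended by 5 kb on both sides.
#' * `junction_entropy_min`: junctions need offset entropy of at least
#'   3 bits to survive filtering.
#' * `gap_intron_min`, `intron_min_len`: an alignment gap is an intron
#'   candidate when larger than 20 nt and at least 30 nt long.
#' * `rpkm_min`, `n_targets`: target selection keeps transcripts with
#'   RPKM strictly above 5 in at least one sample, top 398 by mean RPKM.
#' * Primer constraints: length 23-27 nt (optimum 25), melting temperature
#'   68-72 degrees C (optimum 70), GC 50-70% (optimum 60%), and a product
#'   span suited to the read length of the sequencing platform
#'   (default 300-3000 nt for ~600 bp reads).
#'
#' @param ... Named overrides for any field listed above.
#' @return An object of class `race_config` (a named list).
#' @examples
#' cfg <- race_config(tss_cluster_gap = 25)
#' cfg$tss_cluster_gap
#' @export
race_config <- function(...) {
  cfg <- list(
    mask_identity_min    = 0.80,
    mask_min_align_len   = 50L,
    mask_seed_len        = 11L,
    read_min_len         = 100L,
    qtrim_window         = 3L,
    qtrim_mean_min       = 20,
    tss_cluster_gap      = 51L,
    tts_cluster_gap      = 151L,
    novelty_dist         = 100L,
    cage_window          = 50L,
    polya_window         = 100L,
    primer_proximity     = 50L,
    tail_min_len         = 21L,
    tail_mismatch_frac   = 0.10,
    tail_anchor_slop     = 2L,
    target_flank         = 5000L,
    junction_entropy_min = 3.0,
    gap_intron_min       = 21L,
    intron_min_len       = 30L,
    rpkm_min             = 5.0,
    n_targets            = 398L,
    primer_len_min       = 23L,
    primer_len_opt       = 25L,
    primer_len_max       = 27L,
    primer_tm_min        = 68,
    primer_tm_opt        = 70,
    primer_tm_max        = 72,
    primer_gc_min        = 0.50,
    primer_gc_opt        = 0.60,
    primer_gc_max        = 0.70,
    product_span_min     = 300L,
    product_span_max     = 3000L,
    min_overlap          = 10L,
    max_err_frac         = 0.10,
    mapq_min             = 0L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) abort("unknown config field(s): %s", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  num <- vapply(cfg, is.numeric, logical(1))
  if (!all(num)) abort("all config fields must be numeric")
  strict <- setdiff(names(cfg), "mapq_min")  # a MAPQ floor of 0 is valid
  if (any(unlist(cfg[strict]) <= 0) || cfg$mapq_min < 0)
    abort("all config values must be positive")
  fracs <- c("mask_identity_min", "tail_mismatch_frac", "max_err_frac",
             "primer_gc_min", "primer_gc_opt", "primer_gc_max")
  for (f in fracs) {
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1) abort("config field %s must lie in (0,1)", f)
  }
  structure(cfg, class = "race_config")
}

#' @export
print.race_config <- function(x, ...) {
  cat("RACE analysis thresholds:\n")
  for (n in names(x)) cat(sprintf("  %-20s %s\n", n, format(x[[n]])))
  invisible(x)
}
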