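#' Run the complete boundary-annotation pipeline on a fixture directory
#'
#' Composition of the whole workflow against a directory laid out as
#' written by [simulate_experiment()] (`genome.fa`, `annotated.gtf`,
#' `primers.tsv`, `reads.fastq`, `reads.sam`, `cage.bed`, `polya.bed`):
#' read preprocessing, unique-mapping filtering, on-target accounting,
#' read-to-model collapse, RACE direction assignment, TSS/TTS clustering
#' with novelty and evidence support, polyA-site inference from read
#' tails, locus extension labelling and locus merging, and junction
#' extraction.
#'
#' @param dir Fixture directory.
#' @param target_ids Character vector of targeted locus (gene) ids;
#'   default: every locus in the annotation.
#' @param cfg A [race_config()].
#' @param adapters Adapter sequences for preprocessing (default: the
#'   standard 5'/3' RACE adapters of [sim_config()]).
#' @return A list with all intermediate and final results (see Details
#'   in the package vignette).
#' @export
run_race_pipeline <- function(dir, target_ids = NULL, cfg = race_config(),
                              adapters = NULL) {
  path <- function(f) file.path(dir, f)
  ann <- read_gtf(path("annotated.gtf"))
  genome <- load_genome(path("genome.fa"))
  primers <- read_primer_manifest(path("primers.tsv"))
  psites <- primer_genomic_sites(primers, ann)
  if (is.null(target_ids)) target_ids <- unique(ann$gene_id)
  if (is.null(adapters)) {
    sc <- sim_config()
    adapters <- c(sc$adapter5, sc$adapter3)
  }
  tgt_ann <- ann[ann$gene_id %in% target_ids, , drop = FALSE]

  report <- preprocess_fastq(path("reads.fastq"),
                             tempfile(fileext = ".fastq"), adapters, cfg)

  aln <- filter_unique(read_alignments(path("reads.sam")), cfg)
  ot_targets <- classify_on_target(aln, tgt_ann)
  ot_all <- classify_on_target(aln, ann)
  amplified <- detect_amplified_targets(ot_all$per_locus, target_ids)

  R <- ot_targets$on_count / max(1L, nrow(aln))
  exlen <- exonic_length(ann)
  E <- sum(exlen[names(exlen) %in% target_ids]) / sum(exlen)
  fold <- enrichment_fold(R, E)

  genome_seq <- genome
  junction_obs <- infer_introns(aln, genome_seq, cfg)
  models <- collapse_reads_to_models(aln, genome_seq, cfg, obs = junction_obs)
  models <- assign_models_to_loci(models, ann)
  mt <- transcripts_table(models)
  mt_assigned <- mt[mt$gene_id != "unassigned", , drop = FALSE]
  spans <- locus_spans(ann)
  calls <- assign_race_direction(mt_assigned, spans, psites, cfg)
  tgt_spans <- spans[spans$gene_id %in% target_ids, , drop = FALSE]
  extensions <- label_locus_extension(tgt_spans, mt_assigned, calls)

  cage <- read_bed_points(path("cage.bed"), source = "CAGE")
  polya_tags <- read_bed_points(path("polya.bed"), source = "polyA")

  p5 <- mt_assigned[mt_assigned$transcript_id %in%
    calls$transcript_id[calls$call %in% c("five_prime_product", "both")], ,
    drop = FALSE]
  p3 <- mt_assigned[mt_assigned$transcript_id %in%
    calls$transcript_id[calls$call %in% c("three_prime_product", "both")], ,
    drop = FALSE]
  tss_cl <- cluster_sites(point_features(p5$chrom, p5$tss, p5$strand, "TSS"),
                          "TSS", cfg)
  tts_cl <- cluster_sites(point_features(p3$chrom, p3$tts, p3$strand, "TTS"),
                          "TTS", cfg)
  ann_tss <- transcript_tss(tgt_ann)
  ann_tts <- transcript_tts(tgt_ann)
  tss_cl <- classify_site_novelty(tss_cl, ann_tss, cfg)
  tss_cl <- tag_support(tss_cl, cage, cfg$cage_window)
  tts_cl <- classify_site_novelty(tts_cl, ann_tts, cfg)
  tts_cl <- tag_support(tts_cl, polya_tags, cfg$polya_window)

  polya <- infer_polya_sites(aln, cfg)
  merged <- merge_loci(ann, models)

  junctions_all <- extract_junction_set(junction_obs, cfg = cfg,
                                        entropy_min = 0)
  junctions_entropy <- extract_junction_set(junction_obs, cfg = cfg)

  list(annotation = ann, target_ids = target_ids, primers = primers,
       primer_sites = psites, preprocess_report = report, alignments = aln,
       on_target = ot_targets, per_locus = ot_all$per_locus,
       amplified = amplified,
       enrichment = list(R = R, E = E, fold = fold),
       models = models, direction_calls = calls, extensions = extensions,
       tss_clusters = tss_cl, tts_clusters = tts_cl,
       polya = polya, merged = merged, junction_obs = junction_obs,
       junctions = junctions_all, junctions_entropy = junctions_entropy)
}

#' Score pipeline output against the simulator's truth ledger
#'
#' @param run Output of [run_race_pipeline()].
#' @param fixture Output of [simulate_experiment()] (or a list with
#'   `ledger`, `loci_truth`, `truth`, `cfg`, `mode`).
#' @return List of evaluation metrics:
#' * `on_target_est`, `on_target_true`: estimated (classifier) and
#'   configured on-target read fractions;
#' * `extension_recovery`: fraction of planted locus-end truncations
#'   recovered as extending with the correct sign;
#' * `polya_recall_ge_min`: fraction of reads with planted error-free
#'   tails of at least the detection threshold that were detected;
#' * `polya_fp_subthreshold`: detection rate among planted 20-nt tails;
#' * `junction_recall`: fraction of true introns seen in >= 2 aligned
#'   reads that appear in the entropy-0 junction set.
#' @export
evaluate_pipeline <- function(run, fixture) {
  ledger <- fixture$ledger
  cfgS <- fixture$cfg
  est <- run$on_target$on_count /
    (run$on_target$on_count + run$on_target$off_count)
  truth_p <- unname(cfgS$on_target_frac[fixture$mode])

  lt <- fixture$loci_truth
  ext <- run$extensions
  rec <- c()
  for (i in seq_len(nrow(lt))) {
    if (lt$truncated5[i]) {
      e <- ext[ext$gene_id == lt$gene_id[i] & ext$end == "five_prime", ]
      rec <- c(rec, nrow(e) == 1 && isTRUE(e$extending) &&
                 !is.na(e$signed_length) && e$signed_length < 0)
    }
    if (lt$truncated3[i]) {
      e <- ext[ext$gene_id == lt$gene_id[i] & ext$end == "three_prime", ]
      rec <- c(rec, nrow(e) == 1 && isTRUE(e$extending) &&
                 !is.na(e$signed_length) && e$signed_length > 0)
    }
  }
  ext_recovery <- if (length(rec)) mean(rec) else NA_real_

  calls <- run$polya$read_calls
  led <- ledger[!ledger$multimap, , drop = FALSE]
  tailed <- led[led$tail_len >= race_config()$tail_min_len, , drop = FALSE]
  sub <- led[led$tail_len > 0 & led$tail_len < race_config()$tail_min_len, ,
             drop = FALSE]
  det <- setNames(calls$detected, calls$read_id)
  recall <- if (nrow(tailed))
    mean(vapply(tailed$read_id, function(r) isTRUE(det[[r]]), logical(1)))
  else NA_real_
  fp_sub <- if (nrow(sub))
    mean(vapply(sub$read_id, function(r) isTRUE(det[[r]]), logical(1)))
  else 0

  # true introns supported by >= 2 uniquely aligned reads
  obs <- run$junction_obs %||%
    infer_introns(run$alignments, fixture$genome)
  okey <- paste(obs$chrom, obs$start, obs$end, obs$strand)
  tin <- annotation_introns(fixture$truth)
  tkey <- unique(paste(tin$chrom, tin$start, tin$end, tin$strand))
  counts <- table(okey)
  covered <- intersect(tkey, names(counts)[counts >= 2])
  jkey <- paste(run$junctions$chrom, run$junctions$start,
                run$junctions$end, run$junctions$strand)
  junc_recall <- if (length(covered)) mean(covered %in% jkey) else NA_real_

  list(on_target_est = est, on_target_true = truth_p,
       extension_recovery = ext_recovery,
       polya_recall_ge_min = recall,
       polya_fp_subthreshold = fp_sub,
       junction_recall = junc_recall,
       n_reads = nrow(ledger), n_unique = nrow(run$alignments))
}
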