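# racekit

Tools for targeted **RACE** (rapid amplification of cDNA ends)
experiments read out by long-read sequencing, aimed at annotators and
computational biologists who need to fix the poorly defined 5'/3'
boundaries of lowly expressed genes — long non-coding RNAs in
particular. The package covers the whole computational workflow around
such an experiment: target selection, specificity-masked primer design,
read preprocessing, on-target enrichment accounting, splice-junction
statistics, and the boundary annotation itself (TSS/TTS clustering,
novelty and evidence-support calls, polyA-site inference from read
tails, locus extension and merging). A deterministic simulator produces
complete synthetic experiments with a machine-readable truth ledger, so
every stage runs and is tested fully offline.

## The core quantities

* **Target selection.** RPKM = `1e9 · reads / (exonic length · mapped
  reads)`; targets are transcripts with RPKM > 5 in ≥1 sample and no
  same-strand CAGE tag within ±50 bp of the annotated TSS, ranked by
  mean RPKM.
* **On-target enrichment.** `fold = R / E`, where `R` is the proportion
  of uniquely mapped reads of the targeted experiment overlapping
  target exons and `E` the proportion expected in untargeted
  sequencing (per-tissue proportions averaged unweighted).
* **Boundary rules.** Same-strand end sites merge by single linkage at
  < 51 bp (TSS) / < 151 bp (TTS); a cluster is *novel* when > 100 bp
  from every annotated site, *supported* when a CAGE tag (±50 bp) or
  polyA tag (±100 bp) lies on the same strand; a polyA site requires a
  non-templated terminal run of > 20 nt that is ≥ 90% A (or T on the
  antisense orientation); locus extensions are signed on the
  transcription axis (negative = TSS upstream, positive = TTS
  downstream).
* **Junction support.** Introns need gaps > 20 nt, ≥ 30 nt, canonical
  GT–AG/GC–AG/AT–AC motifs (either strand); support is the Shannon
  entropy (bits) of read-start offsets, filtered at 3 bits.

## Worked example

Simulate a small nested-RACE experiment (6 target loci, 60 reads per
target) and run the full pipeline on the written fixture directory:

```r
library(racekit)
cfg <- sim_config(seed = 11, n_loci = 6, n_offtarget_loci = 4,
                  reads_per_target = 60)
fix <- simulate_experiment(cfg, dir = tempfile("demo"), mode = "nested")
run <- run_race_pipeline(dirname(fix$paths$genome),
                         target_ids = fix$target_ids)

with(run$on_target, cat(sprintf("on-target: %d / %d reads (%.1f%%)\n",
     on_count, on_count + off_count, 100 * on_count / (on_count + off_count))))
#> on-target: 134 / 355 uniquely mapped reads (37.7%)

run$extensions[run$extensions$extending, ]
#>  gene_id         end signed_length extending
#>  TGT0001  five_prime         -1758      TRUE
#>  TGT0001 three_prime          1569      TRUE
#>  TGT0003  five_prime          -926      TRUE
#>  ...
```

The on-target share sits near the configured nested-mode fraction
(36.4%); each extending locus end reports how far the novel TSS
(negative) or TTS (positive) lies beyond the annotated extreme, here
recovering exactly the planted truncations. Clustered TSSs carry
novelty and CAGE-support flags, and polyA sites come with read support
and the longest observed tail:

```r
head(run$tss_clusters[, c("chrom", "strand", "representative", "novel",
                          "supported")], 3)
#>  chrom strand representative novel supported
#>   chr1      -          35626  TRUE      TRUE
#>   chr1      -          65426  TRUE     FALSE
#>   chr1      -          69949  TRUE      TRUE

head(run$polya$sites, 3)
#>  chrom position strand supporting_reads max_tail_length
#>   chr1    16809      +               10              44
#>   chr1    25304      +                7              45
#>   chr1    33296      -               10              41
```

A thin command-line front end (`exec/racekit`) exposes the same steps
as `simulate`, `trim`, `junctions`, `boundaries` and `ontarget`
subcommands.

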