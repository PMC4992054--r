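test_that("RACE direction assignment follows extension and primer rules", {
  cfg <- race_config()
  spans <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                      start = 5000L, end = 8000L, n_transcripts = 1L)
  psites <- data.frame(
    primer_id = c("p5", "p3"), chrom = "chr1",
    start = c(7000L, 5200L), end = c(7025L, 5225L),
    strand = c("-", "+"), direction = c("5prime", "3prime"),
    role = "outer", target_transcript = "t", stringsAsFactors = FALSE)
  tt <- function(tss, tts) data.frame(
    transcript_id = "x", gene_id = "g", chrom = "chr1", strand = "+",
    start = min(tss, tts), end = max(tss, tts) + 1L, n_exons = 1L,
    spliced_len = abs(tts - tss) + 1L, tss = tss, tts = tts,
    stringsAsFactors = FALSE)
  call_of <- function(tss, tts)
    assign_race_direction(tt(tss, tts), spans, psites, cfg)$call
  # TSS 500 nt upstream of the locus 5' extreme
  expect_equal(call_of(4500, 6000), "five_prime_product")
  # 3' end exactly 50 nt from a 5' primer footprint, opposite strand
  expect_equal(call_of(5100, 6950), "five_prime_product")
  # 51 nt away: rule does not fire
  expect_equal(call_of(5100, 6949), "unassigned")
  # 5' end near the 3' primer (same strand) -> 3' product
  expect_equal(call_of(5260, 6500), "three_prime_product")
  # extending both ends -> both
  expect_equal(call_of(4500, 9000), "both")
  expect_equal(call_of(5600, 6500), "unassigned")
})

test_that("site clustering honours the <51 / <151 boundaries", {
  cfg <- race_config()
  mk <- function(pos) point_features("chr1", pos, "+", "TSS")
  c1 <- cluster_sites(mk(c(100, 150)), "TSS", cfg)   # gap 50 < 51: merge
  expect_equal(nrow(c1), 1)
  c2 <- cluster_sites(mk(c(100, 151)), "TSS", cfg)   # gap 51: split
  expect_equal(nrow(c2), 2)
  t1 <- cluster_sites(mk(c(100, 250)), "TTS", cfg)   # gap 150 < 151: merge
  expect_equal(nrow(t1), 1)
  t2 <- cluster_sites(mk(c(100, 251)), "TTS", cfg)   # gap 151: split
  expect_equal(nrow(t2), 2)
  # representative is 5'-most on the transcription axis
  expect_equal(c1$representative, 100)
  cm <- cluster_sites(point_features("chr1", c(100, 150), "-", "TSS"),
                      "TSS", cfg)
  expect_equal(cm$representative, 150)
})

test_that("clustering equals brute-force transitive closure and is idempotent", {
  cfg <- race_config()
  set.seed(13)
  for (i in 1:30) {
    pos <- sample(1:3000, sample(2:60, 1))
    cl <- cluster_sites(point_features("chr1", pos, "+", "TSS"), "TSS", cfg)
    truth <- closure_clusters(pos, cfg$tss_cluster_gap)
    expect_equal(nrow(cl), length(truth))
    expect_equal(sort(cl$representative),
                 sort(vapply(truth, min, numeric(1))))
    # clustering the representatives yields singletons
    again <- cluster_sites(point_features("chr1", cl$representative, "+",
                                          "TSS"), "TSS", cfg)
    expect_equal(nrow(again), nrow(cl))
  }
})

test_that("novelty requires >100 bp distance from annotated sites", {
  cfg <- race_config()
  cl <- cluster_sites(point_features("chr1", 1000, "+", "TSS"), "TSS", cfg)
  ann_at <- function(pos, strand = "+", chrom = "chr1")
    point_features(chrom, pos, strand, "TSS")
  expect_false(classify_site_novelty(cl, ann_at(1100), cfg)$novel)  # 100: known
  expect_true(classify_site_novelty(cl, ann_at(1101), cfg)$novel)   # 101: novel
  # no annotated site on the chromosome: vacuously novel
  expect_true(classify_site_novelty(cl, ann_at(1000, chrom = "chr9"),
                                    cfg)$novel)
  # translation invariance
  cl2 <- cluster_sites(point_features("chr1", 51000, "+", "TSS"), "TSS", cfg)
  expect_equal(classify_site_novelty(cl2, ann_at(51100), cfg)$novel,
               classify_site_novelty(cl, ann_at(1100), cfg)$novel)
})

test_that("evidence support windows are inclusive and stranded", {
  cfg <- race_config()
  cl <- cluster_sites(point_features("chr1", 1000, "+", "TSS"), "TSS", cfg)
  tag_at <- function(pos, strand = "+") point_features("chr1", pos, strand,
                                                       "CAGE")
  expect_true(tag_support(cl, tag_at(1050), cfg$cage_window)$supported)
  expect_false(tag_support(cl, tag_at(1051), cfg$cage_window)$supported)
  expect_true(tag_support(cl, tag_at(950), cfg$cage_window)$supported)
  expect_false(tag_support(cl, tag_at(1050, "-"), cfg$cage_window)$supported)
  # strand-flip symmetry
  clm <- cluster_sites(point_features("chr1", 1000, "-", "TSS"), "TSS", cfg)
  expect_true(tag_support(clm, tag_at(1050, "-"), cfg$cage_window)$supported)
})

test_that("polyA tails need >20 nt and at most 10% mismatches", {
  cfg <- race_config()
  mk_aln <- function(clip_right = "", clip_left = "") {
    data.frame(read_id = "r", chrom = "chr1", strand = "+", flag = 0L,
               mapq = 60L, n_hits = 1L, secondary = FALSE,
               clip_left = clip_left, clip_right = clip_right,
               stringsAsFactors = FALSE) |>
      within({
        block_starts <- list(1000L)
        block_ends <- list(1200L)
      })
  }
  detect <- function(...) infer_polya_sites(mk_aln(...), cfg)
  r21 <- detect(clip_right = strrep("A", 21))
  expect_equal(nrow(r21$sites), 1)
  expect_equal(r21$sites$position, 1199)  # last aligned base
  expect_equal(r21$sites$strand, "+")
  r20 <- detect(clip_right = strrep("A", 20))
  expect_equal(nrow(r20$sites), 0)
  # 30 bases with 3 non-A (10%): accepted; 4 non-A (13%): rejected
  # (exhaustive prefix check: no prefix of the 4-mismatch tail passes)
  b3 <- rep("A", 30); b3[c(10, 20, 29)] <- "C"
  tail3 <- paste(b3, collapse = "")
  expect_equal(nrow(detect(clip_right = tail3)$sites), 1)
  b4 <- rep("A", 30); b4[c(5, 10, 15, 25)] <- "C"
  mm <- cumsum(b4 != "A")
  expect_false(any(seq(21, 30) * 0.1 >= mm[21:30]))  # oracle: all fail
  tail4 <- paste(b4, collapse = "")
  expect_equal(nrow(detect(clip_right = tail4)$sites), 0)
  # T head in the left clip gives a minus-strand site at the first base
  l <- detect(clip_left = strrep("T", 25))
  expect_equal(l$sites$strand, "-")
  expect_equal(l$sites$position, 1000)
  # tail must start at the clip boundary (2 nt slop): a tail buried 10 nt
  # into the clip is not a site
  buried <- paste0(random_dna(10), strrep("A", 30))
  set.seed(30)
  expect_equal(nrow(detect(clip_right = paste0("GCGCGCGCGC",
                                               strrep("A", 30)))$sites), 0)
  # identical sites from several reads are merged with support summed
  two <- rbind(mk_aln(clip_right = strrep("A", 22)),
               mk_aln(clip_right = strrep("A", 25)))
  two$read_id <- c("r1", "r2")
  m <- infer_polya_sites(two, cfg)
  expect_equal(nrow(m$sites), 1)
  expect_equal(m$sites$supporting_reads, 2)
})

test_that("locus extension signs follow the transcription axis", {
  mk_tt <- function(strand, tss, tts) data.frame(
    transcript_id = "x", gene_id = "g", chrom = "chr1", strand = strand,
    start = min(tss, tts), end = max(tss, tts) + 1L, n_exons = 1L,
    spliced_len = 1L, tss = tss, tts = tts, stringsAsFactors = FALSE)
  spans <- function(strand) data.frame(gene_id = "g", chrom = "chr1",
                                       strand = strand, start = 5000L,
                                       end = 8000L, n_transcripts = 1L)
  calls <- data.frame(transcript_id = "x", call = "both",
                      stringsAsFactors = FALSE)
  # new TSS 376 nt upstream on + strand
  e <- label_locus_extension(spans("+"), mk_tt("+", 4624, 7000), calls)
  e5 <- e[e$end == "five_prime", ]
  expect_equal(e5$signed_length, -376)
  expect_true(e5$extending)
  # new TTS equal to the annotated extreme: signed 0, not extending
  e2 <- label_locus_extension(spans("+"), mk_tt("+", 5200, 7999), calls)
  e23 <- e2[e2$end == "three_prime", ]
  expect_equal(e23$signed_length, 0)
  expect_false(e23$extending)
  # minus strand: a new TSS at a *higher* genomic coordinate is upstream
  e3 <- label_locus_extension(spans("-"), mk_tt("-", 8400, 6000), calls)
  e35 <- e3[e3$end == "five_prime", ]
  expect_equal(e35$signed_length, -(8400 - 7999))
  expect_true(e35$extending)
  e33 <- e3[e3$end == "three_prime", ]
  expect_equal(e33$signed_length, 5000 - 6000)
  expect_false(e33$extending)
})

test_that("loci are merged only on same-strand exonic overlap, transitively", {
  pre <- race_annotation(
    chrom = "chr1",
    start = c(1000, 3000, 5000, 9000),
    end = c(1500, 3500, 5500, 9500),
    strand = c("+", "+", "+", "+"),
    transcript_id = c("a1", "b1", "c1", "d1"),
    gene_id = c("A", "B", "C", "D"))
  # bridge A-B exonically
  bridge_ab <- race_annotation("chr1", c(1200, 3100), c(1600, 3300), "+",
                               "n1", "n1")
  m <- merge_loci(pre, bridge_ab)
  expect_true("A+B" %in% m$annotation$gene_id)
  expect_equal(length(unique(m$annotation$gene_id)), 3)
  expect_equal(length(unique(m$annotation$transcript_id)), 5)
  # intronic-only overlap of B does not merge: exons at A plus an exon
  # whose span covers B's gap region only via its intron
  intronic <- race_annotation("chr1", c(1200, 4000), c(1600, 4200), "+",
                              "n2", "n2")
  m2 <- merge_loci(pre, intronic)
  expect_false(any(grepl("\\+", m2$annotation$gene_id)))
  # chain A-B and B-C via two transcripts: single transitive locus
  bridge_bc <- race_annotation("chr1", c(3100, 5100), c(3300, 5300), "+",
                               "n3", "n3")
  m3 <- merge_loci(pre, rbind(as.data.frame(bridge_ab),
                              as.data.frame(bridge_bc)))
  expect_true("A+B+C" %in% m3$annotation$gene_id)
  # locus count never increases; transcripts conserved
  expect_lte(length(unique(m3$annotation$gene_id)),
             length(unique(pre$gene_id)) + 2)
  expect_equal(length(unique(m3$annotation$transcript_id)), 6)
})

test_that("reads collapse to models by intron chain with widest span", {
  set.seed(22)
  g <- strsplit(random_dna(3000), "")[[1]]
  g[501:502] <- c("G", "T"); g[999:1000] <- c("A", "G")
  g[1201:1202] <- c("G", "T"); g[1599:1600] <- c("A", "G")
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(g, collapse = "")))
  chroms <- c(chr1 = 3000L)
  recs <- c(
    sam_record("r1", 0, "chr1", 401, 60, "100M500N100M"),
    sam_record("r2", 0, "chr1", 451, 60, "50M500N150M"),
    sam_record("r3", 0, "chr1", 401, 60, "100M500N200M400N100M"))
  aln <- read_alignments(write_sam(recs, chroms))
  models <- collapse_reads_to_models(aln, genome)
  expect_equal(length(unique(models$transcript_id)), 2)
  # the shared-chain model spans the widest members
  tt <- transcripts_table(models)
  one <- tt[tt$n_exons == 2, ]
  expect_equal(one$start, 400)
  expect_equal(one$end, 1150)
  expect_equal(one$strand, "+")
  mem <- attr(models, "members")
  expect_setequal(mem[[one$transcript_id]], c("r1", "r2"))
})
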