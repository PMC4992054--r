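test_that("constructor enforces exon invariants", {
  expect_error(race_annotation("chr1", 10, 10, "+", "t", "g"), "start < end")
  expect_error(race_annotation("chr1", -1, 10, "+", "t", "g"), "start < end")
  expect_error(race_annotation("chr1", 0, 10, "x", "t", "g"), "strand")
  # abutting exons (no >= 1 bp gap) are rejected
  expect_error(race_annotation("chr1", c(0, 10), c(10, 20), "+",
                               c("t", "t"), c("g", "g")), "abutting")
  expect_error(race_annotation(c("chr1", "chr2"), c(0, 50), c(10, 60), "+",
                               c("t", "t"), c("g", "g")), "multiple")
})

test_that("TSS and TTS are the first and last transcribed bases", {
  plus <- race_annotation("chr1", c(100, 300), c(200, 400), "+", "t1", "g1")
  minus <- race_annotation("chr1", c(100, 300), c(200, 400), "-", "t2", "g2")
  expect_equal(transcript_tss(plus)$position, 100)
  expect_equal(transcript_tts(plus)$position, 399)
  expect_equal(transcript_tss(minus)$position, 399)
  expect_equal(transcript_tts(minus)$position, 100)
  single <- race_annotation("chr1", 5, 6, "+", "t3", "g3")
  expect_equal(transcript_tss(single)$position, 5)
  expect_equal(transcript_tts(single)$position, 5)
  single_m <- race_annotation("chr1", 5, 6, "-", "t4", "g4")
  expect_equal(transcript_tss(single_m)$position, 5)
  expect_equal(transcript_tts(single_m)$position, 5)
})

test_that("TSS and TTS are exchanged under strand flip", {
  set.seed(1)
  for (i in 1:20) {
    n <- sample(1:5, 1)
    lens <- sample(50:300, n, TRUE)
    gaps <- sample(50:500, n, TRUE)
    starts <- cumsum(gaps + c(0L, lens[-n]))
    ends <- starts + lens
    p <- race_annotation("c", starts, ends, "+", "t", "g")
    m <- race_annotation("c", starts, ends, "-", "t", "g")
    expect_equal(transcript_tss(p)$position, transcript_tts(m)$position)
    expect_equal(transcript_tts(p)$position, transcript_tss(m)$position)
  }
})

test_that("exonic union merges overlaps and counts each base once", {
  ov <- race_annotation("chr1", c(0, 5), c(10, 15), "+", c("a", "b"),
                        c("g", "g"))
  u <- exonic_union(ov)
  expect_equal(u$start, 0)
  expect_equal(u$end, 15)
  expect_equal(unname(exonic_length(ov)), 15L)
  dis <- race_annotation("chr1", c(0, 20), c(10, 30), "+", "a", "g")
  expect_equal(unname(exonic_length(dis)), 20L)
  # three transcripts sharing one exon: counted once (brute-force base set)
  sh <- race_annotation("chr1", rep(50, 3), rep(80, 3), "+",
                        c("a", "b", "c"), rep("g", 3))
  expect_equal(unname(exonic_length(sh)),
               length(unique(unlist(Map(seq, 50, 79)))))
})

test_that("exonic union equals brute-force covered bases on random loci", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(1:6, 1)
    s <- sample(0:500, n)
    e <- s + sample(10:100, n, TRUE)
    ann <- suppressWarnings(data.frame(
      chrom = "c", start = s, end = e, strand = "+",
      transcript_id = paste0("t", seq_len(n)), gene_id = "g"))
    class(ann) <- c("race_annotation", "data.frame")
    truth <- length(unique(unlist(Map(function(a, b) seq(a, b - 1), s, e))))
    expect_equal(unname(exonic_length(ann)), truth)
  }
})

test_that("GTF io converts coordinates and round-trips", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(paste("chr1\tsrc\texon\t101\t200\t.\t+\t.",
                   'gene_id "g1"; transcript_id "t1";', sep = "\t"), gtf)
  ann <- read_gtf(gtf)
  expect_equal(ann$start, 100L)  # 1-based inclusive -> 0-based half-open
  expect_equal(ann$end, 200L)
  out <- tempfile(fileext = ".gtf")
  write_gtf(ann, out)
  back <- read_gtf(out)
  expect_equal(back$start, ann$start)
  expect_equal(back$end, ann$end)
  expect_equal(back$strand, ann$strand)
  expect_equal(back$transcript_id, ann$transcript_id)
  expect_equal(back$gene_id, ann$gene_id)
})

test_that("multi-transcript GTF groups into loci; round-trip is faithful", {
  ann <- demo_annotation()
  f <- tempfile(fileext = ".gtf")
  write_gtf(ann, f)
  back <- read_gtf(f)
  o1 <- as.data.frame(ann)[order(ann$transcript_id, ann$start), ]
  o2 <- as.data.frame(back)[order(back$transcript_id, back$start), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o2, o1)
  sp <- locus_spans(back)
  expect_equal(nrow(sp), 2)
  expect_equal(sp$n_transcripts[sp$gene_id == "g1"], 2)
})

test_that("empty and malformed annotation files are handled", {
  empty <- tempfile(fileext = ".gtf")
  file.create(empty)
  expect_equal(nrow(read_gtf(empty)), 0)
  noid <- tempfile(fileext = ".gtf")
  writeLines("chr1\tsrc\texon\t101\t200\t.\t+\t.\tfoo \"bar\";", noid)
  expect_error(read_gtf(noid), "transcript_id|gene_id|malformed")
})

test_that("BED points are native 0-based and round-trip", {
  pts <- point_features("chr1", c(10, 99), c("+", "-"), source = "CAGE")
  f <- tempfile(fileext = ".bed")
  write_bed_points(pts, f)
  back <- read_bed_points(f, source = "CAGE")
  expect_equal(back$position, pts$position)
  expect_equal(back$strand, pts$strand)
})

test_that("coordinate projection is its own inverse within exons", {
  ann <- race_annotation("chr1", c(100, 300), c(200, 400), "-", "t", "g")
  tpos <- c(0L, 50L, 99L, 100L, 199L)
  g <- transcript_to_genomic(ann, tpos)
  expect_equal(genomic_to_transcript(ann, g), tpos)
  expect_equal(g[1], 399)   # 5' end on minus strand
  expect_equal(g[5], 100)
  expect_true(is.na(genomic_to_transcript(ann, 250L)))  # intronic
})
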