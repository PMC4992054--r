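# a small genome with a planted + strand GT..AG intron and a - strand
# CT..AC intron
junction_genome <- function() {
  set.seed(21)
  g <- strsplit(random_dna(3000), "")[[1]]
  # intron A: [500, 1000) GT..AG (plus strand motif)
  g[501:502] <- c("G", "T"); g[999:1000] <- c("A", "G")
  # intron B: [1500, 2000) CT..AC (minus strand GT-AG)
  g[1501:1502] <- c("C", "T"); g[1999:2000] <- c("A", "C")
  # short gap region [2100, 2120) with GT..AG
  g[2101:2102] <- c("G", "T"); g[2119:2120] <- c("A", "G")
  Biostrings::DNAStringSet(c(chr1 = paste(g, collapse = "")))
}

test_that("unique-mapping filter drops multimappers entirely", {
  chroms <- c(chr1 = 3000L)
  recs <- c(sam_record("u1", 0, "chr1", 100, 60, "50M"),
            sam_record("m1", 0, "chr1", 200, 3, "50M", nh = 2),
            sam_record("m1", 256, "chr1", 900, 0, "50M", nh = 2),
            sam_record("u2", 16, "chr1", 300, 60, "50M"),
            sam_record("u3", 0, "chr1", 400, 60, "50M"),
            sam_record("m2", 0, "chr1", 500, 60, "50M"),
            sam_record("m2", 2048, "chr1", 1500, 60, "20M"))
  aln <- read_alignments(write_sam(recs, chroms))
  uni <- filter_unique(aln)
  expect_setequal(uni$read_id, c("u1", "u2", "u3"))
  expect_equal(nrow(uni), 3)
})

test_that("introns require >20 nt gaps, 30 nt minimum and canonical motifs", {
  genome <- junction_genome()
  chroms <- c(chr1 = 3000L)
  recs <- c(
    # 500-nt gap flanked GT..AG on + => junction [500,1000) motif GT-AG +
    sam_record("a", 0, "chr1", 451, 60, "50M500N50M"),
    # 500-nt gap flanked CT..AC => GT-AG junction assigned to -
    sam_record("b", 0, "chr1", 1451, 60, "50M500N50M"),
    # 20-nt gap: never an intron (boundary, ">20" and >=30)
    sam_record("c", 0, "chr1", 2081, 60, "20M20N30M"),
    # 25-nt gap: >20 but below the 30-nt intron minimum
    sam_record("d", 0, "chr1", 2076, 60, "25M25N30M"),
    # big gap with non-canonical flanks: a deletion, not an intron
    sam_record("e", 0, "chr1", 2301, 60, "30M200N30M"))
  aln <- read_alignments(write_sam(recs, chroms))
  obs <- infer_introns(aln, genome)
  expect_equal(nrow(obs), 2)
  a <- obs[obs$read_id == "a", ]
  expect_equal(c(a$start, a$end), c(500, 1000))
  expect_equal(a$motif, "GT-AG")
  expect_equal(a$strand, "+")
  b <- obs[obs$read_id == "b", ]
  expect_equal(b$strand, "-")
  expect_equal(b$motif, "GT-AG")
})

test_that("offset entropy follows the Shannon definition", {
  expect_equal(junction_offset_entropy(rep(5L, 10)), 0)
  expect_equal(junction_offset_entropy(1:8), 3)
  # {a,a,b,c}: -(1/2 log 1/2 + 2 * 1/4 log 1/4) = 1.5 bits
  expect_equal(junction_offset_entropy(c(1, 1, 2, 3)), 1.5)
  expect_error(junction_offset_entropy(integer()), "at least one")
  set.seed(12)
  for (i in 1:10) {
    off <- sample(1:5, sample(1:20, 1), TRUE)
    expect_lte(junction_offset_entropy(off), log2(length(off)) + 1e-12)
  }
})

test_that("junction pooling applies the entropy floor", {
  genome <- junction_genome()
  chroms <- c(chr1 = 3000L)
  # 10 reads over one junction from 10 distinct offsets
  varied <- vapply(1:10, function(i)
    sam_record(paste0("v", i), 0, "chr1", 441 + i, 60,
               sprintf("%dM500N50M", 60 - i)), character(1))
  stacked <- vapply(1:10, function(i)
    sam_record(paste0("s", i), 0, "chr1", 451, 60, "50M500N50M"),
    character(1))
  aln_v <- read_alignments(write_sam(varied, chroms))
  aln_s <- read_alignments(write_sam(stacked, chroms))
  js_v <- extract_junction_set(aln_v, genome, entropy_min = 3)
  expect_equal(nrow(js_v), 1)
  expect_equal(js_v$read_count, 10)
  js_s <- extract_junction_set(aln_s, genome, entropy_min = 3)
  expect_equal(nrow(js_s), 0)
  js_s0 <- extract_junction_set(aln_s, genome, entropy_min = 0)
  expect_equal(nrow(js_s0), 1)
  # empty input
  empty <- read_alignments(write_sam(character(), chroms))
  expect_equal(nrow(extract_junction_set(empty, genome, entropy_min = 0)), 0)
  # junction coordinates do not depend on read order
  js_r <- extract_junction_set(read_alignments(write_sam(rev(varied), chroms)),
                               genome, entropy_min = 0)
  expect_equal(js_r[, c("chrom", "start", "end", "strand", "read_count")],
               js_v[, c("chrom", "start", "end", "strand", "read_count")])
})

test_that("top-quartile selection keeps ceil(n/4) with deterministic ties", {
  mk <- function(n, counts) data.frame(
    chrom = "chr1", start = seq_len(n) * 1000L,
    end = seq_len(n) * 1000L + 500L, strand = "+", motif = "GT-AG",
    read_count = counts, entropy = 3, stringsAsFactors = FALSE)
  j8 <- select_top_quartile(mk(8, 1:8))
  expect_equal(sort(j8$read_count), c(7, 8))
  j1 <- select_top_quartile(mk(1, 5))
  expect_equal(nrow(j1), 1)
  jt <- mk(5, rep(3, 5))
  t1 <- select_top_quartile(jt)
  t2 <- select_top_quartile(jt[sample(1:5), ])
  expect_equal(nrow(t1), 2)
  expect_equal(t1$start, t2$start)  # coordinate tie-break, order-invariant
  for (n in c(2, 3, 4, 7, 9, 100)) {
    expect_equal(nrow(select_top_quartile(mk(n, rep(1, n)))), ceiling(n / 4))
  }
})

test_that("junction set comparison restricts to flanked target spans", {
  loci <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                     start = 10000L, end = 20000L, n_transcripts = 1L)
  mk <- function(start) data.frame(chrom = "chr1", start = start,
                                   end = start + 400L, strand = "+",
                                   motif = "GT-AG", read_count = 5,
                                   entropy = 3, stringsAsFactors = FALSE)
  inside <- mk(12000)
  edge_in <- mk(5000)        # fully inside [5000, 25000]
  outside <- mk(4599)        # start 5001 nt before the span: excluded
  a <- rbind(inside, edge_in, outside)
  cmp_same <- compare_junction_sets(a, a, loci, flank = 5000)
  expect_equal(cmp_same$shared, 2)  # outside junction dropped from both
  expect_equal(cmp_same$onlyA, 0)
  cmp_dis <- compare_junction_sets(inside, mk(15000), loci, flank = 5000)
  expect_equal(cmp_dis$shared, 0)
  expect_equal(cmp_dis$onlyA, 1)
  expect_equal(cmp_dis$onlyB, 1)
})
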