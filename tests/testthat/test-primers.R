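test_that("melting temperature matches an independent nearest-neighbour oracle", {
  # values computed independently with a published unified NN table at
  # 50 mM Na+, 200 nM oligo
  oracle <- c(CGTTGACGTTGACGTTGACGTTGAC = 62.494,
              ACGTACGTACGTACGTACGTACGTA = 60.343,
              GGCATCGGACCTTACGGCAATCGGA = 65.920,
              AGCTTGCATGCCTGCAGGTCGACTC = 66.532)
  got <- melting_temperature(names(oracle))
  expect_true(all(abs(got - unname(oracle)) < 0.5))
})

test_that("Tm is symmetric under reverse complement and monotone in GC", {
  set.seed(3)
  for (i in 1:10) {
    o <- random_dna(25)
    expect_equal(melting_temperature(o), melting_temperature(revcomp(o)),
                 tolerance = 1e-9)
  }
  expect_lt(melting_temperature(strrep("AT", 13)),
            melting_temperature(strrep("GC", 13)))
  expect_error(melting_temperature("ACGTN"), "8")
  expect_error(melting_temperature("ACGTNACGTN"), "ambiguous")
})

test_that("candidate enumeration respects masking and thresholds", {
  cfg <- race_config()
  expect_equal(nrow(enumerate_primer_candidates(strrep("N", 100), "3prime", cfg)), 0)
  # a GC-rich island in an AT desert: only windows fully in the island pass
  set.seed(5)
  island <- "GGCATCGGACCTTACGGCAATCGGAGCCTA"  # 30 nt, ~60% GC
  seq <- paste0(strrep("AT", 40), island, strrep("TA", 40))
  cands <- enumerate_primer_candidates(seq, "3prime", cfg)
  if (nrow(cands)) {
    expect_true(all(cands$t_start >= 80 & cands$t_end <= 80 + 30))
  }
  # exhaustive window oracle at k = 25
  k <- 25
  starts <- 0:(nchar(seq) - k)
  win <- substring(seq, starts + 1, starts + k)
  tm <- melting_temperature(win)
  gc <- gc_fraction(win)
  pass <- which(tm >= 68 & tm <= 72 & gc >= 0.5 & gc <= 0.7)
  expect_setequal(cands$t_start[cands$t_end - cands$t_start == k],
                  starts[pass])
  # masking one base kills every window overlapping it
  masked <- paste0(substr(seq, 1, 94), "N", substr(seq, 96, nchar(seq)))
  c2 <- enumerate_primer_candidates(masked, "3prime", cfg)
  expect_false(any(c2$t_start <= 94 & c2$t_end > 94))
  # every emitted candidate satisfies all bounds
  all_ok <- function(cand) {
    len <- cand$t_end - cand$t_start
    all(len >= cfg$primer_len_min & len <= cfg$primer_len_max &
          cand$tm >= cfg$primer_tm_min & cand$tm <= cfg$primer_tm_max &
          cand$gc >= cfg$primer_gc_min & cand$gc <= cfg$primer_gc_max)
  }
  expect_true(all_ok(cands))
})

test_that("5' candidates are reverse complements of the sense window", {
  seq <- paste0(strrep("AT", 30), "GGCATCGGACCTTACGGCAATCGGAGCCTA",
                strrep("TA", 30))
  c3 <- enumerate_primer_candidates(seq, "3prime")
  c5 <- enumerate_primer_candidates(seq, "5prime")
  expect_equal(nrow(c3), nrow(c5))
  if (nrow(c3)) {
    key3 <- paste(c3$t_start, c3$t_end)
    m <- match(key3, paste(c5$t_start, c5$t_end))
    expect_equal(revcomp(c3$sequence), c5$sequence[m])
  }
})

test_that("primer pairing picks span-eligible outer and closest nested", {
  cfg <- race_config(product_span_min = 300, product_span_max = 3000)
  base <- data.frame(target_transcript_id = "t", direction = "3prime",
                     stringsAsFactors = FALSE)
  mk <- function(t_start, score) cbind(base, t_start = t_start,
                                       t_end = t_start + 25L,
                                       sequence = "A", tm = 70, gc = 0.6,
                                       score = score)
  # single candidate -> outer, nested absent
  one <- mk(100, 1)
  p <- choose_primer_pair(one, "3prime", transcript_len = 1000, cfg = cfg)
  expect_equal(p$outer$t_start, 100)
  expect_null(p$nested)
  # two downstream candidates at +10 and +200: nested is the +10 one
  three <- rbind(mk(100, 1), mk(110, 5), mk(300, 0.5))
  p2 <- choose_primer_pair(three, "3prime", 1000, cfg)
  expect_equal(p2$outer$t_start, 300)  # best score among span-eligible
  # outer at 300 -> downstream means larger t_start; none exist
  expect_null(p2$nested)
  p3 <- choose_primer_pair(rbind(mk(100, 0.5), mk(110, 5), mk(300, 1)),
                           "3prime", 1000, cfg)
  expect_equal(p3$outer$t_start, 100)
  expect_equal(p3$nested$t_start, 110)
  # candidates only upstream of outer -> nested absent
  p4 <- choose_primer_pair(rbind(mk(900, 5), mk(950, 0.5)), "3prime",
                           1300, cfg)
  expect_equal(p4$outer$t_start, 950)
  expect_null(p4$nested)
  # no span-eligible candidate -> undesignable
  p5 <- choose_primer_pair(mk(900, 1), "3prime", 1000, cfg)
  expect_false(p5$designable)
})

test_that("designed primers avoid masked segments and map to the genome", {
  set.seed(11)
  cfgS <- sim_config(seed = 9, n_loci = 3, n_offtarget_loci = 2)
  ref <- simulate_reference(cfgS)
  tt <- transcripts_table(ref$annotated)
  tx <- tt$transcript_id[grepl("^TGT", tt$gene_id)][1]
  man <- design_race_primers(ref$annotated, ref$genome, target_ids = tx)
  if (nrow(man)) {
    sites <- primer_genomic_sites(man, ref$annotated)
    expect_true(all(sites$end - sites$start >= 23))
    seqs <- transcript_sequences(ref$annotated, ref$genome)
    # a 3' primer is a substring of the spliced sense sequence
    for (i in which(man$direction == "3prime")) {
      expect_equal(substr(seqs[[man$target_transcript[i]]],
                          man$t_start[i] + 1, man$t_end[i]),
                   man$sequence[i])
    }
    for (i in which(man$direction == "5prime")) {
      expect_equal(substr(seqs[[man$target_transcript[i]]],
                          man$t_start[i] + 1, man$t_end[i]),
                   revcomp(man$sequence[i]))
    }
  }
  # manifest io round-trip
  f <- tempfile(fileext = ".tsv")
  write_primer_manifest(man, f)
  expect_equal(read_primer_manifest(f)$sequence, man$sequence)
})
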