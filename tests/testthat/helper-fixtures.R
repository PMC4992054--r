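# shared fixture builders; everything is generated in code

qual_str <- function(phreds) intToUtf8(phreds + 33L)

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

random_read <- function(len, q_range = c(2L, 40L)) {
  list(seq = random_dna(len),
       qual = qual_str(sample(q_range[1]:q_range[2], len, TRUE)))
}

# a two-gene annotation used across tests
demo_annotation <- function() {
  race_annotation(
    chrom = rep("chr1", 5),
    start = c(100, 300, 600, 900, 2000),
    end = c(200, 400, 700, 1000, 2300),
    strand = c("+", "+", "+", "+", "-"),
    transcript_id = c("t1", "t1", "t2", "t2", "t3"),
    gene_id = c("g1", "g1", "g1", "g1", "g2"))
}

# brute-force single-linkage closure: positions cluster together iff
# connected through gaps < gap
closure_clusters <- function(pos, gap) {
  pos <- sort(pos)
  if (!length(pos)) return(list())
  groups <- list(pos[1])
  for (p in pos[-1]) {
    last <- groups[[length(groups)]]
    if (p - last[length(last)] < gap) {
      groups[[length(groups)]] <- c(last, p)
    } else {
      groups[[length(groups) + 1L]] <- p
    }
  }
  groups
}

# write a tiny SAM file from record strings
write_sam <- function(records, chroms, path = tempfile(fileext = ".sam")) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chroms), chroms))
  writeLines(c(header, records), path)
  path
}

sam_record <- function(qname, flag, chrom, pos1, mapq, cigar, seq = NULL,
                       nh = 1L) {
  if (is.null(seq)) seq <- "*"
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tNH:i:%d",
          qname, flag, chrom, pos1, mapq, cigar, seq, nh)
}
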