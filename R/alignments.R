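#' Load spliced alignments from SAM or BAM
#'
#' SAM text input is converted on the fly (via [Rsamtools::asBam]).
#' Each record is decomposed into its aligned reference blocks (0-based
#' half-open; both `N` and `D` CIGAR operations split blocks so that
#' gaps can later be classified as introns or deletions by size) and its
#' terminal soft-clipped sequences.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @return A data frame of class `race_alignments`, one row per record:
#'   `read_id`, `chrom`, `strand`, `flag`, `mapq`, `n_hits` (NH tag, NA
#'   when absent), `secondary`, plus list columns `block_starts`,
#'   `block_ends` and clip columns `clip_left`, `clip_right`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) abort("alignment file not found: %s", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  ga <- GenomicAlignments::readGAlignments(
    bam, use.names = FALSE,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "mapq", "seq"), tag = "NH",
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))
  mc <- S4Vectors::mcols(ga)
  n <- length(ga)
  blocks <- GenomicAlignments::extractAlignmentRangesOnReference(
    GenomicAlignments::cigar(ga), pos = GenomicAlignments::start(ga),
    drop.D.ranges = FALSE)
  ops <- GenomicAlignments::explodeCigarOps(GenomicAlignments::cigar(ga))
  lens <- GenomicAlignments::explodeCigarOpLengths(GenomicAlignments::cigar(ga))
  seqs <- as.character(mc$seq)
  first_op <- vapply(ops, function(o) if (length(o)) o[1] else "", character(1))
  last_op <- vapply(ops, function(o) if (length(o)) o[length(o)] else "",
                    character(1))
  lc <- ifelse(first_op == "S",
               vapply(lens, function(l) if (length(l)) l[1] else 0L,
                      integer(1)), 0L)
  rc <- ifelse(last_op == "S",
               vapply(lens, function(l) if (length(l)) l[length(l)] else 0L,
                      integer(1)), 0L)
  nc <- nchar(seqs)
  clip_left <- ifelse(lc > 0, substr(seqs, 1L, lc), "")
  clip_right <- ifelse(rc > 0, substr(seqs, nc - rc + 1L, nc), "")
  out <- data.frame(
    read_id = mc$qname,
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    strand = as.character(GenomicAlignments::strand(ga)),
    flag = mc$flag, mapq = mc$mapq,
    n_hits = if (is.null(mc$NH)) NA_integer_ else mc$NH,
    secondary = bitwAnd(mc$flag, 256L) > 0L | bitwAnd(mc$flag, 2048L) > 0L,
    clip_left = clip_left, clip_right = clip_right,
    stringsAsFactors = FALSE)
  eln <- S4Vectors::elementNROWS(blocks)
  fac <- factor(rep.int(seq_len(n), eln), levels = seq_len(n))
  out$block_starts <- unname(split(unlist(IRanges::start(blocks),
                                          use.names = FALSE) - 1L, fac))
  out$block_ends <- unname(split(unlist(IRanges::end(blocks),
                                        use.names = FALSE), fac))
  class(out) <- c("race_alignments", "data.frame")
  out
}

#' Keep uniquely mapping reads only
#'
#' A read is uniquely mapped when it has no secondary or supplementary
#' records, its NH tag (if present) is 1, and its mapping quality is at
#' least `cfg$mapq_min`. All records of a multi-mapping read are removed.
#'
#' @param aln Alignments from [read_alignments()].
#' @param cfg A [race_config()].
#' @return Filtered `race_alignments` (primary records only).
#' @export
filter_unique <- function(aln, cfg = race_config()) {
  multi_ids <- unique(aln$read_id[aln$secondary |
                                    (!is.na(aln$n_hits) & aln$n_hits > 1L)])
  keep <- !aln$read_id %in% multi_ids & !aln$secondary &
    (is.na(aln$mapq) | aln$mapq >= cfg$mapq_min)
  out <- aln[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("race_alignments", "data.frame")
  out
}

# flat table of aligned blocks, one row per block
alignment_blocks <- function(aln) {
  nb <- lengths(aln$block_starts)
  data.frame(read_id = rep(aln$read_id, nb),
             chrom = rep(aln$chrom, nb),
             start = unlist(aln$block_starts),
             end = unlist(aln$block_ends),
             stringsAsFactors = FALSE)
}

CANONICAL_MOTIFS <- data.frame(
  donor = c("GT", "GC", "AT", "CT", "CT", "GT"),
  acceptor = c("AG", "AG", "AC", "AC", "GC", "AT"),
  motif = c("GT-AG", "GC-AG", "AT-AC", "GT-AG", "GC-AG", "AT-AC"),
  strand = c("+", "+", "+", "-", "-", "-"),
  stringsAsFactors = FALSE)

#' Infer introns from alignment gaps
#'
#' Each gap between consecutive aligned blocks becomes a splice junction
#' when it is larger than `cfg$gap_intron_min - 1` nucleotides (i.e.
#' strictly greater than 20 by default), at least `cfg$intron_min_len`
#' (30) long, and flanked by a canonical splice dinucleotide pair on
#' either genomic strand (GT..AG, GC..AG, AT..AC, or their reverse
#' complements). The junction strand follows the motif orientation, not
#' the read flag, because long-read RACE libraries are unstranded at the
#' read level. Other gaps are treated as deletions.
#'
#' @param aln Alignments from [read_alignments()].
#' @param genome Genome as [Biostrings::DNAStringSet] or FASTA path.
#' @param cfg A [race_config()].
#' @return Data frame of per-read junction observations: `chrom`,
#'   `start`, `end` (0-based half-open intron), `strand`, `motif`,
#'   `read_id`, `offset` (read alignment start relative to the donor,
#'   used for entropy support downstream).
#' @export
infer_introns <- function(aln, genome, cfg = race_config()) {
  genome <- load_genome(genome)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), motif = character(),
                      read_id = character(), offset = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(aln)) return(empty)
  nb <- lengths(aln$block_starts)
  multi <- which(nb >= 2L)
  if (!length(multi)) return(empty)
  ngap <- nb[multi] - 1L
  gs <- unlist(lapply(aln$block_ends[multi], function(x) x[-length(x)]),
               use.names = FALSE)
  ge <- unlist(lapply(aln$block_starts[multi], function(x) x[-1]),
               use.names = FALSE)
  chrom <- rep.int(aln$chrom[multi], ngap)
  rid <- rep.int(aln$read_id[multi], ngap)
  astart <- rep.int(vapply(aln$block_starts[multi], `[`, numeric(1), 1),
                    ngap)
  len <- ge - gs
  keep <- len >= cfg$gap_intron_min & len >= cfg$intron_min_len
  if (!any(keep)) return(empty)
  gs <- gs[keep]; ge <- ge[keep]; chrom <- chrom[keep]; rid <- rid[keep]
  astart <- astart[keep]
  bad <- setdiff(unique(chrom), names(genome))
  if (length(bad)) abort("chromosome %s not in genome", bad[1])
  donor <- character(length(gs)); acceptor <- character(length(gs))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    donor[sel] <- as.character(Biostrings::extractAt(
      genome[[ch]], IRanges::IRanges(gs[sel] + 1L, gs[sel] + 2L)))
    acceptor[sel] <- as.character(Biostrings::extractAt(
      genome[[ch]], IRanges::IRanges(ge[sel] - 1L, ge[sel])))
  }
  hit <- match(paste(donor, acceptor),
               paste(CANONICAL_MOTIFS$donor, CANONICAL_MOTIFS$acceptor))
  ok <- !is.na(hit)
  if (!any(ok)) return(empty)
  out <- data.frame(chrom = chrom[ok], start = gs[ok], end = ge[ok],
                    strand = CANONICAL_MOTIFS$strand[hit[ok]],
                    motif = CANONICAL_MOTIFS$motif[hit[ok]],
                    read_id = rid[ok], offset = astart[ok] - gs[ok],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Shannon entropy of junction support offsets
#'
#' Reads stacked at a single alignment start (PCR duplicates, artefacts)
#' carry less evidence than reads hitting a junction from many distinct
#' offsets. Support is quantified as the base-2 Shannon entropy of the
#' offset distribution.
#'
#' @param offsets Integer vector of alignment-start offsets of the
#'   supporting reads (one entry per read).
#' @return Entropy in bits; 0 when all reads share one offset, at most
#'   `log2(length(offsets))`.
#' @export
junction_offset_entropy <- function(offsets) {
  if (!length(offsets)) abort("entropy requires at least one supporting read")
  p <- table(offsets) / length(offsets)
  -sum(p * log2(p))
}

#' Pool per-read junction observations into a junction set
#'
#' Junction identity is (chrom, intron start, intron end, strand).
#' Junctions whose offset entropy falls below `entropy_min` are excluded.
#'
#' @param aln Unique-filtered alignments, or a precomputed observation
#'   table from [infer_introns()].
#' @param genome Genome (ignored when `aln` is an observation table).
#' @param cfg A [race_config()].
#' @param entropy_min Minimum offset entropy in bits (default from `cfg`;
#'   use 0 to keep everything).
#' @return Data frame of junctions: `chrom`, `start`, `end`, `strand`,
#'   `motif`, `read_count`, `entropy`, sorted by coordinate.
#' @export
extract_junction_set <- function(aln, genome = NULL, cfg = race_config(),
                                 entropy_min = cfg$junction_entropy_min) {
  obs <- if (!is.null(aln$offset) && is.null(aln$block_starts)) aln
         else infer_introns(aln, genome, cfg)
  if (!nrow(obs)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), motif = character(),
                      read_count = integer(), entropy = numeric(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(obs$chrom, obs$start, obs$end, obs$strand, sep = "\r")
  sp <- split(seq_len(nrow(obs)), key)
  out <- do.call(rbind, lapply(sp, function(idx) {
    data.frame(chrom = obs$chrom[idx[1]], start = obs$start[idx[1]],
               end = obs$end[idx[1]], strand = obs$strand[idx[1]],
               motif = obs$motif[idx[1]], read_count = length(idx),
               entropy = junction_offset_entropy(obs$offset[idx]),
               stringsAsFactors = FALSE)
  }))
  out <- out[out$entropy >= entropy_min, , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top quartile of junctions by read coverage
#'
#' Keeps the `ceiling(n/4)` most-covered junctions; ties at the cut are
#' broken deterministically by (chrom, intron start, intron end) order.
#'
#' @param junctions Junction set with a `read_count` column.
#' @return Subset of `junctions`.
#' @export
select_top_quartile <- function(junctions) {
  n <- nrow(junctions)
  if (!n) return(junctions)
  ord <- order(-junctions$read_count, junctions$chrom, junctions$start,
               junctions$end)
  out <- junctions[ord[seq_len(ceiling(n / 4))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare two junction sets around target loci
#'
#' Restricts both sets to junctions lying fully inside any target locus
#' span extended by `flank` on both sides (same strand), then reports the
#' overlap.
#'
#' @param setA,setB Junction sets (see [extract_junction_set()]).
#' @param target_loci Locus spans from [locus_spans()].
#' @param flank Flank in nucleotides (default `cfg$target_flank`).
#' @param cfg A [race_config()].
#' @return List with `onlyA`, `onlyB`, `shared` counts and the restricted
#'   sets `setA`, `setB`.
#' @export
compare_junction_sets <- function(setA, setB, target_loci,
                                  flank = cfg$target_flank,
                                  cfg = race_config()) {
  restrict <- function(js) {
    if (!nrow(js)) return(js)
    keep <- vapply(seq_len(nrow(js)), function(i) {
      sel <- target_loci$chrom == js$chrom[i] &
        target_loci$strand == js$strand[i]
      any(js$start[i] >= target_loci$start[sel] - flank &
            js$end[i] <= target_loci$end[sel] + flank)
    }, logical(1))
    js[keep, , drop = FALSE]
  }
  a <- restrict(setA); b <- restrict(setB)
  ka <- paste(a$chrom, a$start, a$end, a$strand)
  kb <- paste(b$chrom, b$start, b$end, b$strand)
  list(onlyA = length(setdiff(ka, kb)), onlyB = length(setdiff(kb, ka)),
       shared = length(intersect(ka, kb)), setA = a, setB = b)
}
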