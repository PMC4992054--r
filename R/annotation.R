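#' Exon-level annotation table
#'
#' The central annotation container is a plain data frame with one row per
#' exon and columns `chrom`, `start`, `end`, `strand`, `transcript_id`,
#' `gene_id`. Coordinates are 0-based half-open throughout the package;
#' GTF input/output converts at the boundary, BED input is native 0-based.
#' A single internal convention keeps every +/-1 window rule (50, 100,
#' 150 bp, 5 kb) unambiguous.
#'
#' @param chrom,start,end,strand,transcript_id,gene_id Vectors of equal
#'   length describing exons. `start` is 0-based inclusive, `end`
#'   exclusive, `strand` one of `+`, `-`, `*`.
#' @return A `race_annotation` data frame, exons sorted by transcript and
#'   start coordinate.
#' @examples
#' ann <- race_annotation("chr1", c(100, 300), c(200, 400), "+", "t1", "g1")
#' transcript_tss(ann)
#' @export
race_annotation <- function(chrom = character(), start = integer(),
                            end = integer(), strand = character(),
                            transcript_id = character(),
                            gene_id = character()) {
  df <- data.frame(
    chrom = as.character(chrom), start = as.integer(start),
    end = as.integer(end), strand = as.character(strand),
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id), stringsAsFactors = FALSE
  )
  validate_annotation(df)
}

validate_annotation <- function(df) {
  if (nrow(df)) {
    if (any(is.na(df$start)) || any(is.na(df$end)))
      abort("exon coordinates contain NA")
    if (any(df$start < 0L) || any(df$start >= df$end))
      abort("exon intervals must satisfy 0 <= start < end")
    if (!all(df$strand %in% c("+", "-", "*")))
      abort("strand must be one of '+', '-', '*'")
    df <- df[order(df$transcript_id, df$start, df$end), , drop = FALSE]
    rownames(df) <- NULL
    # per-transcript invariants: one chrom/strand, disjoint exons with >=1 bp gap
    by_tx <- split(seq_len(nrow(df)), df$transcript_id)
    for (idx in by_tx) {
      if (length(unique(df$chrom[idx])) != 1L ||
          length(unique(df$strand[idx])) != 1L)
        abort("transcript %s has exons on multiple chromosomes or strands",
              df$transcript_id[idx[1]])
      if (length(idx) > 1L) {
        s <- df$start[idx]; e <- df$end[idx]
        if (any(s[-1] <= e[-length(e)]))
          abort("transcript %s has overlapping or abutting exons",
                df$transcript_id[idx[1]])
      }
    }
    # loci are single-chromosome, single-strand groups of transcripts
    by_gene <- split(seq_len(nrow(df)), df$gene_id)
    for (idx in by_gene) {
      if (length(unique(df$chrom[idx])) != 1L ||
          length(unique(df$strand[idx])) != 1L)
        abort("locus %s mixes chromosomes or strands", df$gene_id[idx[1]])
    }
  }
  class(df) <- c("race_annotation", "data.frame")
  df
}

#' Read a GENCODE-style GTF annotation
#'
#' Exon records are grouped into transcripts and loci via the
#' `transcript_id` and `gene_id` attributes. 1-based inclusive GTF
#' coordinates are converted to the package's 0-based half-open
#' convention.
#'
#' @param path Path to a GTF file.
#' @return A [race_annotation()] data frame.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) abort("annotation file not found: %s", path)
  info <- file.size(path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (info == 0 || !length(lines)) return(race_annotation())
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) abort("malformed GTF %s: %s", path,
                                           conditionMessage(e)))
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  if (!length(gr)) return(race_annotation())
  tx <- S4Vectors::mcols(gr)$transcript_id
  gn <- S4Vectors::mcols(gr)$gene_id
  if (is.null(tx) || anyNA(tx))
    abort("GTF %s has exon records without transcript_id", path)
  if (is.null(gn) || anyNA(gn))
    abort("GTF %s has exon records without gene_id", path)
  race_annotation(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    transcript_id = tx, gene_id = gn
  )
}

#' Write an annotation back to GTF
#'
#' Restores 1-based inclusive coordinates; `read_gtf()` followed by
#' `write_gtf()` round-trips coordinates, identifiers and strands.
#'
#' @param ann A [race_annotation()].
#' @param path Output file path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path, source = "racekit") {
  if (!nrow(ann)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand
  )
  gr$type <- "exon"
  gr$source <- source
  gr$gene_id <- ann$gene_id
  gr$transcript_id <- ann$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Per-transcript summary of an annotation
#'
#' @param ann A [race_annotation()].
#' @return Data frame with one row per transcript: identifiers, span,
#'   exon count, spliced length and 5'/3' terminal bases (`tss`, `tts`,
#'   0-based genomic positions on the transcription axis).
#' @export
transcripts_table <- function(ann) {
  if (!nrow(ann)) {
    return(data.frame(transcript_id = character(), gene_id = character(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer(), n_exons = integer(),
                      spliced_len = integer(), tss = integer(),
                      tts = integer(), stringsAsFactors = FALSE))
  }
  sp <- split(seq_len(nrow(ann)), ann$transcript_id)
  rows <- lapply(sp, function(idx) {
    st <- ann$start[idx]; en <- ann$end[idx]
    strand <- ann$strand[idx[1]]
    lo <- min(st); hi <- max(en)
    data.frame(
      transcript_id = ann$transcript_id[idx[1]],
      gene_id = ann$gene_id[idx[1]],
      chrom = ann$chrom[idx[1]], strand = strand,
      start = lo, end = hi, n_exons = length(idx),
      spliced_len = sum(en - st),
      tss = if (strand == "-") hi - 1L else lo,
      tts = if (strand == "-") lo else hi - 1L,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Transcription start sites of annotated transcripts
#'
#' The TSS is the first transcribed base: the start of the first exon on
#' `+`, the last base of the last exon on `-`.
#'
#' @param ann A [race_annotation()].
#' @return A point-feature data frame (`chrom`, `position`, `strand`,
#'   `transcript_id`, `source`).
#' @export
transcript_tss <- function(ann) {
  tt <- transcripts_table(ann)
  point_features(tt$chrom, tt$tss, tt$strand, source = "TSS",
                 transcript_id = tt$transcript_id)
}

#' Transcription termination sites of annotated transcripts
#'
#' Mirror of [transcript_tss()]: the last transcribed base.
#'
#' @inheritParams transcript_tss
#' @return A point-feature data frame.
#' @export
transcript_tts <- function(ann) {
  tt <- transcripts_table(ann)
  point_features(tt$chrom, tt$tts, tt$strand, source = "TTS",
                 transcript_id = tt$transcript_id)
}

#' Construct a point-feature table
#'
#' Point features carry single-base evidence such as CAGE tag 5' ends or
#' polyA-site cleavage positions.
#'
#' @param chrom,position,strand Vectors; `position` 0-based.
#' @param source Label describing the evidence type.
#' @param ... Further equal-length columns to attach.
#' @return Data frame with class `race_points`.
#' @export
point_features <- function(chrom = character(), position = integer(),
                           strand = character(), source = "point", ...) {
  if (length(position) && any(position < 0)) abort("positions must be >= 0")
  df <- data.frame(chrom = as.character(chrom),
                   position = as.integer(position),
                   strand = as.character(strand),
                   source = if (length(chrom)) rep_len(source, length(chrom)) else character(),
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (n in names(extra)) df[[n]] <- extra[[n]]
  class(df) <- c("race_points", "data.frame")
  df
}

#' Read point features from a BED file
#'
#' BED is natively 0-based; the feature position is the interval start
#' (BED point conventions store a tag at `[pos, pos+1)`).
#'
#' @param path BED file (at least BED6 for stranded evidence).
#' @param source Evidence label to attach (e.g. `"CAGE"`).
#' @return A [point_features()] data frame.
#' @export
read_bed_points <- function(path, source = "point") {
  if (!file.exists(path)) abort("BED file not found: %s", path)
  if (file.size(path) == 0) return(point_features(source = source))
  gr <- rtracklayer::import(path, format = "bed")
  point_features(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr) - 1L,
                 as.character(GenomicRanges::strand(gr)),
                 source = source)
}

#' Write point features as BED6
#'
#' @param points A [point_features()] data frame.
#' @param path Output path.
#' @param score Numeric score column (recycled).
#' @return `path`, invisibly.
#' @export
write_bed_points <- function(points, path, score = 0) {
  df <- data.frame(points$chrom, points$position, points$position + 1L,
                   points$source, rep_len(score, nrow(points)),
                   points$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Locus spans
#'
#' @param ann A [race_annotation()].
#' @return Data frame, one row per locus: `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (union span of all member exons), `n_transcripts`.
#' @export
locus_spans <- function(ann) {
  if (!nrow(ann)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(),
                      end = integer(), n_transcripts = integer(),
                      stringsAsFactors = FALSE))
  }
  sp <- split(seq_len(nrow(ann)), ann$gene_id)
  out <- do.call(rbind, lapply(sp, function(idx) {
    data.frame(gene_id = ann$gene_id[idx[1]], chrom = ann$chrom[idx[1]],
               strand = ann$strand[idx[1]], start = min(ann$start[idx]),
               end = max(ann$end[idx]),
               n_transcripts = length(unique(ann$transcript_id[idx])),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Merged exonic intervals of loci
#'
#' Overlapping or identical exons of a locus are merged so each genomic
#' base is counted once; used for on-target accounting and RPKM exonic
#' lengths.
#'
#' @param ann A [race_annotation()].
#' @param by Grouping column, `"gene_id"` (default) or `"transcript_id"`.
#' @return Data frame of disjoint intervals (`chrom`, `start`, `end`,
#'   `strand`, plus the grouping column), sorted within group.
#' @export
exonic_union <- function(ann, by = "gene_id") {
  if (!nrow(ann)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      group = character(), stringsAsFactors = FALSE)
    names(out)[5] <- by
    return(out)
  }
  sp <- split(seq_len(nrow(ann)), ann[[by]])
  out <- do.call(rbind, lapply(names(sp), function(g) {
    idx <- sp[[g]]
    ir <- IRanges::reduce(IRanges::IRanges(ann$start[idx] + 1L, ann$end[idx]))
    df <- data.frame(chrom = ann$chrom[idx[1]],
                     start = IRanges::start(ir) - 1L,
                     end = IRanges::end(ir),
                     strand = ann$strand[idx[1]],
                     group = g, stringsAsFactors = FALSE)
    df
  }))
  names(out)[5] <- by
  rownames(out) <- NULL
  out
}

#' Total exonic length per locus
#'
#' @inheritParams exonic_union
#' @return Named integer vector of merged exonic lengths.
#' @export
exonic_length <- function(ann, by = "gene_id") {
  u <- exonic_union(ann, by = by)
  if (!nrow(u)) return(setNames(integer(), character()))
  vapply(split(u$end - u$start, u[[by]]), function(x) as.integer(sum(x)),
         integer(1))
}

#' Spliced transcript sequences
#'
#' Extracts the sense-strand spliced (exon-concatenated) sequence of each
#' transcript from a genome.
#'
#' @param ann A [race_annotation()].
#' @param genome A named [Biostrings::DNAStringSet] (or path to a FASTA
#'   file) with one entry per chromosome.
#' @return Named character vector of spliced sequences, 5' to 3'.
#' @export
transcript_sequences <- function(ann, genome) {
  genome <- load_genome(genome)
  if (!nrow(ann)) return(setNames(character(), character()))
  sp <- split(seq_len(nrow(ann)), ann$transcript_id)
  out <- vapply(sp, function(idx) {
    chrom <- ann$chrom[idx[1]]
    if (!chrom %in% names(genome)) abort("chromosome %s not in genome", chrom)
    pieces <- Biostrings::extractAt(
      genome[[chrom]], IRanges::IRanges(ann$start[idx] + 1L, ann$end[idx]))
    s <- paste(as.character(pieces), collapse = "")
    if (ann$strand[idx[1]] == "-") revcomp(s) else s
  }, character(1))
  out
}

#' @keywords internal
load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  if (!methods::is(genome, "DNAStringSet"))
    abort("genome must be a DNAStringSet or FASTA path")
  genome
}

#' Map transcript coordinates to genomic coordinates
#'
#' @param ann Exons of a single transcript (a [race_annotation()] subset).
#' @param tpos Integer vector of 0-based transcript coordinates (positions
#'   along the spliced sense sequence).
#' @return Integer vector of 0-based genomic positions.
#' @export
transcript_to_genomic <- function(ann, tpos) {
  lens <- ann$end - ann$start
  strand <- ann$strand[1]
  if (any(tpos < 0 | tpos >= sum(lens))) abort("transcript position out of range")
  if (strand == "-") {
    # walk exons 3'-to-5' genomically = 5'-to-3' on transcript
    ord <- order(ann$start, decreasing = TRUE)
  } else {
    ord <- order(ann$start)
  }
  offs <- cumsum(c(0L, lens[ord]))[seq_along(ord)]
  vapply(tpos, function(p) {
    i <- findInterval(p, offs)
    within <- p - offs[i]
    e <- ord[i]
    if (strand == "-") ann$end[e] - 1L - within else ann$start[e] + within
  }, numeric(1)) |> as.integer()
}

#' Map genomic positions to transcript coordinates
#'
#' @param ann Exons of a single transcript.
#' @param gpos Integer vector of 0-based genomic positions; positions in
#'   introns or outside the transcript give `NA`.
#' @return Integer vector of 0-based transcript coordinates.
#' @export
genomic_to_transcript <- function(ann, gpos) {
  lens <- ann$end - ann$start
  strand <- ann$strand[1]
  ord <- if (strand == "-") order(ann$start, decreasing = TRUE) else order(ann$start)
  offs <- cumsum(c(0L, lens[ord]))[seq_along(ord)]
  vapply(gpos, function(g) {
    for (i in seq_along(ord)) {
      e <- ord[i]
      if (g >= ann$start[e] && g < ann$end[e]) {
        within <- if (strand == "-") ann$end[e] - 1L - g else g - ann$start[e]
        return(offs[i] + within)
      }
    }
    NA_integer_
  }, integer(1))
}

#' Intron chain of each transcript
#'
#' @param ann A [race_annotation()].
#' @return Data frame of introns (`chrom`, `start`, `end`, `strand`,
#'   `transcript_id`, `gene_id`), 0-based half-open intron coordinates.
#' @export
annotation_introns <- function(ann) {
  if (!nrow(ann)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), transcript_id = character(),
                      gene_id = character(), stringsAsFactors = FALSE))
  }
  sp <- split(seq_len(nrow(ann)), ann$transcript_id)
  out <- do.call(rbind, lapply(sp, function(idx) {
    if (length(idx) < 2L) return(NULL)
    st <- ann$start[idx]; en <- ann$end[idx]
    data.frame(chrom = ann$chrom[idx[1]],
               start = en[-length(en)], end = st[-1],
               strand = ann$strand[idx[1]],
               transcript_id = ann$transcript_id[idx[1]],
               gene_id = ann$gene_id[idx[1]], stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    return(annotation_introns(race_annotation()))
  }
  rownames(out) <- NULL
  out
}
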