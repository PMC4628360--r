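#' Read peaks from a BED or narrowPeak file
#'
#' Parses BED3, BED6 or ENCODE narrowPeak into a \link[GenomicRanges]{GRanges}
#' of peaks. On-disk coordinates are 0-based half-open (the BED convention);
#' in memory they become 1-based closed ranges, so two intervals that merely
#' touch at a coordinate on disk never overlap in memory.
#'
#' @param path Path to a tab-delimited BED-family file.
#' @param dialect One of \code{"bed3"}, \code{"bed6"}, \code{"narrowPeak"}.
#' @return A \code{GRanges} in file order with metadata columns
#'   \code{peak_id} (column 4, or generated \code{peak_<i>} for BED3),
#'   \code{signal} (narrowPeak column 7, BED6 score column, else \code{NA})
#'   and \code{summit} (narrowPeak column 10 as an offset from the peak
#'   start in bp; \code{-1} in the file means absent and becomes \code{NA}).
#' @details Malformed lines abort with an error naming the offending line
#'   number; an interval with \code{end <= start} is rejected. Strand is
#'   ignored: histone-mark peaks are unstranded.
#' @seealso [writePeakBed()], [readHotspotBed()]
#' @export
readPeakBed <- function(path, dialect = c("narrowPeak", "bed6", "bed3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  need <- switch(dialect, bed3 = 3L, bed6 = 6L, narrowPeak = 10L)
  if (length(lines) == 0L) {
    return(GenomicRanges::GRanges(
      peak_id = character(), signal = numeric(), summit = integer()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < need)
  if (length(bad)) {
    stop(sprintf("malformed %s line %d in '%s': expected >= %d fields, got %d",
                 dialect, bad[1L], path, need, nf[bad[1L]]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0) | !nzchar(chrom))
  if (length(bad)) {
    stop(sprintf("malformed %s line %d in '%s': non-numeric coordinates",
                 dialect, bad[1L], path))
  }
  bad <- which(end0 <= start0 | start0 < 0)
  if (length(bad)) {
    stop(sprintf("invalid interval on line %d in '%s': start=%s end=%s (need 0 <= start < end)",
                 bad[1L], path, start0[bad[1L]], end0[bad[1L]]))
  }
  n <- length(lines)
  peak_id <- if (need >= 6L) vapply(fields, `[[`, "", 4L) else sprintf("peak_%d", seq_len(n))
  signal <- rep(NA_real_, n)
  summit <- rep(NA_integer_, n)
  if (dialect == "bed6") {
    signal <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  } else if (dialect == "narrowPeak") {
    signal <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 7L)))
    summit <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 10L)))
    summit[!is.na(summit) & summit < 0L] <- NA_integer_
  }
  if (any(!is.na(signal) & signal < 0)) {
    stop("negative signal value in '", path, "'")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0)
  )
  S4Vectors::mcols(gr)$peak_id <- peak_id
  S4Vectors::mcols(gr)$signal <- signal
  S4Vectors::mcols(gr)$summit <- summit
  gr
}

#' Write peaks to a BED or narrowPeak file
#'
#' Inverse of [readPeakBed()]: emits 0-based half-open coordinates so that
#' a write/read round trip reproduces every interval exactly.
#'
#' @param peaks \code{GRanges} of peaks (metadata columns \code{peak_id},
#'   \code{signal}, \code{summit} used when the dialect needs them).
#' @param path Output path.
#' @param dialect Output dialect; see [readPeakBed()].
#' @return Invisibly, \code{path}.
#' @export
writePeakBed <- function(peaks, path, dialect = c("bed6", "narrowPeak", "bed3")) {
  dialect <- match.arg(dialect)
  n <- length(peaks)
  chrom <- as.character(GenomeInfoDb::seqnames(peaks))
  start0 <- GenomicRanges::start(peaks) - 1
  end0 <- GenomicRanges::end(peaks)
  mc <- S4Vectors::mcols(peaks)
  peak_id <- if ("peak_id" %in% names(mc)) as.character(mc$peak_id) else sprintf("peak_%d", seq_len(n))
  signal <- if ("signal" %in% names(mc)) mc$signal else rep(0, n)
  signal[is.na(signal)] <- 0
  summit <- if ("summit" %in% names(mc)) mc$summit else rep(NA_integer_, n)
  lines <- switch(dialect,
    bed3 = sprintf("%s\t%s\t%s", chrom, format(start0, scientific = FALSE, trim = TRUE),
                   format(end0, scientific = FALSE, trim = TRUE)),
    bed6 = sprintf("%s\t%s\t%s\t%s\t%s\t.", chrom,
                   format(start0, scientific = FALSE, trim = TRUE),
                   format(end0, scientific = FALSE, trim = TRUE),
                   peak_id, format(signal, scientific = FALSE, trim = TRUE)),
    narrowPeak = {
      s <- ifelse(is.na(summit), -1L, as.integer(summit))
      sprintf("%s\t%s\t%s\t%s\t0\t.\t%s\t-1\t-1\t%d", chrom,
              format(start0, scientific = FALSE, trim = TRUE),
              format(end0, scientific = FALSE, trim = TRUE),
              peak_id, format(signal, scientific = FALSE, trim = TRUE), s)
    })
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e))
  })
  on.exit(close(con))
  if (n > 0L) writeLines(lines, con)
  invisible(path)
}

#' Read a gene model table
#'
#' Reads a 6-column tab-delimited gene table with header columns
#' \code{gene_id, chrom, start, end, strand, biotype} (coordinates 0-based
#' half-open, like BED). The transcription start site is derived from
#' strand: the leftmost base for \code{+} genes, the rightmost for \code{-}.
#'
#' @param path Path to the TSV.
#' @return \code{GRanges} with metadata columns \code{gene_id},
#'   \code{biotype} (\code{coding}/\code{ncRNA}) and \code{tss}
#'   (1-based TSS coordinate).
#' @export
readGeneTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  required <- c("gene_id", "chrom", "start", "end", "strand", "biotype")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("gene table '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!all(tab$strand %in% c("+", "-"))) {
    bad <- which(!(tab$strand %in% c("+", "-")))[1L]
    stop(sprintf("unknown strand symbol '%s' (row %d) in '%s'",
                 tab$strand[bad], bad, path))
  }
  if (!all(tab$biotype %in% c("coding", "ncRNA"))) {
    stop("biotype must be 'coding' or 'ncRNA' in '", path, "'")
  }
  if (any(tab$end <= tab$start | tab$start < 0)) {
    stop("invalid gene interval (need 0 <= start < end) in '", path, "'")
  }
  geneGRanges(tab$gene_id, tab$chrom, tab$start, tab$end, tab$strand,
              tab$biotype)
}

#' Build a gene-model GRanges from vectors
#'
#' Programmatic counterpart of [readGeneTable()]; coordinates are 0-based
#' half-open as on disk.
#'
#' @param gene_id,chrom,start,end,strand,biotype Parallel vectors.
#' @return See [readGeneTable()].
#' @export
geneGRanges <- function(gene_id, chrom, start, end, strand, biotype) {
  stopifnot(!anyDuplicated(gene_id), all(strand %in% c("+", "-")))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1, end = end),
    strand = strand
  )
  S4Vectors::mcols(gr)$gene_id <- as.character(gene_id)
  S4Vectors::mcols(gr)$biotype <- as.character(biotype)
  S4Vectors::mcols(gr)$tss <- ifelse(strand == "+",
                                     GenomicRanges::start(gr),
                                     GenomicRanges::end(gr))
  gr
}

#' Write a gene table
#' @param genes Gene \code{GRanges} (see [readGeneTable()]).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeGeneTable <- function(genes, path) {
  tab <- data.frame(
    gene_id = S4Vectors::mcols(genes)$gene_id,
    chrom = as.character(GenomeInfoDb::seqnames(genes)),
    start = GenomicRanges::start(genes) - 1,
    end = GenomicRanges::end(genes),
    strand = as.character(GenomicRanges::strand(genes)),
    biotype = S4Vectors::mcols(genes)$biotype
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a DSB-hotspot map (BED4)
#'
#' Column 4 carries the DMC1 SSDS tag count of each hotspot, the intensity
#' used for \code{log(#tags)} comparisons.
#'
#' @param path Path to a 4-column BED.
#' @return \code{GRanges} with metadata column \code{dmc1_tags}
#'   (non-negative integer).
#' @export
readHotspotBed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(GenomicRanges::GRanges(dmc1_tags = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 4L)
  if (length(bad)) {
    stop(sprintf("malformed hotspot line %d in '%s': expected 4 fields",
                 bad[1L], path))
  }
  start0 <- as.numeric(vapply(fields, `[[`, "", 2L))
  end0 <- as.numeric(vapply(fields, `[[`, "", 3L))
  tags <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  if (any(is.na(start0) | is.na(end0) | end0 <= start0)) {
    stop("invalid hotspot interval in '", path, "'")
  }
  if (any(is.na(tags) | tags < 0)) stop("dmc1 tag counts must be >= 0 in '", path, "'")
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(fields, `[[`, "", 1L),
    ranges = IRanges::IRanges(start = start0 + 1, end = end0)
  )
  S4Vectors::mcols(gr)$dmc1_tags <- as.integer(round(tags))
  gr
}

#' Write a DSB-hotspot map (BED4)
#' @param hotspots \code{GRanges} with \code{dmc1_tags}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeHotspotBed <- function(hotspots, path) {
  lines <- sprintf("%s\t%s\t%s\t%d",
                   as.character(GenomeInfoDb::seqnames(hotspots)),
                   format(GenomicRanges::start(hotspots) - 1,
                          scientific = FALSE, trim = TRUE),
                   format(GenomicRanges::end(hotspots),
                          scientific = FALSE, trim = TRUE),
                   as.integer(S4Vectors::mcols(hotspots)$dmc1_tags))
  writeLines(lines, path)
  invisible(path)
}

#' Read a chrom.sizes table
#' @param path Two-column TSV: chromosome name, length in bp (no header).
#' @return Named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("chrom.sizes '", path, "' needs 2 columns")
  sizes <- as.numeric(tab[[2L]])
  if (any(is.na(sizes) | sizes <= 0)) stop("chromosome sizes must be positive")
  stats::setNames(sizes, tab[[1L]])
}

#' Read a genome FASTA
#'
#' @param path Path to a (multi-)FASTA file.
#' @return \code{DNAStringSet}, uppercased, named by the first whitespace
#'   token of each header. Duplicate record names are an error.
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- vapply(strsplit(names(x), "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(names(x))) {
    stop("duplicate FASTA record name in '", path, "': ",
         names(x)[duplicated(names(x))][1L])
  }
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Query an interval collection for overlaps
#'
#' The overlap kernel underlying every "overlapping" statement in the
#' pipeline: returns the members of \code{index} sharing at least
#' \code{min_overlap} bases with \code{query}, on the same chromosome.
#'
#' @param index \code{GRanges} collection to search.
#' @param query A \code{GRanges} (typically length 1).
#' @param min_overlap Minimum shared bases (>= 1; 1 is the permissive
#'   convention used throughout).
#' @return The overlapping subset of \code{index}.
#' @export
overlapQuery <- function(index, query, min_overlap = 1L) {
  .assert_scalar_number(min_overlap, "min_overlap", lower = 1)
  hits <- .find_overlaps(index, query,
                                      minoverlap = as.integer(min_overlap))
  index[unique(S4Vectors::queryHits(hits))]
}

#' Merge intervals into a disjoint sorted set
#'
#' @param intervals \code{GRanges}.
#' @return Sorted, pairwise-disjoint \code{GRanges} covering exactly the
#'   same bases. Intervals that merely touch (adjacent under half-open
#'   coordinates) are disjoint and stay separate.
#' @export
mergeIntervals <- function(intervals) {
  GenomicRanges::reduce(BiocGenerics::sort(intervals), min.gapwidth = 0L)
}
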