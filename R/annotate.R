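# Genomic classification of differential peaks: genic/intergenic, TSS,
# ncRNA overlap, chromosome distribution.

#' Annotation configuration
#'
#' @param genic_flank Flank in bp added to each gene body for the
#'   genic/intergenic call (default 1000, i.e. "within gene +/- 1 kb").
#' @param tss_window Half-width in bp of the window around each TSS
#'   (default 1000).
#' @return Named list used by the annotation functions.
#' @export
annotationConfig <- function(genic_flank = 1000L, tss_window = 1000L) {
  .assert_scalar_number(genic_flank, "genic_flank", lower = 0)
  .assert_scalar_number(tss_window, "tss_window", lower = 0)
  list(genic_flank = as.integer(genic_flank),
       tss_window = as.integer(tss_window))
}

# Gene bodies extended by the genic flank (clipped at coordinate 1).
.flanked_genes <- function(genes, flank) {
  gr <- GenomicRanges::granges(genes)
  GenomicRanges::start(gr) <- pmax(1L, GenomicRanges::start(gr) - flank)
  GenomicRanges::end(gr) <- GenomicRanges::end(gr) + flank
  gr
}

# TSS windows [tss - w, tss + w) in half-open disk coordinates; the stored
# tss is 1-based, so the window is [tss - w, tss + w - 1] closed.
.tss_windows <- function(genes, w) {
  tss <- S4Vectors::mcols(genes)$tss
  GenomicRanges::GRanges(
    seqnames = GenomeInfoDb::seqnames(genes),
    ranges = IRanges::IRanges(start = pmax(1L, tss - w),
                              end = tss + w - 1L)
  )
}

#' Classify peaks as genic or intergenic
#'
#' A peak is genic iff it shares at least one base with any gene body
#' extended by \code{genic_flank} on both sides; intergenic otherwise.
#'
#' @param peaks Peak \code{GRanges}.
#' @param genes Gene \code{GRanges} (see [readGeneTable()]).
#' @param cfg An [annotationConfig()].
#' @return List with \code{label} (character vector
#'   \code{genic}/\code{intergenic} parallel to \code{peaks}),
#'   \code{n_genic}, \code{n_intergenic}. The two counts always partition
#'   the total.
#' @export
classifyGenic <- function(peaks, genes, cfg = annotationConfig()) {
  flanked <- .flanked_genes(genes, cfg$genic_flank)
  genic <- .overlaps_any(peaks, flanked)
  label <- ifelse(genic, "genic", "intergenic")
  n_genic <- sum(genic)
  n_intergenic <- length(peaks) - n_genic
  stopifnot(n_genic + n_intergenic == length(peaks))
  list(label = label, n_genic = n_genic, n_intergenic = n_intergenic)
}

#' Fraction of peaks at transcription start sites
#'
#' @inheritParams classifyGenic
#' @return Fraction in \code{[0, 1]} of peaks overlapping any TSS window
#'   \code{[tss - w, tss + w)}; 0 when there are no genes or no peaks.
#' @export
tssFraction <- function(peaks, genes, cfg = annotationConfig()) {
  if (length(peaks) == 0L || length(genes) == 0L) return(0)
  wins <- .tss_windows(genes, cfg$tss_window)
  mean(.overlaps_any(peaks, wins))
}

#' Peaks overlapping ncRNA genes, with flanking coding neighbours
#'
#' Overlap uses the plain 1-bp rule with no flank (in contrast to the
#' flanked genic call). For each hit the nearest coding gene strictly to
#' the left and to the right of the peak midpoint is reported with its
#' distance from the midpoint to the gene's nearest boundary; a coding
#' gene spanning the midpoint is reported on both sides at distance 0.
#'
#' @param peaks Peak \code{GRanges} with a \code{peak_id} metadata column.
#' @param genes Gene \code{GRanges} with \code{biotype} populated.
#' @return \code{data.frame} with one row per (peak, overlapped ncRNA)
#'   pair: \code{peak_id}, \code{ncrna_id}, \code{upstream_gene},
#'   \code{upstream_dist}, \code{downstream_gene}, \code{downstream_dist}
#'   (\code{NA} when no coding gene exists on that side).
#' @export
ncrnaOverlap <- function(peaks, genes) {
  empty <- data.frame(peak_id = character(), ncrna_id = character(),
                      upstream_gene = character(), upstream_dist = numeric(),
                      downstream_gene = character(), downstream_dist = numeric(),
                      stringsAsFactors = FALSE)
  biotype <- S4Vectors::mcols(genes)$biotype
  if (is.null(biotype)) stop("gene models must carry a 'biotype' column")
  nc <- genes[biotype == "ncRNA"]
  coding <- genes[biotype == "coding"]
  if (length(nc) == 0L || length(peaks) == 0L) return(empty)
  hits <- .find_overlaps(peaks, nc)
  if (length(hits) == 0L) return(empty)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  mid <- floor((GenomicRanges::start(peaks)[qh] +
                GenomicRanges::end(peaks)[qh]) / 2)
  chr <- as.character(GenomeInfoDb::seqnames(peaks))[qh]
  cod_chr <- as.character(GenomeInfoDb::seqnames(coding))
  cod_start <- GenomicRanges::start(coding)
  cod_end <- GenomicRanges::end(coding)
  cod_id <- S4Vectors::mcols(coding)$gene_id
  up_gene <- up_dist <- down_gene <- down_dist <- rep(NA, length(qh))
  for (i in seq_along(qh)) {
    same <- which(cod_chr == chr[i])
    if (!length(same)) next
    spans <- same[cod_start[same] <= mid[i] & cod_end[same] >= mid[i]]
    left <- same[cod_end[same] < mid[i]]
    right <- same[cod_start[same] > mid[i]]
    if (length(spans)) {
      g <- spans[1L]
      up_gene[i] <- down_gene[i] <- cod_id[g]
      up_dist[i] <- down_dist[i] <- 0
    }
    if (length(left) && is.na(up_gene[i])) {
      g <- left[which.max(cod_end[left])]
      up_gene[i] <- cod_id[g]
      up_dist[i] <- mid[i] - cod_end[g]
    }
    if (length(right) && is.na(down_gene[i])) {
      g <- right[which.min(cod_start[right])]
      down_gene[i] <- cod_id[g]
      down_dist[i] <- cod_start[g] - mid[i]
    }
  }
  pid <- S4Vectors::mcols(peaks)$peak_id
  if (is.null(pid)) pid <- sprintf("peak_%d", seq_along(peaks))
  data.frame(
    peak_id = pid[qh],
    ncrna_id = S4Vectors::mcols(nc)$gene_id[sh],
    upstream_gene = as.character(up_gene),
    upstream_dist = as.numeric(up_dist),
    downstream_gene = as.character(down_gene),
    downstream_dist = as.numeric(down_dist),
    stringsAsFactors = FALSE
  )
}

#' Per-chromosome peak distribution
#'
#' Counts and percentages of peaks per chromosome, plus the Pearson
#' correlation between per-chromosome peak count and chromosome length.
#'
#' @param peaks Peak \code{GRanges}.
#' @param chrom_sizes Named vector of chromosome lengths (bp); every peak
#'   chromosome must appear in it.
#' @return List with \code{table} (\code{data.frame}: \code{chrom},
#'   \code{length}, \code{count}, \code{percent}) and \code{correlation}
#'   (\code{NA} with fewer than 3 chromosomes or zero variance).
#' @export
chromosomeDistribution <- function(peaks, chrom_sizes) {
  chroms <- as.character(GenomeInfoDb::seqnames(peaks))
  unknown <- setdiff(unique(chroms), names(chrom_sizes))
  if (length(unknown)) {
    stop("peak chromosome(s) missing from chrom_sizes: ",
         paste(unknown, collapse = ", "))
  }
  counts <- vapply(names(chrom_sizes), function(ch) sum(chroms == ch), 0L)
  total <- length(peaks)
  percent <- if (total > 0) 100 * counts / total else rep(0, length(counts))
  r <- if (length(chrom_sizes) >= 3L &&
           stats::sd(counts) > 0 && stats::sd(chrom_sizes) > 0) {
    stats::cor(counts, as.numeric(chrom_sizes))
  } else {
    NA_real_
  }
  list(
    table = data.frame(chrom = names(chrom_sizes),
                       length = as.numeric(chrom_sizes),
                       count = as.integer(counts),
                       percent = percent,
                       row.names = NULL, stringsAsFactors = FALSE),
    correlation = r
  )
}

#' Summarize peak annotation
#'
#' Bundles the genic/intergenic, TSS, ncRNA and chromosome summaries into
#' one list, the shape emitted in the pipeline's summary JSON. Categories
#' are non-exclusive counters (a peak may be both at a TSS and on an
#' ncRNA).
#'
#' @inheritParams classifyGenic
#' @param chrom_sizes Optional named vector of chromosome lengths.
#' @return List: \code{n_peaks}, \code{n_genic}, \code{n_intergenic},
#'   \code{pct_genic}, \code{tss_fraction}, \code{pct_tss},
#'   \code{n_ncrna} (distinct peaks overlapping ncRNA), \code{ncrna}
#'   (the pair table), \code{per_chromosome}, \code{chrom_correlation}.
#' @export
annotateSummary <- function(peaks, genes, cfg = annotationConfig(),
                            chrom_sizes = NULL) {
  gen <- classifyGenic(peaks, genes, cfg)
  tssf <- tssFraction(peaks, genes, cfg)
  nc <- ncrnaOverlap(peaks, genes)
  out <- list(
    n_peaks = length(peaks),
    n_genic = gen$n_genic,
    n_intergenic = gen$n_intergenic,
    pct_genic = if (length(peaks)) 100 * gen$n_genic / length(peaks) else 0,
    tss_fraction = tssf,
    pct_tss = 100 * tssf,
    n_ncrna = length(unique(nc$peak_id)),
    ncrna = nc,
    genic_label = gen$label
  )
  if (!is.null(chrom_sizes)) {
    cd <- chromosomeDistribution(peaks, chrom_sizes)
    out$per_chromosome <- cd$table
    out$chrom_correlation <- cd$correlation
  }
  out
}
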