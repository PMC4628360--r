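# Association of differential peaks with meiotic DSB hotspot maps,
# DMC1 intensity comparison, gene-level hotspot summaries, and
# region-level signal ratios (e.g. the pseudoautosomal region).

#' Associate differential peaks with DSB hotspots
#'
#' A peak is associated iff it overlaps at least \code{min_overlap} bases
#' of some hotspot (default 1 bp). When gene models are supplied, the
#' associated peaks are additionally classified genic via
#' [classifyGenic()] to count how many lie within genes.
#'
#' @param peaks Differential peak \code{GRanges} (or a
#'   [DifferentialPeakSet-class], in which case its called peaks are used).
#' @param hotspots Hotspot \code{GRanges} with \code{dmc1_tags}.
#' @param genes Optional gene \code{GRanges}.
#' @param cfg [annotationConfig()] for the genic call.
#' @param min_overlap Minimum shared bases.
#' @return A [HotspotAssociation-class].
#' @export
associateHotspots <- function(peaks, hotspots, genes = NULL,
                              cfg = annotationConfig(), min_overlap = 1L) {
  if (is(peaks, "DifferentialPeakSet")) peaks <- calledPeaks(peaks)
  .assert_scalar_number(min_overlap, "min_overlap", lower = 1)
  hits <- .find_overlaps(peaks, hotspots,
                                      minoverlap = as.integer(min_overlap))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  pid <- S4Vectors::mcols(peaks)$peak_id
  if (is.null(pid)) pid <- sprintf("peak_%d", seq_along(peaks))
  pairs <- data.frame(peak_id = pid[qh], hotspot = sh,
                      stringsAsFactors = FALSE)
  assoc_idx <- sort(unique(qh))
  n_within <- NA_integer_
  if (!is.null(genes) && length(assoc_idx)) {
    n_within <- classifyGenic(peaks[assoc_idx], genes, cfg)$n_genic
  } else if (!is.null(genes)) {
    n_within <- 0L
  }
  new("HotspotAssociation", pairs = pairs,
      nAssociatedPeaks = length(assoc_idx),
      nWithinGenes = as.integer(n_within))
}

#' Compare DMC1 intensities of associated vs all hotspots
#'
#' Intensities are natural-log tag counts, \code{log(#tags)}. Hotspots
#' with zero tags cannot be logged and are excluded from both groups with
#' a message reporting how many were dropped. The associated group is
#' compared against the full hotspot set with the rank-sum test
#' ([ranksumCompare()]).
#'
#' @param assoc A [HotspotAssociation-class].
#' @param hotspots The hotspot \code{GRanges} the association was built
#'   against.
#' @return List with \code{median_associated}, \code{median_all},
#'   \code{p_value}, \code{n_associated}, \code{n_all},
#'   \code{n_zero_dropped}.
#' @export
intensityCompare <- function(assoc, hotspots) {
  tags <- S4Vectors::mcols(hotspots)$dmc1_tags
  if (is.null(tags)) stop("hotspots must carry 'dmc1_tags'")
  assoc_ids <- unique(associationPairs(assoc)$hotspot)
  if (length(assoc_ids) == 0L) {
    stop("no associated hotspots; nothing to compare")
  }
  zero <- tags == 0
  n_zero <- sum(zero)
  if (n_zero > 0) {
    message(n_zero, " hotspot(s) with zero tags excluded from log intensities")
  }
  all_log <- log(tags[!zero])
  assoc_keep <- assoc_ids[!zero[assoc_ids]]
  if (length(assoc_keep) == 0L) {
    stop("all associated hotspots have zero tags")
  }
  assoc_log <- log(tags[assoc_keep])
  cmp <- ranksumCompare(assoc_log, all_log)
  list(median_associated = cmp$median_a,
       median_all = cmp$median_b,
       p_value = cmp$p_value,
       n_associated = length(assoc_keep),
       n_all = length(all_log),
       n_zero_dropped = n_zero)
}

#' Per-gene DSB hotspot summary
#'
#' For each gene: the number of hotspots overlapping the gene body (1-bp
#' rule, so a hotspot straddling a gene boundary counts) and the highest
#' DMC1 tag count among them. Gene length is reported in Mb to two
#' decimals, the shape of a large-gene fragility table.
#'
#' @param genes Gene \code{GRanges}.
#' @param hotspots Hotspot \code{GRanges} with \code{dmc1_tags}.
#' @return \code{data.frame}: \code{gene_id}, \code{length_mb},
#'   \code{n_dsb}, \code{max_dmc1} (\code{NA} for genes without hotspots).
#' @export
geneHotspotSummary <- function(genes, hotspots) {
  tags <- S4Vectors::mcols(hotspots)$dmc1_tags
  hits <- .find_overlaps(genes, hotspots)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  n <- length(genes)
  n_dsb <- integer(n)
  max_tag <- rep(NA_integer_, n)
  if (length(hits)) {
    cnt <- table(qh)
    n_dsb[as.integer(names(cnt))] <- as.integer(cnt)
    mx <- tapply(tags[sh], qh, max)
    max_tag[as.integer(names(mx))] <- as.integer(mx)
  }
  data.frame(
    gene_id = S4Vectors::mcols(genes)$gene_id,
    length_mb = round(GenomicRanges::width(genes) / 1e6, 2),
    n_dsb = n_dsb,
    max_dmc1 = max_tag,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Region-level normalized signal ratio
#'
#' Scale-normalizes each sample's tag count inside a region to a common
#' target depth, averages within condition, and reports the
#' treated/control ratio -- the comparison used for condition-specific
#' signal loss in a region such as the PAR.
#'
#' @param region_counts Named numeric vector of raw tag counts inside the
#'   region, one per sample; or a named list of tag-position \code{GRanges}
#'   to be counted against \code{region}.
#' @param region \code{GRanges} of length 1 (only needed when
#'   \code{region_counts} is a list of tag sets).
#' @param lib_sizes Library size per sample.
#' @param condition \code{control}/\code{treated} label per sample.
#' @param target Normalization target depth (default mean library size).
#' @return List with \code{mean_control}, \code{mean_treated},
#'   \code{ratio} (treated/control; \code{NA} when the control mean is 0)
#'   and \code{undefined} (\code{TRUE} iff the ratio could not be formed).
#' @export
regionSignal <- function(region_counts, region = NULL, lib_sizes, condition,
                         target = NULL) {
  if (is.list(region_counts)) {
    if (is.null(region) || length(region) != 1L) {
      stop("'region' must be a single interval when counting tag sets")
    }
    region_counts <- vapply(region_counts, function(tg) {
      .count_overlaps(region, tg)
    }, 0L)
  }
  if (length(region_counts) != length(condition) ||
      length(lib_sizes) != length(condition)) {
    stop("region_counts, lib_sizes and condition must be parallel")
  }
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  if (is.null(target)) target <- mean(lib_sizes)
  scaled <- region_counts * target / lib_sizes
  mean_c <- mean(scaled[condition == "control"])
  mean_t <- mean(scaled[condition == "treated"])
  if (mean_c > 0) {
    list(mean_control = mean_c, mean_treated = mean_t,
         ratio = mean_t / mean_c, undefined = FALSE)
  } else {
    list(mean_control = mean_c, mean_treated = mean_t,
         ratio = NA_real_, undefined = TRUE)
  }
}
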