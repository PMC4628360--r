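# The multi-step differential-peak procedure: replicate reproducibility ->
# consensus construction -> quantification -> quantile filter -> FC+FDR call.

#' Reproducible peaks between two replicates
#'
#' A peak of replicate 1 is reproducible when it shares at least
#' \code{min_overlap} bases with some peak of replicate 2 (same condition).
#' Each kept peak is extended to the union span of itself and all its
#' matching replicate-2 peaks, so no reproducible signal is clipped.
#'
#' @param rep1,rep2 Peak \code{GRanges} from two replicates of the same
#'   condition.
#' @param min_overlap Minimum shared bases (default 1).
#' @return \code{GRanges} of the reproducible replicate-1 peaks (extended
#'   spans), metadata carried over from \code{rep1}; deterministic given
#'   the inputs.
#' @export
reproduciblePeaks <- function(rep1, rep2, min_overlap = 1L) {
  .assert_scalar_number(min_overlap, "min_overlap", lower = 1)
  hits <- .find_overlaps(rep1, rep2,
                                      minoverlap = as.integer(min_overlap))
  if (length(hits) == 0L) return(rep1[0])
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  keep <- sort(unique(qh))
  min2 <- tapply(GenomicRanges::start(rep2)[sh], qh, min)
  max2 <- tapply(GenomicRanges::end(rep2)[sh], qh, max)
  out <- rep1[keep]
  idx <- as.character(keep)
  GenomicRanges::start(out) <- pmin(GenomicRanges::start(out),
                                    as.integer(min2[idx]))
  GenomicRanges::end(out) <- pmax(GenomicRanges::end(out),
                                  as.integer(max2[idx]))
  out
}

#' Build consensus peaks from replicate peak sets
#'
#' Applies [reproduciblePeaks()] within each condition (a peak must be
#' supported by every replicate of its condition), takes the union of the
#' control-reproducible and treated-reproducible sets, merges overlapping
#' intervals with [mergeIntervals()], and assigns ids in chromosome order.
#' The \code{source} column records whether a consensus interval came from
#' control-reproducible peaks, treated-reproducible peaks, or both.
#'
#' @param sets A [ReplicatePeakSets-class].
#' @param min_overlap Minimum shared bases for reproducibility (default 1).
#' @return \code{GRanges} of consensus peaks with metadata columns
#'   \code{peak_id} and \code{source}
#'   (\code{control-reproducible}/\code{treated-reproducible}/\code{both}).
#' @export
buildConsensus <- function(sets, min_overlap = 1L) {
  stopifnot(is(sets, "ReplicatePeakSets"))
  validObject(sets)
  cond <- sampleConditions(sets)
  reproducible_in <- function(label) {
    reps <- peakSets(sets)[cond == label]
    acc <- reps[[1L]]
    for (i in seq_along(reps)[-1L]) {
      acc <- reproduciblePeaks(acc, reps[[i]], min_overlap)
    }
    acc
  }
  cons_c <- reproducible_in("control")
  cons_t <- reproducible_in("treated")
  merged <- mergeIntervals(c(GenomicRanges::granges(cons_c),
                             GenomicRanges::granges(cons_t)))
  from_c <- .overlaps_any(merged, cons_c)
  from_t <- .overlaps_any(merged, cons_t)
  source <- ifelse(from_c & from_t, "both",
                   ifelse(from_c, "control-reproducible",
                          "treated-reproducible"))
  S4Vectors::mcols(merged)$peak_id <-
    sprintf("peak_%05d", seq_along(merged))
  S4Vectors::mcols(merged)$source <- source
  merged
}

#' Count tags over consensus peaks
#'
#' Counts, per sample, the tags whose position falls inside each consensus
#' interval. Library sizes are the total tag counts per sample, including
#' tags on chromosomes absent from the consensus space (those contribute
#' to depth but to no peak).
#'
#' @param consensus Consensus peak \code{GRanges} (see [buildConsensus()]).
#' @param tags Named list of tag-position \code{GRanges} (width-1 ranges),
#'   one per sample.
#' @param condition \code{control}/\code{treated} label per sample.
#' @return A \code{RangedSummarizedExperiment} with assay \code{counts},
#'   \code{rowRanges = consensus} and \code{colData} columns
#'   \code{condition} and \code{lib_size}.
#' @export
quantifyPeaks <- function(consensus, tags, condition) {
  stopifnot(is.list(tags), length(tags) == length(condition))
  counts <- matrix(0L, nrow = length(consensus), ncol = length(tags),
                   dimnames = list(S4Vectors::mcols(consensus)$peak_id,
                                   names(tags)))
  for (j in seq_along(tags)) {
    counts[, j] <- .count_overlaps(consensus, tags[[j]])
  }
  peakCountMatrix(counts, condition = condition,
                  lib_sizes = vapply(tags, length, 0L),
                  consensus = consensus)
}

#' Assemble a peak count matrix
#'
#' Wraps a raw peak x sample count matrix into the
#' \code{RangedSummarizedExperiment} the pipeline operates on.
#'
#' @param counts Non-negative integer matrix, features x samples, with
#'   rownames (peak ids).
#' @param condition \code{control}/\code{treated} label per sample.
#' @param lib_sizes Positive library size per sample.
#' @param consensus Optional consensus \code{GRanges} parallel to the rows.
#' @return A \code{(Ranged)SummarizedExperiment} with assay \code{counts}.
#' @export
peakCountMatrix <- function(counts, condition, lib_sizes, consensus = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(condition) != ncol(counts) || length(lib_sizes) != ncol(counts)) {
    stop("condition and lib_sizes must have one entry per sample")
  }
  if (!all(condition %in% c("control", "treated"))) {
    stop("condition labels must be 'control' or 'treated'")
  }
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  cd <- S4Vectors::DataFrame(condition = as.character(condition),
                             lib_size = as.numeric(lib_sizes))
  if (!is.null(colnames(counts))) rownames(cd) <- colnames(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("peak_%05d", seq_len(nrow(counts)))
  }
  if (is.null(consensus)) {
    SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts), colData = cd)
  } else {
    stopifnot(length(consensus) == nrow(counts))
    SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts), rowRanges = consensus, colData = cd)
  }
}

#' Quantile filter on mean normalized signal
#'
#' Drops weak peaks before testing: computes the per-feature mean of the
#' log2 normalized values across all samples, takes the nearest-rank
#' (type-1) \code{q}-quantile of those means as the threshold, and retains
#' the features whose mean lies strictly above it.
#'
#' @param nm Matrix of log2 normalized values with rownames, or a
#'   \code{SummarizedExperiment} with a \code{lognorm} assay.
#' @param q Quantile to cut at (default 0.05, i.e. the weakest 5\%).
#' @return Character vector of retained feature ids.
#' @export
quantileFilter <- function(nm, q = 0.05) {
  .assert_scalar_number(q, "q", lower = 0, upper = 1, strict_lower = TRUE)
  if (q >= 1) stop("'q' must be < 1")
  m <- if (is(nm, "SummarizedExperiment")) {
    as.matrix(SummarizedExperiment::assay(nm, "lognorm"))
  } else {
    as.matrix(nm)
  }
  if (nrow(m) < 2L) stop("need at least 2 features to filter")
  means <- rowMeans(m)
  srt <- sort(means)
  thr <- srt[ceiling(q * length(srt))]
  retained <- names(means)[means > thr]
  if (length(retained) == 0L) {
    stop("quantile filter retained no features (all row means tied at ",
         format(thr), "); lower 'q' or inspect the data")
  }
  retained
}

#' Call differential peaks
#'
#' Runs the moderated t-test and BH FDR adjustment on the retained
#' features and calls a peak differential iff its linear fold change
#' satisfies \code{2^|log_fc| > fc_cut} and its q-value is below
#' \code{fdr_cut}; direction follows the sign of the log fold change.
#'
#' @param nm \code{SummarizedExperiment} with a \code{lognorm} assay, a
#'   \code{condition} column in \code{colData} and (optionally) consensus
#'   \code{rowRanges}; or a plain matrix plus \code{condition}.
#' @param retained Feature ids to test (from [quantileFilter()]); must be a
#'   subset of the features of \code{nm}.
#' @param fc_cut Linear fold-change threshold (default 1.5), applied
#'   symmetrically to increases and decreases.
#' @param fdr_cut FDR threshold on BH q-values (default 0.05).
#' @param quantile_cut The quantile used upstream, recorded in the result
#'   (default 0.05).
#' @param condition Condition labels (matrix input only).
#' @param mod Optional [ModerationParams-class]; estimated from the
#'   retained features when \code{NULL}.
#' @return A [DifferentialPeakSet-class].
#' @export
callDifferential <- function(nm, retained, fc_cut = 1.5, fdr_cut = 0.05,
                             quantile_cut = 0.05, condition = NULL,
                             mod = NULL) {
  .assert_scalar_number(fc_cut, "fc_cut", lower = 1)
  .assert_scalar_number(fdr_cut, "fdr_cut", lower = 0, upper = 1)
  if (is(nm, "SummarizedExperiment")) {
    m <- as.matrix(SummarizedExperiment::assay(nm, "lognorm"))
    condition <- as.character(SummarizedExperiment::colData(nm)$condition)
    gr <- tryCatch(SummarizedExperiment::rowRanges(nm),
                   error = function(e) NULL)
  } else {
    m <- as.matrix(nm)
    gr <- NULL
    if (is.null(condition)) stop("'condition' required for matrix input")
  }
  missing_ids <- setdiff(retained, rownames(m))
  if (length(missing_ids)) {
    stop("retained ids absent from the matrix: ",
         paste(utils::head(missing_ids, 3), collapse = ", "))
  }
  m <- m[retained, , drop = FALSE]
  res <- moderatedTTest(m, condition, mod)
  res$q <- bhFdr(res$p)
  called <- (2^abs(res$log_fc) > fc_cut) & (res$q < fdr_cut)
  res$direction <- ifelse(!called, "ns", ifelse(res$log_fc > 0, "up", "down"))
  if (is.null(gr)) {
    gr <- GenomicRanges::GRanges(rep("unknown", nrow(res)),
                                 IRanges::IRanges(seq_len(nrow(res)), width = 1))
    S4Vectors::mcols(gr)$peak_id <- res$feature_id
    S4Vectors::mcols(gr)$source <- NA_character_
  } else {
    idx <- match(retained, S4Vectors::mcols(gr)$peak_id)
    if (anyNA(idx)) idx <- match(retained, rownames(m))
    gr <- gr[idx]
    if (is.null(S4Vectors::mcols(gr)$source)) {
      S4Vectors::mcols(gr)$source <- NA_character_
    }
    S4Vectors::mcols(gr) <-
      S4Vectors::mcols(gr)[, c("peak_id", "source"), drop = FALSE]
  }
  S4Vectors::mcols(gr)$log_fc <- res$log_fc
  S4Vectors::mcols(gr)$fc <- res$fc
  S4Vectors::mcols(gr)$t <- res$t
  S4Vectors::mcols(gr)$p <- res$p
  S4Vectors::mcols(gr)$q <- res$q
  S4Vectors::mcols(gr)$direction <- res$direction
  new("DifferentialPeakSet",
      peaks = gr,
      thresholds = list(fc_cut = fc_cut, fdr_cut = fdr_cut,
                        quantile_cut = quantile_cut),
      nUp = sum(res$direction == "up"),
      nDown = sum(res$direction == "down"))
}

#' Run the full differential-peak procedure
#'
#' Convenience wrapper fixing the stage order of the procedure:
#' reproducibility -> consensus -> quantification -> scale normalization ->
#' log transform -> quantile filter -> moderated test with FC/FDR call.
#' The quantile threshold is computed only over reproducible (consensus)
#' peaks, never over the raw peak sets.
#'
#' @param sets A [ReplicatePeakSets-class].
#' @param tags Named list of tag-position \code{GRanges} per sample, or
#'   \code{NULL} when \code{counts} is given.
#' @param counts Optional precomputed counts matrix (rows = consensus
#'   peaks in [buildConsensus()] order).
#' @param min_overlap,fc_cut,fdr_cut,quantile_cut,pseudocount Procedure
#'   parameters (defaults 1 bp, 1.5, 0.05, 0.05, 1).
#' @param target Normalization target depth (default mean library size).
#' @return List with elements \code{consensus} (\code{GRanges}),
#'   \code{se} (the normalized \code{SummarizedExperiment}),
#'   \code{retained} (ids passing the quantile filter) and
#'   \code{diff} (a [DifferentialPeakSet-class]).
#' @export
differentialPeakPipeline <- function(sets, tags = NULL, counts = NULL,
                                     min_overlap = 1L, fc_cut = 1.5,
                                     fdr_cut = 0.05, quantile_cut = 0.05,
                                     pseudocount = 1, target = NULL) {
  consensus <- buildConsensus(sets, min_overlap)
  if (!is.null(tags)) {
    se <- quantifyPeaks(consensus, tags, sampleConditions(sets))
  } else if (!is.null(counts)) {
    se <- peakCountMatrix(counts, sampleConditions(sets), libSizes(sets),
                          consensus = consensus)
  } else {
    stop("provide either 'tags' or 'counts'")
  }
  se <- scaleNormalize(se, target = target)
  se <- logTransform(se, pseudocount = pseudocount)
  retained <- quantileFilter(se, q = quantile_cut)
  diff <- callDifferential(se, retained, fc_cut = fc_cut, fdr_cut = fdr_cut,
                           quantile_cut = quantile_cut)
  list(consensus = consensus, se = se, retained = retained, diff = diff)
}

#' Write a DifferentialPeakSet to disk
#'
#' Emits the full results table as TSV and the called peaks as BED6
#' (score column = linear fold change).
#'
#' @param dps A [DifferentialPeakSet-class].
#' @param tsv_path,bed_path Output paths (either may be \code{NULL} to
#'   skip).
#' @return Invisibly, a list of the written paths.
#' @export
writeDifferentialPeaks <- function(dps, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path)) {
    tab <- resultsTable(dps)
    num <- vapply(tab, is.numeric, TRUE) & !(names(tab) %in% c("start", "end"))
    tab[num] <- lapply(tab[num], function(x) signif(x, 6))
    utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(bed_path)) {
    called <- calledPeaks(dps)
    S4Vectors::mcols(called)$signal <-
      signif(S4Vectors::mcols(called)$fc, 4)
    writePeakBed(called, bed_path, dialect = "bed6")
  }
  invisible(list(tsv = tsv_path, bed = bed_path))
}
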