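#' @import methods
NULL

#' ModerationParams: empirical-Bayes variance prior
#'
#' Parameters of the scaled inverse-chi-square prior on per-feature
#' variances used by the moderated t-test: prior degrees of freedom
#' \code{d0} (may be \code{Inf}, meaning complete shrinkage to a common
#' variance) and prior variance \code{s0sq}.
#'
#' @slot d0 Prior degrees of freedom (>= 0, possibly \code{Inf}).
#' @slot s0sq Prior variance (> 0).
#' @slot nFeatures Number of variances the fit used.
#' @seealso [estimateModeration()], [moderatedTTest()]
#' @export
setClass("ModerationParams",
  representation(d0 = "numeric", s0sq = "numeric", nFeatures = "integer"),
  prototype(d0 = Inf, s0sq = 1, nFeatures = 0L)
)

setValidity("ModerationParams", function(object) {
  if (length(object@d0) != 1L || is.na(object@d0) || object@d0 < 0) {
    return("d0 must be a single value >= 0 (Inf allowed)")
  }
  if (length(object@s0sq) != 1L || is.na(object@s0sq) || object@s0sq <= 0) {
    return("s0sq must be a single positive value")
  }
  TRUE
})

#' @describeIn ModerationParams Prior degrees of freedom.
#' @param object A \code{ModerationParams}.
#' @export
setGeneric("priorDf", function(object) standardGeneric("priorDf"))

#' @rdname ModerationParams
#' @export
setMethod("priorDf", "ModerationParams", function(object) object@d0)

#' @describeIn ModerationParams Prior variance.
#' @export
setGeneric("priorVar", function(object) standardGeneric("priorVar"))

#' @rdname ModerationParams
#' @export
setMethod("priorVar", "ModerationParams", function(object) object@s0sq)

setMethod("show", "ModerationParams", function(object) {
  cat("ModerationParams\n")
  cat("  prior df (d0):      ",
      if (is.infinite(object@d0)) "Inf (complete shrinkage)" else format(object@d0, digits = 4),
      "\n", sep = "")
  cat("  prior variance s0^2:", format(object@s0sq, digits = 4), "\n")
  cat("  fitted on:          ", object@nFeatures, "feature variances\n")
})

#' ReplicatePeakSets: per-sample peak sets for a two-condition design
#'
#' Container for the replicate peak sets entering consensus construction:
#' one \code{GRanges} of peaks per sample, a condition label per sample
#' (\code{control}/\code{treated}) and a library size (total mapped tags)
#' per sample. Exactly two conditions with at least two replicates each
#' are required.
#'
#' @slot peaks Named \code{list} of \code{GRanges}.
#' @slot condition Character vector parallel to \code{peaks}.
#' @slot libSizes Numeric vector parallel to \code{peaks}.
#' @export
setClass("ReplicatePeakSets",
  representation(peaks = "list", condition = "character", libSizes = "numeric")
)

setValidity("ReplicatePeakSets", function(object) {
  n <- length(object@peaks)
  if (length(object@condition) != n || length(object@libSizes) != n) {
    return("peaks, condition and libSizes must have equal length")
  }
  if (!all(vapply(object@peaks, is, TRUE, "GRanges"))) {
    return("every element of peaks must be a GRanges")
  }
  tab <- table(object@condition)
  if (length(tab) != 2L) return("exactly 2 conditions required")
  if (!all(sort(names(tab)) == c("control", "treated"))) {
    return("condition labels must be 'control' and 'treated'")
  }
  if (any(tab < 2L)) return("each condition needs >= 2 replicates")
  if (any(object@libSizes <= 0)) return("library sizes must be positive")
  TRUE
})

#' Construct a ReplicatePeakSets
#' @param peaks Named list of peak \code{GRanges}, one per sample.
#' @param condition \code{control}/\code{treated} label per sample.
#' @param lib_sizes Total mapped tags per sample.
#' @return A validated [ReplicatePeakSets-class] object.
#' @export
replicatePeakSets <- function(peaks, condition, lib_sizes) {
  if (is.null(names(peaks))) {
    names(peaks) <- sprintf("%s_r%d", condition,
                            stats::ave(seq_along(condition), condition,
                                       FUN = seq_along))
  }
  new("ReplicatePeakSets", peaks = peaks,
      condition = as.character(condition), libSizes = as.numeric(lib_sizes))
}

#' @describeIn ReplicatePeakSets Condition label per sample.
#' @param object A \code{ReplicatePeakSets}.
#' @export
setGeneric("sampleConditions", function(object) standardGeneric("sampleConditions"))

#' @rdname ReplicatePeakSets
#' @export
setMethod("sampleConditions", "ReplicatePeakSets", function(object) {
  stats::setNames(object@condition, names(object@peaks))
})

#' @describeIn ReplicatePeakSets Library size per sample.
#' @export
setGeneric("libSizes", function(object) standardGeneric("libSizes"))

#' @rdname ReplicatePeakSets
#' @export
setMethod("libSizes", "ReplicatePeakSets", function(object) {
  stats::setNames(object@libSizes, names(object@peaks))
})

#' @describeIn ReplicatePeakSets Peak list accessor.
#' @export
setGeneric("peakSets", function(object) standardGeneric("peakSets"))

#' @rdname ReplicatePeakSets
#' @export
setMethod("peakSets", "ReplicatePeakSets", function(object) object@peaks)

setMethod("show", "ReplicatePeakSets", function(object) {
  cat("ReplicatePeakSets with", length(object@peaks), "samples\n")
  for (i in seq_along(object@peaks)) {
    cat(sprintf("  %-12s %-8s %6d peaks, library %s\n",
                names(object@peaks)[i], object@condition[i],
                length(object@peaks[[i]]),
                format(object@libSizes[i], big.mark = ",")))
  }
})

#' DifferentialPeakSet: the result of differential peak calling
#'
#' Holds the consensus peaks that survived the quantile filter together
#' with their moderated-t results (log2 fold change treated vs control,
#' t, p, BH q, direction call) and the thresholds used. A peak is called
#' differential iff its linear fold change exceeds \code{fc_cut} and its
#' BH-adjusted q-value is below \code{fdr_cut}.
#'
#' @slot peaks \code{GRanges} of tested consensus peaks; metadata columns
#'   \code{peak_id}, \code{source}, \code{log_fc}, \code{fc}, \code{t},
#'   \code{p}, \code{q}, \code{direction} (\code{up}/\code{down}/\code{ns}).
#' @slot thresholds Named list: \code{fc_cut}, \code{fdr_cut},
#'   \code{quantile_cut}.
#' @slot nUp,nDown Number of peaks called up / down.
#' @seealso [callDifferential()]
#' @export
setClass("DifferentialPeakSet",
  representation(peaks = "GRanges", thresholds = "list",
                 nUp = "integer", nDown = "integer")
)

setValidity("DifferentialPeakSet", function(object) {
  mc <- S4Vectors::mcols(object@peaks)
  need <- c("peak_id", "log_fc", "fc", "t", "p", "q", "direction")
  if (!all(need %in% names(mc))) {
    return(paste("peaks must carry metadata columns:", paste(need, collapse = ", ")))
  }
  dir <- mc$direction
  if (!all(dir %in% c("up", "down", "ns"))) {
    return("direction must be up/down/ns")
  }
  if (sum(dir == "up") != object@nUp || sum(dir == "down") != object@nDown) {
    return("nUp/nDown inconsistent with direction labels")
  }
  if (any(dir == "up" & mc$log_fc <= 0) || any(dir == "down" & mc$log_fc >= 0)) {
    return("direction must match the sign of log_fc")
  }
  TRUE
})

#' @describeIn DifferentialPeakSet Number of up-called peaks.
#' @param object A \code{DifferentialPeakSet}.
#' @export
setGeneric("nUp", function(object) standardGeneric("nUp"))

#' @rdname DifferentialPeakSet
#' @export
setMethod("nUp", "DifferentialPeakSet", function(object) object@nUp)

#' @describeIn DifferentialPeakSet Number of down-called peaks.
#' @export
setGeneric("nDown", function(object) standardGeneric("nDown"))

#' @rdname DifferentialPeakSet
#' @export
setMethod("nDown", "DifferentialPeakSet", function(object) object@nDown)

#' @describeIn DifferentialPeakSet Thresholds used for the call.
#' @export
setGeneric("callThresholds", function(object) standardGeneric("callThresholds"))

#' @rdname DifferentialPeakSet
#' @export
setMethod("callThresholds", "DifferentialPeakSet", function(object) object@thresholds)

#' @describeIn DifferentialPeakSet All tested peaks with their statistics,
#'   as a \code{data.frame} (one row per retained consensus peak).
#' @export
setGeneric("resultsTable", function(object) standardGeneric("resultsTable"))

#' @rdname DifferentialPeakSet
#' @export
setMethod("resultsTable", "DifferentialPeakSet", function(object) {
  gr <- object@peaks
  mc <- as.data.frame(S4Vectors::mcols(gr))
  data.frame(
    peak_id = mc$peak_id,
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    mc[, setdiff(names(mc), "peak_id"), drop = FALSE],
    stringsAsFactors = FALSE
  )
})

#' @describeIn DifferentialPeakSet \code{GRanges} of the peaks called
#'   differential (up or down).
#' @export
setGeneric("calledPeaks", function(object) standardGeneric("calledPeaks"))

#' @rdname DifferentialPeakSet
#' @export
setMethod("calledPeaks", "DifferentialPeakSet", function(object) {
  object@peaks[S4Vectors::mcols(object@peaks)$direction != "ns"]
})

setMethod("show", "DifferentialPeakSet", function(object) {
  cat("DifferentialPeakSet\n")
  cat("  tested peaks: ", length(object@peaks), "\n", sep = "")
  cat("  called:       ", object@nUp + object@nDown,
      " (", object@nUp, " up, ", object@nDown, " down)\n", sep = "")
  th <- object@thresholds
  cat(sprintf("  thresholds:   |FC| > %s, q < %s (quantile filter %s)\n",
              format(th$fc_cut), format(th$fdr_cut),
              format(th$quantile_cut)))
})

#' HotspotAssociation: differential peaks overlapping DSB hotspots
#'
#' Records which differential peaks overlap a DSB-hotspot map, the matched
#' hotspot indices, and how many associated peaks lie within genes.
#'
#' @slot pairs \code{data.frame} with columns \code{peak_id},
#'   \code{hotspot} (index into the hotspot map).
#' @slot nAssociatedPeaks Number of distinct associated peaks.
#' @slot nWithinGenes Of those, the number classified genic
#'   (\code{NA} when no gene models were supplied).
#' @seealso [associateHotspots()]
#' @export
setClass("HotspotAssociation",
  representation(pairs = "data.frame", nAssociatedPeaks = "integer",
                 nWithinGenes = "integer")
)

#' @describeIn HotspotAssociation Peak/hotspot pair table.
#' @param object A \code{HotspotAssociation}.
#' @export
setGeneric("associationPairs", function(object) standardGeneric("associationPairs"))

#' @rdname HotspotAssociation
#' @export
setMethod("associationPairs", "HotspotAssociation", function(object) object@pairs)

#' @describeIn HotspotAssociation Number of associated peaks.
#' @export
setGeneric("nAssociatedPeaks", function(object) standardGeneric("nAssociatedPeaks"))

#' @rdname HotspotAssociation
#' @export
setMethod("nAssociatedPeaks", "HotspotAssociation", function(object) object@nAssociatedPeaks)

#' @describeIn HotspotAssociation Number of associated peaks within genes.
#' @export
setGeneric("nWithinGenes", function(object) standardGeneric("nWithinGenes"))

#' @rdname HotspotAssociation
#' @export
setMethod("nWithinGenes", "HotspotAssociation", function(object) object@nWithinGenes)

setMethod("show", "HotspotAssociation", function(object) {
  cat("HotspotAssociation\n")
  cat("  associated peaks:   ", object@nAssociatedPeaks, "\n")
  cat("  ... within genes:   ",
      if (is.na(object@nWithinGenes)) "NA (no gene models supplied)" else object@nWithinGenes,
      "\n")
  cat("  peak-hotspot pairs: ", nrow(object@pairs), "\n")
})
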