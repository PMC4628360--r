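# Microarray-style differential expression and ChIP/expression integration.

#' Call differentially expressed genes
#'
#' Per-gene moderated t-test on a log2 expression matrix; a gene is called
#' iff its linear fold change satisfies \code{2^|log_fc| > fc_cut} and its
#' raw p-value is below \code{p_cut}. Raw p (not FDR) is thresholded here,
#' matching common microarray practice for small designs; the q-value is
#' still reported.
#'
#' @param em Log2 expression matrix (genes x samples, rownames = gene
#'   ids).
#' @param condition \code{control}/\code{treated} label per sample (>= 2
#'   per condition).
#' @param fc_cut Linear fold-change threshold (default 1.5).
#' @param p_cut Raw p-value threshold (default 0.05).
#' @param mod Optional [ModerationParams-class].
#' @return \code{data.frame} with the [moderatedTTest()] columns plus
#'   \code{q}, \code{called}, \code{direction}.
#' @export
deGenes <- function(em, condition, fc_cut = 1.5, p_cut = 0.05, mod = NULL) {
  .assert_scalar_number(fc_cut, "fc_cut", lower = 1)
  .assert_scalar_number(p_cut, "p_cut", lower = 0, upper = 1)
  res <- moderatedTTest(as.matrix(em), condition, mod)
  res$q <- bhFdr(res$p)
  res$called <- (2^abs(res$log_fc) > fc_cut) & (res$p < p_cut)
  res$direction <- ifelse(!res$called, "ns",
                          ifelse(res$log_fc > 0, "up", "down"))
  res
}

#' Shortlist genes by a stronger fold-change cut
#'
#' Subset of the supplied results with linear \code{|FC| >= fc_cut}
#' (inclusive boundary: a fold change of exactly 2 passes the default).
#'
#' @param results \code{data.frame} from [deGenes()] (typically
#'   pre-filtered to the called genes).
#' @param fc_cut Inclusive linear fold-change threshold (default 2).
#' @return Character vector of gene ids.
#' @export
shortlistGenes <- function(results, fc_cut = 2) {
  .assert_scalar_number(fc_cut, "fc_cut", lower = 1)
  results$feature_id[2^abs(results$log_fc) >= fc_cut]
}

#' Integrate expression changes with TSS peak signal
#'
#' For each differentially expressed gene, finds the consensus peaks
#' overlapping its TSS window and reports the ChIP fold change as the
#' ratio of mean normalized treated signal to mean normalized control
#' signal over those peaks. Genes with no peak near their TSS get an
#' undetermined ChIP fold change (rendered \code{ND} on disk). Every DE
#' gene yields exactly one record.
#'
#' @param de \code{data.frame} from [deGenes()]; only rows with
#'   \code{called == TRUE} are integrated.
#' @param se \code{SummarizedExperiment} of consensus peaks with a
#'   \code{scaled} assay and \code{condition} in \code{colData} (see
#'   [scaleNormalize()]).
#' @param genes Gene \code{GRanges}; DE gene ids must resolve here
#'   (unresolvable ids are skipped with a warning).
#' @param tss_window TSS window half-width in bp (default 1000).
#' @return \code{data.frame}: \code{gene_id}, \code{fc_expression}
#'   (linear), \code{direction}, \code{fc_chip} (linear or \code{NA}),
#'   \code{tss_peak_ids} (comma-separated or \code{NA}).
#' @export
integrateWithPeaks <- function(de, se, genes, tss_window = 1000L) {
  .assert_scalar_number(tss_window, "tss_window", lower = 0)
  called <- de[de$called, , drop = FALSE]
  gene_ids <- S4Vectors::mcols(genes)$gene_id
  unresolved <- setdiff(called$feature_id, gene_ids)
  if (length(unresolved)) {
    warning("skipping DE gene(s) not in the gene models: ",
            paste(utils::head(unresolved, 5), collapse = ", "))
    called <- called[called$feature_id %in% gene_ids, , drop = FALSE]
  }
  if (nrow(called) == 0L) {
    return(data.frame(gene_id = character(), fc_expression = numeric(),
                      direction = character(), fc_chip = numeric(),
                      tss_peak_ids = character(), stringsAsFactors = FALSE))
  }
  peaks <- SummarizedExperiment::rowRanges(se)
  scaled <- as.matrix(SummarizedExperiment::assay(se, "scaled"))
  cond <- as.character(SummarizedExperiment::colData(se)$condition)
  pid <- S4Vectors::mcols(peaks)$peak_id
  gidx <- match(called$feature_id, gene_ids)
  tw <- .tss_windows(genes[gidx], as.integer(tss_window))
  hits <- .find_overlaps(tw, peaks)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  fc_chip <- rep(NA_real_, nrow(called))
  peak_ids <- rep(NA_character_, nrow(called))
  for (i in unique(qh)) {
    rows <- sh[qh == i]
    mc <- mean(scaled[rows, cond == "control", drop = FALSE])
    mt <- mean(scaled[rows, cond == "treated", drop = FALSE])
    fc_chip[i] <- if (mc > 0) mt / mc else NA_real_
    peak_ids[i] <- paste(pid[rows], collapse = ",")
  }
  data.frame(
    gene_id = called$feature_id,
    fc_expression = called$fc,
    direction = called$direction,
    fc_chip = fc_chip,
    tss_peak_ids = peak_ids,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write an integration table
#'
#' Renders undetermined ChIP fold changes as the literal string \code{ND}.
#'
#' @param integration \code{data.frame} from [integrateWithPeaks()].
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writeIntegrationTable <- function(integration, path) {
  out <- integration
  out$fc_expression <- signif(out$fc_expression, 3)
  out$fc_chip <- ifelse(is.na(out$fc_chip), "ND",
                        format(signif(out$fc_chip, 3)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "ND")
  invisible(path)
}
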