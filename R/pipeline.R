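# Config-driven end-to-end orchestration: differential peaks -> annotation
# -> hotspot association -> sequence features -> differential expression ->
# integration, with a JSON summary and a plain-text log.

#' Validate a run configuration
#'
#' A run config is a YAML file or named list with a \code{simulate} block
#' (a seed plus optional [simConfig()] overrides) or an \code{inputs}
#' block (paths to replicate narrowPeak files, a counts TSV, gene table,
#' hotspot BED, chrom.sizes, FASTA, expression TSV, PAR counts), plus
#' optional \code{thresholds} (\code{fc_cut} 1.5, \code{fdr_cut} 0.05,
#' \code{quantile_cut} 0.05, \code{genic_flank} 1000, \code{tss_window}
#' 1000, \code{at_min_len} 8, \code{min_overlap} 1, \code{pseudocount} 1)
#' and \code{output_dir}.
#'
#' @param cfg Path to a YAML file or a named list.
#' @return The validated config list with defaults filled in.
#' @export
runConfig <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1L) {
    if (!file.exists(cfg)) stop("config file not found: ", cfg)
    cfg <- yaml::read_yaml(cfg)
  }
  stopifnot(is.list(cfg))
  th_default <- list(fc_cut = 1.5, fdr_cut = 0.05, quantile_cut = 0.05,
                    genic_flank = 1000L, tss_window = 1000L,
                    at_min_len = 8L, min_overlap = 1L, pseudocount = 1)
  th <- utils::modifyList(th_default, cfg$thresholds %||% list())
  .assert_scalar_number(th$fc_cut, "fc_cut", lower = 1)
  .assert_scalar_number(th$fdr_cut, "fdr_cut", lower = 0, upper = 1)
  .assert_scalar_number(th$quantile_cut, "quantile_cut", lower = 0, upper = 1)
  cfg$thresholds <- th
  if (is.null(cfg$simulate) && is.null(cfg$inputs)) {
    stop("config needs a 'simulate' or an 'inputs' block")
  }
  if (!is.null(cfg$inputs)) {
    paths <- unlist(cfg$inputs[vapply(cfg$inputs, is.character, TRUE)])
    missing_paths <- paths[!file.exists(paths)]
    if (length(missing_paths)) {
      stop("input path(s) do not exist: ",
           paste(missing_paths, collapse = ", "))
    }
  }
  if (is.null(cfg$output_dir)) stop("config needs 'output_dir'")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes, in fixed order: differential peak calling (reproducibility,
#' consensus, quantification, normalization, quantile filter, moderated
#' test), annotation, hotspot association with intensity comparison and
#' PAR-like region signal, large-gene sequence features, differential
#' expression, and TSS integration. Emits all TSV/BED outputs, a summary
#' JSON whose counts satisfy \code{n_up + n_down = n_differential}, and a
#' run log recording the package version, seed and thresholds. Stages
#' whose inputs are absent (hotspot map, FASTA, expression matrix) are
#' skipped with a logged notice; any stage error aborts the run naming the
#' stage. Outputs carry no timestamps, so a rerun with the same config is
#' byte-identical.
#'
#' @param cfg Run configuration (path or list); see [runConfig()].
#' @return Invisibly, a list with the pipeline objects (\code{genome},
#'   \code{consensus}, \code{se}, \code{diff}, \code{annotation},
#'   \code{hotspot}, \code{par}, \code{features}, \code{de},
#'   \code{integration}, \code{truth}, \code{summary}).
#' @export
runAll <- function(cfg) {
  cfg <- runConfig(cfg)
  th <- cfg$thresholds
  out_dir <- cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    paste0("diffmark ", as.character(utils::packageVersion("diffmark"))),
    paste0("thresholds: ",
           paste(sprintf("%s=%s", names(th), vapply(th, format, "")),
                 collapse = " "))
  )
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  acfg <- annotationConfig(genic_flank = th$genic_flank,
                           tss_window = th$tss_window)

  # ---- inputs -------------------------------------------------------------
  genome <- NULL
  truth <- list()
  par_counts <- NULL
  expr <- NULL
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    scfg <- stage("simulate", do.call(simConfig, sim_args))
    note("simulate: seed ", scfg$seed)
    genome <- stage("simulate", generateGenome(scfg))
    pk <- stage("simulate", generatePeakReplicates(scfg, genome))
    sets <- pk$sets
    consensus <- stage("diffpeaks", buildConsensus(sets, th$min_overlap))
    cnt <- stage("simulate",
                 generateCounts(scfg, consensus, hotspots = genome$hotspots))
    counts <- SummarizedExperiment::assay(cnt$se, "counts")
    truth$peaks <- cnt$truth
    par_counts <- generateParCounts(scfg)
    ex <- stage("simulate",
                generateExpression(scfg, genome, cnt$truth, consensus,
                                   tss_window = th$tss_window))
    expr <- ex
    truth$genes <- ex$truth
    genes <- genome$genes
    hotspots <- genome$hotspots
    chrom_sizes <- genome$chrom_sizes
    fasta <- genome$fasta
    par_region <- genome$par_region
    lib_sizes <- scfg$lib_sizes
  } else {
    inp <- cfg$inputs
    sets <- stage("read", {
      reps <- lapply(inp$replicate_peaks, readPeakBed,
                     dialect = inp$peak_dialect %||% "narrowPeak")
      replicatePeakSets(reps, condition = unlist(inp$replicate_conditions),
                        lib_sizes = unlist(inp$lib_sizes))
    })
    consensus <- stage("diffpeaks", buildConsensus(sets, th$min_overlap))
    counts <- stage("read", {
      tab <- utils::read.delim(inp$counts, check.names = FALSE)
      m <- as.matrix(tab[, -1, drop = FALSE])
      rownames(m) <- tab[[1L]]
      m
    })
    genes <- if (!is.null(inp$genes)) readGeneTable(inp$genes) else NULL
    hotspots <- if (!is.null(inp$hotspots)) readHotspotBed(inp$hotspots) else NULL
    chrom_sizes <- if (!is.null(inp$chrom_sizes)) readChromSizes(inp$chrom_sizes) else NULL
    fasta <- if (!is.null(inp$fasta)) readGenomeFasta(inp$fasta) else NULL
    par_region <- NULL
    if (!is.null(inp$par_region)) {
      m <- regmatches(inp$par_region,
                      regexec("^(.+):([0-9]+)-([0-9]+)$", inp$par_region))[[1]]
      if (length(m) != 4L) stop("par_region must look like 'chrom:start-end'")
      par_region <- GenomicRanges::GRanges(
        m[2], IRanges::IRanges(as.numeric(m[3]) + 1, as.numeric(m[4])))
    }
    if (!is.null(inp$par_counts)) {
      pc <- utils::read.delim(inp$par_counts, header = FALSE)
      par_counts <- stats::setNames(pc[[2L]], pc[[1L]])
    }
    if (!is.null(inp$expression)) {
      tab <- utils::read.delim(inp$expression, check.names = FALSE)
      ev <- as.matrix(tab[, -1, drop = FALSE])
      rownames(ev) <- tab[[1L]]
      expr <- list(values = ev,
                   condition = unlist(inp$expression_conditions))
    }
    lib_sizes <- unlist(inp$lib_sizes)
  }

  # ---- differential peaks -------------------------------------------------
  result <- stage("diffpeaks", {
    se <- peakCountMatrix(counts, sampleConditions(sets), lib_sizes,
                          consensus = consensus)
    se <- scaleNormalize(se)
    se <- logTransform(se, pseudocount = th$pseudocount)
    retained <- quantileFilter(se, q = th$quantile_cut)
    diff <- callDifferential(se, retained, fc_cut = th$fc_cut,
                             fdr_cut = th$fdr_cut,
                             quantile_cut = th$quantile_cut)
    list(se = se, retained = retained, diff = diff)
  })
  diff <- result$diff
  called <- calledPeaks(diff)
  note("diffpeaks: ", length(consensus), " consensus, ",
       length(result$retained), " retained, ",
       nUp(diff) + nDown(diff), " called (", nUp(diff), " up, ",
       nDown(diff), " down)")
  writeDifferentialPeaks(diff,
                         tsv_path = file.path(out_dir, "differential_peaks.tsv"),
                         bed_path = file.path(out_dir, "called_peaks.bed"))

  summary <- list(
    n_consensus = length(consensus),
    n_retained = length(result$retained),
    n_differential = nUp(diff) + nDown(diff),
    n_up = nUp(diff),
    n_down = nDown(diff)
  )
  stopifnot(summary$n_up + summary$n_down == summary$n_differential)

  # ---- annotation ---------------------------------------------------------
  annotation <- NULL
  if (!is.null(genes)) {
    annotation <- stage("annotate",
                        annotateSummary(called, genes, acfg, chrom_sizes))
    note("annotate: ", annotation$n_genic, " genic / ",
         annotation$n_intergenic, " intergenic, ",
         sprintf("%.1f%%", annotation$pct_tss), " at TSS, ",
         annotation$n_ncrna, " on ncRNA")
    summary$n_genic <- annotation$n_genic
    summary$n_intergenic <- annotation$n_intergenic
    summary$pct_genic <- annotation$pct_genic
    summary$pct_tss <- annotation$pct_tss
    summary$n_ncrna <- annotation$n_ncrna
    if (!is.null(annotation$chrom_correlation)) {
      summary$chrom_length_correlation <- annotation$chrom_correlation
    }
    ann_tab <- data.frame(
      peak_id = S4Vectors::mcols(called)$peak_id,
      chrom = as.character(GenomeInfoDb::seqnames(called)),
      start = GenomicRanges::start(called) - 1,
      end = GenomicRanges::end(called),
      genic = annotation$genic_label,
      stringsAsFactors = FALSE)
    utils::write.table(ann_tab, file.path(out_dir, "annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    note("annotate: skipped (no gene models)")
    summary$stages_skipped <- c(summary$stages_skipped, "annotate")
  }

  # ---- hotspot association ------------------------------------------------
  hotspot <- NULL
  par_sig <- NULL
  if (!is.null(hotspots)) {
    hotspot <- stage("hotspots", {
      assoc <- associateHotspots(called, hotspots, genes, acfg)
      cmp <- if (nAssociatedPeaks(assoc) > 0) {
        intensityCompare(assoc, hotspots)
      } else {
        NULL
      }
      list(assoc = assoc, intensity = cmp)
    })
    note("hotspots: ", nAssociatedPeaks(hotspot$assoc),
         " differential peaks on hotspots")
    summary$n_hotspot_associated <- nAssociatedPeaks(hotspot$assoc)
    summary$n_hotspot_within_genes <- nWithinGenes(hotspot$assoc)
    if (!is.null(hotspot$intensity)) {
      summary$median_log_tags_associated <- hotspot$intensity$median_associated
      summary$median_log_tags_all <- hotspot$intensity$median_all
      summary$intensity_p <- hotspot$intensity$p_value
    }
    if (!is.null(genes)) {
      ghs <- stage("hotspots", geneHotspotSummary(genes, hotspots))
      utils::write.table(ghs, file.path(out_dir, "gene_hotspots.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  } else {
    note("hotspots: skipped (no hotspot map)")
    summary$stages_skipped <- c(summary$stages_skipped, "hotspots")
  }
  if (!is.null(par_counts) && !is.null(lib_sizes)) {
    par_sig <- stage("hotspots",
                     regionSignal(par_counts, lib_sizes = lib_sizes,
                                  condition = sampleConditions(sets)))
    summary$par_ratio <- par_sig$ratio
    note("hotspots: PAR-like region treated/control ratio ",
         format(par_sig$ratio, digits = 3))
  }

  # ---- sequence features --------------------------------------------------
  features <- NULL
  if (!is.null(fasta) && !is.null(genes)) {
    large <- S4Vectors::mcols(genes)$large
    feat_genes <- if (!is.null(large)) genes[large] else genes
    features <- stage("seqfeat",
                      geneFeatureTable(feat_genes, fasta,
                                       min_len = th$at_min_len))
    utils::write.table(features, file.path(out_dir, "gene_features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("seqfeat: features for ", nrow(features),
         " gene(s), AT-stretch min length ", th$at_min_len)
  } else {
    note("seqfeat: skipped (no FASTA)")
    summary$stages_skipped <- c(summary$stages_skipped, "seqfeat")
  }

  # ---- differential expression + integration ------------------------------
  de <- NULL
  integration <- NULL
  if (!is.null(expr)) {
    de <- stage("diffexpr", deGenes(expr$values, expr$condition,
                                    fc_cut = th$fc_cut))
    shortlist <- shortlistGenes(de[de$called, , drop = FALSE])
    note("diffexpr: ", sum(de$called), " DE genes, ",
         length(shortlist), " on the FC>=2 shortlist")
    summary$n_de_genes <- sum(de$called)
    summary$n_shortlist <- length(shortlist)
    de_out <- de
    num <- vapply(de_out, is.numeric, TRUE)
    de_out[num] <- lapply(de_out[num], signif, 6)
    utils::write.table(de_out, file.path(out_dir, "de_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(shortlist, file.path(out_dir, "shortlist.txt"))
    if (!is.null(genes)) {
      integration <- stage("integrate",
                           integrateWithPeaks(de, result$se, genes,
                                              tss_window = th$tss_window))
      writeIntegrationTable(integration,
                            file.path(out_dir, "integration.tsv"))
      summary$n_integrated <- nrow(integration)
      summary$n_chip_nd <- sum(is.na(integration$fc_chip))
    }
  } else {
    note("diffexpr: skipped (no expression matrix)")
    summary$stages_skipped <- c(summary$stages_skipped, "diffexpr")
  }

  # ---- report -------------------------------------------------------------
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(genome = genome, sets = sets, consensus = consensus,
                 se = result$se, retained = result$retained, diff = diff,
                 annotation = annotation, hotspot = hotspot, par = par_sig,
                 features = features, de = de, integration = integration,
                 truth = truth, summary = summary))
}
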