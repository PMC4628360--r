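# Synthetic-data generator: genome, replicate peak sets, negative-binomial
# count matrices and expression matrices with ground-truth labels, so the
# whole pipeline is testable without external data.

#' Simulation configuration
#'
#' Defaults encode the study design the pipeline targets: a two-condition,
#' two-replicate ChIP experiment over ~2000 consensus peaks with a small,
#' strongly asymmetric differential fraction (5\% at linear fold change 3,
#' 97:3 up:down), negative-binomial tag counts (dispersion 0.05, mean
#' depth 50 per peak) under imbalanced library sizes, heavy-tailed
#' (log-normal) DMC1 hotspot intensities, a PAR-like region losing half
#' its signal in the treated condition at depth 200, a handful of very
#' large (>= 0.5 Mb) AT-rich genes, and a 3 vs 3 expression design with
#' 5\% differential genes at fold change 2 partially linked to
#' differential TSS peaks.
#'
#' @param seed Mandatory RNG seed; every generator derives its streams
#'   from it and is fully deterministic given it.
#' @param n_chromosomes,chrom_lengths Genome shape; lengths default to a
#'   linearly decreasing ladder from 3 Mb.
#' @param n_consensus_peaks Number of base peaks.
#' @param peak_width Range (bp) peak widths are drawn from.
#' @param n_genes,n_large_genes,large_gene_min Gene counts; large genes
#'   are at least \code{large_gene_min} bp.
#' @param ncrna_fraction Fraction of (non-large) genes that are ncRNA.
#' @param n_hotspots Hotspot count, apportioned to chromosomes in
#'   proportion to length.
#' @param hotspot_width Hotspot width (bp).
#' @param hotspot_meanlog,hotspot_sdlog Log-normal law of DMC1 tag counts.
#' @param diff_fraction,up_fraction,effect_fc Differential peak fraction,
#'   probability a differential peak goes up, and linear effect size.
#' @param nb_dispersion,mean_depth,depth_sdlog Negative-binomial noise:
#'   dispersion and mean tags per peak. \code{depth_sdlog} adds an
#'   optional log-normal spread to per-peak baselines; the default 0 keeps
#'   every baseline at the stated mean depth.
#' @param lib_sizes Library sizes of the four ChIP samples (control x2,
#'   treated x2), deliberately imbalanced.
#' @param dropout,jitter_bp Per-replicate peak dropout probability and
#'   boundary jitter (bp).
#' @param tss_peak_fraction Fraction of genes receiving a TSS peak.
#' @param hotspot_peak_fraction Fraction of base peaks placed on hotspots
#'   (sampled with probability proportional to hotspot intensity, so
#'   peak-bearing hotspots skew hot).
#' @param par_width,par_ratio,par_depth PAR-like region width, injected
#'   treated/control signal ratio, and control tag depth in the region.
#' @param background_at,large_gene_at Genome background and large-gene AT
#'   fractions.
#' @param de_fraction,de_log_fc,expr_noise_sd,expr_baseline_mean,expr_baseline_sd
#'   Expression design: differential gene fraction, injected |log2 FC|,
#'   residual noise sd, and baseline law.
#' @param n_expr_reps Replicates per condition on the expression side.
#' @param link_prob Probability that a differential expression gene is
#'   linked to a same-sign differential TSS peak.
#' @return Named list of class \code{sim_config}.
#' @export
simConfig <- function(seed,
                      n_chromosomes = 6L,
                      chrom_lengths = NULL,
                      n_consensus_peaks = 2000L,
                      peak_width = c(500L, 2000L),
                      n_genes = 300L,
                      n_large_genes = 3L,
                      large_gene_min = 5e5,
                      ncrna_fraction = 0.15,
                      n_hotspots = 500L,
                      hotspot_width = 1000L,
                      hotspot_meanlog = log(100),
                      hotspot_sdlog = 1.0,
                      diff_fraction = 0.05,
                      up_fraction = 0.97,
                      effect_fc = 3,
                      nb_dispersion = 0.05,
                      mean_depth = 50,
                      depth_sdlog = 0,
                      lib_sizes = c(1.0e6, 1.2e6, 0.85e6, 1.1e6),
                      dropout = 0.05,
                      jitter_bp = 50L,
                      tss_peak_fraction = 0.5,
                      hotspot_peak_fraction = 0.15,
                      par_width = 5e4,
                      par_ratio = 0.5,
                      par_depth = 200,
                      background_at = 0.58,
                      large_gene_at = 0.64,
                      de_fraction = 0.05,
                      de_log_fc = 1,
                      expr_noise_sd = 0.25,
                      expr_baseline_mean = 8,
                      expr_baseline_sd = 1,
                      n_expr_reps = 3L,
                      link_prob = 0.8) {
  if (missing(seed)) stop("'seed' is mandatory")
  .assert_scalar_number(seed, "seed")
  if (is.null(chrom_lengths)) {
    n <- n_chromosomes
    chrom_lengths <- round(3e6 * seq(1, 0.2, length.out = n))
  }
  names(chrom_lengths) <- sprintf("chr%d", seq_along(chrom_lengths))
  for (p in c("ncrna_fraction", "diff_fraction", "up_fraction", "dropout",
              "tss_peak_fraction", "hotspot_peak_fraction", "de_fraction",
              "link_prob")) {
    .assert_scalar_number(get(p), p, lower = 0, upper = 1)
  }
  .assert_scalar_number(nb_dispersion, "nb_dispersion", lower = 0)
  .assert_scalar_number(effect_fc, "effect_fc", lower = 1)
  cfg <- list(
    seed = seed, n_chromosomes = length(chrom_lengths),
    chrom_lengths = chrom_lengths,
    n_consensus_peaks = n_consensus_peaks, peak_width = peak_width,
    n_genes = n_genes, n_large_genes = n_large_genes,
    large_gene_min = large_gene_min, ncrna_fraction = ncrna_fraction,
    n_hotspots = n_hotspots, hotspot_width = hotspot_width,
    hotspot_meanlog = hotspot_meanlog, hotspot_sdlog = hotspot_sdlog,
    diff_fraction = diff_fraction, up_fraction = up_fraction,
    effect_fc = effect_fc, nb_dispersion = nb_dispersion,
    mean_depth = mean_depth, depth_sdlog = depth_sdlog,
    lib_sizes = lib_sizes, dropout = dropout, jitter_bp = jitter_bp,
    tss_peak_fraction = tss_peak_fraction,
    hotspot_peak_fraction = hotspot_peak_fraction,
    par_width = par_width, par_ratio = par_ratio, par_depth = par_depth,
    background_at = background_at, large_gene_at = large_gene_at,
    de_fraction = de_fraction, de_log_fc = de_log_fc,
    expr_noise_sd = expr_noise_sd,
    expr_baseline_mean = expr_baseline_mean,
    expr_baseline_sd = expr_baseline_sd,
    n_expr_reps = n_expr_reps, link_prob = link_prob
  )
  class(cfg) <- c("sim_config", "list")
  cfg
}

# Random DNA of a given AT fraction (A/T and C/G split evenly).
.random_dna <- function(n, at_fraction) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c(at_fraction / 2, at_fraction / 2,
                        (1 - at_fraction) / 2, (1 - at_fraction) / 2)),
        collapse = "")
}

# Place n non-overlapping intervals of the given widths on [1, L];
# errors when they cannot fit.
.place_nonoverlapping <- function(widths, L) {
  n <- length(widths)
  if (n == 0L) return(data.frame(start = integer(), end = integer()))
  free <- L - sum(widths)
  if (free < 0) {
    stop("infeasible packing: ", sum(widths), " bp of features on a ",
         L, " bp chromosome")
  }
  gaps <- diff(c(0, sort(stats::runif(n, 0, free))))
  starts <- cumsum(gaps) + cumsum(c(0, widths[-n])) + 1
  data.frame(start = as.integer(round(starts)),
             end = as.integer(round(starts) + widths - 1L))
}

#' Generate a synthetic genome
#'
#' Builds chromosome sizes, non-overlapping gene models (including the
#' configured number of very large AT-rich genes), a hotspot map with
#' per-chromosome counts proportional to chromosome length and log-normal
#' DMC1 intensities, a PAR-like region at the end of the last chromosome,
#' and the genome FASTA. Deterministic given the config seed.
#'
#' @param cfg A [simConfig()].
#' @param make_fasta Set \code{FALSE} to skip sequence synthesis (the
#'   slowest part) when only intervals are needed.
#' @return List: \code{chrom_sizes}, \code{genes} (\code{GRanges}),
#'   \code{hotspots} (\code{GRanges} with \code{dmc1_tags}),
#'   \code{par_region} (\code{GRanges}), \code{fasta}
#'   (\code{DNAStringSet} or \code{NULL}).
#' @export
generateGenome <- function(cfg, make_fasta = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    sizes <- cfg$chrom_lengths
    n_chr <- length(sizes)

    # genes: large genes on the largest chromosomes, one each; the rest
    # apportioned by length
    n_small <- cfg$n_genes - cfg$n_large_genes
    if (n_small < 0) stop("n_large_genes exceeds n_genes")
    if (cfg$n_large_genes > 0 &&
        0.45 * max(sizes) < cfg$large_gene_min) {
      stop("infeasible packing: chromosomes too short for a ",
           cfg$large_gene_min, " bp gene")
    }
    big_chr <- order(sizes, decreasing = TRUE)[seq_len(cfg$n_large_genes)]
    # deterministic proportional allocation keeps every chromosome packable
    alloc <- floor(n_small * sizes / sum(sizes))
    short <- n_small - sum(alloc)
    if (short > 0) {
      top <- order(sizes, decreasing = TRUE)[seq_len(short)]
      alloc[top] <- alloc[top] + 1L
    }
    gene_rows <- list()
    for (ci in seq_len(n_chr)) {
      n_large_here <- sum(big_chr == ci)
      widths_large <- if (n_large_here > 0) {
        round(stats::runif(n_large_here, cfg$large_gene_min,
                           min(1.6 * cfg$large_gene_min, 0.45 * sizes[ci])))
      } else {
        numeric()
      }
      widths_small <- round(pmin(pmax(
        stats::rlnorm(alloc[ci], log(1.5e4), 0.6), 2e3),
        min(8e4, sizes[ci] / 10)))
      widths <- c(widths_large, widths_small)
      if (length(widths) == 0L) next
      pos <- .place_nonoverlapping(widths, sizes[ci])
      gene_rows[[ci]] <- data.frame(
        chrom = names(sizes)[ci], start0 = pos$start - 1L, end0 = pos$end,
        large = c(rep(TRUE, length(widths_large)),
                  rep(FALSE, length(widths_small)))
      )
    }
    gtab <- do.call(rbind, gene_rows)
    n_g <- nrow(gtab)
    gtab$strand <- sample(c("+", "-"), n_g, replace = TRUE)
    gtab$biotype <- ifelse(gtab$large, "coding",
                           ifelse(stats::runif(n_g) < cfg$ncrna_fraction,
                                  "ncRNA", "coding"))
    ord <- order(match(gtab$chrom, names(sizes)), gtab$start0)
    gtab <- gtab[ord, ]
    gtab$gene_id <- sprintf("gene_%04d", seq_len(n_g))
    genes <- geneGRanges(gtab$gene_id, gtab$chrom, gtab$start0, gtab$end0,
                         gtab$strand, gtab$biotype)
    S4Vectors::mcols(genes)$large <- gtab$large

    # hotspots: counts per chromosome ~ multinomial with prob ~ length
    hs_alloc <- as.vector(stats::rmultinom(1, cfg$n_hotspots,
                                           prob = sizes / sum(sizes)))
    hs_rows <- list()
    for (ci in seq_len(n_chr)) {
      k <- hs_alloc[ci]
      if (k == 0L) next
      start1 <- sort(sample.int(max(1L, sizes[ci] - cfg$hotspot_width), k))
      hs_rows[[ci]] <- data.frame(chrom = names(sizes)[ci], start1 = start1)
    }
    htab <- do.call(rbind, hs_rows)
    hotspots <- GenomicRanges::GRanges(
      seqnames = htab$chrom,
      ranges = IRanges::IRanges(start = htab$start1,
                                width = cfg$hotspot_width))
    S4Vectors::mcols(hotspots)$dmc1_tags <- pmax(
      1L, as.integer(round(stats::rlnorm(length(hotspots),
                                         cfg$hotspot_meanlog,
                                         cfg$hotspot_sdlog))))

    last <- names(sizes)[n_chr]
    par_region <- GenomicRanges::GRanges(
      last, IRanges::IRanges(start = sizes[[n_chr]] - cfg$par_width + 1L,
                             end = sizes[[n_chr]]))

    fasta <- NULL
    if (make_fasta) {
      seqs <- lapply(seq_len(n_chr), function(ci) {
        .random_dna(sizes[[ci]], cfg$background_at)
      })
      names(seqs) <- names(sizes)
      # overwrite large-gene bodies with AT-rich sequence
      for (i in which(S4Vectors::mcols(genes)$large)) {
        ch <- as.character(GenomeInfoDb::seqnames(genes))[i]
        s <- GenomicRanges::start(genes)[i]
        e <- GenomicRanges::end(genes)[i]
        substr(seqs[[ch]], s, e) <- .random_dna(e - s + 1L, cfg$large_gene_at)
      }
      fasta <- Biostrings::DNAStringSet(unlist(seqs))
    }
    list(chrom_sizes = sizes, genes = genes, hotspots = hotspots,
         par_region = par_region, fasta = fasta)
  })
}

#' Generate replicate peak sets
#'
#' Places a base peak set over gene TSSs, hotspots (sampled with
#' probability proportional to intensity) and random background, then
#' derives each replicate by independent peak dropout and boundary jitter.
#' Jitter never inverts a peak.
#'
#' @param cfg A [simConfig()].
#' @param genome Output of [generateGenome()].
#' @return List: \code{sets} (a [ReplicatePeakSets-class] with samples
#'   \code{control_r1/r2}, \code{treated_r1/r2}) and \code{base_peaks}
#'   (the \code{GRanges} the replicates were derived from).
#' @export
generatePeakReplicates <- function(cfg, genome) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 1L, {
    sizes <- cfg$chrom_lengths
    genes <- genome$genes
    hotspots <- genome$hotspots
    n_total <- cfg$n_consensus_peaks

    n_tss <- min(round(cfg$tss_peak_fraction * length(genes)), n_total)
    n_hs <- min(round(cfg$hotspot_peak_fraction * n_total),
                length(hotspots), n_total - n_tss)
    n_bg <- n_total - n_tss - n_hs

    widths <- function(k) round(stats::runif(k, cfg$peak_width[1],
                                             cfg$peak_width[2]))
    rows <- list()
    if (n_tss > 0) {
      gi <- sample(seq_along(genes), n_tss)
      w <- widths(n_tss)
      tss <- S4Vectors::mcols(genes)$tss[gi]
      rows$tss <- data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(genes))[gi],
        start = pmax(1L, as.integer(tss - round(w / 2))), w = w,
        origin = "tss")
    }
    if (n_hs > 0) {
      tags <- S4Vectors::mcols(hotspots)$dmc1_tags
      hi <- sample(seq_along(hotspots), n_hs, prob = tags / sum(tags))
      w <- widths(n_hs)
      mid <- round((GenomicRanges::start(hotspots)[hi] +
                    GenomicRanges::end(hotspots)[hi]) / 2)
      rows$hs <- data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(hotspots))[hi],
        start = pmax(1L, as.integer(mid - round(w / 2))), w = w,
        origin = "hotspot")
    }
    if (n_bg > 0) {
      ci <- sample(seq_along(sizes), n_bg, replace = TRUE,
                   prob = sizes / sum(sizes))
      w <- widths(n_bg)
      start <- vapply(seq_len(n_bg), function(i) {
        sample.int(max(1L, sizes[[ci[i]]] - w[i]), 1L)
      }, 0L)
      rows$bg <- data.frame(chrom = names(sizes)[ci], start = start, w = w,
                            origin = "background")
    }
    tab <- do.call(rbind, rows)
    base <- GenomicRanges::GRanges(
      seqnames = tab$chrom,
      ranges = IRanges::IRanges(start = tab$start, width = tab$w))
    S4Vectors::mcols(base)$origin <- tab$origin
    base <- BiocGenerics::sort(base)
    S4Vectors::mcols(base)$base_id <- sprintf("base_%05d", seq_along(base))

    jitter_rep <- function() {
      keep <- stats::runif(length(base)) >= cfg$dropout
      gr <- base[keep]
      if (cfg$jitter_bp > 0 && length(gr)) {
        j1 <- round(stats::runif(length(gr), -cfg$jitter_bp, cfg$jitter_bp))
        j2 <- round(stats::runif(length(gr), -cfg$jitter_bp, cfg$jitter_bp))
        ns <- pmax(1L, as.integer(GenomicRanges::start(gr) + j1))
        ne <- as.integer(GenomicRanges::end(gr) + j2)
        ne <- pmax(ne, ns + 49L)  # floor width 50 bp; jitter never inverts
        IRanges::ranges(gr) <- IRanges::IRanges(start = ns, end = ne)
      }
      gr
    }
    samples <- c("control_r1", "control_r2", "treated_r1", "treated_r2")
    reps <- lapply(samples, function(s) jitter_rep())
    names(reps) <- samples
    sets <- replicatePeakSets(
      reps, condition = c("control", "control", "treated", "treated"),
      lib_sizes = cfg$lib_sizes)
    list(sets = sets, base_peaks = base)
  })
}

#' Generate negative-binomial peak counts with ground truth
#'
#' Draws per-peak baselines from a log-normal law around the configured
#' mean depth, samples the differential subset (biased toward
#' hotspot-overlapping peaks when a genome is supplied, mirroring the
#' association of altered marks with strong hotspots), assigns signs with
#' the configured up:down asymmetry, and emits NB counts with mean
#' \code{baseline x (lib/mean lib) x FC^treated} and the configured
#' dispersion (Poisson in the dispersion -> 0 limit).
#'
#' @param cfg A [simConfig()].
#' @param consensus Consensus peak \code{GRanges}, or an integer number of
#'   abstract peaks.
#' @param hotspots Optional hotspot \code{GRanges}; differential peaks are
#'   sampled with tripled weight on hotspot-overlapping peaks.
#' @param seed_offset Stream offset so multiple independent matrices can
#'   be drawn from one config.
#' @return List: \code{se} (counts \code{SummarizedExperiment}; see
#'   [peakCountMatrix()]) and \code{truth} (\code{data.frame}
#'   \code{peak_id}, \code{log_fc} of the injected differential peaks).
#' @export
generateCounts <- function(cfg, consensus, hotspots = NULL, seed_offset = 0L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$nb_dispersion < 0) stop("dispersion must be >= 0")
  with_seed(cfg$seed + 2L + seed_offset, {
    if (is.numeric(consensus) && length(consensus) == 1L) {
      n <- as.integer(consensus)
      ids <- sprintf("peak_%05d", seq_len(n))
      gr <- NULL
    } else {
      gr <- consensus
      n <- length(gr)
      ids <- S4Vectors::mcols(gr)$peak_id
      if (is.null(ids)) ids <- sprintf("peak_%05d", seq_len(n))
    }
    baseline <- stats::rlnorm(n, log(cfg$mean_depth) - cfg$depth_sdlog^2 / 2,
                              cfg$depth_sdlog)
    n_diff <- round(cfg$diff_fraction * n)
    weight <- rep(1, n)
    if (!is.null(hotspots) && !is.null(gr)) {
      weight[.overlaps_any(gr, hotspots)] <- 3
    }
    diff_idx <- if (n_diff > 0) {
      sample(seq_len(n), n_diff, prob = weight / sum(weight))
    } else {
      integer()
    }
    sign <- ifelse(stats::runif(n_diff) < cfg$up_fraction, 1, -1)
    log_fc <- rep(0, n)
    log_fc[diff_idx] <- sign * log2(cfg$effect_fc)

    libs <- cfg$lib_sizes
    cond <- c("control", "control", "treated", "treated")
    size_factor <- libs / mean(libs)
    counts <- matrix(0L, nrow = n, ncol = 4L,
                     dimnames = list(ids, c("control_r1", "control_r2",
                                            "treated_r1", "treated_r2")))
    for (j in 1:4) {
      mu <- baseline * size_factor[j]
      if (cond[j] == "treated") mu <- mu * 2^log_fc
      counts[, j] <- if (cfg$nb_dispersion < 1e-8) {
        stats::rpois(n, mu)
      } else {
        stats::rnbinom(n, mu = mu, size = 1 / cfg$nb_dispersion)
      }
    }
    se <- peakCountMatrix(counts, cond, libs, consensus = gr)
    truth <- data.frame(peak_id = ids[diff_idx],
                        log_fc = log_fc[diff_idx],
                        stringsAsFactors = FALSE)
    list(se = se, truth = truth)
  })
}

#' Generate PAR-like region counts
#'
#' Per-sample Poisson tag counts inside the PAR-like region with the
#' injected treated/control ratio, scaled by library size.
#'
#' @param cfg A [simConfig()].
#' @return Named vector of counts for the four ChIP samples.
#' @export
generateParCounts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 3L, {
    libs <- cfg$lib_sizes
    cond <- c("control", "control", "treated", "treated")
    mu <- cfg$par_depth * (libs / mean(libs)) *
      ifelse(cond == "treated", cfg$par_ratio, 1)
    stats::setNames(stats::rpois(4L, mu),
                    c("control_r1", "control_r2", "treated_r1", "treated_r2"))
  })
}

#' Generate a log2 expression matrix with ground truth
#'
#' Gaussian log2 intensities for every gene over a 3 vs 3 design, with a
#' configured fraction of differential genes. With probability
#' \code{link_prob} a differential gene is drawn from the genes whose TSS
#' window holds an injected differential peak and inherits that peak's
#' sign, reproducing the peak/expression agreement structure; the
#' remainder are unlinked with random sign.
#'
#' @param cfg A [simConfig()].
#' @param genome Output of [generateGenome()].
#' @param peak_truth \code{data.frame} of injected differential peaks
#'   (\code{peak_id}, \code{log_fc}) as returned by [generateCounts()].
#' @param consensus Consensus \code{GRanges} resolving the truth peak ids
#'   to coordinates (may be \code{NULL}: no linkage then).
#' @param tss_window TSS window half-width used for linkage (default 1000).
#' @return List: \code{values} (genes x samples log2 matrix),
#'   \code{condition}, \code{truth} (\code{data.frame} \code{gene_id},
#'   \code{log_fc}, \code{linked}).
#' @export
generateExpression <- function(cfg, genome, peak_truth = NULL,
                               consensus = NULL, tss_window = 1000L) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 4L, {
    genes <- genome$genes
    ids <- S4Vectors::mcols(genes)$gene_id
    n_g <- length(genes)
    reps <- cfg$n_expr_reps
    cond <- rep(c("control", "treated"), each = reps)
    baseline <- stats::rnorm(n_g, cfg$expr_baseline_mean, cfg$expr_baseline_sd)
    vals <- matrix(stats::rnorm(n_g * 2 * reps, 0, cfg$expr_noise_sd),
                   nrow = n_g) + baseline
    colnames(vals) <- sprintf("%s_e%d", cond, rep(seq_len(reps), 2))
    rownames(vals) <- ids

    n_de <- round(cfg$de_fraction * n_g)
    linked_pool <- integer()
    pool_sign <- numeric()
    if (!is.null(peak_truth) && nrow(peak_truth) > 0 && !is.null(consensus)) {
      tw <- .tss_windows(genes, as.integer(tss_window))
      tp <- consensus[match(peak_truth$peak_id,
                            S4Vectors::mcols(consensus)$peak_id)]
      ok <- !is.na(GenomicRanges::start(tp))
      tp <- tp[ok]
      tp_lfc <- peak_truth$log_fc[ok]
      hits <- .find_overlaps(tw, tp)
      linked_pool <- unique(S4Vectors::queryHits(hits))
      first_hit <- !duplicated(S4Vectors::queryHits(hits))
      pool_sign <- stats::setNames(
        sign(tp_lfc[S4Vectors::subjectHits(hits)[first_hit]]),
        S4Vectors::queryHits(hits)[first_hit])
    }
    n_linked <- min(round(cfg$link_prob * n_de), length(linked_pool))
    de_linked <- linked_pool[sample.int(length(linked_pool))][seq_len(n_linked)]
    rest_pool <- setdiff(seq_len(n_g), de_linked)
    n_rest <- max(0L, n_de - n_linked)
    de_rest <- rest_pool[sample.int(length(rest_pool))][seq_len(n_rest)]
    de_idx <- c(de_linked, de_rest)
    de_sign <- c(as.numeric(pool_sign[as.character(de_linked)]),
                 sample(c(-1, 1), length(de_rest), replace = TRUE))
    if (length(de_idx)) {
      shift <- de_sign * cfg$de_log_fc
      vals[de_idx, cond == "treated"] <-
        vals[de_idx, cond == "treated"] + shift
    }
    truth <- data.frame(
      gene_id = ids[de_idx],
      log_fc = de_sign * cfg$de_log_fc,
      linked = c(rep(TRUE, length(de_linked)), rep(FALSE, length(de_rest))),
      stringsAsFactors = FALSE)
    list(values = vals, condition = cond, truth = truth)
  })
}

#' Write a simulated study to disk
#'
#' Runs all generators and writes the inputs in the pipeline's on-disk
#' formats (narrowPeak replicates, counts TSV, gene table, hotspot BED4,
#' chrom.sizes, FASTA, expression TSV) plus ground-truth TSVs, so a full
#' run can start from files alone.
#'
#' @param cfg A [simConfig()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of generated objects (see the individual
#'   generators).
#' @export
writeSimulatedStudy <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genome <- generateGenome(cfg)
  peaks <- generatePeakReplicates(cfg, genome)
  consensus <- buildConsensus(peaks$sets)
  counts <- generateCounts(cfg, consensus, hotspots = genome$hotspots)
  par_counts <- generateParCounts(cfg)
  expr <- generateExpression(cfg, genome, counts$truth, consensus)

  for (s in names(peakSets(peaks$sets))) {
    writePeakBed(peakSets(peaks$sets)[[s]],
                 file.path(dir, paste0(s, ".narrowPeak")),
                 dialect = "narrowPeak")
  }
  cm <- SummarizedExperiment::assay(counts$se, "counts")
  utils::write.table(
    data.frame(peak_id = rownames(cm), cm, check.names = FALSE),
    file.path(dir, "peak_counts.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  writeGeneTable(genome$genes, file.path(dir, "genes.tsv"))
  writeHotspotBed(genome$hotspots, file.path(dir, "hotspots.bed"))
  writeLines(sprintf("%s\t%d", names(genome$chrom_sizes),
                     as.integer(genome$chrom_sizes)),
             file.path(dir, "chrom.sizes"))
  if (!is.null(genome$fasta)) {
    Biostrings::writeXStringSet(genome$fasta, file.path(dir, "genome.fa"))
  }
  ev <- expr$values
  utils::write.table(
    data.frame(gene_id = rownames(ev), ev, check.names = FALSE),
    file.path(dir, "expression.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(counts$truth, file.path(dir, "truth_peaks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr$truth, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("%s\t%d", names(par_counts), as.integer(par_counts)),
             file.path(dir, "par_counts.tsv"))
  invisible(list(genome = genome, peaks = peaks, consensus = consensus,
                 counts = counts, par_counts = par_counts, expr = expr))
}
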