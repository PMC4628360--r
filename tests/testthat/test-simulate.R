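test_that("generators are deterministic under a fixed seed", {
  cfg <- simConfig(seed = 1, n_consensus_peaks = 200, n_genes = 30,
                   n_hotspots = 60, n_large_genes = 0,
                   chrom_lengths = c(8e5, 6e5, 4e5))
  g1 <- generateGenome(cfg)
  g2 <- generateGenome(cfg)
  expect_identical(as.character(g1$fasta), as.character(g2$fasta))
  expect_identical(gr_to_df(g1$genes), gr_to_df(g2$genes))
  expect_identical(mcols(g1$hotspots)$dmc1_tags, mcols(g2$hotspots)$dmc1_tags)
  p1 <- generatePeakReplicates(cfg, g1)
  p2 <- generatePeakReplicates(cfg, g2)
  expect_identical(lapply(peakSets(p1$sets), gr_to_df),
                   lapply(peakSets(p2$sets), gr_to_df))
  c1 <- generateCounts(cfg, 200)
  c2 <- generateCounts(cfg, 200)
  expect_identical(SummarizedExperiment::assay(c1$se),
                   SummarizedExperiment::assay(c2$se))
  expect_identical(c1$truth, c2$truth)
  # and the caller's RNG stream is untouched
  set.seed(42); before <- rnorm(1)
  set.seed(42); invisible(generateGenome(cfg, make_fasta = FALSE))
  expect_identical(rnorm(1), before)
})

test_that("the genome honours its structural configuration", {
  cfg <- simConfig(seed = 2, n_genes = 60, n_large_genes = 3,
                   n_hotspots = 300,
                   chrom_lengths = c(3e6, 2.5e6, 2e6, 1.5e6))
  g <- generateGenome(cfg, make_fasta = FALSE)
  w <- width(g$genes)
  expect_equal(sum(w >= 5e5), 3L)
  expect_true(all(mcols(g$genes)$biotype %in% c("coding", "ncRNA")))
  # genes never overlap one another
  expect_equal(length(mergeIntervals(g$genes)), length(g$genes))
  # hotspot tag counts are positive; PAR sits at the end of the last chrom
  expect_true(all(mcols(g$hotspots)$dmc1_tags >= 1L))
  expect_equal(end(g$par_region), unname(g$chrom_sizes[length(g$chrom_sizes)]))
  # too many genes for the genome errors out
  tiny <- simConfig(seed = 3, n_genes = 300, n_large_genes = 0,
                    chrom_lengths = c(5e4, 5e4))
  expect_error(generateGenome(tiny, make_fasta = FALSE), "infeasible packing")
})

test_that("hotspot counts scale with chromosome length", {
  cfg <- simConfig(seed = 4, n_chromosomes = 20, n_hotspots = 1000,
                   n_genes = 60)
  g <- generateGenome(cfg, make_fasta = FALSE)
  per_chrom <- table(factor(as.character(seqnames(g$hotspots)),
                            levels = names(g$chrom_sizes)))
  expect_gte(cor(as.numeric(per_chrom), as.numeric(g$chrom_sizes)), 0.9)
})

test_that("replicate dropout and jitter behave as configured", {
  base_cfg <- simConfig(seed = 5, n_consensus_peaks = 300, n_genes = 40,
                        dropout = 0, jitter_bp = 0)
  g <- generateGenome(base_cfg, make_fasta = FALSE)
  pk <- generatePeakReplicates(base_cfg, g)
  reps <- peakSets(pk$sets)
  expect_identical(gr_to_df(reps[[1]]), gr_to_df(reps[[2]]))
  expect_identical(gr_to_df(reps[[1]]), gr_to_df(reps[[4]]))

  all_gone <- simConfig(seed = 6, n_consensus_peaks = 100, n_genes = 40,
                        dropout = 1)
  pk0 <- generatePeakReplicates(all_gone, g)
  expect_length(peakSets(pk0$sets)[[1]], 0L)

  # dropout 0.1: fraction of base peaks kept by BOTH replicates of a
  # condition ~ 0.9^2 = 0.81 (binomial expectation over 50 seeds)
  fracs <- vapply(1:50, function(s) {
    cfg <- simConfig(seed = 1000 + s, n_consensus_peaks = 200, n_genes = 40,
                     dropout = 0.1, jitter_bp = 0)
    pk <- generatePeakReplicates(cfg, g)
    reps <- peakSets(pk$sets)
    both <- length(intersect(mcols(reps[[1]])$base_id,
                             mcols(reps[[2]])$base_id))
    both / length(pk$base_peaks)
  }, 0)
  expect_equal(mean(fracs), 0.81, tolerance = 0.04)

  # jitter never inverts a peak
  jit <- simConfig(seed = 7, n_consensus_peaks = 300, n_genes = 40,
                   jitter_bp = 200)
  pkj <- generatePeakReplicates(jit, g)
  expect_true(all(vapply(peakSets(pkj$sets),
                         function(gr) all(width(gr) >= 1), TRUE)))
})

test_that("count generation matches its configured noise and effect model", {
  # dispersion -> 0 with no effects behaves like Poisson
  cfg <- simConfig(seed = 8, nb_dispersion = 0, diff_fraction = 0,
                   lib_sizes = rep(1e6, 4), mean_depth = 50)
  g <- generateCounts(cfg, 2000)
  m <- SummarizedExperiment::assay(g$se)
  vmr <- apply(m, 1, var) / rowMeans(m)
  expect_gt(mean(vmr), 0.8)
  expect_lt(mean(vmr), 1.2)

  # injected log_fc = 1 at depth 1000, tiny dispersion: empirical ratio ~ 2
  cfg2 <- simConfig(seed = 9, nb_dispersion = 0.001, mean_depth = 1000,
                    diff_fraction = 0.05, up_fraction = 1, effect_fc = 2,
                    lib_sizes = rep(1e6, 4))
  g2 <- generateCounts(cfg2, 1000)
  m2 <- SummarizedExperiment::assay(g2$se)
  idx <- match(g2$truth$peak_id, rownames(m2))
  ratio <- rowMeans(m2[idx, 3:4]) / rowMeans(m2[idx, 1:2])
  expect_equal(mean(ratio), 2, tolerance = 0.05)
  expect_true(all(ratio > 1.7 & ratio < 2.3))

  # up:down 97:3 over ~100 differential peaks
  cfg3 <- simConfig(seed = 10, diff_fraction = 0.05)
  g3 <- generateCounts(cfg3, 2000)
  expect_gte(sum(g3$truth$log_fc > 0), 90)
  expect_error(
    generateCounts(simConfig(seed = 1, nb_dispersion = -1), 100),
    "nb_dispersion")
})

test_that("expression generation links DE genes to differential TSS peaks", {
  cfg <- simConfig(seed = 11, link_prob = 1, n_genes = 200,
                   tss_peak_fraction = 1, diff_fraction = 0.1)
  genome <- generateGenome(cfg, make_fasta = FALSE)
  pk <- generatePeakReplicates(cfg, genome)
  cons <- buildConsensus(pk$sets)
  cnt <- generateCounts(cfg, cons)
  ex <- generateExpression(cfg, genome, cnt$truth, cons)
  linked <- ex$truth[ex$truth$linked, ]
  expect_gt(nrow(linked), 0)
  genes <- genome$genes
  tp <- cons[match(cnt$truth$peak_id, mcols(cons)$peak_id)]
  for (r in seq_len(nrow(linked))) {
    gi <- match(linked$gene_id[r], mcols(genes)$gene_id)
    tss <- mcols(genes)$tss[gi]
    win <- GRanges(seqnames(genes)[gi],
                   IRanges(max(1, tss - 1000), tss + 999))
    hit <- GenomicRanges::findOverlaps(win, tp)
    expect_gt(length(hit), 0)
    signs <- sign(cnt$truth$log_fc[subjectHits(hit)])
    expect_true(sign(linked$log_fc[r]) %in% signs)
  }

  # zero DE fraction -> null matrix (no injected shifts recorded)
  ex0 <- generateExpression(simConfig(seed = 12, de_fraction = 0), genome)
  expect_equal(nrow(ex0$truth), 0L)

  # injected FC 2 at small noise: near-complete recovery by deGenes
  cfg_p <- simConfig(seed = 13, de_fraction = 0.05, expr_noise_sd = 0.1,
                     n_genes = 200)
  gp <- generateGenome(cfg_p, make_fasta = FALSE)
  exp <- generateExpression(cfg_p, gp)
  de <- deGenes(exp$values, exp$condition)
  called <- de$feature_id[de$called]
  expect_gte(mean(exp$truth$gene_id %in% called), 0.95)
})

test_that("a simulated study round-trips through the file readers", {
  cfg <- simConfig(seed = 14, n_consensus_peaks = 150, n_genes = 40,
                   n_hotspots = 50, n_large_genes = 0,
                   chrom_lengths = c(1e6, 7e5, 5e5))
  dir <- withr::local_tempdir()
  objs <- writeSimulatedStudy(cfg, dir)
  expect_no_warning({
    reps <- lapply(file.path(dir, sprintf("%s.narrowPeak",
                                          names(peakSets(objs$peaks$sets)))),
                   readPeakBed, dialect = "narrowPeak")
    genes <- readGeneTable(file.path(dir, "genes.tsv"))
    hs <- readHotspotBed(file.path(dir, "hotspots.bed"))
    sizes <- readChromSizes(file.path(dir, "chrom.sizes"))
    fa <- readGenomeFasta(file.path(dir, "genome.fa"))
  })
  expect_equal(length(genes), length(objs$genome$genes))
  expect_equal(length(hs), length(objs$genome$hotspots))
  expect_equal(unname(sizes), unname(as.numeric(objs$genome$chrom_sizes)))
  expect_equal(names(fa), names(objs$genome$chrom_sizes))
  expect_equal(vapply(reps, length, 0L),
               unname(vapply(peakSets(objs$peaks$sets), length, 0L)))
})
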