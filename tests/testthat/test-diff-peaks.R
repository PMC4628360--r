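test_that("replicate reproducibility keeps supported peaks with union spans", {
  r1 <- GRanges("chr1", IRanges(c(101, 501), c(300, 700)))
  mcols(r1)$peak_id <- c("a", "b")
  # identical replicates: everything kept, spans unchanged
  out <- reproduciblePeaks(r1, r1)
  expect_equal(granges(out), granges(r1))
  # disjoint replicates: nothing kept
  r2 <- GRanges("chr1", IRanges(c(1001), c(1200)))
  expect_length(reproduciblePeaks(r1, r2), 0L)
  # BED [100,300) vs [250,400): kept with union span [100,400)
  a <- GRanges("chr1", IRanges(101, 300))
  b <- GRanges("chr1", IRanges(251, 400))
  out <- reproduciblePeaks(a, b)
  expect_equal(c(start(out), end(out)), c(101, 400))

  # brute-force pair oracle on random sets
  set.seed(301)
  for (rep in 1:15) {
    d1 <- random_intervals(sample(10:60, 1))
    d2 <- random_intervals(sample(10:60, 1))
    got <- reproduciblePeaks(df_to_gr(d1), df_to_gr(d2))
    want_idx <- integer(); want_s <- integer(); want_e <- integer()
    for (i in seq_len(nrow(d1))) {
      s <- d1$start[i]; e <- d1$end[i]; hit <- FALSE
      for (j in seq_len(nrow(d2))) {
        if (d1$chrom[i] == d2$chrom[j] &&
            bf_overlap_width(d1$start[i], d1$end[i],
                             d2$start[j], d2$end[j]) >= 1) {
          hit <- TRUE
          s <- min(s, d2$start[j]); e <- max(e, d2$end[j])
        }
      }
      if (hit) {
        want_idx <- c(want_idx, i); want_s <- c(want_s, s); want_e <- c(want_e, e)
      }
    }
    expect_equal(mcols(got)$peak_id, sprintf("p%03d", want_idx))
    expect_equal(start(got), want_s)
    expect_equal(end(got), want_e)
  }
})

test_that("consensus construction labels provenance and matches set algebra", {
  mk <- function(s, e) GRanges("chr1", IRanges(s, e))
  sets <- replicatePeakSets(
    list(c1 = mk(c(101, 1001), c(200, 1100)),
         c2 = mk(c(151, 5001), c(250, 5100)),
         t1 = mk(c(101, 3001), c(200, 3100)),
         t2 = mk(c(121, 3051), c(220, 3140))),
    condition = c("control", "control", "treated", "treated"),
    lib_sizes = rep(1e6, 4))
  cons <- buildConsensus(sets)
  src <- setNames(mcols(cons)$source, start(cons))
  # region ~[101,250] reproducible in both conditions -> single merged "both"
  expect_equal(unname(src["101"]), "both")
  # region ~[3001,3140] reproducible only in treated
  expect_equal(unname(src["3001"]), "treated-reproducible")
  # peaks at 1001 and 5001 are unreplicated -> absent
  expect_length(cons, 2L)
  expect_equal(mcols(cons)$peak_id, c("peak_00001", "peak_00002"))

  # bitmap oracle: consensus cover equals union of per-condition
  # all-replicate-supported extended spans
  set.seed(302)
  for (rep in 1:10) {
    L <- 10000L
    dfs <- replicate(4, random_intervals(30, chroms = "chr1", L = L),
                     simplify = FALSE)
    sets <- replicatePeakSets(
      setNames(lapply(dfs, df_to_gr), c("c1", "c2", "t1", "t2")),
      condition = c("control", "control", "treated", "treated"),
      lib_sizes = rep(1e6, 4))
    cons <- buildConsensus(sets)
    cover_of <- function(gr) bf_bitmap(gr_to_df(gr), "chr1", 11000L)
    rc <- reproduciblePeaks(df_to_gr(dfs[[1]]), df_to_gr(dfs[[2]]))
    rt <- reproduciblePeaks(df_to_gr(dfs[[3]]), df_to_gr(dfs[[4]]))
    want <- cover_of(rc) | cover_of(rt)
    expect_equal(cover_of(cons), want)
  }
  # fewer than 2 replicates per condition is rejected
  expect_error(replicatePeakSets(
    list(c1 = mk(1, 10), t1 = mk(1, 10), t2 = mk(1, 10)),
    condition = c("control", "treated", "treated"),
    lib_sizes = rep(1e6, 3)), ">= 2 replicates")
})

test_that("tag quantification counts in-peak tags and full library sizes", {
  cons <- GRanges("chr1", IRanges(101, 200))
  mcols(cons)$peak_id <- "peak_00001"
  tag_pos <- function(chrom, pos) GRanges(chrom, IRanges(pos, pos))
  tags <- list(
    s1 = tag_pos("chr1", c(110, 150, 200, 201, 50)),  # 3 in, 2 out
    s2 = tag_pos("chr2", c(10, 20))                   # other chromosome
  )
  se <- quantifyPeaks(cons, tags, c("control", "treated"))
  expect_equal(unname(SummarizedExperiment::assay(se, "counts")[1, ]),
               c(3L, 0L))
  expect_equal(SummarizedExperiment::colData(se)$lib_size, c(5, 2))

  # empty consensus: no rows, libraries still computed
  se0 <- quantifyPeaks(cons[0], tags, c("control", "treated"))
  expect_equal(nrow(se0), 0L)
  expect_equal(SummarizedExperiment::colData(se0)$lib_size, c(5, 2))

  # brute-force membership oracle
  set.seed(303)
  peaks <- random_intervals(40, chroms = "chr1")
  pos <- sample.int(10000L, 500, replace = TRUE)
  tg <- list(s1 = tag_pos("chr1", pos), s2 = tag_pos("chr1", pos[1:100]))
  se <- quantifyPeaks(df_to_gr(peaks), tg, c("control", "treated"))
  want <- vapply(seq_len(nrow(peaks)), function(i) {
    sum(pos >= peaks$start[i] & pos <= peaks$end[i])
  }, 0L)
  expect_equal(unname(SummarizedExperiment::assay(se)[, 1]), want)
})

test_that("quantile filter uses nearest-rank quantile with strict retention", {
  ladder <- matrix(rep(1:100, 2), ncol = 2,
                   dimnames = list(sprintf("p%03d", 1:100), NULL))
  kept <- quantileFilter(ladder, q = 0.05)
  expect_length(kept, 95L)                      # threshold 5, means > 5
  expect_false("p005" %in% kept)
  expect_true("p006" %in% kept)

  m4 <- matrix(rep(1:4, 2), ncol = 2, dimnames = list(letters[1:4], NULL))
  expect_setequal(quantileFilter(m4, q = 0.5), c("c", "d"))  # threshold 2

  tied <- matrix(5, nrow = 10, ncol = 2,
                 dimnames = list(letters[1:10], NULL))
  expect_error(quantileFilter(tied, q = 0.05), "lower 'q'")
  expect_error(quantileFilter(ladder[1, , drop = FALSE]), "2 features")
})

test_that("differential calling recovers a strong injected peak", {
  set.seed(304)
  n <- 200
  mu <- rep(100, n)
  counts <- sapply(1:4, function(j) rnbinom(n, mu = mu, size = 1 / 0.01))
  counts[7, 3:4] <- rnbinom(2, mu = 400, size = 1 / 0.01)   # 4-fold up
  rownames(counts) <- sprintf("p%03d", 1:n)
  cond <- c("control", "control", "treated", "treated")
  se <- peakCountMatrix(counts, cond, rep(1e6, 4))
  se <- logTransform(scaleNormalize(se))
  d <- callDifferential(se, rownames(counts))
  rt <- resultsTable(d)
  expect_equal(rt$direction[7], "up")
  expect_equal(sum(rt$direction != "ns"), 1L)
  # an infinite FC threshold silences every call regardless of p
  d2 <- callDifferential(se, rownames(counts), fc_cut = Inf)
  expect_equal(nUp(d2) + nDown(d2), 0L)
})

test_that("null simulations stay call-free and tallies partition features", {
  calls <- vapply(1:25, function(s) {
    cfg <- simConfig(seed = 4000 + s, diff_fraction = 0)
    g <- generateCounts(cfg, 500)
    se <- logTransform(scaleNormalize(g$se))
    d <- callDifferential(se, quantileFilter(se))
    rt <- resultsTable(d)
    expect_equal(sum(rt$direction == "up") + sum(rt$direction == "down") +
                   sum(rt$direction == "ns"), nrow(rt))
    nUp(d) + nDown(d)
  }, 0L)
  expect_gte(mean(calls == 0L), 0.95)
})

test_that("the pipeline wrapper is deterministic and filters after consensus", {
  set.seed(305)
  cfg <- simConfig(seed = 99, n_consensus_peaks = 300)
  genome <- generateGenome(cfg, make_fasta = FALSE)
  pk <- generatePeakReplicates(cfg, genome)
  cnt <- generateCounts(cfg, buildConsensus(pk$sets))
  run <- function() {
    differentialPeakPipeline(pk$sets,
                             counts = SummarizedExperiment::assay(cnt$se))
  }
  r1 <- run(); r2 <- run()
  expect_identical(resultsTable(r1$diff), resultsTable(r2$diff))
  expect_identical(r1$retained, r2$retained)
  # the quantile threshold is computed over consensus peaks only: every
  # retained id is a consensus id and 5% of consensus rows are dropped
  expect_true(all(r1$retained %in% mcols(r1$consensus)$peak_id))
  n <- length(r1$consensus)
  expect_lte(length(r1$retained), n - floor(0.05 * n) + 1)
  expect_lt(length(r1$retained), n)
})
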