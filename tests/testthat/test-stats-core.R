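test_that("scale normalization equalizes effective depth", {
  m <- matrix(c(10, 0, 4, 8), nrow = 2,
              dimnames = list(c("p1", "p2"), c("s1", "s2")))
  out <- scaleNormalize(m, lib_sizes = c(2e6, 1e6), target = 1e6)
  expect_equal(out["p1", "s1"], 5)          # per-million arithmetic
  expect_equal(out[, "s2"], m[, "s2"])      # library == target: unchanged
  expect_error(scaleNormalize(m, lib_sizes = c(0, 1e6)), "zero library size")

  # algebraic oracle: scaled column sum x (library/target) == raw column sum
  set.seed(201)
  m <- matrix(rpois(400, 30), nrow = 100)
  libs <- runif(4, 5e5, 2e6)
  sc <- scaleNormalize(m, libs, target = 1e6)
  expect_equal(colSums(sc) * libs / 1e6, colSums(m), tolerance = 1e-12)
  # equal effective totals when all columns share a common raw total
  m2 <- matrix(25, nrow = 40, ncol = 4)
  sc2 <- scaleNormalize(sweep(m2, 2, c(1, 2, 3, 4), `*`),
                        lib_sizes = c(1, 2, 3, 4) * 1e6)
  expect_equal(max(abs(colSums(sc2) - mean(colSums(sc2)))) /
                 mean(colSums(sc2)), 0, tolerance = 1e-9)
})

test_that("log transform applies the pseudocount and preserves order", {
  m <- matrix(c(0, 3, 7, 1), 2)
  out <- logTransform(m, pseudocount = 1)
  expect_equal(out[1, 1], 0)
  expect_equal(out[2, 1], 2)               # log2(3 + 1)
  expect_error(logTransform(m, pseudocount = 0), "pseudocount")
  set.seed(202)
  x <- matrix(rexp(300), ncol = 3)
  lt <- logTransform(x, pseudocount = 0.5)
  for (j in 1:3) expect_equal(order(lt[, j]), order(x[, j]))
})

test_that("moderation fit recovers known prior parameters and handles edges", {
  set.seed(203)
  d0 <- 8; s0sq <- 0.5; dg <- 4
  sigma2 <- s0sq * d0 / rchisq(5000, d0)
  v <- sigma2 * rchisq(5000, dg) / dg
  mp <- estimateModeration(v, dg)
  expect_lt(abs(priorDf(mp) - d0) / d0, 0.30)
  expect_lt(abs(priorVar(mp) - s0sq) / s0sq, 0.10)

  expect_equal(priorDf(estimateModeration(rep(2, 50), 4)), Inf)
  expect_error(estimateModeration(v, 0), "residual_df")
  expect_error(estimateModeration(rep(0, 50), 4), "pseudocount")
})

test_that("moderation fit agrees with the limma reference on shared data", {
  library(limma)
  set.seed(204)
  m <- matrix(rnorm(500 * 4, 8, 0.5), 500,
              dimnames = list(paste0("f", 1:500), NULL))
  cond <- c("control", "control", "treated", "treated")
  fit <- eBayes(lmFit(m, model.matrix(~ factor(cond, c("control", "treated")))))
  res <- moderatedTTest(m, cond)
  v <- (apply(m[, 1:2], 1, var) + apply(m[, 3:4], 1, var)) / 2
  mp <- estimateModeration(v, 2)
  expect_equal(priorDf(mp), fit$df.prior, tolerance = 1e-8)
  expect_equal(priorVar(mp), fit$s2.prior, tolerance = 1e-8)
  expect_equal(res$t, unname(fit$t[, 2]), tolerance = 1e-10)
  expect_equal(res$p, unname(fit$p.value[, 2]), tolerance = 1e-10)
})

test_that("moderated t matches its closed form and limiting cases", {
  # hand-computed single feature: control {1.0, 1.2}, treated {3.0, 3.2},
  # d0 = 2, s0^2 = 0.02 -> s2_pooled = 0.02, s2_tilde = 0.02,
  # t = 2 / sqrt(0.02) = 14.142136, p = 2 P(T_4 < -14.142136)
  m <- matrix(c(1.0, 1.2, 3.0, 3.2), nrow = 1,
              dimnames = list("f1", NULL))
  cond <- c("control", "control", "treated", "treated")
  mod <- new("ModerationParams", d0 = 2, s0sq = 0.02, nFeatures = 1L)
  res <- moderatedTTest(m, cond, mod)
  expect_equal(res$log_fc, 2)
  expect_equal(res$t, 14.142136, tolerance = 1e-6)
  expect_equal(res$p, 0.00014512817, tolerance = 1e-8)

  set.seed(205)
  m <- matrix(rnorm(200 * 4), 200, dimnames = list(paste0("f", 1:200), NULL))
  # d0 = 0: exactly the ordinary pooled two-sample t
  res0 <- moderatedTTest(m, cond, new("ModerationParams", d0 = 0, s0sq = 1))
  plain <- apply(m, 1, function(x) {
    tt <- t.test(x[3:4], x[1:2], var.equal = TRUE)
    c(tt$statistic, tt$p.value)
  })
  expect_equal(res0$t, unname(plain[1, ]), tolerance = 1e-10)
  expect_equal(res0$p, unname(plain[2, ]), tolerance = 1e-10)
  # d0 = Inf: common variance s0^2 for every feature
  resI <- moderatedTTest(m, cond, new("ModerationParams", d0 = Inf, s0sq = 0.25))
  lfc <- rowMeans(m[, 3:4]) - rowMeans(m[, 1:2])
  expect_equal(resI$t, unname(lfc / (0.5 * sqrt(1 / 2 + 1 / 2))),
               tolerance = 1e-12)

  expect_error(moderatedTTest(m[, 1:3], cond[1:3]), ">= 2 samples")
})

test_that("shrunk variance lies between the observed and prior variance", {
  set.seed(206)
  cond <- c("control", "control", "treated", "treated")
  m <- matrix(rnorm(300 * 4, 0, sqrt(rep(rexp(300, 2), 4))), 300,
              dimnames = list(paste0("f", 1:300), NULL))
  dg <- 2
  v <- (apply(m[, 1:2], 1, var) + apply(m[, 3:4], 1, var)) / 2
  mod <- new("ModerationParams", d0 = 4, s0sq = 0.5, nFeatures = 300L)
  res <- moderatedTTest(m, cond, mod)
  s2_tilde <- (res$log_fc / res$t)^2  # (SE)^2 with 1/n1+1/n2 = 1
  lo <- pmin(v, 0.5); hi <- pmax(v, 0.5)
  keep <- abs(v - 0.5) > 1e-12
  expect_true(all(s2_tilde[keep] > lo[keep] & s2_tilde[keep] < hi[keep]))
})

test_that("BH q-values match the hand step-up and its invariants", {
  expect_equal(bhFdr(c(0.005, 0.01, 0.03, 0.04)), c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  expect_equal(bhFdr(0.03), 0.03)
  expect_error(bhFdr(c(0.2, 1.4)), "\\[0, 1\\]")

  set.seed(207)
  for (rep in 1:20) {
    p <- runif(sample(5:100, 1))^2
    q <- bhFdr(p)
    expect_true(all(q >= p / length(p) - 1e-15 & q <= 1))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))    # monotone along sorted p
    # q <= alpha reproduces the BH step-up rejection set at level alpha
    m <- length(p)
    for (alpha in c(0.01, 0.05, 0.2)) {
      ps <- sort(p)
      kmax <- suppressWarnings(max(which(ps <= alpha * seq_len(m) / m)))
      reject <- if (is.finite(kmax)) p <= ps[kmax] else rep(FALSE, m)
      expect_equal(q <= alpha, reject)
    }
  }
})

test_that("chi-square matches the 2x2 closed form", {
  res <- chisqIndependence(matrix(c(10, 20, 20, 10), 2))
  expect_equal(res$statistic, 60 * (10 * 10 - 20 * 20)^2 / (30 * 30 * 30 * 30),
               tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_equal(res$p_value, 0.00982327, tolerance = 1e-6)

  # table equal to its own expectation -> X2 = 0, p = 1
  res0 <- chisqIndependence(matrix(c(10, 20, 10, 20), 2))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_equal(chisqIndependence(matrix(1:6, 2))$df, 2)
  expect_error(chisqIndependence(matrix(c(0, 0, 5, 5), 2)), "marginal")

  set.seed(208)
  for (rep in 1:100) {
    tab <- matrix(sample(1:50, 4, replace = TRUE), 2)
    res <- chisqIndependence(tab)
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    n <- sum(tab)
    want <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(res$statistic, want, tolerance = 1e-10)
    expect_equal(res$p_value, pchisq(want, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("hypergeometric enrichment matches combinatorial counts", {
  universe <- sprintf("g%02d", 1:20)
  term <- universe[1:10]
  res <- hypergeomEnrichment(term, universe, list(T1 = term))
  expect_equal(res$p, 1 / choose(20, 10), tolerance = 1e-12)

  # exact tail summation oracle on a random instance
  set.seed(209)
  hits <- sample(universe, 7)
  members <- sample(universe, 8)
  res <- hypergeomEnrichment(hits, universe, list(T1 = members))
  k <- length(intersect(hits, members))
  tail_sum <- sum(sapply(k:7, function(x) dhyper(x, 8, 12, 7)))
  expect_equal(res$p, tail_sum, tolerance = 1e-12)

  # disjoint term: k = 0, upper tail covers everything -> p = 1
  res0 <- hypergeomEnrichment(universe[1:5], universe, list(T1 = universe[6:10]))
  expect_equal(res0$k, 0L)
  expect_equal(res0$p, 1)

  expect_warning(
    out <- hypergeomEnrichment(universe[1:5], universe,
                               list(T1 = universe[1:4], T2 = character())),
    "skipped")
  expect_equal(out$term, "T1")
  expect_error(hypergeomEnrichment(c("zz", universe[1]), universe, list()),
               "outside the universe")
})

test_that("rank-sum comparison reports medians and a tie-corrected p", {
  same <- ranksumCompare(1:10, 1:10)
  expect_equal(same$median_a, same$median_b)
  expect_gt(same$p_value, 0.9)

  shift <- ranksumCompare(1:20, 101:120)
  expect_equal(shift$median_b - shift$median_a, 100)
  expect_lt(shift$p_value, 1e-4)

  single <- ranksumCompare(3, 5)
  expect_equal(single$median_a, 3)
  expect_equal(single$median_b, 5)
  expect_true(single$p_value > 0 && single$p_value <= 1)
  expect_error(ranksumCompare(numeric(), 1:3), "non-empty")
})
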