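# Statistical kernel: normalization, empirical-Bayes moderation, moderated
# t-test, FDR, chi-square, hypergeometric enrichment, rank-sum comparison.

#' Scale-factor normalization of a count matrix
#'
#' Multiplies each sample's counts by \code{target / library_size}, so that
#' all samples are put on a common effective sequencing depth before any
#' comparison between conditions.
#'
#' @param counts Non-negative numeric matrix (features x samples) or a
#'   \code{SummarizedExperiment} carrying a \code{counts} assay and a
#'   \code{lib_size} column in its \code{colData}.
#' @param lib_sizes Positive library size per sample (total mapped tags);
#'   ignored for the \code{SummarizedExperiment} method.
#' @param target Normalization target depth; defaults to the mean library
#'   size across samples.
#' @return Same container as the input: the matrix method returns the
#'   scaled matrix; the \code{SummarizedExperiment} method returns the
#'   object with an added \code{scaled} assay and the target recorded in
#'   \code{metadata()$norm_target}.
#' @details Peak counts are usually a subset of the mapped reads, so column
#'   sums below the library sizes are expected; a column sum exceeding its
#'   library size triggers a warning, not an error.
#' @export
setGeneric("scaleNormalize", function(counts, lib_sizes = NULL, target = NULL)
  standardGeneric("scaleNormalize"))

#' @rdname scaleNormalize
#' @export
setMethod("scaleNormalize", "matrix", function(counts, lib_sizes = NULL, target = NULL) {
  if (is.null(lib_sizes) || length(lib_sizes) != ncol(counts)) {
    stop("need one library size per sample")
  }
  if (any(lib_sizes <= 0)) stop("library sizes must be positive (zero library size)")
  if (any(counts < 0)) stop("counts must be non-negative")
  cs <- colSums(counts)
  if (any(cs > lib_sizes)) {
    warning("column sum exceeds library size for sample(s): ",
            paste(colnames(counts)[cs > lib_sizes], collapse = ", "))
  }
  if (is.null(target)) target <- mean(lib_sizes)
  .assert_scalar_number(target, "target", lower = 0, strict_lower = TRUE)
  sweep(counts, 2L, target / lib_sizes, `*`)
})

#' @rdname scaleNormalize
#' @export
setMethod("scaleNormalize", "SummarizedExperiment",
  function(counts, lib_sizes = NULL, target = NULL) {
    se <- counts
    libs <- SummarizedExperiment::colData(se)$lib_size
    if (is.null(libs)) stop("colData must carry a 'lib_size' column")
    m <- SummarizedExperiment::assay(se, "counts")
    if (is.null(target)) target <- mean(libs)
    SummarizedExperiment::assay(se, "scaled") <-
      scaleNormalize(as.matrix(m), libs, target)
    S4Vectors::metadata(se)$norm_target <- target
    se
  })

#' Log2 transform with pseudocount
#'
#' \code{x -> log2(x + pseudocount)}; monotone in its input. This is the
#' substrate the moderated t-test operates on.
#'
#' @param x Non-negative matrix of scaled counts, or a
#'   \code{SummarizedExperiment} with a \code{scaled} assay.
#' @param pseudocount Positive offset added before taking logs (default 1).
#' @return The matrix method returns the log2 matrix; the
#'   \code{SummarizedExperiment} method adds a \code{lognorm} assay and
#'   records \code{metadata()$pseudocount}.
#' @export
setGeneric("logTransform", function(x, pseudocount = 1)
  standardGeneric("logTransform"))

#' @rdname logTransform
#' @export
setMethod("logTransform", "matrix", function(x, pseudocount = 1) {
  .assert_scalar_number(pseudocount, "pseudocount", lower = 0, strict_lower = TRUE)
  if (any(x < 0)) stop("values must be non-negative")
  log2(x + pseudocount)
})

#' @rdname logTransform
#' @export
setMethod("logTransform", "SummarizedExperiment", function(x, pseudocount = 1) {
  SummarizedExperiment::assay(x, "lognorm") <-
    logTransform(as.matrix(SummarizedExperiment::assay(x, "scaled")), pseudocount)
  S4Vectors::metadata(x)$pseudocount <- pseudocount
  x
})

# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)), used by the method-of-moments moderation fit.
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Estimate empirical-Bayes moderation parameters
#'
#' Fits the scaled inverse-chi-square prior on per-feature variances by the
#' method of moments on log variances: if \eqn{s_g^2 \sim s_0^2 F(d_g, d_0)}
#' then \eqn{e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)} has mean
#' \eqn{\log s_0^2 + \log(d_0/2) - \psi(d_0/2)} and variance
#' \eqn{\psi'(d_g/2) + \psi'(d_0/2)}. Matching the observed mean and
#' variance of \eqn{e_g} yields \eqn{d_0} (via the trigamma inverse) and
#' \eqn{s_0^2}. When the observed spread of log variances does not exceed
#' the \eqn{\psi'(d_g/2)} floor the variances are effectively exchangeable
#' and \code{d0 = Inf} (complete shrinkage) is returned.
#'
#' @param variances Per-feature sample variances (finite, >= 0; at least 10
#'   positive values recommended for a stable fit).
#' @param residual_df Residual degrees of freedom each variance was
#'   computed with (integer >= 1; \code{n1 + n2 - 2} for a two-group design).
#' @return A [ModerationParams-class] object.
#' @export
estimateModeration <- function(variances, residual_df) {
  .assert_scalar_number(residual_df, "residual_df", lower = 1)
  v <- variances[is.finite(variances)]
  if (all(v == 0)) {
    stop("all variances are zero; add a pseudocount or jitter before fitting")
  }
  v <- v[v > 0]
  if (length(v) < 2L) stop("need at least 2 positive finite variances")
  dg <- residual_df
  e <- log(v) - digamma(dg / 2) + log(dg / 2)
  emean <- mean(e)
  evar <- stats::var(e)
  spread <- evar - trigamma(dg / 2)
  if (spread <= 0) {
    d0 <- Inf
    s0sq <- exp(emean)
  } else {
    d0 <- 2 * trigamma_inverse(spread)
    s0sq <- exp(emean - log(d0 / 2) + digamma(d0 / 2))
  }
  new("ModerationParams", d0 = d0, s0sq = s0sq, nFeatures = length(v))
}

#' Moderated two-group t-test
#'
#' Per-feature two-sample test of treated vs control on log2-scale values,
#' with the per-feature pooled variance shrunk toward the prior:
#' \deqn{\tilde{s}^2_g = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
#'       t_g = \frac{\bar{y}_{g,T} - \bar{y}_{g,C}}
#'                  {\tilde{s}_g\sqrt{1/n_1 + 1/n_2}}}
#' with two-sided p-values from a t-distribution on \eqn{d_0 + d_g} degrees
#' of freedom. At \code{d0 = 0} this is exactly the ordinary pooled
#' two-sample t-test; at \code{d0 = Inf} every feature shares the common
#' variance \code{s0sq} and the reference distribution is normal.
#'
#' @param values Numeric matrix of log2 normalized values (features x
#'   samples) with rownames as feature ids, or a
#'   \code{SummarizedExperiment} with a \code{lognorm} assay and a
#'   \code{condition} column in \code{colData}.
#' @param condition \code{control}/\code{treated} label per sample
#'   (matrix method only).
#' @param mod A [ModerationParams-class]; when \code{NULL}, estimated from
#'   the data with [estimateModeration()].
#' @return \code{data.frame} with columns \code{feature_id}, \code{log_fc}
#'   (log2 treated minus control), \code{fc} (linear \code{2^log_fc}),
#'   \code{t}, \code{p}, \code{df_total}.
#' @export
setGeneric("moderatedTTest", function(values, condition, mod = NULL)
  standardGeneric("moderatedTTest"))

#' @rdname moderatedTTest
#' @export
setMethod("moderatedTTest", "matrix", function(values, condition, mod = NULL) {
  condition <- as.character(condition)
  if (length(condition) != ncol(values)) {
    stop("need one condition label per sample")
  }
  if (!all(condition %in% c("control", "treated"))) {
    stop("condition labels must be 'control' or 'treated'")
  }
  n1 <- sum(condition == "control")
  n2 <- sum(condition == "treated")
  if (n1 < 2L || n2 < 2L) {
    stop("each condition needs >= 2 samples for the moderated t-test")
  }
  ctrl <- values[, condition == "control", drop = FALSE]
  trt <- values[, condition == "treated", drop = FALSE]
  mean_c <- rowMeans(ctrl)
  mean_t <- rowMeans(trt)
  var_c <- apply(ctrl, 1L, stats::var)
  var_t <- apply(trt, 1L, stats::var)
  dg <- n1 + n2 - 2L
  s2 <- ((n1 - 1) * var_c + (n2 - 1) * var_t) / dg
  if (is.null(mod)) mod <- estimateModeration(s2, dg)
  d0 <- priorDf(mod)
  s0sq <- priorVar(mod)
  s2_tilde <- if (is.infinite(d0)) {
    rep(s0sq, length(s2))
  } else {
    (d0 * s0sq + dg * s2) / (d0 + dg)
  }
  log_fc <- mean_t - mean_c
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  t_stat <- log_fc / se
  df_total <- d0 + dg
  p <- 2 * stats::pt(-abs(t_stat), df = df_total)
  ids <- rownames(values)
  if (is.null(ids)) ids <- sprintf("feature_%d", seq_len(nrow(values)))
  data.frame(
    feature_id = ids, log_fc = log_fc, fc = 2^log_fc,
    t = t_stat, p = p, df_total = df_total,
    row.names = NULL, stringsAsFactors = FALSE
  )
})

#' @rdname moderatedTTest
#' @export
setMethod("moderatedTTest", "SummarizedExperiment",
  function(values, condition, mod = NULL) {
    cond <- SummarizedExperiment::colData(values)$condition
    if (is.null(cond)) stop("colData must carry a 'condition' column")
    moderatedTTest(as.matrix(SummarizedExperiment::assay(values, "lognorm")),
                   as.character(cond), mod)
  })

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j},
#' capped at 1, returned in input order.
#'
#' @param p_values Numeric vector of p-values in \code{[0, 1]}.
#' @return Vector of q-values, same length and order.
#' @export
bhFdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Pearson chi-square test of independence
#'
#' \eqn{X^2 = \sum (O - E)^2 / E} on an r x c contingency table with
#' \eqn{(r-1)(c-1)} degrees of freedom and an upper-tail chi-square
#' p-value; no continuity correction.
#'
#' @param table Non-negative integer matrix with positive row and column
#'   sums.
#' @return List with \code{statistic}, \code{df}, \code{p_value}.
#' @export
chisqIndependence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("table entries must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row or column marginal in contingency table")
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' Hypergeometric term enrichment
#'
#' Upper-tail hypergeometric test of each term's overrepresentation in a
#' hit set drawn from a universe, with BH adjustment across terms: with
#' \code{N} universe features, \code{K} of them in the term, \code{n} hits
#' and \code{k} hits in the term, \eqn{p = P(X \ge k)} for
#' \eqn{X \sim \mathrm{Hypergeom}(N, K, n)}.
#'
#' @param hits Character vector of hit feature ids (must be a subset of
#'   \code{universe}).
#' @param universe Character vector of all feature ids.
#' @param term_sets Named list mapping term -> character vector of feature
#'   ids; ids outside the universe are dropped, and terms left empty are
#'   skipped with a warning.
#' @return \code{data.frame} with columns \code{term}, \code{k}, \code{K},
#'   \code{n}, \code{N}, \code{p}, \code{q}.
#' @export
hypergeomEnrichment <- function(hits, universe, term_sets) {
  hits <- unique(as.character(hits))
  universe <- unique(as.character(universe))
  outside <- setdiff(hits, universe)
  if (length(outside)) {
    stop("hit(s) outside the universe: ", paste(utils::head(outside, 3), collapse = ", "))
  }
  N <- length(universe)
  n <- length(hits)
  rows <- lapply(names(term_sets), function(term) {
    members <- intersect(unique(as.character(term_sets[[term]])), universe)
    K <- length(members)
    if (K == 0L) {
      warning("term '", term, "' has no members in the universe; skipped")
      return(NULL)
    }
    k <- length(intersect(hits, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q <- bhFdr(out$p)
  out
}

#' Rank-sum comparison of two samples
#'
#' Mann-Whitney U test (normal approximation with midrank tie correction)
#' plus the two group medians -- the comparison used for DSB-hotspot
#' intensity distributions.
#'
#' @param a,b Non-empty numeric vectors.
#' @return List with \code{median_a}, \code{median_b}, \code{p_value}.
#' @export
ranksumCompare <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be non-empty")
  }
  res <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
  list(median_a = stats::median(a), median_b = stats::median(b),
       p_value = res$p.value)
}
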