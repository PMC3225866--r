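# Paired signed-rank statistics across dataset pairs and Fisher
# enrichment tests.

# Exact null distribution of W+ for integer ranks 1..n: probabilities over
# 0..n(n+1)/2 by the standard generating-function recursion (equivalent to
# enumerating all 2^n sign assignments).
signedRankNull <- function(n) {
  M <- n * (n + 1L) / 2L
  f <- c(1, rep(0, M))
  for (r in seq_len(n)) {
    shifted <- c(rep(0, r), f[seq_len(M + 1L - r)])
    f <- f + shifted
  }
  f / 2^n
}

#' Paired Wilcoxon signed-rank test
#'
#' Tests the pairwise differences `d = tumor - normal` of one feature across
#' dataset pairs.  Zero differences are dropped; `|d|` is ranked with
#' midranks and `W+` is the sum of ranks of positive differences.
#'
#' Modes:
#' \describe{
#'   \item{`auto`}{exact two-sided tail of `W+` over all `2^n` sign
#'     assignments when the nonzero `|d|` are free of ties, otherwise the
#'     normal approximation with continuity correction 0.5 and tie-corrected
#'     variance `n(n+1)(2n+1)/24 - sum(t^3 - t)/48`.}
#'   \item{`exact`}{forces the exact tail using integer ranks with
#'     deterministic tie-breaking (ties in `|d|` ranked in input order).
#'     Valid when tied `|d|` do not mix signs -- e.g. when ties are an
#'     artifact of rounded input values; a warning is issued otherwise.}
#'   \item{`approx`}{forces the normal approximation.}
#' }
#' The two-sided p-value is `min(1, 2 * min(lower tail, upper tail))`.
#'
#' @param normal,tumor numeric vectors of paired feature values.
#' @param mode `"auto"` (default), `"exact"` or `"approx"`.
#' @return list of class `"htest"` with `statistic` (`W+`), `p.value`,
#'   `method`, plus `nUsed` (pairs with nonzero difference) and `tendency`
#'   (`"Up"`/`"Down"`, the sign of `mean(tumor - normal)`).
#' @export
wilcoxonSignedRank <- function(normal, tumor,
                               mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (length(normal) != length(tumor))
    stop("'normal' and 'tumor' must have equal length")
  d <- tumor - normal
  if (any(!is.finite(d))) stop("all paired values must be finite")
  tendency <- if (mean(d) >= 0) "Up" else "Down"
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero")
  ties <- anyDuplicated(abs(d)) > 0L

  if (mode == "auto") mode <- if (ties) "approx" else "exact"

  if (mode == "exact") {
    if (ties) {
      tab <- split(sign(d), abs(d))
      if (any(vapply(tab, function(s) length(unique(s)) > 1L, TRUE)))
        warning("tied |d| mix signs; exact integer-rank tail is approximate")
    }
    r <- rank(abs(d), ties.method = "first")
    W <- sum(r[d > 0])
    null <- signedRankNull(n)
    lo <- sum(null[seq_len(W + 1L)])
    hi <- sum(null[(W + 1L):length(null)])
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    mu <- n * (n + 1) / 4
    cnt <- as.vector(table(abs(d)))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(cnt^3 - cnt) / 48
    if (sigma2 <= 0) stop("degenerate variance: all |d| identical")
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  structure(list(
    statistic = c("W+" = W), p.value = p,
    method = paste("paired Wilcoxon signed-rank test,", method),
    alternative = "two.sided",
    data.name = "tumor - normal",
    nUsed = n, tendency = tendency), class = "htest")
}

#' Fisher enrichment test of two gene sets
#'
#' One-sided (greater) hypergeometric tail on the 2x2 table of
#' `query`/`reference` membership within `universe`, i.e. the probability of
#' an overlap at least as large as observed when drawing `|query|` genes
#' from the universe.
#'
#' @param query,reference,universe character vectors of gene symbols; both
#'   `query` and `reference` must be subsets of `universe`.
#' @return list with `overlap`, `pValue` (one-sided) and `oddsRatio`
#'   (the sample odds ratio, possibly `Inf`).
#' @export
fisherEnrichment <- function(query, reference, universe) {
  query <- unique(as.character(query))
  reference <- unique(as.character(reference))
  universe <- unique(as.character(universe))
  if (!all(query %in% universe))
    stop("'query' must be a subset of 'universe'")
  if (!all(reference %in% universe))
    stop("'reference' must be a subset of 'universe'")
  U <- length(universe); Q <- length(query); R <- length(reference)
  k <- length(intersect(query, reference))
  p <- stats::phyper(k - 1, R, U - R, Q, lower.tail = FALSE)
  oddsTop <- k * (U - R - Q + k)
  oddsBot <- (Q - k) * (R - k)
  odds <- if (oddsBot == 0) {
    if (oddsTop == 0) NaN else Inf
  } else oddsTop / oddsBot
  list(overlap = k, pValue = p, oddsRatio = odds)
}

#' Compare a feature panel across dataset pairs
#'
#' For each feature of a per-dataset panel of (normal, tumor) values,
#' computes the cohort means, the direction of the tumor tendency and (when
#' at least two dataset pairs are available) the paired Wilcoxon signed-rank
#' p-value.
#'
#' @param panel data.frame with columns `dataset`, `feature`, `normal`,
#'   `tumor` (one row per dataset and feature); rows with a missing cohort
#'   value are excluded with a warning.
#' @param mode test mode passed to [wilcoxonSignedRank()].
#' @return data.frame with one row per feature: `feature`, `nDatasets`,
#'   `meanNormal`, `meanTumor`, `tendency`, `W`, `pValue`, `method`
#'   (`W`/`pValue`/`method` are `NA` for a single dataset or when all
#'   differences vanish).
#' @export
compareFeatures <- function(panel, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(panel),
            all(c("dataset", "feature", "normal", "tumor") %in% names(panel)))
  ok <- is.finite(panel$normal) & is.finite(panel$tumor)
  if (any(!ok)) {
    warning(sum(!ok), " dataset/feature row(s) with a missing cohort ",
            "value excluded")
    panel <- panel[ok, , drop = FALSE]
  }
  rows <- lapply(split(panel, panel$feature), function(df) {
    out <- data.frame(feature = df$feature[1L], nDatasets = nrow(df),
                      meanNormal = mean(df$normal),
                      meanTumor = mean(df$tumor),
                      tendency = if (mean(df$tumor - df$normal) >= 0)
                        "Up" else "Down",
                      W = NA_real_, pValue = NA_real_,
                      method = NA_character_,
                      stringsAsFactors = FALSE)
    if (nrow(df) >= 2L && any(df$tumor != df$normal)) {
      ht <- wilcoxonSignedRank(df$normal, df$tumor, mode = mode)
      out$W <- unname(ht$statistic)
      out$pValue <- ht$p.value
      out$method <- ht$method
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$feature), , drop = FALSE]
}

#' Bundled feature panel of twenty tumor/normal cohort pairs
#'
#' A reference panel of published per-dataset signaling-network features for
#' twenty microarray tumor/normal cohort pairs spanning eleven tumor types
#' (leukemia, breast, cervical, esophageal, glioma, head-and-neck, lung,
#' oral-tongue, pancreas, prostate, renal and vulva datasets).  Features
#' include network sizes, usage fractions, link distances, frequencies,
#' path lengths, power-law exponents, motif counts, clustering statistics
#' and entropies -- the input to the cross-dataset comparison stage.
#'
#' @return data.frame with columns `dataset`, `feature`, `normal`, `tumor`.
#' @export
cohortFeaturePanel <- function() {
  path <- system.file("extdata", "cohort_feature_panel.tsv",
                      package = "corsignet", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
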