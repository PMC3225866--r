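# Correlation weighting: Pearson correlation per link, link distances,
# correlation categories and assembly of the weighted network.

#' Pearson correlation of two sample vectors
#'
#' Plain product-moment correlation
#' \deqn{\rho_{xy} = \frac{\sum_i (x_i-\bar x)(y_i-\bar y)}
#'   {\sqrt{\sum_i (x_i-\bar x)^2\, \sum_i (y_i-\bar y)^2}}}
#' over the `n` samples of a cohort.  When either vector has zero variance
#' the correlation is undefined and `NA` is returned; [buildWeightedNetwork()]
#' maps that sentinel to the maximal link distance 1.
#'
#' @param x,y numeric vectors of equal length `n >= 3`, all values finite.
#' @return a single value in `[-1, 1]`, or `NA` when undefined.
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("at least 3 samples are required")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("all values must be finite")
  dx <- x - mean(x); dy <- y - mean(y)
  vx <- sum(dx * dx); vy <- sum(dy * dy)
  if (vx == 0 || vy == 0) return(NA_real_)
  r <- sum(dx * dy) / sqrt(vx * vy)
  max(-1, min(1, r))
}

#' Link distance from a correlation coefficient
#'
#' `d = 1 - |rho|`: strongly co-regulated neighbors (induction or inhibition
#' alike, hence the absolute value) are close, uncorrelated ones far.
#' Undefined correlations (`NA`) map to the maximal distance 1.
#'
#' @param rho numeric vector of correlations in `[-1, 1]` (values beyond 1 by
#'   more than `1e-9` are an error; smaller excursions are clamped).
#' @return numeric vector of distances in `[0, 1]`.
#' @export
linkDistance <- function(rho) {
  a <- abs(rho)
  if (any(a > 1 + 1e-9, na.rm = TRUE))
    stop("|rho| exceeds 1 beyond tolerance")
  a <- pmin(a, 1)
  ifelse(is.na(rho), 1, 1 - a)
}

#' Correlation category of a link
#'
#' Categorizes `|rho|` into `none` (`[0, 0.3)`), `low` (`[0.3, 0.5]`) and
#' `high` (`(0.5, 1]`).  Both boundaries belong to `low`, making the ties at
#' the published interval bounds deterministic.  Undefined correlations are
#' `none`.
#'
#' @param rho numeric vector of correlations in `[-1, 1]` (or `NA`).
#' @return factor with levels `none`, `low`, `high`.
#' @export
correlationCategory <- function(rho) {
  a <- abs(rho)
  if (any(a > 1 + 1e-9, na.rm = TRUE)) stop("|rho| must lie in [-1, 1]")
  out <- ifelse(is.na(a), "none",
                ifelse(a < 0.3, "none", ifelse(a <= 0.5, "low", "high")))
  factor(out, levels = c("none", "low", "high"))
}

#' Build the correlation-weighted network for one cohort
#'
#' Keeps every interaction whose two genes are both present in the cohort's
#' expression matrix, weights it with the Pearson correlation of the two
#' expression profiles and the link distance `1 - |rho|`, and drops the rest
#' (reported via a message).  Links between zero-variance genes are kept with
#' `rho = NA` and distance 1 so the graph stays intact while such links are
#' maximally unattractive to the shortest-path search.
#'
#' @param interactions data.frame with character columns `geneA`, `geneB`
#'   (see [readInteractionList()]).
#' @param expr cohort expression (`SummarizedExperiment` or numeric matrix).
#' @return a [WeightedNetwork-class] object.
#' @export
buildWeightedNetwork <- function(interactions, expr) {
  stopifnot(is.data.frame(interactions),
            all(c("geneA", "geneB") %in% names(interactions)))
  m <- exprValues(expr)
  a <- as.character(interactions$geneA)
  b <- as.character(interactions$geneB)
  present <- a %in% rownames(m) & b %in% rownames(m)
  if (sum(present) == 0L)
    stop("no interaction has expression for both genes")
  if (any(!present))
    message(sum(!present), " link(s) dropped: gene without expression data")
  a <- a[present]; b <- b[present]
  if (any(a == b)) stop("self-interactions are not allowed")

  # row-standardize once, then rho per link is a cross-product row sum
  ctr <- m - rowMeans(m)
  ss <- sqrt(rowSums(ctr * ctr))
  rho <- rowSums(ctr[a, , drop = FALSE] * ctr[b, , drop = FALSE]) /
    (ss[a] * ss[b])
  rho[ss[a] == 0 | ss[b] == 0] <- NA_real_
  rho <- pmax(-1, pmin(1, rho))

  key <- linkKey(a, b)
  if (anyDuplicated(key)) stop("duplicated interactions in input")
  ord <- order(key)
  el <- cbind(pmin(a, b), pmax(a, b))[ord, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = el[, 1L], to = el[, 2L],
               rho = unname(rho[ord]),
               distance = unname(linkDistance(rho[ord]))),
    directed = FALSE,
    vertices = sort(unique(c(a, b))))
  methods::new("WeightedNetwork", graph = g)
}
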