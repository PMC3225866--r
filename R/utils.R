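# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0)
    stop("'seed' must be a single non-negative integer")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Accept either a SummarizedExperiment (first assay) or a plain numeric
# matrix with gene rownames and sample colnames.
exprValues <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    m <- SummarizedExperiment::assay(x, 1L)
  } else if (is.matrix(x) && is.numeric(x)) {
    m <- x
  } else {
    stop("expression input must be a SummarizedExperiment or a numeric matrix")
  }
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix must carry gene rownames and sample colnames")
  m
}

# Canonical undirected link keys: endpoints sorted within the pair.
linkKey <- function(a, b) {
  swap <- a > b
  key_a <- ifelse(swap, b, a)
  key_b <- ifelse(swap, a, b)
  paste(key_a, key_b, sep = "\r")
}

linkKeyUnpack <- function(key) {
  parts <- strsplit(key, "\r", fixed = TRUE)
  data.frame(geneA = vapply(parts, `[`, "", 1L),
             geneB = vapply(parts, `[`, "", 2L))
}

# Consecutive-node link keys along one pathway node sequence.
pathLinkKeys <- function(nodes) {
  n <- length(nodes)
  linkKey(nodes[-n], nodes[-1L])
}
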