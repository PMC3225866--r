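# End-to-end orchestration for one or many tumor/normal dataset pairs.

#' Analysis configuration
#'
#' Validates and assembles the configuration driving [runFullAnalysis()].
#'
#' @param datasets list of dataset entries, each a list with `id`, `normal`
#'   and `tumor` (paths to cohort expression TSVs).
#' @param interactions path to the interaction edge list.
#' @param receptors,tfs paths to the role gene lists.
#' @param cancerGenes optional path to the cancer-mutated gene list.
#' @param seed integer seed (stratification), >= 0.
#' @param hubK hubs per cohort for [selectCancerHubs()]; default 50.
#' @param hubFraction hub-removal fraction in (0, 1); default 0.10.
#' @param outDir optional output directory for [writeFeatureReport()].
#' @return a validated list of class `"corsignet_config"`.
#' @export
analysisConfig <- function(datasets, interactions, receptors, tfs,
                           cancerGenes = NULL, seed = 1, hubK = 50,
                           hubFraction = 0.10, outDir = NULL) {
  stopifnot(is.list(datasets), length(datasets) >= 1L)
  for (d in datasets)
    if (!all(c("id", "normal", "tumor") %in% names(d)))
      stop("each dataset entry needs 'id', 'normal' and 'tumor'")
  if (seed < 0) stop("'seed' must be >= 0")
  if (hubFraction <= 0 || hubFraction >= 1)
    stop("'hubFraction' must lie in (0, 1)")
  if (hubK < 1) stop("'hubK' must be >= 1")
  structure(list(datasets = datasets, interactions = interactions,
                 receptors = receptors, tfs = tfs,
                 cancerGenes = cancerGenes, seed = as.integer(seed),
                 hubK = hubK, hubFraction = hubFraction, outDir = outDir),
            class = "corsignet_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' @param path configuration file; the structure mirrors the arguments of
#'   [analysisConfig()].
#' @return a validated configuration, see [analysisConfig()].
#' @export
readAnalysisConfig <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  do.call(analysisConfig, cfg)
}

#' Analyze one tumor/normal dataset pair
#'
#' The per-dataset stage of the pipeline: stratify the cohorts to equal
#' sample numbers, build the correlation-weighted network per cohort,
#' extract all receptor-to-transcription-factor pathways, prune to the
#' pathway-used largest connected component, compute the feature panel and
#' -- when a cancer-mutated gene list is supplied -- the three motif counts
#' on the shared triangles of both cohorts' networks.
#'
#' @param exprNormal,exprTumor cohort expression (`SummarizedExperiment` or
#'   matrix).
#' @param interactions interaction data.frame (`geneA`, `geneB`).
#' @param receptors,tfs role gene lists (character vectors).
#' @param cancerGenes optional character vector of cancer-mutated genes.
#' @param seed stratification seed.
#' @param hubK,hubFraction see [analysisConfig()].
#' @return list with `features` (two-row data.frame, one per cohort),
#'   `motifs` (data.frame `motif`, `cohort`, `count`; `NULL` without
#'   `cancerGenes`), and the two [SignalingNetwork-class] objects
#'   `signalingNormal`, `signalingTumor`.
#' @export
runDatasetPair <- function(exprNormal, exprTumor, interactions, receptors,
                           tfs, cancerGenes = NULL, seed = 1, hubK = 50,
                           hubFraction = 0.10) {
  strat <- stratifyCohort(exprNormal, exprTumor, seed)
  analyse <- function(expr) {
    net <- buildWeightedNetwork(interactions, expr)
    paths <- extractPathways(net, receptors, tfs)
    buildSignalingNetwork(net, paths)
  }
  snetN <- analyse(strat$a)
  snetT <- analyse(strat$b)
  featN <- cbind(cohort = "normal", networkFeatures(snetN, hubFraction))
  featT <- cbind(cohort = "tumor", networkFeatures(snetT, hubFraction))
  features <- rbind(featN, featT)

  motifs <- NULL
  if (!is.null(cancerGenes) && length(cancerGenes) > 0L) {
    hubs <- selectCancerHubs(snetN@nodeFreq, snetT@nodeFreq, cancerGenes,
                             k = hubK)
    tri <- enumerateSharedTriangles(snetN, snetT, hubs)
    integ <- countIntegrationMotifs(tri)
    maint <- countMaintenanceMotifs(tri)
    comp <- countComparativeMotifs(snetN@pathways, snetT@pathways)
    motifs <- data.frame(
      motif = rep(c("integration", "maintenance", "comparative"), each = 2L),
      cohort = rep(c("normal", "tumor"), 3L),
      count = c(integ, maint, comp))
  }
  list(features = features, motifs = motifs,
       signalingNormal = snetN, signalingTumor = snetT)
}

#' Run the full analysis over all configured dataset pairs
#'
#' For each dataset pair: stratify, build both weighted networks, extract
#' pathways, prune, compute features and motifs (see [runDatasetPair()]);
#' afterwards the per-dataset feature panels are compared across datasets
#' with paired Wilcoxon tests.  A failing dataset is logged and skipped; at
#' least one dataset must succeed.  Identical configuration and seed give
#' identical output.
#'
#' @param config a configuration from [analysisConfig()] or
#'   [readAnalysisConfig()].
#' @return list with `features`, `motifs`, `comparison` (data.frames),
#'   `failed` (named character vector of error messages, possibly empty) and
#'   `provenance`; written to `config$outDir` via [writeFeatureReport()]
#'   when set.
#' @export
runFullAnalysis <- function(config) {
  stopifnot(inherits(config, "corsignet_config"))
  interactions <- readInteractionList(config$interactions)
  receptors <- readGeneList(config$receptors, "receptor")
  tfs <- readGeneList(config$tfs, "transcription_factor")
  cancerGenes <- if (!is.null(config$cancerGenes))
    readGeneList(config$cancerGenes, "cancer_mutated") else NULL

  features <- list(); motifs <- list(); failed <- character(0)
  for (d in config$datasets) {
    t0 <- Sys.time()
    res <- tryCatch({
      runDatasetPair(readExpressionMatrix(d$normal),
                     readExpressionMatrix(d$tumor),
                     interactions, receptors, tfs, cancerGenes,
                     seed = config$seed, hubK = config$hubK,
                     hubFraction = config$hubFraction)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("dataset '", d$id, "' failed: ", conditionMessage(res))
      failed[d$id] <- conditionMessage(res)
      next
    }
    message(sprintf("dataset '%s' done in %.1fs", d$id,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    feat <- res$features
    long <- do.call(rbind, lapply(
      setdiff(names(feat), "cohort"), function(f)
        data.frame(dataset = d$id, cohort = feat$cohort, feature = f,
                   value = feat[[f]])))
    features[[d$id]] <- long
    if (!is.null(res$motifs))
      motifs[[d$id]] <- cbind(dataset = d$id, res$motifs)
  }
  if (length(features) == 0L) stop("all datasets failed")

  features <- do.call(rbind, features)
  rownames(features) <- NULL
  motifs <- if (length(motifs) > 0L) {
    m <- do.call(rbind, motifs); rownames(m) <- NULL; m
  } else data.frame(dataset = character(0), motif = character(0),
                    cohort = character(0), count = numeric(0))

  wide <- features[features$cohort == "normal",
                   c("dataset", "feature", "value")]
  names(wide)[3L] <- "normal"
  tum <- features[features$cohort == "tumor", c("dataset", "feature", "value")]
  wide$tumor <- tum$value[match(paste(wide$dataset, wide$feature),
                                paste(tum$dataset, tum$feature))]
  comparison <- compareFeatures(wide)

  out <- list(features = features, motifs = motifs, comparison = comparison,
              failed = failed,
              provenance = list(seed = config$seed, hubK = config$hubK,
                                hubFraction = config$hubFraction,
                                nDatasets = length(config$datasets)))
  if (!is.null(config$outDir)) writeFeatureReport(out, config$outDir)
  out
}

#' Write a synthetic study as standard pipeline input files
#'
#' Materializes [generatePairedCohorts()] output as the four standard input
#' files (interaction TSV, two expression TSVs, receptor and TF lists) so
#' the pipeline consumes synthetic data exactly like real data.
#'
#' @param study a list from [generatePairedCohorts()].
#' @param dir output directory, created if needed.
#' @return invisibly, a named list of the written paths (usable as fields of
#'   [analysisConfig()]).
#' @export
writeSyntheticStudy <- function(study, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  p <- list(interactions = file.path(dir, "interactions.tsv"),
            normal = file.path(dir, "expr_normal.tsv"),
            tumor = file.path(dir, "expr_tumor.tsv"),
            receptors = file.path(dir, "receptors.txt"),
            tfs = file.path(dir, "tfs.txt"))
  utils::write.table(study$interactions, p$interactions, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeExpr <- function(se, path) {
    m <- exprValues(se)
    df <- data.frame(gene = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeExpr(study$normal, p$normal)
  writeExpr(study$tumor, p$tumor)
  writeLines(study$receptors, p$receptors)
  writeLines(study$tfs, p$tfs)
  invisible(p)
}
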