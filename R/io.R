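# Input/output: expression matrices, interaction lists, gene lists,
# cohort stratification and the report writer.

#' Assemble a cohort expression matrix
#'
#' Wraps a genes-by-samples numeric matrix into a
#' \linkS4class{SummarizedExperiment} after validating the invariants every
#' downstream step relies on: unique gene ids, at least three samples, all
#' values finite.  Expression is assumed gene-level and pre-normalized;
#' duplicate gene rows are an error rather than being silently aggregated.
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols,
#'   trimmed of surrounding whitespace), samples in columns.
#' @return a `SummarizedExperiment` with a single assay `"exprs"`.
#' @export
makeExpressionMatrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  genes <- trimws(rownames(values))
  if (is.null(genes) || any(genes == ""))
    stop("all rows must carry a gene symbol")
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0L)
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  if (ncol(values) < 3L)
    stop("at least 3 samples are required, got ", ncol(values))
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("samples must carry unique labels")
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 genes[bad[1L, 1L]], colnames(values)[bad[1L, 2L]]))
  rownames(values) <- genes
  SummarizedExperiment::SummarizedExperiment(assays = list(exprs = values))
}

#' Read a cohort expression matrix from TSV/CSV
#'
#' Expected layout: a header row of sample labels, first column gene symbols,
#' one gene per row.  Row and column order are preserved.  Duplicate genes,
#' non-numeric cells and cohorts of fewer than three samples are hard errors;
#' missing values are not supported (the matrices are assumed complete after
#' normalization).
#'
#' @param path path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return a `SummarizedExperiment`, see [makeExpressionMatrix()].
#' @export
readExpressionMatrix <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L) stop("expression file must have gene + sample columns")
  genes <- trimws(raw[[1L]])
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric expression value '%s' at gene '%s', sample '%s'",
                 vals[bad[1L, 1L], bad[1L, 2L]], genes[bad[1L, 1L]],
                 colnames(vals)[bad[1L, 2L]]))
  dimnames(num) <- list(genes, colnames(vals))
  makeExpressionMatrix(num)
}

#' Read an undirected protein-interaction edge list
#'
#' Two tab-separated gene symbols per line; lines starting with `#` are
#' skipped, as is an optional header line (detected when its two fields
#' reappear nowhere else and equal common header words).  Self-pairs are
#' dropped with a warning; `(a,b)` and `(b,a)` are identical and deduplicated.
#'
#' @param path path to the two-column TSV.
#' @return data.frame with character columns `geneA`, `geneB`
#'   (canonical order `geneA < geneB`, rows sorted, no duplicates).
#' @export
readInteractionList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) stop("no interactions found in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L))
    stop(sprintf("malformed interaction line %d (expected 2 fields, got %d)",
                 line_no[which(nf != 2L)[1L]], nf[nf != 2L][1L]))
  a <- trimws(vapply(parts, `[`, "", 1L))
  b <- trimws(vapply(parts, `[`, "", 2L))
  if (tolower(a[1L]) %in% c("genea", "gene_a", "gene1", "protein1", "source") ||
      tolower(b[1L]) %in% c("geneb", "gene_b", "gene2", "protein2", "target")) {
    a <- a[-1L]; b <- b[-1L]
  }
  self <- a == b
  if (any(self)) {
    warning(sum(self), " self-interaction line(s) dropped")
    a <- a[!self]; b <- b[!self]
  }
  key <- linkKey(a, b)
  dup <- duplicated(key)
  if (any(dup))
    message(sum(dup), " duplicate interaction line(s) collapsed")
  df <- linkKeyUnpack(sort(unique(key)))
  if (nrow(df) == 0L) stop("no interactions left after filtering in ", path)
  df
}

#' Read a role gene list (receptors, transcription factors, cancer genes)
#'
#' One symbol per line; `#` comments allowed; duplicates collapsed.
#' Receptor and transcription-factor lists must be non-empty; the
#' cancer-mutated list is optional and may be empty (warning only).
#'
#' @param path path to the file.
#' @param role one of `"receptor"`, `"transcription_factor"`,
#'   `"cancer_mutated"`.
#' @return sorted character vector of unique symbols, with the role recorded
#'   in attribute `"role"`.
#' @export
readGeneList <- function(path,
                         role = c("receptor", "transcription_factor",
                                  "cancer_mutated")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  syms <- sort(unique(lines[!grepl("^#", lines) & nzchar(lines)]))
  if (length(syms) == 0L) {
    if (role == "cancer_mutated") {
      warning("cancer-mutated gene list is empty: ", path)
    } else {
      stop("empty ", role, " gene list: ", path)
    }
  }
  structure(syms, role = role)
}

#' Balance two cohorts by random deletion of the overrepresented class
#'
#' Samples of the larger cohort are deleted uniformly at random (without
#' replacement, driven by `seed`) until both cohorts hold the same number of
#' samples; the smaller cohort is returned unchanged.  Both inputs must share
#' an identical gene-id ordering.
#'
#' @param a,b cohort expression matrices (`SummarizedExperiment` or numeric
#'   matrix).
#' @param seed integer seed controlling the deletion.
#' @return list with elements `a` and `b`, both `SummarizedExperiment`s with
#'   `min(ncol(a), ncol(b))` samples.
#' @export
stratifyCohort <- function(a, b, seed) {
  ma <- exprValues(a); mb <- exprValues(b)
  if (!identical(rownames(ma), rownames(mb)))
    stop("cohorts must share an identical gene_id ordering")
  n <- min(ncol(ma), ncol(mb))
  shrink <- function(m, sub_seed) {
    if (ncol(m) == n) return(m)
    keep <- withSeed(sub_seed, sort(sample.int(ncol(m), n)))
    m[, keep, drop = FALSE]
  }
  list(a = makeExpressionMatrix(shrink(ma, seed)),
       b = makeExpressionMatrix(shrink(mb, seed + 1L)))
}

#' Write the feature/motif/comparison report of a pipeline run
#'
#' Writes `features.tsv` (one row per dataset, cohort and feature),
#' `motifs.tsv`, `comparison.tsv` and a machine-readable twin `report.json`.
#' Numbers are written with 15 significant digits so a re-read reproduces
#' them to at least 12 significant digits.
#'
#' @param results list with data.frame elements `features`
#'   (`dataset`, `cohort`, `feature`, `value`), `motifs`
#'   (`dataset`, `motif`, `cohort`, `count`) and `comparison`
#'   (see [compareFeatures()]); extra metadata elements (scalars or lists)
#'   are carried into the JSON report.
#' @param dir output directory, created if needed.
#' @return invisibly, the paths of the written files.
#' @export
writeFeatureReport <- function(results, dir) {
  stopifnot(is.list(results))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x)
      formatC(x, format = "g", digits = 15))
    df
  }
  paths <- character(0)
  for (nm in c("features", "motifs", "comparison")) {
    if (is.null(results[[nm]])) next
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(fmt(results[[nm]]), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(results, jp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(c(paths, jp))
}

#' Re-read a written report
#'
#' @param dir directory previously passed to [writeFeatureReport()].
#' @return the report list as stored in `report.json`.
#' @export
readFeatureReport <- function(dir) {
  jp <- file.path(dir, "report.json")
  if (!file.exists(jp)) stop("no report.json under ", dir)
  jsonlite::read_json(jp, simplifyVector = TRUE)
}
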