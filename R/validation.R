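#' Build a knockout-expression experiment container
#'
#' Wraps a gene x sample expression matrix and its condition labels
#' (`"wt"` for wild type, `"ko:<gene>"` for a knockout of that gene) in a
#' [SummarizedExperiment::SummarizedExperiment].
#'
#' @param values numeric matrix, genes as rows (rownames = gene ids),
#'   samples as columns (colnames = sample ids).
#' @param conditions character vector of per-sample condition labels.
#' @return A `SummarizedExperiment` with assay `"expr"` and colData column
#'   `condition`.
#' @export
expressionExperiment <- function(values, conditions) {
  if (is.null(rownames(values))) stop("gene rownames required", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("gene identifiers must be unique", call. = FALSE)
  if (length(conditions) != ncol(values))
    stop("one condition label per sample required", call. = FALSE)
  bad <- !(conditions == "wt" | grepl("^ko:.+", conditions))
  if (any(bad))
    stop("condition labels must be 'wt' or 'ko:<gene>'", call. = FALSE)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%d", seq_len(ncol(values)))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = values),
    colData = S4Vectors::DataFrame(condition = conditions,
                                   row.names = colnames(values)))
}

#' Read / write a knockout-expression TSV
#'
#' Format: genes as rows, samples as columns; first row the sample
#' identifiers, second row the condition labels (`wt` or `ko:<gene>`),
#' then one row per gene.
#'
#' @param path file path.
#' @param se a `SummarizedExperiment` from [expressionExperiment()].
#' @return `readExpression()`: a `SummarizedExperiment`;
#'   `writeExpression()`: `path` invisibly.
#' @export
readExpression <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L)
    stop("expression file needs a sample row, a condition row and genes",
         call. = FALSE)
  sampleIds <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][-1L]
  conditions <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]][-1L]
  body <- read.table(text = lines[-(1:2)], sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE)
  values <- as.matrix(body[, -1L, drop = FALSE])
  rownames(values) <- body[[1L]]
  colnames(values) <- sampleIds
  storage.mode(values) <- "double"
  expressionExperiment(values, conditions)
}

#' @rdname readExpression
#' @export
writeExpression <- function(se, path) {
  values <- SummarizedExperiment::assay(se, 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(values)), collapse = "\t"), con)
  writeLines(paste(c("condition",
                     as.character(SummarizedExperiment::colData(se)$condition)),
                   collapse = "\t"), con)
  body <- cbind(rownames(values),
                format(values, digits = 15, trim = TRUE, scientific = FALSE))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Binarize a knockout-expression matrix
#'
#' `"gene_mean"` codes a value 1 when it exceeds the gene's cross-sample
#' mean; `"two_means"` splits each gene's samples into two clusters by
#' one-dimensional k-means (initialized at the gene's extreme values) and
#' codes the higher-centroid cluster 1.  Constant genes have no threshold;
#' they are coded all-0 with one collapsed warning.
#'
#' @param se a `SummarizedExperiment` from [expressionExperiment()].
#' @param method `"gene_mean"` (default) or `"two_means"`.
#' @return The input with an added/replaced integer assay `"binary"`.
#' @export
binarizeExpression <- function(se, method = c("gene_mean", "two_means")) {
  method <- match.arg(method)
  values <- SummarizedExperiment::assay(se, "expr")
  if (ncol(values) < 1L) stop("need at least one sample", call. = FALSE)
  bin <- matrix(0L, nrow = nrow(values), ncol = ncol(values),
                dimnames = dimnames(values))
  constant <- apply(values, 1L, function(x) max(x) == min(x))
  for (g in which(!constant)) {
    x <- values[g, ]
    if (method == "gene_mean") {
      bin[g, ] <- as.integer(x > mean(x))
    } else {
      km <- kmeans(x, centers = matrix(range(x), ncol = 1L))
      hi <- which.max(km$centers)
      bin[g, ] <- as.integer(km$cluster == hi)
    }
  }
  if (any(constant))
    warning(sum(constant), " constant gene(s) coded all-0 (no threshold exists)")
  SummarizedExperiment::assay(se, "binary") <- bin
  se
}

#' Experimentally affected gene set EXP_O(g)
#'
#' Genes whose consensus Boolean expression (majority vote across
#' replicate samples) differs between the knockout-of-`gene` samples and
#' the wild-type samples.  Genes with a tied vote in either condition are
#' excluded with a warning; the knocked-out gene itself is not reported
#' (its change is forced by the intervention, not observed influence).
#'
#' @param se a binarized `SummarizedExperiment` (see
#'   [binarizeExpression()]).
#' @param gene the knocked-out gene (condition label `ko:<gene>`).
#' @return Character vector of affected genes.
#' @export
affectedGeneSet <- function(se, gene) {
  if (!"binary" %in% SummarizedExperiment::assayNames(se))
    stop("binarize the expression first (assay 'binary' missing)", call. = FALSE)
  bin <- SummarizedExperiment::assay(se, "binary")
  cond <- as.character(SummarizedExperiment::colData(se)$condition)
  wt <- bin[, cond == "wt", drop = FALSE]
  ko <- bin[, cond == paste0("ko:", gene), drop = FALSE]
  if (ncol(wt) < 1L || ncol(ko) < 1L)
    stop("need at least one wild-type and one knockout(", gene, ") sample",
         call. = FALSE)
  consensus <- function(m) {
    ones <- rowSums(m); n <- ncol(m)
    out <- rep(NA_integer_, nrow(m))
    out[ones * 2L > n] <- 1L
    out[ones * 2L < n] <- 0L
    out  # NA = tie
  }
  cw <- consensus(wt); ck <- consensus(ko)
  tie <- is.na(cw) | is.na(ck)
  if (any(tie))
    warning(sum(tie), " gene(s) excluded due to tied replicate votes")
  affected <- rownames(bin)[!tie & cw != ck]
  setdiff(affected, gene)
}

#' GDI out-neighborhood GDI_O(g)
#'
#' @param gdi a [GDINetwork-class].
#' @param gene source gene.
#' @return Character vector of genes with a positive-influence edge from
#'   `gene`.
#' @export
gdiOutSet <- function(gdi, gene) {
  if (!gene %in% gdi@nodes) stop("unknown gene: ", gene, call. = FALSE)
  sort(gdi@edges$target[gdi@edges$source == gene])
}

#' Precision ratio of GDI predictions against knockout experiments
#'
#' `|expSet intersect gdiSet| / |expSet|`: the fraction of experimentally
#' knockout-affected genes that the GDI out-neighborhood predicts.
#'
#' @param expSet experimentally affected genes (EXP_O(g)); must be
#'   non-empty, an empty set raises a classed `gdinet_undefined_ratio`
#'   error rather than returning 0.
#' @param gdiSet predicted affected genes (GDI_O(g)).
#' @return Numeric in \[0, 1\].
#' @examples
#' precisionRatio(letters[1:4], letters[3:6])  # 0.5
#' @export
precisionRatio <- function(expSet, gdiSet) {
  expSet <- unique(expSet)
  if (length(expSet) == 0L)
    stopWithClass("gdinet_undefined_ratio",
                  "precision ratio undefined for an empty experimental set")
  length(intersect(expSet, unique(gdiSet))) / length(expSet)
}

#' Synthesize a knockout-expression dataset with a planted affected set
#'
#' Stands in for external microarray compendia so the validation pipeline
#' is testable end to end (synthetic data; the real-data path is a file
#' format contract only).  Each gene gets a baseline level drawn once from
#' a unit-variance normal around a global mean; in knockout samples the
#' genes of `gdiOutSet(gdi, gene)` are shifted down by `effectSize`, and
#' the knocked-out gene itself is set low by the same amount.  Independent
#' Gaussian measurement noise with standard deviation `noiseSd` is added
#' to every cell.  With `noiseSd = 0` and a large effect, the pipeline
#' recovers the planted set exactly.
#'
#' @param gdi a [GDINetwork-class] (defines the planted affected set).
#' @param gene gene to knock out.
#' @param nWt,nKo number of wild-type / knockout replicate samples.
#' @param noiseSd measurement-noise standard deviation.
#' @param effectSize downward expression shift of affected genes in
#'   knockout samples (same units as the expression values).
#' @param baselineMean global mean expression level.
#' @param seed optional integer seed.
#' @return A `SummarizedExperiment` (assay `"expr"`) with
#'   `metadata()$plantedSet` recording the planted affected genes.
#' @export
synthesizeKnockoutDataset <- function(gdi, gene, nWt = 9L, nKo = 3L,
                                      noiseSd = 0.25, effectSize = 2,
                                      baselineMean = 8, seed = NULL) {
  if (!gene %in% gdi@nodes) stop("unknown gene: ", gene, call. = FALSE)
  if (nWt < 1L || nKo < 1L) stop("need at least one sample per condition",
                                 call. = FALSE)
  genes <- gdi@nodes
  affected <- gdiOutSet(gdi, gene)
  withSeed(seed, {
    baseline <- rnorm(length(genes), mean = baselineMean, sd = 1)
    names(baseline) <- genes
    n <- nWt + nKo
    values <- matrix(rep(baseline, n), nrow = length(genes),
                     dimnames = list(genes,
                                     c(sprintf("wt%d", seq_len(nWt)),
                                       sprintf("ko%d", seq_len(nKo)))))
    koCols <- nWt + seq_len(nKo)
    values[affected, koCols] <- values[affected, koCols] - effectSize
    values[gene, koCols] <- values[gene, koCols] - effectSize
    values <- values + matrix(rnorm(length(values), sd = noiseSd),
                              nrow = nrow(values))
    se <- expressionExperiment(values,
                               c(rep("wt", nWt),
                                 rep(paste0("ko:", gene), nKo)))
    S4Vectors::metadata(se)$plantedSet <- affected
    S4Vectors::metadata(se)$knockoutGene <- gene
    se
  })
}

#' Run the validation pipeline for one knocked-out gene
#'
#' Binarizes the expression, derives the experimentally affected set and
#' compares it with the GDI out-neighborhood.
#'
#' @param gdi a [GDINetwork-class].
#' @param se expression `SummarizedExperiment`.
#' @param gene knocked-out gene.
#' @param method binarization method (see [binarizeExpression()]).
#' @return list: `gene`, `expSet`, `gdiSet`, `nExp`, `nGdi`,
#'   `nIntersect`, `ratio`.
#' @export
validateKnockout <- function(gdi, se, gene,
                             method = c("gene_mean", "two_means")) {
  binary <- suppressWarnings(binarizeExpression(se, method = match.arg(method)))
  expSet <- suppressWarnings(affectedGeneSet(binary, gene))
  gdiSet <- gdiOutSet(gdi, gene)
  list(gene = gene, expSet = expSet, gdiSet = gdiSet,
       nExp = length(expSet), nGdi = length(gdiSet),
       nIntersect = length(intersect(expSet, gdiSet)),
       ratio = if (length(expSet) == 0L) NA_real_
               else precisionRatio(expSet, gdiSet))
}
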