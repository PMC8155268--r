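#' Read a gene-by-sample expression matrix from delimited text
#'
#' The canonical on-disk layout is genes in rows: the first column holds gene
#' identifiers and the header row holds sample identifiers. Set
#' `genes_in_rows = FALSE` for the transposed dialect (samples in rows,
#' genes across the header); the returned matrix is always genes x samples.
#'
#' @param path Path to a delimited text file.
#' @param delimiter Field separator; tab by default, use "," for CSV.
#' @param genes_in_rows Logical; whether rows of the file are genes.
#' @return Numeric matrix, genes in rows, with unique `rownames` (genes) and
#'   `colnames` (samples). Empty cells become `NA`.
#' @export
read_expression <- function(path, delimiter = "\t", genes_in_rows = TRUE) {
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "", row.names = NULL,
                           na.strings = c("NA", ""))
  if (ncol(raw) < 2L) stop("expression file needs an identifier column plus at least one data column")
  ids <- raw[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate %s identifier(s): %s",
                 if (genes_in_rows) "gene" else "sample",
                 paste(unique(dup), collapse = ", ")))
  }
  body <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(vals) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric cell '%s' at row %d (id %s), column %d (%s)",
                 body[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], ids[bad[1L, 1L]],
                 bad[1L, 2L], colnames(body)[bad[1L, 2L]]))
  }
  dimnames(vals) <- list(ids, colnames(body))
  if (!genes_in_rows) vals <- t(vals)
  if (anyDuplicated(rownames(vals))) {
    stop(sprintf("duplicate gene identifier(s): %s",
                 paste(unique(rownames(vals)[duplicated(rownames(vals))]), collapse = ", ")))
  }
  vals
}

#' Write an expression matrix as delimited text (genes in rows)
#'
#' @param m Numeric genes x samples matrix with dimnames.
#' @param path Output file path.
#' @param delimiter Field separator.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, delimiter = "\t") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  # 17 significant digits so the round trip reproduces doubles exactly
  body <- array(sprintf("%.17g", m), dim = dim(m))
  body[is.na(m)] <- ""
  df <- data.frame(gene = rownames(m), body, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene", colnames(m))
  utils::write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields `name`, `description`,
#' then member identifiers. Duplicate members within a line are collapsed.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (the member genes), with a
#'   `descriptions` attribute (named character vector) and class
#'   `"gene_set_collection"`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop(sprintf("GMT line %d has %d field(s); need name, description and >=1 member", i, length(f)))
    nm <- f[[1L]]
    if (nm %in% names(sets)) stop(sprintf("duplicate gene-set name '%s' (line %d)", nm, i))
    sets[[nm]] <- unique(f[-(1:2)])
    desc[[nm]] <- f[[2L]]
  }
  structure(sets, descriptions = desc, class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#'
#' @param sets Named list of character vectors (optionally a
#'   `gene_set_collection` with a `descriptions` attribute).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else ""
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column score table (gene, score)
#'
#' Used for externally supplied per-gene scores such as ligand-based
#' druggability.
#'
#' @param path Path to a TSV with a header row and columns gene, score.
#' @return data.frame with character `gene` and numeric `score`.
#' @export
read_score_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("score table needs two columns: gene, score")
  out <- data.frame(gene = as.character(df[[1L]]), score = as.numeric(df[[2L]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene)) {
    stop(sprintf("duplicate gene in score table: %s",
                 paste(unique(out$gene[duplicated(out$gene)]), collapse = ", ")))
  }
  out
}

#' Screen genes for missingness and zero variance; impute the remainder
#'
#' Genes with a missing fraction above `max_missing_frac` are dropped; the
#' remaining missing values are imputed with the gene's median across samples;
#' genes whose imputed variance is `<= min_variance` are then dropped, so
#' downstream correlations are total and well defined. The variance screen runs
#' after imputation, which makes the filter idempotent.
#'
#' @param m Genes x samples numeric matrix (may contain `NA`).
#' @param max_missing_frac Maximum tolerated fraction of missing samples per
#'   gene, in `[0, 1)`.
#' @param min_variance Genes with variance at or below this are removed.
#' @return List with `matrix` (filtered, imputed, all finite) and `report`, a
#'   `qc_report`: data.frame `removed_genes` (gene, reason), data.frame
#'   `removed_samples` (empty here; see [detect_sample_outliers()]), and the
#'   thresholds used.
#' @export
quality_filter <- function(m, max_missing_frac = 0.5, min_variance = 0) {
  stopifnot(is.matrix(m), max_missing_frac >= 0, max_missing_frac < 1)
  miss <- rowMeans(is.na(m))
  drop_miss <- rownames(m)[miss > max_missing_frac]
  keep <- m[!(rownames(m) %in% drop_miss), , drop = FALSE]
  if (anyNA(keep)) {
    for (i in which(rowSums(is.na(keep)) > 0L)) {
      v <- keep[i, ]
      v[is.na(v)] <- stats::median(v, na.rm = TRUE)
      keep[i, ] <- v
    }
  }
  vars <- apply(keep, 1L, stats::var)
  drop_var <- rownames(keep)[vars <= min_variance]
  keep <- keep[!(rownames(keep) %in% drop_var), , drop = FALSE]
  if (nrow(keep) == 0L) stop("quality_filter removed every gene")
  removed <- data.frame(
    gene = c(drop_miss, drop_var),
    reason = c(rep("missing-fraction", length(drop_miss)),
               rep("zero-variance", length(drop_var))),
    stringsAsFactors = FALSE)
  report <- structure(list(
    removed_genes = removed,
    removed_samples = data.frame(sample = character(0), reason = character(0),
                                 stringsAsFactors = FALSE),
    thresholds = list(max_missing_frac = max_missing_frac,
                      min_variance = min_variance)),
    class = "qc_report")
  list(matrix = keep, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Quality report: %d gene(s) removed (%d missing-fraction, %d zero-variance), %d sample(s) flagged\n",
              nrow(x$removed_genes),
              sum(x$removed_genes$reason == "missing-fraction"),
              sum(x$removed_genes$reason == "zero-variance"),
              nrow(x$removed_samples)))
  invisible(x)
}

#' Flag outlying samples by hierarchical clustering
#'
#' Samples are clustered by average linkage on Euclidean distance; the tree is
#' cut at the given quantile of its merge heights; samples falling in clusters
#' holding fewer than 10% of all samples are flagged. Deterministic codification
#' of the usual by-eye dendrogram inspection.
#'
#' @param m Genes x samples matrix (samples are clustered).
#' @param cut_height_quantile Quantile of merge heights at which to cut, in
#'   `(0, 1]`. At 1 the cut sits at the root and nothing is flagged.
#' @return Character vector of flagged sample identifiers (possibly empty).
#' @export
detect_sample_outliers <- function(m, cut_height_quantile = 0.95) {
  stopifnot(is.matrix(m), ncol(m) >= 3L,
            cut_height_quantile > 0, cut_height_quantile <= 1)
  d <- stats::dist(t(m))
  h <- stats::hclust(d, method = "average")
  h$height <- cummax(h$height)   # clamp fp inversions from tied distances
  if (max(h$height) == 0) return(character(0))
  cl <- stats::cutree(h, h = stats::quantile(h$height, cut_height_quantile))
  sizes <- table(cl)
  small <- as.integer(names(sizes)[sizes < 0.1 * ncol(m)])
  sort(colnames(m)[cl %in% small])
}
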