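#' Log2-transform an expression matrix
#'
#' @param m Genes x samples numeric matrix.
#' @param offset Nonnegative pseudo-value added before taking logs.
#' @return Matrix of `log2(m + offset)`.
#' @export
log2_transform <- function(m, offset = 0) {
  stopifnot(is.matrix(m), offset >= 0)
  bad <- which(m + offset <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("value %g at gene %s, sample %s is <= 0 after offset %g",
                 m[bad[1L, 1L], bad[1L, 2L]], rownames(m)[bad[1L, 1L]],
                 colnames(m)[bad[1L, 2L]], offset))
  }
  log2(m + offset)
}

# unscaled median absolute deviation per row; selection by MAD rank is
# invariant to the 1.4826 consistency constant, so it is omitted
row_mad <- function(m) {
  apply(m, 1L, function(x) stats::median(abs(x - stats::median(x))))
}

#' Collapse probe-level rows to gene symbols
#'
#' Probes mapping to zero or to several genes are dropped (ambiguous
#' annotation); when several probes map to one gene, the probe with the
#' highest MAD across samples represents the gene.
#'
#' @param m Probe x sample matrix (rownames are probe identifiers).
#' @param probe_map data.frame with columns `probe` and `gene`; a probe
#'   repeated on several rows encodes multi-mapping.
#' @return Gene x sample matrix with unique gene rownames.
#' @export
collapse_probes <- function(m, probe_map) {
  stopifnot(is.matrix(m), all(c("probe", "gene") %in% colnames(probe_map)))
  pm <- unique(probe_map[, c("probe", "gene")])
  n_genes <- table(pm$probe)
  multi <- names(n_genes)[n_genes > 1L]
  pm <- pm[!(pm$probe %in% multi) & pm$probe %in% rownames(m), , drop = FALSE]
  if (nrow(pm) == 0L) stop("no probe maps uniquely to a gene present in the matrix")
  mads <- row_mad(m[pm$probe, , drop = FALSE])
  # per gene keep max-MAD probe; ties by probe id for determinism
  pm <- pm[order(pm$gene, -mads, pm$probe), , drop = FALSE]
  pm <- pm[!duplicated(pm$gene), , drop = FALSE]
  # preserve the probes' original row order in the output
  pm <- pm[order(match(pm$probe, rownames(m))), , drop = FALSE]
  out <- m[pm$probe, , drop = FALSE]
  rownames(out) <- pm$gene
  out
}

#' Keep the most variable genes by median absolute deviation
#'
#' Genes are ranked by unscaled MAD descending; the top `n_top` are retained in
#' their original relative order. Ties at the selection boundary are broken by
#' gene identifier (lexicographic) for determinism.
#'
#' @param m Genes x samples matrix.
#' @param n_top Number of genes to keep; if `>= nrow(m)` the input is returned.
#' @return Filtered matrix.
#' @export
mad_filter <- function(m, n_top) {
  stopifnot(is.matrix(m), n_top >= 1L)
  if (n_top >= nrow(m)) return(m)
  mads <- row_mad(m)
  ord <- order(-mads, rownames(m))
  chosen <- rownames(m)[ord[seq_len(n_top)]]
  m[rownames(m) %in% chosen, , drop = FALSE]
}
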