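# module label palette, ordered; echoes the conventional module colour
# vocabulary ("grey" is reserved for unassigned genes)
MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue", "darkred",
  "darkgreen", "darkturquoise", "darkgrey", "orange", "darkorange", "white",
  "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet",
  "darkolivegreen", "darkmagenta")

module_labels <- function(n) {
  if (n <= length(MODULE_COLORS)) MODULE_COLORS[seq_len(n)]
  else c(MODULE_COLORS, sprintf("module%03d", seq_len(n - length(MODULE_COLORS))))
}

# relabel clusters by descending size with a deterministic tie-break on the
# lexicographically smallest member gene; "grey" stays grey
relabel_by_size <- function(assignment) {
  mods <- setdiff(unique(assignment), "grey")
  if (length(mods) == 0L) return(assignment)
  sizes <- vapply(mods, function(mm) sum(assignment == mm), integer(1L))
  first_gene <- vapply(mods, function(mm) min(names(assignment)[assignment == mm]),
                       character(1L))
  ord <- order(-sizes, first_gene)
  new <- stats::setNames(module_labels(length(mods)), mods[ord])
  out <- ifelse(assignment == "grey", "grey", new[assignment])
  stats::setNames(out, names(assignment))
}

#' Detect co-expression modules from a topological overlap matrix
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`; the
#' dendrogram is cut at a quantile of its merge heights; clusters reaching
#' `min_module_size` become modules, labelled by descending size from a fixed
#' colour palette; all other genes are assigned to `"grey"`.
#'
#' @param tom Symmetric TOM with gene dimnames.
#' @param min_module_size Smallest gene count for a cluster to become a module.
#' @param cut_height_quantile Quantile of merge heights at which the tree is
#'   cut (default 0.85).
#' @return Named character vector mapping gene to module label, class
#'   `module_partition`.
#' @export
detect_modules <- function(tom, min_module_size = 100L,
                           cut_height_quantile = 0.85) {
  stopifnot(is.matrix(tom), nrow(tom) == ncol(tom), !is.null(rownames(tom)),
            min_module_size >= 2L,
            cut_height_quantile > 0, cut_height_quantile <= 1)
  genes <- rownames(tom)
  if (nrow(tom) < min_module_size) {
    warning("fewer genes than min_module_size: all genes assigned to grey")
    return(structure(stats::setNames(rep("grey", length(genes)), genes),
                     class = "module_partition"))
  }
  h <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  # tied dissimilarities can leave merge heights non-monotone by ~1e-16,
  # which cutree rejects; clamp the inversions
  h$height <- cummax(h$height)
  # nudge the cut so merges exactly at the quantile height are included
  # even when interpolation lands a few ulps below them
  cut_h <- stats::quantile(h$height, cut_height_quantile) + 1e-10
  cl <- stats::cutree(h, h = cut_h)
  sizes <- table(cl)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  assignment <- stats::setNames(
    ifelse(cl %in% keep, paste0("cluster", cl), "grey"), genes)
  structure(relabel_by_size(assignment), class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  tab <- sort(table(unclass(x)), decreasing = TRUE)
  cat(sprintf("Module partition: %d genes in %d module(s) (+ grey)\n",
              length(x), length(setdiff(names(tab), "grey"))))
  print(tab)
  invisible(x)
}

#' Module eigengenes
#'
#' For each non-grey module, member genes are standardised (mean 0, SD 1
#' across samples) and the first right-singular vector of the member x sample
#' block is taken as the module eigengene (unit norm), sign-oriented so that
#' its mean correlation with member genes is nonnegative. The fraction of
#' variance it explains is reported.
#'
#' @param m Genes x samples expression matrix covering the partition's genes.
#' @param partition Named gene -> module vector ([detect_modules()]).
#' @return Object of class `module_eigengenes`: list with `eigengenes`
#'   (module x sample matrix) and `var_explained` (named numeric).
#' @export
module_eigengenes <- function(m, partition) {
  stopifnot(is.matrix(m), all(names(partition) %in% rownames(m)))
  mods <- setdiff(unique(unclass(partition)), "grey")
  mods <- mods[order(match(mods, MODULE_COLORS, nomatch = length(MODULE_COLORS) + 1L), mods)]
  if (length(mods) == 0L) stop("partition has no non-grey module")
  eig <- matrix(0, length(mods), ncol(m), dimnames = list(mods, colnames(m)))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (mm in mods) {
    x <- m[names(partition)[partition == mm], , drop = FALSE]
    z <- (x - rowMeans(x)) / apply(x, 1L, stats::sd)
    sv <- svd(z, nu = 0L, nv = 1L)
    e <- sv$v[, 1L]
    # rows of z are standardised, so sign(mean member correlation) equals
    # sign(sum of member covariances with the eigengene)
    if (sum(z %*% (e - mean(e))) < 0) e <- -e
    eig[mm, ] <- e
    ve[mm] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  structure(list(eigengenes = eig, var_explained = ve),
            class = "module_eigengenes")
}

#' Merge modules with correlated eigengenes
#'
#' Eigengene dissimilarity is `1 - cor`; while any module pair is closer than
#' `merge_cut_height`, the closest pair is merged and the merged module's
#' eigengene recomputed from expression. Grey is never merged. Labels are
#' reassigned by descending size afterwards.
#'
#' @param m Genes x samples expression matrix.
#' @param partition Named gene -> module vector.
#' @param merge_cut_height Dissimilarity below which modules merge
#'   (default 0.15, i.e. eigengene correlation above 0.85).
#' @return Merged `module_partition`.
#' @export
merge_similar_modules <- function(m, partition, merge_cut_height = 0.15) {
  stopifnot(merge_cut_height >= 0, merge_cut_height < 1)
  part <- stats::setNames(unclass(partition), names(partition))
  repeat {
    mods <- setdiff(unique(part), "grey")
    if (length(mods) < 2L || merge_cut_height == 0) break
    e <- module_eigengenes(m, part)$eigengenes[mods, , drop = FALSE]
    d <- 1 - stats::cor(t(e))
    diag(d) <- Inf
    if (min(d) >= merge_cut_height) break
    hit <- which(d == min(d), arr.ind = TRUE)[1L, ]   # deterministic: first index pair
    pair <- sort(rownames(d)[hit])
    part[part == pair[2L]] <- pair[1L]
  }
  structure(relabel_by_size(part), class = "module_partition")
}
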