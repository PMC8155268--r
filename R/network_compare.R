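#' Venn decomposition of 2 or 3 named gene lists
#'
#' @param lists Named list of 2 or 3 character vectors.
#' @return Object of class `venn_counts`: list with `regions` (named integer
#'   vector over all 2^k - 1 membership regions, names like `"A&B"` meaning
#'   "in A and B only") and `totals` (per-list sizes after deduplication).
#' @export
venn_decompose <- function(lists) {
  if (!is.list(lists) || length(lists) < 2L || length(lists) > 3L) {
    stop("venn_decompose needs 2 or 3 named lists")
  }
  if (is.null(names(lists)) || any(!nzchar(names(lists)))) {
    names(lists) <- LETTERS[seq_along(lists)]
  }
  lists <- lapply(lists, unique)
  all_genes <- unique(unlist(lists))
  member <- vapply(lists, function(l) all_genes %in% l, logical(length(all_genes)))
  member <- matrix(member, nrow = length(all_genes))
  key <- apply(member, 1L, function(r) paste(names(lists)[r], collapse = "&"))
  combos <- unlist(lapply(seq_along(lists), function(k) {
    apply(utils::combn(names(lists), k), 2L, paste, collapse = "&")
  }))
  regions <- stats::setNames(integer(length(combos)), combos)
  tab <- table(key)
  regions[names(tab)] <- as.integer(tab)
  structure(list(regions = regions,
                 totals = vapply(lists, length, integer(1L))),
            class = "venn_counts")
}

#' @export
print.venn_counts <- function(x, ...) {
  cat("Venn region counts (exclusive regions):\n")
  print(x$regions)
  invisible(x)
}

#' Rank genes by scaled connectivity
#'
#' Rank 1 is the most connected gene; ties are broken by gene identifier
#' (lexicographic) so ranking is deterministic.
#'
#' @param profile `connectivity_profile` (data.frame gene, k, K).
#' @param restrict_to Optional subset of genes to rank within.
#' @return data.frame gene, K, rank.
#' @export
rank_scaled_connectivity <- function(profile, restrict_to = NULL) {
  df <- as.data.frame(profile)[, c("gene", "K")]
  if (!is.null(restrict_to)) {
    if (!all(restrict_to %in% df$gene)) stop("restrict_to contains genes absent from the profile")
    df <- df[df$gene %in% restrict_to, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no genes to rank")
  df <- df[order(-df$K, df$gene), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

# shared assembly of a rank-divergence comparison from per-gene rank pairs
rank_divergence_table <- function(gene, K_a, rank_a, K_b, rank_b,
                                  n_bins = 20L, rank_space = NULL) {
  tab <- data.frame(gene = gene, K_a = K_a, rank_a = rank_a,
                    K_b = K_b, rank_b = rank_b,
                    abs_rank_diff = abs(rank_a - rank_b),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$abs_rank_diff, tab$gene), ]
  rownames(tab) <- NULL
  if (is.null(rank_space)) rank_space <- nrow(tab)
  breaks <- seq(0, max(rank_space - 1L, 1L), length.out = n_bins + 1L)
  counts <- tabulate(cut(tab$abs_rank_diff, breaks, include.lowest = TRUE),
                     nbins = n_bins)
  structure(list(table = tab,
                 mean_abs_rank_diff = mean(tab$abs_rank_diff),
                 histogram = data.frame(bin_low = breaks[-length(breaks)],
                                        bin_high = breaks[-1L],
                                        count = counts)),
            class = "connectivity_comparison")
}

#' @export
print.connectivity_comparison <- function(x, ...) {
  cat(sprintf("Connectivity rank divergence over %d common genes; mean |rank difference| = %.1f\n",
              nrow(x$table), x$mean_abs_rank_diff))
  print(utils::head(x$table, 10L), row.names = FALSE)
  invisible(x)
}

#' Rank divergence from externally supplied connectivity ranks
#'
#' Builds the same comparison as [connectivity_rank_divergence()] from
#' per-gene scaled connectivities and ranks that were computed elsewhere —
#' for example a published table of per-network hub rankings.
#'
#' @param gene Gene identifiers.
#' @param K_a,rank_a,K_b,rank_b Scaled connectivity and rank of each gene in
#'   the two networks.
#' @param rank_space Size of the rank universe (for the histogram range);
#'   defaults to the number of genes supplied.
#' @param n_bins Equal-width histogram bins (default 20).
#' @return Object of class `connectivity_comparison`.
#' @export
rank_divergence_from_ranks <- function(gene, K_a, rank_a, K_b, rank_b,
                                       rank_space = NULL, n_bins = 20L) {
  stopifnot(length(gene) > 0L,
            length(K_a) == length(gene), length(rank_a) == length(gene),
            length(K_b) == length(gene), length(rank_b) == length(gene))
  rank_divergence_table(gene, K_a, rank_a, K_b, rank_b,
                        n_bins = n_bins, rank_space = rank_space)
}

#' Scaled-connectivity rank divergence between two networks
#'
#' Both profiles are restricted to their common genes; each restriction is
#' ranked (1 = strongest hub); the per-gene absolute rank difference flags
#' genes that are hubs in one network but peripheral in the other. With
#' `rank_within = "full"`, ranks are computed over each network's complete
#' gene set before restriction, reproducing rank scales like 1..10,000 even
#' when the intersection is smaller.
#'
#' @param a,b `connectivity_profile` objects.
#' @param rank_within `"common"` (default) or `"full"`.
#' @param n_bins Equal-width histogram bins for the summary (default 20).
#' @return Object of class `connectivity_comparison`: `table` (gene, K_a,
#'   rank_a, K_b, rank_b, abs_rank_diff, sorted by divergence),
#'   `mean_abs_rank_diff`, `histogram`.
#' @export
connectivity_rank_divergence <- function(a, b, rank_within = c("common", "full"),
                                         n_bins = 20L) {
  rank_within <- match.arg(rank_within)
  common <- intersect(a$gene, b$gene)
  if (length(common) == 0L) stop("the two profiles share no genes")
  ra <- rank_scaled_connectivity(a, if (rank_within == "common") common else NULL)
  rb <- rank_scaled_connectivity(b, if (rank_within == "common") common else NULL)
  ra <- ra[match(common, ra$gene), ]
  rb <- rb[match(common, rb$gene), ]
  rank_space <- if (rank_within == "common") length(common)
                else max(nrow(as.data.frame(a)), nrow(as.data.frame(b)))
  rank_divergence_table(common, ra$K, ra$rank, rb$K, rb$rank,
                        n_bins = n_bins, rank_space = rank_space)
}

#' Cross-tabulate two module partitions
#'
#' Counts common genes per (module in A, module in B) cell and tests each cell
#' for over-representation with the hypergeometric upper tail on the
#' common-gene universe; BH across cells. Grey is excluded.
#'
#' @param pa,pb Named gene -> module vectors.
#' @return data.frame module_a, module_b, size_a, size_b, overlap, p_value,
#'   adjusted_p (sizes restricted to common genes), sorted by adjusted_p.
#' @export
module_crosstab <- function(pa, pb) {
  common <- intersect(names(pa), names(pb))
  if (length(common) == 0L) stop("partitions share no genes")
  pa <- pa[common]; pb <- pb[common]
  mods_a <- setdiff(unique(unclass(pa)), "grey")
  mods_b <- setdiff(unique(unclass(pb)), "grey")
  rows <- list()
  for (ma in mods_a) {
    ga <- common[pa == ma]
    for (mb in mods_b) {
      gb <- common[pb == mb]
      x <- length(intersect(ga, gb))
      rows[[length(rows) + 1L]] <- data.frame(
        module_a = ma, module_b = mb,
        size_a = length(ga), size_b = length(gb), overlap = x,
        p_value = hypergeometric_p(x, length(ga), length(gb), length(common)),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(module_a = character(0), module_b = character(0),
                      size_a = integer(0), size_b = integer(0),
                      overlap = integer(0), p_value = numeric(0),
                      adjusted_p = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$adjusted_p <- bh_adjust(out$p_value)
  out <- out[order(out$adjusted_p, out$p_value, out$module_a, out$module_b), ]
  rownames(out) <- NULL
  out
}

#' Top correlated neighbours of a gene
#'
#' Spearman (default) correlation of the target gene against every other gene
#' in the matrix; the strongest `top_n` positive-to-negative ordered
#' neighbours are returned with their coefficients.
#'
#' @param m Genes x samples expression matrix.
#' @param target Gene identifier present in `m` and nonconstant.
#' @param method Correlation method (default "spearman").
#' @param top_n Number of neighbours (capped at gene count - 1).
#' @return data.frame gene, rho, sorted by descending rho (ties by gene id).
#' @export
gene_neighbors <- function(m, target, method = "spearman", top_n = 50L) {
  stopifnot(is.matrix(m), top_n >= 1L)
  if (!target %in% rownames(m)) stop(sprintf("target gene '%s' not in matrix", target))
  tv <- m[target, ]
  if (stats::sd(tv) == 0) stop(sprintf("target gene '%s' is constant", target))
  others <- setdiff(rownames(m), target)
  rho <- as.numeric(stats::cor(tv, t(m[others, , drop = FALSE]), method = method))
  df <- data.frame(gene = others, rho = rho, stringsAsFactors = FALSE)
  df <- df[order(-df$rho, df$gene), , drop = FALSE]
  df <- utils::head(df, min(top_n, nrow(df)))
  rownames(df) <- NULL
  df
}

#' Join externally supplied druggability scores with connectivity ranks
#'
#' For each connectivity profile, genes present in both the score table and
#' the profile are ranked by score (positive scores only, descending) and the
#' top `top_n` kept, each annotated with its connectivity rank in that
#' profile. Pairwise overlap counts of the top sets quantify how much the
#' networks agree on druggable hubs.
#'
#' @param scores data.frame gene, score ([read_score_table()]).
#' @param profiles Named list of `connectivity_profile` objects.
#' @param top_n Genes kept per profile (default 30).
#' @return List with `top_sets` (named list of data.frames gene, score,
#'   connectivity_rank) and `overlap` (symmetric matrix of top-set overlap
#'   counts).
#' @export
druggability_rank_join <- function(scores, profiles, top_n = 30L) {
  stopifnot(is.list(profiles), length(profiles) >= 1L, top_n >= 1L)
  top_sets <- lapply(profiles, function(pr) {
    pr <- as.data.frame(pr)
    joint <- scores[scores$gene %in% pr$gene & scores$score > 0, , drop = FALSE]
    if (nrow(joint) == 0L && nrow(scores[scores$gene %in% pr$gene, ]) == 0L) {
      stop("score table shares no genes with a connectivity profile")
    }
    joint <- joint[order(-joint$score, joint$gene), , drop = FALSE]
    joint <- utils::head(joint, min(top_n, nrow(joint)))
    ranks <- rank_scaled_connectivity(pr)
    joint$connectivity_rank <- ranks$rank[match(joint$gene, ranks$gene)]
    rownames(joint) <- NULL
    joint
  })
  nm <- names(profiles)
  ov <- matrix(0L, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    ov[i, j] <- length(intersect(top_sets[[i]]$gene, top_sets[[j]]$gene))
  }
  list(top_sets = top_sets, overlap = ov)
}
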