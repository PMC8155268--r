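#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= x)` of drawing at least `x` members of a
#' gene set of size `K_set` when sampling `n` genes without replacement from a
#' universe of `N` genes. Equivalent to a one-sided Fisher exact test.
#'
#' @param x Observed overlap.
#' @param n Module (query list) size.
#' @param K_set Gene-set size within the universe.
#' @param N Universe size.
#' @return p-value in `[0, 1]`.
#' @export
hypergeometric_p <- function(x, n, K_set, N) {
  if (x < 0 || n < 0 || K_set < 0 || N < 1 || x > min(n, K_set) ||
      n > N || K_set > N) {
    stop("invalid hypergeometric bounds: need x <= min(n, K_set) and n, K_set <= N")
  }
  stats::phyper(x - 1, K_set, N - K_set, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in the input order. Re-adjusting the output is not
#'   meaningful; adjusted values are final.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation analysis of a module partition
#'
#' Every non-grey module is tested against every gene set (intersected with
#' the universe; empty intersections are skipped) with the upper-tail
#' hypergeometric test. BH adjustment is pooled across all (module, set)
#' records by default, or within each module with `pool = "per_module"`.
#'
#' @param partition Named gene -> module vector.
#' @param sets `gene_set_collection` (or named list of character vectors).
#' @param universe Background gene identifiers; defaults to the partition's
#'   genes and must contain all of them.
#' @param pool `"global"` (default) or `"per_module"` BH pooling.
#' @return data.frame with columns module, set, N, n, K_set, x, p_value,
#'   adjusted_p, sorted by adjusted_p then p_value.
#' @export
enrich_partition <- function(partition, sets, universe = names(partition),
                             pool = c("global", "per_module")) {
  pool <- match.arg(pool)
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  if (!all(names(partition) %in% universe)) {
    stop("universe must contain every gene in the partition")
  }
  mods <- setdiff(unique(unclass(partition)), "grey")
  N <- length(universe)
  rows <- list()
  for (mm in mods) {
    members <- names(partition)[partition == mm]
    for (sn in names(sets)) {
      set_u <- intersect(sets[[sn]], universe)
      if (length(set_u) == 0L) next
      x <- length(intersect(members, set_u))
      rows[[length(rows) + 1L]] <- data.frame(
        module = mm, set = sn, N = N, n = length(members),
        K_set = length(set_u), x = x,
        p_value = hypergeometric_p(x, length(members), length(set_u), N),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(module = character(0), set = character(0),
                      N = integer(0), n = integer(0), K_set = integer(0),
                      x = integer(0), p_value = numeric(0),
                      adjusted_p = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  if (pool == "global") {
    out$adjusted_p <- bh_adjust(out$p_value)
  } else {
    out$adjusted_p <- stats::ave(out$p_value, out$module, FUN = bh_adjust)
  }
  out <- out[order(out$adjusted_p, out$p_value, out$module, out$set), ]
  rownames(out) <- NULL
  out
}
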