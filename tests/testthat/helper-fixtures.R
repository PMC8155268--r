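# shared fixture builders and independent oracles

rand_expression <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  m
}

# brute-force pairwise Pearson correlation from the covariance/SD definition
oracle_cor <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    xi <- m[i, ]; xj <- m[j, ]
    out[i, j] <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      ((length(xi) - 1) * sd(xi) * sd(xj))
  }
  out
}

# naive triple-loop TOM from the defining sums
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - diag(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(out) <- dimnames(a)
  out
}

# random valid adjacency (symmetric, [0,1], unit diagonal)
rand_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(sprintf("g%03d", seq_len(n)), sprintf("g%03d", seq_len(n)))
  a
}

# hypergeometric upper tail by exhaustive enumeration of all draws
oracle_hyper_enum <- function(x, n, K_set, N) {
  draws <- combn(N, n)
  hits <- apply(draws, 2L, function(d) sum(d <= K_set))
  mean(hits >= x)
}

# BH step-up evaluated literally: q_(i) = min_{j >= i} p_(j) * m / j, capped
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[ord] <- q
  out
}

# least squares by the normal equations
oracle_lsq <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- X %*% beta
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(slope = beta[2L], r_squared = r2)
}

# write an expression matrix to a temp TSV and return the path
tmp_expression_file <- function(m, delimiter = "\t") {
  path <- tempfile(fileext = ".tsv")
  write_expression(m, path, delimiter = delimiter)
  path
}

# a degree sequence whose binned log-log frequency curve is exactly linear:
# values 1, 10, 100 isolated in their own bins with counts 100, 10, 1
powerlaw_degrees <- function() {
  c(rep(1, 100), rep(10, 10), rep(100, 1))
}
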