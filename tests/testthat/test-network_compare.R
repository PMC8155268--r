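test_that("venn regions follow set algebra", {
  v <- venn_decompose(list(A = c("1", "2", "3"), B = c("2", "3", "4"),
                           C = c("3", "4", "5")))
  expect_identical(unname(v$regions[c("A", "B", "C")]), c(1L, 0L, 1L))
  expect_identical(unname(v$regions["A&B"]), 1L)
  expect_identical(unname(v$regions["B&C"]), 1L)
  expect_identical(unname(v$regions["A&C"]), 0L)
  expect_identical(unname(v$regions["A&B&C"]), 1L)
  expect_identical(sum(v$regions), 5L)  # |union|
  # identical lists concentrate in the centre
  v2 <- venn_decompose(list(X = letters[1:5], Y = letters[1:5], Z = letters[1:5]))
  expect_identical(unname(v2$regions["X&Y&Z"]), 5L)
  expect_identical(sum(v2$regions), 5L)
  # disjoint lists populate only unique regions
  v3 <- venn_decompose(list(A = c("a"), B = c("b", "c")))
  expect_identical(unname(v3$regions), c(1L, 2L, 0L))
  expect_error(venn_decompose(list(A = "a")), "2 or 3")
})

test_that("venn counts are invariant to list order", {
  set.seed(181)
  l <- list(A = sample(letters, 10), B = sample(letters, 15), C = sample(letters, 8))
  v1 <- venn_decompose(l)
  v2 <- venn_decompose(l[c(3, 1, 2)])
  expect_identical(unname(v1$regions["A&B&C"]), unname(v2$regions["C&A&B"]))
  expect_identical(unname(v1$regions["A"]), unname(v2$regions["A"]))
  expect_identical(sum(v1$regions), sum(v2$regions))
})

test_that("connectivity ranking is descending with lexicographic ties", {
  prof <- structure(data.frame(gene = c("a", "b", "c"), k = c(4, 2, 1),
                               K = c(1.0, 0.5, 0.25)),
                    class = c("connectivity_profile", "data.frame"))
  r <- rank_scaled_connectivity(prof)
  expect_identical(r$rank, 1:3)
  expect_identical(r$gene, c("a", "b", "c"))
  prof$K <- c(0.5, 0.5, 1)
  r2 <- rank_scaled_connectivity(prof)
  expect_identical(r2$gene, c("c", "a", "b"))   # tie a/b broken by id
  set.seed(191)
  K <- runif(50)
  prof3 <- structure(data.frame(gene = sprintf("g%02d", 1:50), k = K, K = K),
                     class = c("connectivity_profile", "data.frame"))
  r3 <- rank_scaled_connectivity(prof3)
  expect_identical(r3$gene, prof3$gene[order(-K, prof3$gene)])  # sort oracle
  expect_error(rank_scaled_connectivity(prof, restrict_to = "zz"), "absent")
})

test_that("rank divergence reproduces printed worked examples and is symmetric", {
  path <- system.file("extdata", "gse50705_brca_scaled_connectivity_top10.tsv",
                      package = "coexdiff")
  tab <- read.delim(path)
  cmp <- rank_divergence_from_ranks(tab$gene, tab$K_mcf7, tab$rank_mcf7,
                                                          tab$K_brca, tab$rank_brca,
                                          rank_space = 10000)
  got <- setNames(cmp$table$abs_rank_diff, cmp$table$gene)
  expect_equal(unname(got["SUSD2"]), 9927)
  expect_equal(unname(got["CLU"]), 9917)
  expect_equal(unname(got["TMPRSS3"]), 9793)
  expect_equal(unname(got["CYP2J2"]), 9638)
  expect_equal(unname(got), abs(tab$rank_mcf7 - tab$rank_brca)[match(names(got), tab$gene)])
  # identical profiles: zero divergence
  prof <- structure(data.frame(gene = letters[1:5], k = 5:1, K = (5:1) / 5),
                    class = c("connectivity_profile", "data.frame"))
  same <- connectivity_rank_divergence(prof, prof)
  expect_true(all(same$table$abs_rank_diff == 0))
  expect_equal(same$mean_abs_rank_diff, 0)
  # symmetry under swapping the networks
  set.seed(201)
  profB <- prof; profB$K <- runif(5)
  d1 <- connectivity_rank_divergence(prof, profB)
  d2 <- connectivity_rank_divergence(profB, prof)
  expect_equal(setNames(d1$table$abs_rank_diff, d1$table$gene),
               setNames(d2$table$abs_rank_diff, d2$table$gene)[d1$table$gene])
  expect_error(connectivity_rank_divergence(
    prof, structure(data.frame(gene = "zz", k = 1, K = 1),
                    class = c("connectivity_profile", "data.frame"))),
    "no genes|share")
})

test_that("module cross-tabulation counts and tests overlaps", {
  pa <- structure(c(a = "blue", b = "blue", c = "turquoise",
                    d = "turquoise", e = "turquoise", f = "grey"),
                  class = "module_partition")
  ct_id <- module_crosstab(pa, pa)
  diag_cells <- ct_id[ct_id$module_a == ct_id$module_b, ]
  expect_setequal(diag_cells$overlap, c(2L, 3L))
  off <- ct_id[ct_id$module_a != ct_id$module_b, ]
  expect_true(all(off$overlap == 0L))
  # hand tally on a 6-gene fixture
  pb <- structure(c(a = "blue", b = "turquoise", c = "turquoise",
                    d = "turquoise", e = "grey", f = "blue"),
                  class = "module_partition")
  ct <- module_crosstab(pa, pb)
  cell <- function(x, y) ct$overlap[ct$module_a == x & ct$module_b == y]
  expect_identical(cell("blue", "blue"), 1L)
  expect_identical(cell("blue", "turquoise"), 1L)
  expect_identical(cell("turquoise", "turquoise"), 2L)
  expect_identical(cell("turquoise", "blue"), 0L)
  # all-grey partner yields an empty table
  pg <- structure(setNames(rep("grey", 6), names(pa)), class = "module_partition")
  expect_identical(nrow(module_crosstab(pa, pg)), 0L)
  expect_error(module_crosstab(pa, structure(c(zz = "blue"),
                                             class = "module_partition")),
               "share")
})

test_that("gene neighbours match a rank-then-Pearson oracle", {
  set.seed(211)
  m <- rand_expression(5, 20, seed = 211)
  m["g005", ] <- m["g001", ]           # duplicate of the target
  nb <- gene_neighbors(m, "g001", top_n = 4)
  expect_identical(nb$gene[1], "g005")
  expect_equal(nb$rho[1], 1)
  rank_oracle <- sapply(setdiff(rownames(m), "g001"), function(g) {
    cor(rank(m["g001", ]), rank(m[g, ]))
  })
  expect_equal(setNames(nb$rho, nb$gene), rank_oracle[nb$gene], tolerance = 1e-12)
  # top_n larger than available: everything returned
  expect_identical(nrow(gene_neighbors(m, "g001", top_n = 99)), 4L)
  m["g002", ] <- 3
  expect_error(gene_neighbors(m, "g002"), "constant")
})

test_that("druggability join ranks positive scores and counts overlaps", {
  set.seed(221)
  genes <- sprintf("g%02d", 1:10)
  scores <- data.frame(gene = genes,
                       score = c(5, 4, 3, 2, 1, -1, -2, 0.5, 0.4, 0.3))
  K <- runif(10)
  prof <- structure(data.frame(gene = genes, k = K, K = K),
                    class = c("connectivity_profile", "data.frame"))
  same <- druggability_rank_join(scores, list(a = prof, b = prof), top_n = 3)
  expect_identical(same$overlap["a", "b"], 3L)
  expect_identical(same$top_sets$a$gene, c("g01", "g02", "g03"))
  ranks <- rank_scaled_connectivity(prof)
  expect_identical(same$top_sets$a$connectivity_rank,
                   ranks$rank[match(c("g01", "g02", "g03"), ranks$gene)])
  # all-negative scores: empty top sets, zero overlap
  neg <- data.frame(gene = genes, score = -abs(scores$score))
  none <- druggability_rank_join(neg, list(a = prof, b = prof), top_n = 3)
  expect_identical(nrow(none$top_sets$a), 0L)
  expect_identical(none$overlap["a", "b"], 0L)
})

test_that("cytoscape export thresholds edges and lists every node", {
  a <- rand_adjacency(4, seed = 231)
  part <- structure(setNames(c("blue", "blue", "turquoise", "grey"),
                             rownames(a)), class = "module_partition")
  out <- export_cytoscape(a, part, threshold = 0.5, exclude_grey = FALSE)
  # brute-force pair scan
  expected <- 0L
  for (i in 1:3) for (j in (i + 1):4) if (a[i, j] >= 0.5) expected <- expected + 1L
  expect_identical(nrow(out$edges), expected)
  expect_true(all(out$edges$weight >= 0.5))
  expect_identical(nrow(out$nodes), 4L)
  # threshold above the maximum: no edges, nodes remain
  hi <- export_cytoscape(a, part, threshold = 1, exclude_grey = FALSE)
  expect_identical(nrow(hi$edges), 0L)
  expect_identical(nrow(hi$nodes), 4L)
  # threshold 0: complete graph on non-grey genes
  lo <- export_cytoscape(a, part, threshold = 0)
  expect_identical(nrow(lo$edges), 3L)   # 3 non-grey genes -> 3 pairs
  expect_false("grey" %in% lo$nodes$module)
  expect_error(export_cytoscape(a, part, threshold = 2), "threshold")
})
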