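# block TOM with two planted clusters
planted_tom <- function(sizes, within = 0.8, between = 0.05) {
  n <- sum(sizes)
  tom <- matrix(between, n, n)
  stops <- cumsum(sizes); starts <- c(1, head(stops, -1) + 1)
  for (b in seq_along(sizes)) {
    idx <- starts[b]:stops[b]
    tom[idx, idx] <- within
  }
  diag(tom) <- 1
  dimnames(tom) <- list(sprintf("g%03d", 1:n), sprintf("g%03d", 1:n))
  tom
}

test_that("planted TOM blocks are recovered exactly", {
  tom <- planted_tom(c(60, 60))
  part <- detect_modules(tom, min_module_size = 50)
  expect_identical(sort(unique(unclass(part))), c("blue", "turquoise"))
  expect_true(all(part[1:60] == part[[1]]))
  expect_true(all(part[61:120] == part[[61]]))
  expect_false(part[[1]] == part[[61]])
  # labels ordered by size: unequal blocks get turquoise for the larger
  tom2 <- planted_tom(c(70, 55))
  part2 <- detect_modules(tom2, min_module_size = 50)
  expect_identical(unname(part2[[1]]), "turquoise")
  expect_identical(unname(part2[[80]]), "blue")
})

test_that("undersized inputs and oversized thresholds give all-grey", {
  tom <- planted_tom(c(10, 10))
  expect_warning(part <- detect_modules(tom, min_module_size = 50), "grey")
  expect_true(all(part == "grey"))
})

test_that("partition covers every gene exactly once and is permutation-stable", {
  tom <- planted_tom(c(40, 30, 25), within = 0.7)
  part <- detect_modules(tom, min_module_size = 20)
  expect_identical(length(part), nrow(tom))
  expect_identical(sum(table(unclass(part))), nrow(tom))
  set.seed(101)
  perm <- sample(nrow(tom))
  part_perm <- detect_modules(tom[perm, perm], min_module_size = 20)
  # same clusters up to label identity: co-membership must match
  same <- outer(part, part, "==")
  same_perm <- outer(part_perm[names(part)], part_perm[names(part)], "==")
  expect_identical(same, same_perm)
  # identical labels across repeated runs (deterministic palette)
  expect_identical(part, detect_modules(tom, min_module_size = 20))
})

test_that("eigengenes are unit-norm first principal components, sign-oriented", {
  # module of identical genes: rank one, all variance explained
  prof <- rnorm(30)
  m <- rbind(g1 = prof, g2 = prof, g3 = prof, g4 = rnorm(30))
  colnames(m) <- sprintf("s%02d", 1:30)
  part <- structure(c(g1 = "blue", g2 = "blue", g3 = "blue", g4 = "grey"),
                    class = "module_partition")
  e <- module_eigengenes(m, part)
  expect_equal(e$var_explained[["blue"]], 1)
  z <- (prof - mean(prof)) / sd(prof)
  expect_equal(abs(cor(e$eigengenes["blue", ], z)), 1)
  expect_equal(sum(e$eigengenes["blue", ]^2), 1)   # unit norm
  # 2-gene module vs closed-form 2x2 SVD: eigengene is the scaled sum of
  # the standardized profiles (first right-singular vector)
  set.seed(111)
  m2 <- rbind(a = rnorm(10), b = rnorm(10))
  colnames(m2) <- sprintf("s%d", 1:10)
  p2 <- structure(c(a = "blue", b = "blue"), class = "module_partition")
  e2 <- module_eigengenes(m2, p2)
  z2 <- t(apply(m2, 1, function(x) (x - mean(x)) / sd(x)))
  cr <- cor(z2[1, ], z2[2, ])
  v_oracle <- if (cr >= 0) z2[1, ] + z2[2, ] else z2[1, ] - z2[2, ]
  v_oracle <- v_oracle / sqrt(sum(v_oracle^2))
  expect_equal(abs(sum(e2$eigengenes["blue", ] * v_oracle)), 1, tolerance = 1e-12)
})

test_that("eigengene orientation keeps mean member correlation nonnegative", {
  set.seed(121)
  for (rep in 1:5) {
    sim <- simulate_expression(synthetic_spec(n_samples = 40,
                                              module_sizes = rep(15, 2),
                                              n_background = 10,
                                              seed = 1000 + rep))
    part <- structure(sim$truth$partition, class = "module_partition")
    e <- module_eigengenes(sim$expression, part)
    for (mm in rownames(e$eigengenes)) {
      members <- names(part)[part == mm]
      cors <- apply(sim$expression[members, , drop = FALSE], 1,
                    cor, e$eigengenes[mm, ])
      expect_gte(mean(cors), 0)
    }
  }
})

test_that("eigengene merging follows the dissimilarity rule", {
  set.seed(131)
  base <- rnorm(50)
  m <- rbind(
    a1 = base + rnorm(50, sd = 0.1), a2 = base + rnorm(50, sd = 0.1),
    a3 = base + rnorm(50, sd = 0.1),
    b1 = base + rnorm(50, sd = 0.1), b2 = base + rnorm(50, sd = 0.1),
    c1 = rnorm(50), c2 = rnorm(50))
  colnames(m) <- sprintf("s%02d", 1:50)
  part <- structure(c(a1 = "blue", a2 = "blue", a3 = "blue",
                      b1 = "brown", b2 = "brown",
                      c1 = "turquoise", c2 = "turquoise"),
                    class = "module_partition")
  # height 0: nothing qualifies
  expect_identical(unclass(merge_similar_modules(m, part, 0))[names(part)],
                   unclass(relabelled <- structure(
                     c(a1 = "turquoise", a2 = "turquoise", a3 = "turquoise",
                       b1 = "blue", b2 = "blue", c1 = "brown", c2 = "brown"),
                     class = "module_partition"))[names(part)])
  # blue and brown track the same latent profile, so their eigengene
  # dissimilarity is ~0 and they merge; the random module stays apart
  merged <- merge_similar_modules(m, part, 0.15)
  u <- unclass(merged)
  expect_identical(u[["a1"]], u[["b1"]])
  expect_false(u[["a1"]] == u[["c1"]])
  # merged labels are reassigned by size: the 5-gene union is turquoise
  expect_identical(u[["a1"]], "turquoise")
  # two modules with identical eigengenes merge at any positive height
  part2 <- structure(c(a1 = "blue", a2 = "blue", b1 = "brown", b2 = "brown",
                       a3 = "grey", c1 = "grey", c2 = "grey"),
                     class = "module_partition")
  m2 <- m
  m2["b1", ] <- m2["a1", ]; m2["b2", ] <- m2["a2", ]   # duplicated module
  merged2 <- merge_similar_modules(m2, part2, 1e-6)
  expect_identical(unclass(merged2)[["a1"]], unclass(merged2)[["b1"]])
})
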