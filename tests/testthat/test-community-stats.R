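test_that("fourth root transforms elementwise and rejects negatives", {
  expect_equal(fourth_root(matrix(c(16, 0, 81, 1), 2)),
               matrix(c(2, 0, 3, 1), 2))
  expect_error(fourth_root(matrix(-1)), "negative")
})

test_that("Bray-Curtis matches hand values and vegan on random data", {
  X <- rbind(a = c(1, 0), b = c(0, 1), c = c(2, 2), d = c(1, 3))
  D <- bray_curtis(X)
  expect_equal(D["a", "b"], 1)          # disjoint
  expect_equal(D["c", "d"], 0.25)       # (1+1)/8
  expect_equal(diag(unclass(D)), setNames(rep(0, 4), rownames(X)))
  set.seed(7)
  for (k in 1:10) {
    Y <- matrix(rexp(40), 8, 5) * (matrix(runif(40), 8, 5) > 0.3)
    Y[1, ] <- Y[1, ] + 0.01           # avoid all-zero rows
    Dm <- bray_curtis(Y)
    Dv <- as.matrix(vegan::vegdist(Y, "bray"))
    expect_equal(max(abs(unclass(Dm) - Dv)), 0, tolerance = 1e-12)
    expect_true(all(Dm >= 0 & Dm <= 1))
    expect_equal(unclass(Dm), t(unclass(Dm)), tolerance = 1e-15)
  }
})

test_that("identical samples give zero distance; zero pairs warn", {
  X <- rbind(c(1, 2), c(1, 2))
  expect_equal(bray_curtis(X)[1, 2], 0)
  Z <- rbind(c(0, 0), c(0, 0), c(1, 1))
  expect_warning(D <- bray_curtis(Z), "all-zero")
  expect_equal(D[1, 2], 0)
  sim <- bray_curtis(X, similarity = TRUE)
  expect_equal(sim[1, 2], 1)
})

test_that("UPGMA reproduces the hand-worked 3-leaf example", {
  D <- matrix(c(0, 2, 6, 2, 0, 8, 6, 8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(D)
  expect_equal(tr$merges$height, c(2, 7))
  nwk <- to_newick(tr)
  ph <- ape::read.tree(text = nwk)
  cp <- ape::cophenetic.phylo(ph)
  expect_equal(cp["A", "B"], 2)
  expect_equal(cp["A", "C"], 7)
  expect_equal(cp["B", "C"], 7)
})

test_that("UPGMA agrees with hclust group-average on random matrices", {
  set.seed(11)
  for (k in 1:10) {
    n <- sample(4:8, 1)
    X <- matrix(rexp(n * 4), n, 4)
    rownames(X) <- paste0("s", seq_len(n))
    D <- bray_curtis(X)
    tr <- upgma(D)
    hc <- hclust(as.dist(D), method = "average")
    expect_equal(sort(tr$merges$height), sort(hc$height), tolerance = 1e-12)
    expect_equal(cophenetic_matrix(tr)[rownames(D), rownames(D)],
                 as.matrix(cophenetic(hc))[rownames(D), rownames(D)],
                 tolerance = 1e-12)
    expect_true(all(diff(tr$merges$height) >= -1e-12))  # monotone
  }
})

test_that("UPGMA output is invariant to input row permutation", {
  set.seed(12)
  X <- matrix(rexp(24), 6, 4)
  rownames(X) <- paste0("s", 1:6)
  D <- bray_curtis(X)
  perm <- sample(6)
  tr1 <- upgma(D)
  tr2 <- upgma(D[perm, perm])
  expect_equal(tr1$merges$height, tr2$merges$height, tolerance = 1e-12)
  expect_equal(cophenetic_matrix(tr1)[rownames(D), rownames(D)],
               cophenetic_matrix(tr2)[rownames(D), rownames(D)],
               tolerance = 1e-12)
})

test_that("degenerate all-equal distances merge at a single height", {
  D <- matrix(0.4, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  tr <- upgma(D)
  expect_equal(tr$merges$height, rep(0.4, 3), tolerance = 1e-12)
  # documented tie order: first merge is the smallest label pair
  expect_equal(tr$merges$a[1], -1)
  expect_equal(tr$merges$b[1], -2)
})

test_that("Newick export round-trips and handles 2 leaves and odd labels", {
  D2 <- matrix(c(0, 0.3, 0.3, 0), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  expect_match(to_newick(upgma(D2)), "^\\(A:0\\.15,B:0\\.15\\);$")
  Dq <- matrix(c(0, 0.2, 0.2, 0), 2, 2,
               dimnames = list(c("a b", "c:d"), c("a b", "c:d")))
  nwk <- to_newick(upgma(Dq))
  ph <- ape::read.tree(text = nwk)
  expect_setequal(gsub("'", "", ph$tip.label), c("a b", "c:d"))
  # round trip: cophenetic distances equal merge heights
  set.seed(13)
  X <- matrix(rexp(20), 5, 4)
  rownames(X) <- paste0("s", 1:5)
  tr <- upgma(bray_curtis(X))
  cp <- ape::cophenetic.phylo(ape::read.tree(text = to_newick(tr)))
  expect_equal(cp[rownames(X), rownames(X)],
               cophenetic_matrix(tr)[rownames(X), rownames(X)],
               tolerance = 1e-8)
})

test_that("distance matrix CSV round-trips", {
  D <- bray_curtis(matrix(rexp(20), 5, 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_distance_csv(D, path)
  back <- read_distance_csv(path)
  expect_equal(unclass(back), unclass(D), tolerance = 1e-12)
})

test_that("Kruskal-Wallis matches the hand example and stats::kruskal.test", {
  kw <- kruskal_wallis(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(kw$H, 2.4)
  expect_equal(kw$df, 1)
  same <- kruskal_wallis(c(5, 5, 5, 5), rep(c("a", "b"), 2))
  expect_equal(same$H, 0)
  set.seed(21)
  for (k in 1:10) {
    y <- sample(1:8, 20, replace = TRUE)  # forces ties
    g <- sample(c("a", "b", "c"), 20, replace = TRUE)
    if (length(unique(g)) < 2) next
    mine <- kruskal_wallis(y, g)
    ref <- stats::kruskal.test(y, factor(g))
    expect_equal(mine$H, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    # rank-based: invariant under monotone transform
    mono <- kruskal_wallis(exp(y / 2), g)
    expect_equal(mono$H, mine$H, tolerance = 1e-12)
  }
})

test_that("Dunn's z relates to H for 2 groups and is antisymmetric", {
  set.seed(22)
  y <- rnorm(16)                         # no ties
  g <- rep(c("a", "b"), each = 8)
  dn <- dunns_posthoc(y, g)
  kw <- kruskal_wallis(y, g)
  expect_equal(dn$z^2, kw$H, tolerance = 1e-9)
  # swapping labels flips the sign
  g2 <- rep(c("b", "a"), each = 8)
  dn2 <- dunns_posthoc(y, g2)
  expect_equal(dn2$z, -dn$z, tolerance = 1e-12)
  # equal-rank groups score zero
  dn3 <- dunns_posthoc(c(1, 2, 1, 2), c("a", "a", "b", "b"))
  expect_equal(dn3$z, 0)
  # bonferroni multiplies and caps at 1
  y3 <- rnorm(30); g3 <- rep(c("a", "b", "c"), 10)
  adj <- dunns_posthoc(y3, g3, adjust = "bonferroni")
  raw <- dunns_posthoc(y3, g3)
  expect_equal(adj$p_adjusted, pmin(1, raw$p * 3), tolerance = 1e-12)
})
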