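test_that("correlation distance matches hand-computed Pearson values", {
  x <- cbind(s1 = c(1, 2, 3), s2 = c(2, 4, 6), s3 = c(-1, -2, -3), s4 = c(1, 3, 2))
  rownames(x) <- paste0("g", 1:3)
  d <- as.matrix(correlation_distance(x))
  expect_equal(d["s1", "s2"], 0)                  # identical up to scale
  expect_equal(d["s1", "s3"], 2)                  # perfect anticorrelation
  expect_equal(d["s1", "s4"], 0.5)                # r = 0.5 by hand
  expect_true(all(d >= 0 & d <= 2))
  bad <- cbind(s1 = c(1, 2, 3), s2 = c(5, 5, 5))
  rownames(bad) <- paste0("g", 1:3)
  expect_error(correlation_distance(bad), "constant")
})

test_that("ward linkage reproduces the Lance-Williams hand computation", {
  d <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d["a", "b"] <- d["b", "a"] <- 1
  d["a", "c"] <- d["c", "a"] <- 4
  d["b", "c"] <- d["c", "b"] <- 4
  tree <- ward_linkage(as.dist(d))
  expect_equal(tree$merge[1, ], c(-1L, -2L))       # first merge {a, b}
  ## d({a,b}, c) = (2*4 + 2*4 - 1*1) / 3 = 5
  expect_equal(tree$height, c(1, 5))
  expect_equal(cut_k(tree, 2), c(a = 1L, b = 1L, c = 2L))

  two <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  t2 <- ward_linkage(as.dist(two))
  expect_equal(t2$height, 3)

  asym <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(ward_linkage(asym), "symmetric")
})

test_that("ward linkage agrees with the reference implementation", {
  for (s in 1:12) {
    set.seed(s)
    n <- sample(3:9, 1)
    x <- random_matrix(25, n, seed = s + 100)
    d <- correlation_distance(x)
    mine <- ward_linkage(d)
    ref <- hclust(d, method = "ward.D")
    expect_identical(mine$merge, ref$merge)
    expect_equal(mine$height, ref$height, tolerance = 1e-12)
    mine2 <- ward_linkage(d, squared = TRUE)
    ref2 <- hclust(d, method = "ward.D2")
    expect_identical(mine2$merge, ref2$merge)
    expect_equal(mine2$height, ref2$height, tolerance = 1e-12)
  }
})

test_that("cut_k covers the degenerate and labeled cases", {
  x <- random_matrix(30, 6, seed = 2)
  tree <- ward_linkage(correlation_distance(x))
  expect_equal(unname(cut_k(tree, 1)), rep(1L, 6))
  expect_equal(unname(cut_k(tree, 6)), 1:6)        # first-appearance numbering
  expect_error(cut_k(tree, 0), "between")
  expect_error(cut_k(tree, 7), "between")
  ## agrees with cutree (up to renaming) when heights are monotone
  for (k in 2:5) {
    expect_equal(adjusted_rand_index(cut_k(tree, k), cutree(tree, k)), 1)
  }
})

test_that("clustering is invariant to gene and sample order", {
  co <- default_cohort()
  ts <- tumor_slice(co)
  cl <- cut_k(ward_linkage(correlation_distance(ts$x)), 2)
  set.seed(8)
  gperm <- sample(nrow(ts$x)); sperm <- sample(ncol(ts$x))
  cl2 <- cut_k(ward_linkage(correlation_distance(ts$x[gperm, sperm])), 2)
  expect_equal(adjusted_rand_index(cl[names(cl2)], cl2), 1)
})

test_that("bootstrap support equals a naive independent recomputation", {
  x <- random_matrix(40, 6, seed = 31)
  n_boot <- 15L
  bs <- bootstrap_support(x, n_boot = n_boot, seed = 99)
  expect_true(all(bs$support >= 0 & bs$support <= 1))

  ## naive loop: same substream scheme, reference clustering implementation
  ref_tree <- hclust(correlation_distance(x), method = "ward.D")
  clades_of <- function(tree) {
    n <- nrow(tree$merge) + 1L
    out <- vector("list", n - 1L)
    for (s in seq_len(n - 1L)) {
      grab <- function(v) if (v < 0) -v else out[[v]]
      out[[s]] <- sort(c(grab(tree$merge[s, 1]), grab(tree$merge[s, 2])))
    }
    vapply(out, paste, character(1), collapse = ",")
  }
  ref <- clades_of(ref_tree)
  seeds <- derive_seeds(99, n_boot)
  hits <- numeric(length(ref))
  for (b in seq_len(n_boot)) {
    set.seed(seeds[b])
    xb <- x[sample.int(nrow(x), nrow(x), replace = TRUE), ]
    rownames(xb) <- sprintf("r%d", seq_len(nrow(xb)))
    hits <- hits + (ref %in% clades_of(hclust(correlation_distance(xb), method = "ward.D")))
  }
  expect_equal(bs$support, hits / n_boot)

  one <- bootstrap_support(x, n_boot = 1, seed = 4)
  expect_true(all(one$support %in% c(0, 1)))
  expect_error(bootstrap_support(x, n_boot = 0), "n_boot")
})

test_that("well-separated blocks get high support, noise does not", {
  ## two planted sample blocks with a strong shared shift
  set.seed(55)
  x <- random_matrix(300, 10, seed = 55, sd = 0.5)
  x[1:100, 6:10] <- x[1:100, 6:10] + 2
  bs <- bootstrap_support(x, n_boot = 200, seed = 7)
  ## locate the two block clades by membership
  cl <- cut_k(bs$tree, 2)
  blockA <- unname(sort(which(cl == cl[["s01"]])))
  blockB <- unname(sort(which(cl == cl[["s06"]])))
  merge <- bs$tree$merge
  clade_sets <- vector("list", nrow(merge))
  for (s in seq_len(nrow(merge))) {
    grab <- function(v) if (v < 0) -v else clade_sets[[v]]
    clade_sets[[s]] <- sort(c(grab(merge[s, 1]), grab(merge[s, 2])))
  }
  iA <- which(vapply(clade_sets, identical, logical(1), blockA))
  iB <- which(vapply(clade_sets, identical, logical(1), blockB))
  sup <- c(if (length(iA)) bs$support[iA], if (length(iB)) bs$support[iB])
  expect_true(length(sup) >= 1 && all(sup >= 0.95))

  noise <- random_matrix(120, 10, seed = 77)
  bn <- bootstrap_support(noise, n_boot = 100, seed = 13)
  expect_lt(median(bn$support[-length(bn$support)]), 0.8)  # root clade always 1
})

test_that("pca components satisfy the decomposition identities", {
  co <- default_cohort()
  ts <- tumor_slice(co)
  pc <- pca_first_components(ts$x, 3)
  expect_equal(dim(pc$scores), c(17L, 3L))
  ## planted subtype split is reflected in the first component
  pc1_b <- pc$scores[ts$subtype == "B", 1]; pc1_a <- pc$scores[ts$subtype == "A", 1]
  auc <- wilcoxon_rank_sum(pc1_b, pc1_a)$U / (length(pc1_a) * length(pc1_b))
  expect_gte(max(auc, 1 - auc), 0.9)

  ## one dominant planted direction captures most of the variance
  pd0 <- random_matrix(200, 10, seed = 66, sd = 0.5)
  pd0[1:100, 6:10] <- pd0[1:100, 6:10] + 2
  expect_gte(pca_first_components(pd0, 1)$variance_fraction[1], 0.5)

  x <- random_matrix(40, 8, seed = 21)
  full <- pca_first_components(x, 8)
  xc <- x - rowMeans(x)
  expect_equal(full$total_variance, sum(apply(t(xc), 2, var)), tolerance = 1e-8)
  expect_equal(sum(full$variance_fraction), 1, tolerance = 1e-8)

  dup <- cbind(x, s99 = x[, 1])
  pd <- pca_first_components(dup, 2)
  expect_equal(pd$scores["s01", ], pd$scores["s99", ], tolerance = 1e-8)
  expect_error(pca_first_components(x, 9), "n_components")
})

test_that("newick export is parseable and carries supports", {
  skip_if_not_installed("ape")
  x <- random_matrix(30, 6, seed = 44)
  bs <- bootstrap_support(x, n_boot = 10, seed = 3)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(bs$tree, path, bs$support)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, colnames(x))
  expect_equal(ape::Ntip(phy), 6)
})
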