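test_that("two-group fit matches hand-pooled computations", {
  x <- rbind(g1 = c(0, 0, 1, 1), g2 = c(1, 2, 3, 5))
  colnames(x) <- paste0("s", 1:4)
  grp <- c("a", "a", "b", "b")
  fit <- fit_two_group(x, grp)
  expect_equal(fit$beta, c(1, 2.5))
  expect_equal(fit$s2, c(0, 1.25))     # pooled: (0.5 + 2) / 2
  expect_equal(fit$df, c(2L, 2L))
  expect_equal(fit$v, c(1, 1))
  ## swapping labels negates the effect, leaves s2
  fit2 <- fit_two_group(x, c("b", "b", "a", "a"))
  expect_equal(fit2$beta, -fit$beta)
  expect_equal(fit2$s2, fit$s2)
  expect_error(fit_two_group(x, c("a", "b", "b", "b")), ">= 2 samples")
})

test_that("trigamma inversion meets its tolerance", {
  for (y in c(0.1, 1e-3, 0.5, 2, 50)) {
    x <- trigamma_inverse(y)
    expect_lt(abs(trigamma(x) - y), 1e-10)
  }
  expect_error(trigamma_inverse(-1), "positive")
})

test_that("prior estimation recovers planted hyperparameters", {
  ## s2 ~ (s0^2 d0 / chisq_d0) * chisq_d / d with d0 = 4, s0^2 = 2, d = 4
  set.seed(2026)
  n <- 20000
  sigma2 <- 4 * 2 / rchisq(n, df = 4)
  s2 <- sigma2 * rchisq(n, df = 4) / 4
  pr <- estimate_prior(s2, 4)
  expect_lt(abs(pr$d0 - 4) / 4, 0.1)
  expect_lt(abs(pr$s0_2 - 2) / 2, 0.1)
  ## and agrees with the reference empirical-Bayes implementation
  skip_if_not_installed("limma")
  ref <- limma::fitFDist(s2, df1 = 4)
  expect_equal(pr$d0, ref$df2, tolerance = 1e-6)
  expect_equal(pr$s0_2, ref$scale, tolerance = 1e-6)
})

test_that("degenerate prior follows the moments formula", {
  s2 <- rep(3, 50)
  pr <- estimate_prior(s2, 6)
  expect_true(is.infinite(pr$d0))
  e <- log(3) - digamma(3) + log(3)
  expect_equal(pr$s0_2, exp(e))
  expect_error(estimate_prior(rep(0, 50), 4), "zero")
})

test_that("moderated statistics follow the posterior-variance formula", {
  fits <- data.frame(gene_id = "g", beta = 2, s2 = 5, df = 2, v = 1)
  tab <- moderated_test(fits, list(d0 = 4, s0_2 = 2))
  expect_equal(tab$s2_post, 3)                     # (4*2 + 2*5) / 6
  expect_equal(tab$df_total, 6)
  expect_equal(tab$t_mod, 2 / sqrt(3))
  ## d0 = 0: ordinary t recovered
  x <- random_matrix(30, 8, seed = 17)
  grp <- rep(c("a", "b"), each = 4)
  f <- fit_two_group(x, grp)
  plain <- moderated_test(f, list(d0 = 0, s0_2 = 1))
  tt <- apply(x, 1, function(v) t.test(v[5:8], v[1:4], var.equal = TRUE)$statistic)
  expect_equal(plain$t_mod, unname(tt), tolerance = 1e-10)
  ## shrinkage: posterior variance lies between s2 and s0^2
  pr <- estimate_prior(f$s2, f$df[1])
  mod <- moderated_test(f, pr)
  expect_true(all(mod$s2_post >= pmin(f$s2, pr$s0_2) - 1e-12 &
                  mod$s2_post <= pmax(f$s2, pr$s0_2) + 1e-12))
  expect_true(all(mod$q >= mod$p - 1e-12))
})

test_that("moderated pipeline agrees with the reference on a fixture", {
  skip_if_not_installed("limma")
  co <- generate_cohort(synth_config(n_genes = 500, seed = 9))
  grp <- ifelse(co$samples$tissue == "tumor_vasculature", "tumor", "normal")
  mine <- moderated_de(co$matrix, grp)
  design <- cbind(1, grp == "tumor")
  ref <- limma::eBayes(limma::lmFit(co$matrix, design))
  expect_equal(mine$logFC, unname(ref$coefficients[, 2]), tolerance = 1e-8)
  expect_equal(mine$t_mod, unname(ref$t[, 2]), tolerance = 1e-6)
  expect_equal(mine$p, unname(ref$p.value[, 2]), tolerance = 1e-6)
})

test_that("BH adjustment implements step-up exactly", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(12)
  p <- runif(200)^2
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))    # q preserves the p ranking
  expect_equal(q, p.adjust(p, "BH"))               # reference implementation
})

test_that("wilcoxon rank-sum matches enumeration and handles ties", {
  res <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(res$p, 1/3)                         # 1/6 extreme table, doubled
  expect_true(res$exact)
  tie <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tie$p, 1)
  expect_false(tie$exact)
  set.seed(7)
  for (i in 1:20) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- rnorm(n1); y <- rnorm(n2, mean = runif(1, -1, 1))
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(wilcoxon_rank_sum(x, y, alt)$p, enum_wilcoxon_p(x, y, alt),
                   tolerance = 1e-12, info = paste("iter", i, alt))
    }
    expect_equal(wilcoxon_rank_sum(x, y)$p,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("row_wilcoxon is consistent with the scalar version", {
  x <- random_matrix(40, 12, seed = 23)
  g1 <- rep(c(TRUE, FALSE), each = 6)
  rw <- vasculotype:::row_wilcoxon(x, g1)
  for (i in c(1, 7, 40)) {
    ref <- wilcoxon_rank_sum(x[i, g1], x[i, !g1])
    expect_equal(rw$p[i], ref$p)
    expect_equal(unname(rw$W[i]), ref$W)
  }
})

test_that("Welch t-test matches the reference and handles degeneracy", {
  res <- two_sample_t(c(1, 2), c(4, 6))
  ref <- t.test(c(1, 2), c(4, 6))
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  ## p decreases monotonically with the shift
  ps <- vapply(c(0.5, 1, 2, 4), function(d) two_sample_t(c(1, 2, 3), c(1, 2, 3) + d)$p, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_equal(two_sample_t(c(2, 2), c(2, 2))$p, 1)
  expect_error(two_sample_t(c(1, 1), c(2, 2)), "infinite")
})
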