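test_that("marker score is the mean of row Z-scores", {
  x <- random_matrix(20, 6, seed = 10)
  single <- marker_score(x, "g001")
  expect_equal(as.numeric(single), unname(row_zscore(x["g001", , drop = FALSE])[1, ]))
  multi <- marker_score(x, c("g001", "g002", "g003"))
  expect_equal(as.numeric(multi), unname(colMeans(row_zscore(x[1:3, ]))))
  ## constant marker rows contribute zeros
  xc <- x; xc["g001", ] <- 5
  suppressWarnings(mc <- marker_score(xc, "g001"))
  expect_equal(as.numeric(mc), rep(0, 6))
  ms <- marker_score(x, c("g001", "NOPE"))
  expect_equal(attr(ms, "missing"), "NOPE")
  expect_error(marker_score(x, c("NOPE1", "NOPE2")), "NOPE1")
})

test_that("pericyte markers separate the planted subtypes", {
  co <- default_cohort()
  ts <- tumor_slice(co)
  markers <- co$truth$gene_roles$gene_id[co$truth$gene_roles$role == "pericyte_marker"]
  sc <- marker_score(ts$x, markers)
  a <- sc[ts$subtype == "A"]; b <- sc[ts$subtype == "B"]
  expect_gt(mean(b), mean(a))
  expect_lt(two_sample_t(b, a)$p, 0.05)
  ## the score ordering recapitulates the subtype split
  ord <- attr(sc, "ordering")
  top8 <- ts$ann$subtype[match(head(ord, 8), ts$ann$sample_id)]
  expect_true(mean(top8 == "B") >= 7/8)
})

test_that("spearman correlation matches rank-Pearson by hand", {
  expect_equal(spearman_correlation(1:5, (1:5)^3)$rho, 1)
  expect_equal(spearman_correlation(1:5, -(1:5)^3)$rho, -1)
  expect_equal(spearman_correlation(c(1, 2, 3), c(1, 3, 2))$rho, 0.5)
  set.seed(14)
  x <- rnorm(20); y <- rnorm(20) + 0.3 * x
  mine <- spearman_correlation(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
  expect_error(spearman_correlation(1:2, 2:1), "at least 3")
})

test_that("fisher exact 2x2 matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(c(5, 0, 0, 5)), 2/252, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(c(5, 0, 0, 5), "greater"), 1/252, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(c(2, 4, 1, 2)), 1)       # proportional rows
  expect_error(fisher_exact_2x2(c(-1, 2, 3, 4)), "non-negative")
  set.seed(19)
  for (i in 1:50) {
    tab <- sample(0:8, 4, replace = TRUE)
    if (sum(tab) == 0) next
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(fisher_exact_2x2(tab, alt),
                   enum_fisher_p(tab[1], tab[2], tab[3], tab[4], alt),
                   tolerance = 1e-12, info = paste(tab, collapse = ","))
    }
    expect_equal(fisher_exact_2x2(tab),
                 fisher.test(matrix(tab, 2, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("signature overlap builds the right table and tail", {
  u <- sprintf("G%02d", 1:10)
  res <- signature_overlap(u[1:5], u[1:5], u)
  expect_equal(res$overlap, 5)
  expect_equal(res$p, 1/252, tolerance = 1e-12)
  disj <- signature_overlap(u[1:5], u[6:10], u)
  expect_equal(disj$p, 1)
  ## overlap at expectation is unremarkable
  mid <- signature_overlap(u[1:5], u[c(1, 6:9)], u)    # overlap 1 < expected 2.5
  expect_gte(mid$p, 0.5)
  expect_error(signature_overlap(c(u[1:3], "ZZZ"), u[1:5], u), "ZZZ")
})

test_that("planted signatures segregate, null signatures do not", {
  co <- default_cohort()
  ts <- tumor_slice(co)
  roles <- co$truth$gene_roles
  sig <- roles$gene_id[roles$shift_subtype != 0]
  res <- induced_segregation(ts$x, sig, ts$subtype)
  expect_equal(res$ari, 1)
  expect_equal(res$misassigned, 0)
  nulls <- head(roles$gene_id[roles$role == "null"], 300)
  rn <- induced_segregation(ts$x, nulls, ts$subtype)
  expect_lt(rn$ari, 0.5)
  expect_error(induced_segregation(ts$x, sig, rep("A", ncol(ts$x))), "2 groups")
  expect_error(induced_segregation(ts$x, c("NOPE1", "NOPE2"), ts$subtype), "signature genes")
})

test_that("clinical association applies the right test per covariate", {
  co <- default_cohort()
  ts <- tumor_slice(co)
  labels <- ts$subtype
  ann <- ts$ann
  res <- clinical_association(labels, ann)
  expect_setequal(res$covariate,
                  c("mvd_class", "er_status", "her2_status", "node_status",
                    "grade", "tumor_size", "recurrence"))
  expect_equal(res$test[res$covariate == "tumor_size"], "welch_t")
  expect_equal(res$test[res$covariate == "mvd_class"], "fisher")
  ## identical covariate across clusters -> p = 1
  ann2 <- ann; ann2$er_status <- "pos"
  r2 <- clinical_association(labels, ann2)
  expect_true(is.na(r2$p[r2$covariate == "er_status"]))   # constant: untestable
  ann3 <- ann; ann3$er_status <- ifelse(seq_len(nrow(ann)) %% 2 == 0, "pos", "neg")
  ## perfectly balanced alternation is testable; p well-defined
  r3 <- clinical_association(labels, ann3)
  expect_true(r3$p[r3$covariate == "er_status"] > 0)
  ## fully cluster-separated binary covariate: single-table probability
  ann4 <- ann; ann4$node_status <- ifelse(labels == "A", "pos", "neg")
  r4 <- clinical_association(labels, ann4)
  expect_equal(r4$p[r4$covariate == "node_status"], 1 / choose(17, 8), tolerance = 1e-12)
  ## entirely missing covariate is reported untestable
  ann5 <- ann; ann5$grade <- NA
  r5 <- clinical_association(labels, ann5)
  expect_true(is.na(r5$p[r5$covariate == "grade"]))
})
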