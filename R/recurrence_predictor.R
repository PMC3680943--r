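## Subtype-adjusted recurrence predictor. The outcome signal in tumor
## vasculature is masked by the much larger inter-subtype differences, so
## before selecting outcome-associated genes the per-gene mean difference
## between subtypes (estimated on training samples only) is removed from the
## subtype-B profiles. Gene selection (Wilcoxon rank-sum), subtype
## adjustment and classifier training (LDA) are all nested inside
## leave-one-out cross-validation; nothing outside a fold's training set
## touches its held-out sample.

#' Remove inter-subtype mean differences
#'
#' Computes, from training samples only, the per-gene difference
#' Delta = mean(subtype B) - mean(subtype A), and subtracts it from every
#' subtype-B column of the matrix (training and, when present, held-out
#' samples labeled B). Subtype-A columns are untouched; after adjustment the
#' per-gene training means of the two subtypes are equal.
#'
#' @param x Expression matrix (genes x tumor samples).
#' @param subtype Vector of `"A"`/`"B"` labels over the columns of `x`.
#' @param training_ids Column ids forming the training set (default: all).
#' @return List with `matrix` (adjusted) and `delta` (the per-gene
#'   adjustment vector, B minus A).
#' @export
subtype_adjust <- function(x, subtype, training_ids = colnames(x)) {
  if (length(subtype) != ncol(x)) stop_vt("subtype length != sample count")
  subtype <- as.character(subtype)
  bad <- setdiff(training_ids, colnames(x))
  if (length(bad)) stop_vt("unknown training id(s): %s", paste(bad, collapse = ", "))
  tr <- colnames(x) %in% training_ids
  a_tr <- tr & subtype == "A"; b_tr <- tr & subtype == "B"
  if (!any(a_tr) || !any(b_tr)) stop_vt("training set must contain both subtypes (A: %d, B: %d)", sum(a_tr), sum(b_tr))
  delta <- rowMeans(x[, b_tr, drop = FALSE]) - rowMeans(x[, a_tr, drop = FALSE])
  out <- x
  is_b <- subtype == "B"
  out[, is_b] <- out[, is_b, drop = FALSE] - delta
  list(matrix = out, delta = delta)
}

#' Select outcome-associated genes by Wilcoxon rank-sum
#'
#' Ranks genes by ascending two-sided Wilcoxon rank-sum p-value for the
#' outcome comparison; exact ties are broken by descending distance of the
#' rank-sum from its null expectation, then by gene id, so the selection is
#' deterministic. Returns the top `k` gene ids in rank order.
#'
#' @param x Expression matrix (genes x samples).
#' @param outcome Binary outcome labels over columns (e.g. `"yes"`/`"no"`).
#' @param k Number of genes to select (`k <= nrow(x)`).
#' @return Character vector of `k` gene ids.
#' @export
wilcoxon_select <- function(x, outcome, k) {
  if (length(outcome) != ncol(x)) stop_vt("outcome length != sample count")
  outcome <- as.character(outcome)
  lev <- unique(outcome)
  if (length(lev) != 2L) stop_vt("outcome must have exactly 2 classes, got %d", length(lev))
  if (k > nrow(x)) stop_vt("k (%d) exceeds gene count (%d)", k, nrow(x))
  rw <- row_wilcoxon(x, outcome == lev[1L])
  ord <- order(rw$p, -abs(rw$W - rw$E_W), rownames(x), method = "radix")
  rownames(x)[utils::head(ord, k)]
}

#' Train a linear discriminant classifier
#'
#' Gaussian LDA with pooled within-class covariance and empirical class
#' priors. When the pooled covariance is singular or ill-conditioned
#' (condition number above 1e8) a ridge of `1e-6 * trace / k` is added to
#' the diagonal.
#'
#' @param features Numeric matrix, samples x k features.
#' @param labels Class label per sample (2 classes, >= 2 samples each).
#' @param positive The class whose posterior probability is reported as the
#'   prediction score (default `"yes"`, the recurrence class).
#' @return An `lda_model` list: `classes`, `means`, `cov`, `cov_inv`,
#'   `priors`, `ridge`, `positive`.
#' @export
lda_train <- function(features, labels, positive = "yes") {
  features <- as.matrix(features)
  if (ncol(features) < 1L) stop_vt("need at least one feature")
  labels <- as.character(labels)
  if (nrow(features) != length(labels)) stop_vt("features rows != labels length")
  classes <- unique(labels)
  if (length(classes) != 2L) stop_vt("LDA here supports exactly 2 classes, got %d", length(classes))
  if (!positive %in% classes) positive <- classes[2L]
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2L)) stop_vt("each class needs >= 2 training samples (got %s)",
                                paste(counts, collapse = ", "))
  k <- ncol(features)
  n <- nrow(features)
  means <- do.call(rbind, lapply(classes, function(cl) colMeans(features[labels == cl, , drop = FALSE])))
  centered <- features - means[match(labels, classes), , drop = FALSE]
  cov <- crossprod(centered) / (n - 2L)
  ridge <- 0
  cond <- tryCatch(kappa(cov, exact = TRUE), error = function(e) Inf)
  if (!is.finite(cond) || cond > 1e8) {
    ridge <- 1e-6 * sum(diag(cov)) / k
    if (ridge <= 0) ridge <- 1e-8
    cov <- cov + diag(ridge, k)
  }
  cov_inv <- tryCatch(solve(cov), error = function(e) {
    ridge <<- ridge + 1e-6 * (sum(diag(cov)) / k + 1e-8)
    solve(cov + diag(ridge, k))
  })
  structure(list(classes = classes, means = means, cov = cov, cov_inv = cov_inv,
                 priors = as.numeric(counts) / n, ridge = ridge, positive = positive),
            class = "lda_model")
}

#' Predict with a trained LDA model
#'
#' Returns the maximum-posterior class and the posterior probability of the
#' positive (recurrence) class.
#'
#' @param model An `lda_model` from [lda_train()].
#' @param x A feature vector or matrix (samples x k).
#' @return For a single sample, a list with `label` and `score`; for a
#'   matrix, a data.frame with one row per sample.
#' @export
lda_predict <- function(model, x) {
  single <- is.null(dim(x))
  x <- matrix(as.numeric(x), ncol = ncol(model$means), byrow = single)
  disc <- vapply(seq_along(model$classes), function(g) {
    mu <- model$means[g, ]
    drop(x %*% model$cov_inv %*% mu) - drop(mu %*% model$cov_inv %*% mu) / 2 + log(model$priors[g])
  }, numeric(nrow(x)))
  disc <- matrix(disc, nrow = nrow(x))
  shift <- disc - apply(disc, 1L, max)
  post <- exp(shift) / rowSums(exp(shift))
  ipos <- match(model$positive, model$classes)
  label <- model$classes[max.col(disc, ties.method = "first")]
  if (single) list(label = label[1L], score = post[1L, ipos])
  else data.frame(label = label, score = post[, ipos])
}

#' Nested leave-one-out cross-validated recurrence prediction
#'
#' For each tumor sample held out in turn: (1) optionally remove the
#' inter-subtype mean difference estimated on the training samples (the
#' held-out sample is adjusted too when labeled subtype B); (2) select the
#' `k` most outcome-associated genes on the training samples by Wilcoxon
#' rank-sum; (3) train LDA on the training samples; (4) predict the held-out
#' sample. Reports per-fold selections and predictions, overall accuracy,
#' the 2x2 confusion table and the Fisher exact p-value for predicted vs
#' actual labels.
#'
#' `selection = "leaky"` deliberately performs gene selection once on the
#' full data before the loop; it exists only to demonstrate (in tests) the
#' optimistic bias that nesting prevents, and must not be used for real
#' analysis.
#'
#' @param x Expression matrix (genes x tumor samples).
#' @param subtype Subtype label (`"A"`/`"B"`) per column.
#' @param outcome Outcome label (`"yes"`/`"no"`) per column.
#' @param k Number of genes per fold (default 6).
#' @param adjust Apply the subtype adjustment (default TRUE).
#' @param strict_subtype Re-derive the held-out sample's subtype by nearest
#'   training-centroid correlation instead of trusting its annotation.
#' @param selection `"nested"` (default) or `"leaky"` (diagnostic only).
#' @param positive Outcome class treated as "recurrence" for scores.
#' @return A `cv_report` list: `folds` (data.frame), `selected` (list per
#'   fold), `accuracy`, `confusion`, `fisher_p`, `k`, `adjusted`.
#' @export
loocv_run <- function(x, subtype, outcome, k = 6L, adjust = TRUE,
                      strict_subtype = FALSE, selection = c("nested", "leaky"),
                      positive = "yes") {
  selection <- match.arg(selection)
  validate_expression_matrix(x, min_samples = 3L)
  subtype <- as.character(subtype); outcome <- as.character(outcome)
  if (length(subtype) != ncol(x) || length(outcome) != ncol(x))
    stop_vt("subtype/outcome length != sample count")
  if (length(unique(outcome)) != 2L) stop_vt("outcome must have 2 classes")
  if (min(table(outcome)) < 2L) stop_vt("need >= 2 samples per outcome class")
  ids <- colnames(x)
  n <- ncol(x)
  leaky_genes <- if (selection == "leaky") {
    xa <- if (adjust) subtype_adjust(x, subtype)$matrix else x
    wilcoxon_select(xa, outcome, k)
  } else NULL

  folds <- vector("list", n)
  selected <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (length(unique(outcome[tr])) < 2L || min(table(outcome[tr])) < 2L)
      stop_vt("fold %d (holding out %s): training set lacks 2 samples of each outcome class", i, ids[i])
    sub_i <- subtype
    if (strict_subtype) {
      cent_a <- rowMeans(x[, tr[subtype[tr] == "A"], drop = FALSE])
      cent_b <- rowMeans(x[, tr[subtype[tr] == "B"], drop = FALSE])
      sub_i[i] <- if (stats::cor(x[, i], cent_b) > stats::cor(x[, i], cent_a)) "B" else "A"
    }
    if (adjust) {
      if (!all(c("A", "B") %in% sub_i[tr]))
        stop_vt("fold %d (holding out %s): training set lacks a subtype", i, ids[i])
      xa <- subtype_adjust(x, sub_i, training_ids = ids[tr])$matrix
    } else xa <- x
    genes <- if (selection == "leaky") leaky_genes
             else wilcoxon_select(xa[, tr, drop = FALSE], outcome[tr], k)
    model <- lda_train(t(xa[genes, tr, drop = FALSE]), outcome[tr], positive = positive)
    pred <- lda_predict(model, xa[genes, i])
    selected[[i]] <- genes
    folds[[i]] <- data.frame(sample_id = ids[i], subtype = sub_i[i],
                             actual = outcome[i], predicted = pred$label,
                             score = pred$score, stringsAsFactors = FALSE)
  }
  folds <- do.call(rbind, folds)
  confusion <- base::table(factor(folds$predicted, levels = sort(unique(outcome))),
                           factor(folds$actual, levels = sort(unique(outcome))))
  accuracy <- mean(folds$predicted == folds$actual)
  fisher_p <- if (all(dim(confusion) == 2L)) fisher_exact_2x2(unclass(confusion)) else NA_real_
  structure(list(folds = folds, selected = selected, accuracy = accuracy,
                 confusion = confusion, fisher_p = fisher_p, k = as.integer(k),
                 adjusted = adjust, strict_subtype = strict_subtype,
                 selection = selection),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Nested LOOCV recurrence predictor (k = %d, %s, selection %s)\n",
              x$k, if (x$adjusted) "subtype-adjusted" else "unadjusted", x$selection))
  cat(sprintf("  accuracy: %d/%d = %.1f%%   Fisher exact p = %.4g\n",
              sum(x$folds$predicted == x$folds$actual), nrow(x$folds),
              100 * x$accuracy, x$fisher_p))
  print(x$confusion)
  invisible(x)
}

#' Scan predictor gene-set sizes
#'
#' Runs the nested LOOCV predictor for each `k` in `k_range` and reports the
#' accuracy per size and the best size (ties broken toward the smallest k).
#'
#' @inheritParams loocv_run
#' @param k_range Gene-set sizes to test (default 2:100).
#' @return List with `accuracies` (data.frame k, accuracy), `best_k`,
#'   `best_accuracy`.
#' @export
size_scan <- function(x, subtype, outcome, k_range = 2:100, adjust = TRUE,
                      strict_subtype = FALSE) {
  if (length(k_range) == 0L) stop_vt("k_range is empty")
  if (max(k_range) > nrow(x)) stop_vt("max(k_range) exceeds gene count (%d)", nrow(x))
  if (min(k_range) < 1L) stop_vt("k_range must be >= 1")
  acc <- vapply(k_range, function(k) {
    loocv_run(x, subtype, outcome, k = k, adjust = adjust,
              strict_subtype = strict_subtype)$accuracy
  }, numeric(1))
  best <- which.max(acc)  # which.max takes the first (smallest k) on ties
  list(accuracies = data.frame(k = as.integer(k_range), accuracy = acc),
       best_k = as.integer(k_range[best]), best_accuracy = acc[best])
}
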