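## Gene-wise two-group statistics with empirical-Bayes variance moderation.
## The hierarchical model: per-gene residual variances s2_g ~ s0^2 * d0 /
## chisq(d0); the posterior variance (d0*s0^2 + d*s2)/(d0 + d) replaces s2
## in the t-statistic, which then has d0 + d degrees of freedom. Hyper-
## parameters are estimated from the observed log-variances by method of
## moments on the log scale (digamma/trigamma identities).

#' Per-gene two-group linear fit
#'
#' Ordinary unpaired two-group fit: effect = mean(group 2) - mean(group 1),
#' pooled within-group variance on n1 + n2 - 2 degrees of freedom, and
#' unscaled effect variance v = 1/n1 + 1/n2.
#'
#' @param x Expression matrix (genes x samples).
#' @param groups Vector of two levels over the columns of `x` (character,
#'   factor or logical); the effect is the second level minus the first,
#'   with factor levels respected and character levels sorted (so
#'   `c("normal", "tumor")` yields tumor minus normal, and relabeling the
#'   groups negates the effect).
#' @return Data frame with columns `gene_id`, `beta`, `s2`, `df`, `v`.
#' @export
fit_two_group <- function(x, groups) {
  validate_expression_matrix(x, min_samples = 4L)
  if (length(groups) != ncol(x)) stop_vt("groups length (%d) != sample count (%d)", length(groups), ncol(x))
  if (is.logical(groups)) groups <- ifelse(groups, "TRUE", "FALSE")[seq_along(groups)]
  lev <- if (is.factor(groups)) levels(droplevels(groups)) else sort(unique(as.character(groups)))
  groups <- as.character(groups)
  if (length(lev) != 2L) stop_vt("groups must have exactly 2 levels, got %d", length(lev))
  i1 <- which(groups == lev[1L]); i2 <- which(groups == lev[2L])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L) stop_vt("each group needs >= 2 samples (got %d and %d)", n1, n2)
  m1 <- rowMeans(x[, i1, drop = FALSE]); m2 <- rowMeans(x[, i2, drop = FALSE])
  ss1 <- rowSums((x[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, i2, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2L
  data.frame(gene_id = rownames(x),
             beta = m2 - m1,
             s2 = (ss1 + ss2) / df,
             df = df,
             v = 1 / n1 + 1 / n2,
             stringsAsFactors = FALSE)
}

#' Invert the trigamma function
#'
#' Solves `trigamma(x) = y` for `x > 0` by Newton iteration (with the
#' large-x start `x ~ 1/y`) to absolute tolerance 1e-10 on the trigamma
#' scale.
#'
#' @param y Positive target value(s).
#' @return `x` with `trigamma(x) = y`.
#' @export
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy) || yy <= 0) stop_vt("trigamma_inverse needs a positive finite target")
    x <- if (yy > 1) 1 / sqrt(yy) else 0.5 + 1 / yy
    for (it in 1:100) {
      f <- trigamma(x) - yy
      if (abs(f) < 1e-10) break
      step <- f / psigamma(x, deriv = 2L)
      xn <- x - step
      if (!is.finite(xn) || xn <= 0) xn <- x / 2
      x <- xn
    }
    x
  }, numeric(1))
}

#' Estimate the variance-moderation prior
#'
#' Method-of-moments on the log variances: with e_g = log(s2_g) -
#' digamma(d/2) + log(d/2), solve `trigamma(d0/2) = var(e) - trigamma(d/2)`
#' for d0 by trigamma inversion and set `s0^2 = exp(mean(e) + digamma(d0/2)
#' - log(d0/2))`. When the observed dispersion does not exceed what d
#' degrees of freedom alone produce, the prior is degenerate: d0 infinite
#' and s0^2 = exp(mean(e)).
#'
#' @param s2 Per-gene residual variances (at least 10 positive values).
#' @param df Common residual degrees of freedom of the fits.
#' @return List of class `moderation_prior` with `d0` and `s0_2`.
#' @export
estimate_prior <- function(s2, df) {
  if (length(df) != 1L || df < 1) stop_vt("df must be a single value >= 1")
  if (all(s2 <= 0)) stop_vt("all residual variances are zero; cannot estimate a prior")
  pos <- s2 > 0
  if (sum(pos) < 10L) stop_vt("need at least 10 genes with positive variance, got %d", sum(pos))
  if (!all(pos)) warning(sprintf("%d zero variance(s) excluded from prior estimation", sum(!pos)), call. = FALSE)
  e <- log(s2[pos]) - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- exp(mean(e))
  }
  structure(list(d0 = d0, s0_2 = s0_2), class = "moderation_prior")
}

#' Moderated t-test table
#'
#' Shrinks each gene's variance toward the prior, forms the moderated
#' t-statistic on d0 + d degrees of freedom (normal in the infinite-d0
#' limit) and adjusts the two-sided p-values by Benjamini-Hochberg. The
#' degenerate prior d0 = 0 is accepted and reproduces the ordinary
#' (unmoderated) t-test.
#'
#' @param fits Output of [fit_two_group()].
#' @param prior A `moderation_prior` (or list with `d0`, `s0_2`).
#' @return Data frame (`ModeratedDETable`): `gene_id`, `logFC`, `s2`,
#'   `s2_post`, `t_mod`, `df_total`, `p`, `q`.
#' @export
moderated_test <- function(fits, prior) {
  d0 <- prior$d0; s0_2 <- prior$s0_2
  if (is.null(d0) || is.null(s0_2) || d0 < 0 || s0_2 <= 0) stop_vt("invalid moderation prior")
  d <- fits$df
  s2_post <- if (is.infinite(d0)) rep(s0_2, nrow(fits)) else (d0 * s0_2 + d * fits$s2) / (d0 + d)
  t_mod <- fits$beta / sqrt(s2_post * fits$v)
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  data.frame(gene_id = fits$gene_id, logFC = fits$beta, s2 = fits$s2,
             s2_post = s2_post, t_mod = t_mod, df_total = df_total,
             p = p, q = bh_adjust(p), stringsAsFactors = FALSE)
}

#' Moderated differential expression between two groups
#'
#' Convenience wrapper: fit, estimate the prior from all genes, and test.
#' The returned table is sorted by the input gene order.
#'
#' @inheritParams fit_two_group
#' @return A `ModeratedDETable` data frame (see [moderated_test()]).
#' @export
moderated_de <- function(x, groups) {
  fits <- fit_two_group(x, groups)
  prior <- estimate_prior(fits$s2, fits$df[1L])
  tab <- moderated_test(fits, prior)
  attr(tab, "prior") <- prior
  tab
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up procedure: `q_(i) = min_{j >= i} m p_(j) / j`, capped at 1 and
#' mapped back to the input order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop_vt("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(m / (m:1) * p[o]))
  q[order(o)]
}

#' Wilcoxon rank-sum test
#'
#' Rank-sum statistic W of `x` (sum of the ranks of `x` in the pooled
#' sample). The p-value is exact -- from the null distribution of the
#' rank-sum, equivalent to enumeration over assignments -- whenever the
#' smaller group has at most `exact_limit` observations and there are no
#' ties; otherwise a normal approximation with tie correction and 0.5
#' continuity correction is used. Two-sided exact p doubles the smaller
#' tail (capped at 1).
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or `"less"`.
#' @param exact_limit Largest min-group size for exact computation.
#' @return List with `W` (rank-sum of `x`), `U` (Mann-Whitney statistic),
#'   `p`, and `exact` (logical).
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = c("two.sided", "greater", "less"),
                              exact_limit = 12L) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L) stop_vt("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && min(n1, n2) <= exact_limit
  if (exact) {
    p <- switch(alternative,
      two.sided = min(1, 2 * min(stats::pwilcox(U, n1, n2),
                                 stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE))),
      greater = stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE),
      less = stats::pwilcox(U, n1, n2))
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - sum(tie_tab^3 - tie_tab) / ((n1 + n2) * (n1 + n2 - 1)))
    sigma <- sqrt(sigma2)
    if (sigma == 0) {
      p <- 1
    } else {
      z <- U - mu
      p <- switch(alternative,
        two.sided = min(1, 2 * stats::pnorm((abs(z) - 0.5) / sigma, lower.tail = FALSE)),
        greater = stats::pnorm((z - 0.5) / sigma, lower.tail = FALSE),
        less = stats::pnorm((z + 0.5) / sigma))
    }
  }
  list(W = W, U = U, p = p, exact = exact)
}

## Vectorized two-sided Wilcoxon over the rows of a matrix; same conventions
## as wilcoxon_rank_sum. Used by the predictor's per-fold gene selection.
row_wilcoxon <- function(x, in_group1) {
  n1 <- sum(in_group1); n2 <- sum(!in_group1)
  stopifnot(n1 > 0, n2 > 0)
  r <- matrixStats::rowRanks(x, ties.method = "average")
  W <- rowSums(r[, in_group1, drop = FALSE])
  U <- W - n1 * (n1 + 1) / 2
  has_ties <- apply(x, 1L, anyDuplicated) > 0L
  p <- numeric(nrow(x))
  ex <- !has_ties & min(n1, n2) <= 12L
  if (any(ex)) {
    lo <- stats::pwilcox(U[ex], n1, n2)
    hi <- stats::pwilcox(U[ex] - 1, n1, n2, lower.tail = FALSE)
    p[ex] <- pmin(1, 2 * pmin(lo, hi))
  }
  if (any(!ex)) {
    idx <- which(!ex)
    for (i in idx) {
      g1 <- x[i, in_group1]; g2 <- x[i, !in_group1]
      p[i] <- wilcoxon_rank_sum(g1, g2)$p
    }
  }
  list(W = W, U = U, p = p, E_W = n1 * (n1 + n2 + 1) / 2)
}

#' Welch two-sample t-test
#'
#' Welch statistic with Satterthwaite degrees of freedom and two-sided
#' p-value. Degenerate inputs: if both groups are constant and equal the
#' test is vacuous and p = 1 is returned; if both are constant but unequal
#' the statistic is infinite and an error is raised.
#'
#' @param x,y Numeric vectors with at least 2 values each.
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop_vt("each group needs >= 2 values")
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 && v2 == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = NA_real_, p = 1))
    stop_vt("both groups constant with different means: t statistic infinite")
  }
  se2 <- v1 / length(x) + v2 / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (v1^2 / (length(x)^2 * (length(x) - 1)) + v2^2 / (length(y)^2 * (length(y) - 1)))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df = df))
}
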