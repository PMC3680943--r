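## Characterization of discovered clusters: pericyte-marker scoring and
## ordering, rank correlation, Fisher exact tests, gene-signature overlap
## and signature-induced segregation, and clinical-covariate association.

#' Pericyte-marker score per sample
#'
#' Mean of the row-Z-scored expression of the marker genes in each sample.
#' Ordering samples by this score is the "pericyte ordering"; score ties are
#' broken by sample id so the ordering is deterministic. Markers absent from
#' the matrix are reported in the `missing` attribute (at least one must be
#' present).
#'
#' @param x Expression matrix.
#' @param markers A gene set (list with `members`) or character vector of
#'   gene symbols.
#' @return Named numeric vector of scores with attributes `missing` and
#'   `ordering` (sample ids sorted by decreasing score).
#' @export
marker_score <- function(x, markers) {
  if (is.list(markers)) markers <- markers$members
  markers <- unique(as.character(markers))
  present <- markers[markers %in% rownames(x)]
  if (length(present) == 0L)
    stop_vt("no marker present in the matrix; requested: %s", paste(markers, collapse = ", "))
  z <- suppressWarnings(row_zscore(x[present, , drop = FALSE]))
  score <- colMeans(z)
  ord <- order(-score, colnames(x))
  attr(score, "missing") <- setdiff(markers, present)
  attr(score, "ordering") <- colnames(x)[ord]
  score
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values with p-value from the
#' t approximation on n - 2 degrees of freedom.
#'
#' @param x,y Paired numeric vectors, at least 3 observations.
#' @return List with `rho` and `p`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop_vt("x and y differ in length")
  n <- length(x)
  if (n < 3L) stop_vt("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop_vt("constant vector: correlation undefined")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric test with fixed margins. The two-sided p-value sums
#' the probabilities of all tables whose point probability does not exceed
#' that of the observed table (probability-mass rule, with a 1 + 1e-7
#' relative tolerance for floating-point equality), not the doubled
#' one-sided tail.
#'
#' @param tab 2x2 matrix (or length-4 vector, row-major `a, b, c, d`) of
#'   non-negative counts.
#' @param alternative `"two.sided"`, `"greater"` (positive association of
#'   row 1 with column 1) or `"less"`.
#' @return The p-value.
#' @export
fisher_exact_2x2 <- function(tab, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), 2L, 2L, byrow = TRUE)
  if (any(dim(tab) != 2L)) stop_vt("table must be 2x2")
  if (anyNA(tab) || any(tab < 0) || any(tab != round(tab))) stop_vt("counts must be non-negative integers")
  if (sum(tab) == 0) stop_vt("empty table")
  a <- tab[1L, 1L]
  m <- tab[1L, 1L] + tab[2L, 1L]   # column-1 total ("white balls")
  n <- tab[1L, 2L] + tab[2L, 2L]   # column-2 total
  k <- tab[1L, 1L] + tab[1L, 2L]   # row-1 total ("drawn")
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  switch(alternative,
    two.sided = sum(dens[dens <= obs * (1 + 1e-7)]),
    greater = sum(dens[support >= a]),
    less = sum(dens[support <= a]))
}

#' Gene-signature overlap test
#'
#' Builds the 2x2 membership table of two gene sets within a universe and
#' returns the one-sided (over-representation) Fisher exact p-value.
#'
#' @param set_a,set_b Gene sets (lists with `members`) or character vectors.
#' @param universe The universe gene set (superset of both).
#' @return List with `table` (2x2 matrix), `overlap`, `expected`, `p`.
#' @export
signature_overlap <- function(set_a, set_b, universe) {
  memb <- function(s) unique(as.character(if (is.list(s)) s$members else s))
  a <- memb(set_a); b <- memb(set_b); u <- memb(universe)
  off_a <- setdiff(a, u); off_b <- setdiff(b, u)
  if (length(off_a) || length(off_b))
    stop_vt("set members outside the universe: %s",
            paste(utils::head(c(off_a, off_b), 10), collapse = ", "))
  nab <- length(intersect(a, b))
  tab <- matrix(c(nab, length(a) - nab,
                  length(b) - nab, length(u) - length(a) - length(b) + nab),
                2L, 2L, byrow = TRUE,
                dimnames = list(c("in_a", "not_a"), c("in_b", "not_b")))
  list(table = tab, overlap = nab,
       expected = length(a) * length(b) / length(u),
       p = fisher_exact_2x2(tab, alternative = "greater"))
}

#' Segregation induced by a gene signature
#'
#' Subsets the matrix to the signature genes present, clusters the samples
#' (correlation distance, Ward linkage), cuts at the number of label groups
#' and reports agreement with the given labels: the adjusted Rand index and
#' the minimal misassignment count over cluster-label matchings.
#'
#' @param x Expression matrix.
#' @param signature Gene set or character vector of gene symbols.
#' @param labels Known group labels, one per sample (>= 2 groups).
#' @return List with `clusters`, `misassigned`, `ari`, `n_genes_used`.
#' @export
induced_segregation <- function(x, signature, labels) {
  if (is.list(signature)) signature <- signature$members
  labels <- as.character(labels)
  if (length(labels) != ncol(x)) stop_vt("labels length != sample count")
  k <- length(unique(labels))
  if (k < 2L) stop_vt("labels must contain at least 2 groups")
  present <- intersect(unique(signature), rownames(x))
  if (length(present) < 2L) stop_vt("fewer than 2 signature genes present in the matrix")
  xs <- x[present, , drop = FALSE]
  cl <- cut_k(ward_linkage(correlation_distance(xs)), k)
  list(clusters = cl,
       misassigned = misassignment_count(cl, labels),
       ari = adjusted_rand_index(cl, labels),
       n_genes_used = length(present))
}

#' Association of cluster labels with clinical covariates
#'
#' For each covariate: categorical covariates are tested by Fisher's exact
#' test on the cluster-by-category table (the internal 2x2 implementation
#' when both factors are binary, [stats::fisher.test()] otherwise);
#' continuous covariates by the Welch t-test between two clusters. Samples
#' with a missing covariate are dropped per covariate, with counts reported.
#' A covariate that is entirely missing or constant is reported untestable
#' (`p = NA`) rather than raising an error.
#'
#' @param labels Cluster assignment, one per row of `table` (NAs allowed;
#'   those samples are dropped).
#' @param table Sample annotation data.frame.
#' @param covariates Covariate column names; default: the conventional
#'   clinical columns present in `table`.
#' @return Data frame with `covariate`, `test`, `p`, `n_used`, `n_dropped`.
#' @export
clinical_association <- function(labels, table,
                                 covariates = intersect(c("mvd_class", "er_status", "her2_status",
                                                          "node_status", "grade", "tumor_size",
                                                          "recurrence"), names(table))) {
  labels <- as.character(labels)
  if (length(labels) != nrow(table)) stop_vt("labels length != annotation rows")
  keep0 <- !is.na(labels)
  if (length(unique(labels[keep0])) < 2L) stop_vt("need at least 2 clusters")
  out <- lapply(covariates, function(cv) {
    v <- table[[cv]]
    keep <- keep0 & !is.na(v)
    n_used <- sum(keep); n_dropped <- sum(keep0) - n_used
    l <- labels[keep]; vv <- v[keep]
    untestable <- function(test) data.frame(covariate = cv, test = test, p = NA_real_,
                                            n_used = n_used, n_dropped = n_dropped)
    if (n_used == 0L || length(unique(l)) < 2L) return(untestable("none"))
    if (is.numeric(vv) && length(unique(vv)) > 6L) {
      if (length(unique(l)) != 2L) return(untestable("welch_t"))
      g <- split(vv, l)
      if (min(lengths(g)) < 2L || all(vapply(g, stats::var, numeric(1)) == 0))
        return(untestable("welch_t"))
      p <- two_sample_t(g[[1L]], g[[2L]])$p
      return(data.frame(covariate = cv, test = "welch_t", p = p,
                        n_used = n_used, n_dropped = n_dropped))
    }
    if (length(unique(vv)) < 2L) return(untestable("fisher"))
    tab <- base::table(l, vv)   # `table` argument shadows base::table here
    p <- if (all(dim(tab) == 2L)) fisher_exact_2x2(unclass(tab)) else stats::fisher.test(tab)$p.value
    data.frame(covariate = cv, test = "fisher", p = p,
               n_used = n_used, n_dropped = n_dropped)
  })
  do.call(rbind, out)
}
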