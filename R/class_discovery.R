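## Unsupervised class discovery: hierarchical clustering of samples with
## Ward's minimum-variance method on a correlation distance, tree cutting,
## bootstrap clade support by gene resampling, and PCA summaries.

#' Correlation distance between samples
#'
#' d(i, j) = 1 - Pearson correlation of sample columns i and j computed
#' across genes; values lie in `[0, 2]`.
#'
#' @param x Expression matrix (genes x samples) with at least 2 genes.
#' @return A `dist` object over samples.
#' @export
correlation_distance <- function(x) {
  validate_expression_matrix(x, min_samples = 2L)
  if (nrow(x) < 2L) stop_vt("correlation distance needs at least 2 genes")
  sds <- matrixStats::colSds(x)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    stop_vt("constant sample column(s), correlation undefined: %s",
            paste(utils::head(bad, 5), collapse = ", "))
  }
  d <- 1 - stats::cor(x)
  stats::as.dist(d)
}

#' Ward hierarchical clustering by Lance-Williams updates
#'
#' Agglomerative clustering under Ward's minimum-variance criterion applied
#' to the supplied distances. The default is the classical recurrence on the
#' distances as given (not squared), the historical default of hierarchical
#' clustering implementations; `squared = TRUE` runs the recurrence on
#' squared distances and reports square-rooted merge heights instead. With a
#' non-Euclidean (for example correlation) distance, merge heights are not
#' guaranteed to be monotone.
#'
#' Ties in the minimum inter-cluster distance are broken toward the pair of
#' clusters created earliest, making the tree deterministic.
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @param squared Run the update on squared distances (see Details).
#' @return An object of class `hclust` (merge, height, order, labels).
#' @export
ward_linkage <- function(d, squared = FALSE) {
  if (inherits(d, "dist")) {
    dm <- as.matrix(d)
  } else if (is.matrix(d)) {
    if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12))
      stop_vt("distance matrix must be symmetric")
    dm <- d
  } else stop_vt("d must be a dist object or a symmetric matrix")
  n <- nrow(dm)
  if (n < 2L) stop_vt("need at least 2 samples to cluster")
  if (any(dm < 0)) stop_vt("distances must be non-negative")
  labels <- rownames(dm)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (squared) dm <- dm^2
  diag(dm) <- Inf

  size <- rep(1L, n)
  id <- -seq_len(n)          # hclust convention: negative = singleton leaf
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    ## earliest-created pair wins ties: scan in creation order
    act <- which(active)
    best <- c(NA_integer_, NA_integer_); bestd <- Inf
    for (jj in seq_along(act)[-1L]) {
      j <- act[jj]
      col <- dm[act[seq_len(jj - 1L)], j]
      mi <- which.min(col)
      if (col[mi] < bestd) {
        bestd <- col[mi]
        best <- c(act[mi], j)
      }
    }
    i <- best[1L]; j <- best[2L]
    a <- id[i]; b <- id[j]
    ## hclust row convention: singletons (by leaf index) before aggregates
    key <- function(v) if (v < 0) -v else n + v
    merge[step, ] <- if (key(a) < key(b)) c(a, b) else c(b, a)
    height[step] <- if (squared) sqrt(bestd) else bestd
    ## Lance-Williams update for Ward's method
    ni <- size[i]; nj <- size[j]
    for (k in which(active)) {
      if (k == i || k == j) next
      nk <- size[k]
      dnew <- ((ni + nk) * dm[i, k] + (nj + nk) * dm[j, k] - nk * bestd) / (ni + nj + nk)
      dm[i, k] <- dm[k, i] <- dnew
    }
    size[i] <- ni + nj
    active[j] <- FALSE
    id[i] <- step
  }
  order <- tree_leaf_order(merge)
  structure(list(merge = merge, height = height, order = order,
                 labels = labels, method = if (squared) "ward.squared" else "ward",
                 dist.method = "user"),
            class = "hclust")
}

tree_leaf_order <- function(merge) {
  n <- nrow(merge) + 1L
  rec <- function(node) {
    if (node < 0) return(-node)
    c(rec(merge[node, 1L]), rec(merge[node, 2L]))
  }
  rec(n - 1L)
}

## leaf index sets for every internal node, in merge order
tree_clades <- function(tree) {
  merge <- tree$merge
  n <- nrow(merge) + 1L
  clades <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    get <- function(v) if (v < 0) -v else clades[[v]]
    clades[[s]] <- sort(c(get(merge[s, 1L]), get(merge[s, 2L])))
  }
  clades
}

#' Cut a dendrogram into k clusters
#'
#' Removes the k - 1 merges with the largest heights (later merges win exact
#' ties) and labels the resulting components. With monotone heights this is
#' the usual horizontal cut; it remains well defined when Ward-on-correlation
#' heights invert. Cluster numbers are assigned by order of first appearance
#' over the input sample order.
#'
#' @param tree An `hclust` tree.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Named integer vector of cluster labels, one per sample.
#' @export
cut_k <- function(tree, k) {
  n <- nrow(tree$merge) + 1L
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > n) stop_vt("k must be between 1 and %d", n)
  k <- as.integer(k)
  keep <- rep(TRUE, n - 1L)
  if (k > 1L) {
    ord <- order(tree$height, seq_len(n - 1L))  # ties -> later merge is "higher"
    keep[utils::tail(ord, k - 1L)] <- FALSE
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  clades <- tree_clades(tree)
  for (s in which(keep)) {
    members <- clades[[s]]
    r <- find(members[1L])
    for (m in members[-1L]) parent[find(m)] <- r
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- match(roots, unique(roots))  # numbering by first appearance
  names(labels) <- tree$labels
  labels
}

#' Bootstrap clade support by gene resampling
#'
#' Clusters the full data, then repeats the clustering on `n_boot` resamples
#' of the genes (rows, with replacement, at full size) and reports for each
#' internal node of the full-data tree the proportion of resampled trees
#' containing exactly the same leaf set as a clade -- the ordinary bootstrap
#' probability. Substream seeds are derived per iteration from the master
#' seed, so any single iteration is reproducible in isolation.
#'
#' @param x Expression matrix (genes x samples).
#' @param n_boot Number of bootstrap iterations (>= 1).
#' @param seed Master seed.
#' @param squared Passed to [ward_linkage()].
#' @return A list with `tree` (the full-data `hclust`), `support` (numeric,
#'   one value per internal node in merge order), `n_boot` and `seed`.
#' @export
bootstrap_support <- function(x, n_boot, seed = 1L, squared = FALSE) {
  if (!is.numeric(n_boot) || length(n_boot) != 1L || n_boot < 1) stop_vt("n_boot must be >= 1")
  n_boot <- as.integer(n_boot)
  validate_expression_matrix(x, min_samples = 2L)
  tree <- ward_linkage(correlation_distance(x), squared = squared)
  ref <- vapply(tree_clades(tree), paste, character(1), collapse = ",")
  hits <- numeric(length(ref))
  seeds <- derive_seeds(seed, n_boot)
  ng <- nrow(x)
  for (b in seq_len(n_boot)) {
    set.seed(seeds[b])
    xb <- x[sample.int(ng, ng, replace = TRUE), , drop = FALSE]
    rownames(xb) <- sprintf("r%d", seq_len(ng))  # resampled rows are anonymous
    tb <- ward_linkage(correlation_distance(xb), squared = squared)
    got <- vapply(tree_clades(tb), paste, character(1), collapse = ",")
    hits <- hits + (ref %in% got)
  }
  list(tree = tree, support = hits / n_boot, n_boot = n_boot, seed = seed)
}

#' Principal components of the samples
#'
#' Rows (genes) are mean-centered, then the samples are decomposed as
#' observations in gene space. Returns per-sample scores on the leading
#' components and the fraction of total centered variance each explains.
#'
#' @param x Expression matrix.
#' @param n_components Number of leading components, at most `min(dim(x))`.
#' @return List with `scores` (samples x components), `variance_fraction`,
#'   and `total_variance`.
#' @export
pca_first_components <- function(x, n_components = 2L) {
  validate_expression_matrix(x, min_samples = 2L)
  if (n_components > min(dim(x))) stop_vt("n_components exceeds min(dim(x)) = %d", min(dim(x)))
  xc <- x - rowMeans(x)
  pc <- stats::prcomp(t(xc), center = FALSE, scale. = FALSE)
  vars <- pc$sdev^2
  total <- sum(vars)
  idx <- seq_len(n_components)
  list(scores = pc$x[, idx, drop = FALSE],
       variance_fraction = vars[idx] / total,
       total_variance = total)
}

#' Write a dendrogram with supports as Newick
#'
#' Internal nodes are labeled with their bootstrap support (rounded
#' percentage) when given; branch lengths are derived from merge heights
#' (clamped at zero for height inversions).
#'
#' @param tree An `hclust` tree.
#' @param path Output path.
#' @param support Optional per-internal-node support in merge order.
#' @export
write_newick <- function(tree, path, support = NULL) {
  merge <- tree$merge
  n <- nrow(merge) + 1L
  h <- tree$height
  lab <- function(s) {
    if (is.null(support)) "" else format(round(100 * support[s], 1))
  }
  rec <- function(node, parent_h) {
    if (node < 0) {
      sprintf("%s:%g", tree$labels[-node], max(parent_h, 0))
    } else {
      bl <- max(parent_h - h[node], 0)
      sprintf("(%s,%s)%s:%g", rec(merge[node, 1L], h[node]), rec(merge[node, 2L], h[node]), lab(node), bl)
    }
  }
  top <- n - 1L
  txt <- sprintf("(%s,%s)%s;", rec(merge[top, 1L], h[top]), rec(merge[top, 2L], h[top]), lab(top))
  writeLines(txt, path)
  invisible(path)
}
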