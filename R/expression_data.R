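## Expression-matrix data model, file I/O, probe collapsing, variance
## filtering and row scaling. Matrices are plain numeric matrices with gene
## ids as rownames and sample ids as colnames; all values are assumed to be
## on the log2 scale and already normalized. Missing values are unsupported.

#' Validate an expression matrix
#'
#' Checks the invariants every statistical operation relies on: a numeric
#' matrix with unique gene (row) and sample (column) ids and no missing
#' entries.
#'
#' @param x Numeric matrix, genes in rows, samples in columns.
#' @param min_samples Minimum number of columns required (default 1).
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(x, min_samples = 1L) {
  if (!is.matrix(x) || !is.numeric(x)) stop_vt("expression matrix must be a numeric matrix")
  if (nrow(x) < 1L) stop_vt("expression matrix must contain at least 1 gene")
  if (ncol(x) < min_samples) stop_vt("expression matrix must contain at least %d sample(s)", min_samples)
  if (is.null(rownames(x)) || is.null(colnames(x))) stop_vt("expression matrix must carry gene and sample ids")
  if (anyDuplicated(rownames(x))) {
    dup <- unique(rownames(x)[duplicated(rownames(x))])
    stop_vt("duplicate gene id(s): %s", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (anyDuplicated(colnames(x))) {
    dup <- unique(colnames(x)[duplicated(colnames(x))])
    stop_vt("duplicate sample id(s): %s", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (anyNA(x)) stop_vt("expression matrix contains missing values (unsupported)")
  invisible(x)
}

#' Read an expression matrix from a tab-delimited file
#'
#' Expects a UTF-8 TSV whose header row holds sample ids (first cell
#' `gene_id`) and whose first column holds gene ids. Values must be numeric
#' log2 intensities with no missing entries.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop_vt("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop_vt("matrix file %s has an empty data section", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  ncols <- length(header)
  sample_ids <- header[-1L]
  if (length(sample_ids) < 1L) stop_vt("matrix file %s has no sample columns", path)
  body <- fields[-1L]
  widths <- lengths(body)
  if (any(widths != ncols)) {
    bad <- which(widths != ncols)[1L]
    stop_vt("ragged row %d in %s: %d fields, expected %d", bad + 1L, path, widths[bad], ncols)
  }
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(ncols - 1L))
  )
  ## vapply yields samples x genes; transpose to genes x samples
  m <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = ncols - 1L)
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop_vt("non-numeric or missing value at row %d (gene %s), column %d (sample %s) of %s",
            idx[1L], gene_ids[idx[1L]], idx[2L], sample_ids[idx[2L]], path)
  }
  dimnames(m) <- list(gene_ids, sample_ids)
  validate_expression_matrix(m)
  m
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]: round-tripping reproduces values to
#' full printed precision (values are written with 15 significant digits).
#'
#' @param x Expression matrix.
#' @param path Output path.
#' @export
write_expression_matrix <- function(x, path) {
  validate_expression_matrix(x)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1L, function(v) paste(format(v, digits = 15, trim = TRUE, scientific = FALSE), collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Read / write a sample annotation table
#'
#' CSV with one row per sample; the `sample_id` column is mandatory and must
#' be unique. Conventional columns are `tissue`
#' (`normal_vasculature`/`tumor_vasculature`), `mvd_class` (`high`/`low`),
#' `subtype` (`A`/`B`), `recurrence` (`yes`/`no`), `er_status`, `her2_status`,
#' `node_status` (`pos`/`neg`), `grade` and `tumor_size`; fields that do not
#' apply (for example subtype on normal samples) are `NA`.
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop_vt("file not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(tab)) stop_vt("annotation %s lacks a sample_id column", path)
  if (anyDuplicated(tab$sample_id)) stop_vt("duplicate sample_id in %s", path)
  tab
}

#' @rdname read_sample_table
#' @param tab Sample table to write.
#' @export
write_sample_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene set
#'
#' Either a plain list (one gene symbol per line) or a GMT file
#' (tab-delimited: name, description, members...). Plain files take their set
#' name from the file name.
#'
#' @param path Path to the gene-set file.
#' @return For plain files, a list with `name` and `members`; for GMT, a
#'   named list of such sets.
#' @param gmt Force GMT parsing; by default decided by the `.gmt` extension.
#' @export
read_gene_set <- function(path, gmt = grepl("\\.gmt$", path, ignore.case = TRUE)) {
  if (!file.exists(path)) stop_vt("file not found: %s", path)
  if (gmt) {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    sets <- lapply(lines, function(l) {
      f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
      if (length(f) < 3L) stop_vt("malformed GMT line: %s", substr(l, 1, 60))
      list(name = f[1L], members = unique(f[-(1:2)]))
    })
    names(sets) <- vapply(sets, `[[`, character(1), "name")
    sets
  } else {
    members <- readLines(path, encoding = "UTF-8")
    members <- unique(trimws(members[nzchar(trimws(members))]))
    if (length(members) == 0L) stop_vt("gene set %s is empty", path)
    list(name = tools::file_path_sans_ext(basename(path)), members = members)
  }
}

#' Interquartile range under the linear-interpolation convention
#'
#' Q3 minus Q1 with quantiles computed by linear interpolation between order
#' statistics at positions `1 + (n - 1) p` (R's default type-7 convention).
#' The strict `> 2` variable-gene filter is sensitive to this convention, so
#' it is pinned here rather than left to a caller.
#'
#' @param values Numeric vector, at least one value, no NAs.
#' @return The interquartile range (scalar).
#' @export
iqr <- function(values) {
  if (length(values) < 1L) stop_vt("iqr requires at least one value")
  if (anyNA(values)) stop_vt("iqr: missing values unsupported")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  q[2L] - q[1L]
}

row_iqrs <- function(x) {
  q <- matrixStats::rowQuantiles(x, probs = c(0.25, 0.75), type = 7L)
  unname(q[, 2L] - q[, 1L])
}

#' Collapse probes to genes by maximal interquartile range
#'
#' For genes represented by multiple probes, only the probe with the largest
#' IQR across all samples is retained. Exact IQR ties are broken by the
#' lexicographically smallest probe id so the result is deterministic.
#'
#' @param x Expression matrix with probe ids as rownames.
#' @param map Data frame with columns `probe_id` and `gene_symbol`
#'   (many probes to one symbol).
#' @return Expression matrix with one row per gene symbol.
#' @export
collapse_probes <- function(x, map) {
  validate_expression_matrix(x)
  if (!all(c("probe_id", "gene_symbol") %in% names(map)))
    stop_vt("probe map must have columns probe_id and gene_symbol")
  if (anyDuplicated(map$probe_id)) stop_vt("probe map assigns some probe more than one symbol")
  idx <- match(rownames(x), map$probe_id)
  if (anyNA(idx)) {
    missing <- rownames(x)[is.na(idx)]
    stop_vt("unmapped probe(s): %s", paste(utils::head(missing, 10), collapse = ", "))
  }
  symbol <- map$gene_symbol[idx]
  iq <- row_iqrs(x)
  ord <- order(symbol, -iq, rownames(x), method = "radix")
  keep <- ord[!duplicated(symbol[ord])]
  out <- x[keep, , drop = FALSE]
  rownames(out) <- symbol[keep]
  out
}

#' Filter genes by interquartile range
#'
#' Keeps exactly the rows whose IQR across samples is strictly greater than
#' `threshold`, preserving row order. This is the most-variable-gene filter
#' used ahead of class discovery.
#'
#' @param x Expression matrix.
#' @param threshold Non-negative IQR cutoff (strict inequality).
#' @return The filtered matrix.
#' @export
iqr_filter <- function(x, threshold) {
  validate_expression_matrix(x)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop_vt("threshold must be a single non-negative number")
  keep <- row_iqrs(x) > threshold
  if (!any(keep))
    stop_vt("iqr_filter removed every row at threshold %g; lower the threshold", threshold)
  x[keep, , drop = FALSE]
}

#' Z-score each gene row
#'
#' Subtracts the row mean and divides by the row sample standard deviation
#' (n - 1 denominator); constant rows become all zeros with a warning rather
#' than aborting (heatmap scaling should not kill a pipeline).
#'
#' @param x Expression matrix with at least 2 samples.
#' @return Matrix of the same shape with rows scaled.
#' @export
row_zscore <- function(x) {
  validate_expression_matrix(x, min_samples = 2L)
  mu <- rowMeans(x)
  sdv <- matrixStats::rowSds(x)
  const <- sdv == 0
  if (any(const)) {
    warning(sprintf("%d constant row(s) z-scored to zeros", sum(const)), call. = FALSE)
    sdv[const] <- 1
  }
  out <- (x - mu) / sdv
  out[const, ] <- 0
  out
}
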