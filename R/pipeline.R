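## End-to-end orchestration: collapse -> filter -> class discovery (all
## samples, then tumor-only) -> moderated DE tables -> marker and clinical
## analyses -> subtype-adjusted recurrence predictor. Every run writes its
## fully-resolved configuration next to the outputs so results are
## reproducible from the report directory alone.

#' Pipeline configuration
#'
#' Aggregates the analysis parameters. Defaults follow the published method
#' parameters: IQR filter threshold 2, 10,000 bootstrap iterations, 6-gene
#' predictor, FDR threshold 0.05.
#'
#' @param matrix Path to the expression TSV (or an in-memory matrix).
#' @param annotation Path to the sample CSV (or a data.frame).
#' @param probe_map Optional path to a probe map CSV (`probe_id`,
#'   `gene_symbol`) or a data.frame; when given, probes are collapsed first.
#' @param out_dir Output directory.
#' @param iqr_threshold Strict IQR cutoff for the variable-gene filter.
#' @param n_boot Bootstrap iterations for clade support.
#' @param k_predictor Genes per predictor fold.
#' @param fdr_threshold FDR significance threshold for reporting counts.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(matrix, annotation, out_dir, probe_map = NULL,
                            iqr_threshold = 2, n_boot = 10000L, k_predictor = 6L,
                            fdr_threshold = 0.05, seed = 1L) {
  if (iqr_threshold < 0 || n_boot < 1 || k_predictor < 1 || fdr_threshold < 0)
    stop_vt("pipeline thresholds must be non-negative (and counts >= 1)")
  structure(list(matrix = matrix, annotation = annotation, probe_map = probe_map,
                 out_dir = out_dir, iqr_threshold = iqr_threshold,
                 n_boot = as.integer(n_boot), k_predictor = as.integer(k_predictor),
                 fdr_threshold = fdr_threshold, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; `overrides` (typically
#' parsed CLI flags) take precedence over file values.
#'
#' @param path YAML file path.
#' @param overrides Named list of values overriding the file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

pipeline_log <- function(con, stage, ...) {
  msg <- sprintf("[%s] %s", stage, sprintf(...))
  writeLines(msg, con)
  message(msg)
}

#' Run the full vasculature analysis pipeline
#'
#' Executes, in order: probe collapsing (if a probe map is supplied), the
#' strict IQR variable-gene filter, class discovery with bootstrap clade
#' support over all samples, tumor-only clustering cut at k = 2, moderated
#' differential expression for the tumor-vs-normal, B-vs-A and
#' high-vs-low-MVD contrasts, pericyte-marker scoring, clinical-covariate
#' association, and the subtype-adjusted nested-LOOCV recurrence predictor.
#' All outputs, a structured log, and the resolved configuration are
#' written under `config$out_dir`. Identical inputs and configuration give
#' identical outputs.
#'
#' Subtype labels for the DE contrast and the predictor come from the
#' annotation's `subtype` column when present, otherwise from the tumor-only
#' clustering (cluster ids mapped to `A`/`B` with `B` the cluster with the
#' higher pericyte-marker score).
#'
#' @param config A [pipeline_config()].
#' @param markers Pericyte marker symbols used for the marker analysis.
#' @return A list with every stage's result (invisibly also written to
#'   disk).
#' @export
run_full_pipeline <- function(config,
                              markers = c("ACTA2", "PDGFRB", "RGS5", "LAMB1")) {
  if (!inherits(config, "pipeline_config")) stop_vt("config must be a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(config$out_dir, "pipeline.log"), "wt")
  on.exit(close(logcon))

  x <- if (is.character(config$matrix)) read_expression_matrix(config$matrix) else config$matrix
  ann <- if (is.character(config$annotation)) read_sample_table(config$annotation) else config$annotation
  orphans <- c(setdiff(colnames(x), ann$sample_id), setdiff(ann$sample_id, colnames(x)))
  if (length(orphans))
    stop_vt("sample ids disagree between matrix and annotation: %s",
            paste(utils::head(orphans, 10), collapse = ", "))
  ann <- ann[match(colnames(x), ann$sample_id), ]
  pipeline_log(logcon, "load", "matrix %d genes x %d samples; seed %d",
               nrow(x), ncol(x), config$seed)

  if (!is.null(config$probe_map)) {
    map <- if (is.character(config$probe_map)) utils::read.csv(config$probe_map, stringsAsFactors = FALSE) else config$probe_map
    x <- collapse_probes(x, map)
    pipeline_log(logcon, "collapse", "probes collapsed to %d genes", nrow(x))
  }

  xf <- iqr_filter(x, config$iqr_threshold)
  pipeline_log(logcon, "filter", "IQR > %g keeps %d of %d genes",
               config$iqr_threshold, nrow(xf), nrow(x))
  write_expression_matrix(xf, file.path(config$out_dir, "filtered_matrix.tsv"))

  boot_all <- bootstrap_support(xf, n_boot = config$n_boot, seed = config$seed)
  write_newick(boot_all$tree, file.path(config$out_dir, "tree_all_samples.nwk"), boot_all$support)
  cut_all <- cut_k(boot_all$tree, 2L)
  pipeline_log(logcon, "cluster", "all-sample tree: median clade support %.3f",
               stats::median(boot_all$support))

  is_tumor <- ann$tissue == "tumor_vasculature"
  xt <- xf[, is_tumor, drop = FALSE]
  boot_tum <- bootstrap_support(xt, n_boot = config$n_boot, seed = config$seed + 1L)
  write_newick(boot_tum$tree, file.path(config$out_dir, "tree_tumor_samples.nwk"), boot_tum$support)
  cl_tumor <- cut_k(boot_tum$tree, 2L)
  pipeline_log(logcon, "cluster", "tumor-only cut at k=2: sizes %s",
               paste(base::table(cl_tumor), collapse = "/"))

  subtype <- ann$subtype
  if (all(is.na(subtype[is_tumor]))) {
    ms_t <- tryCatch(marker_score(x[, is_tumor, drop = FALSE], markers), error = function(e) NULL)
    b_cluster <- if (is.null(ms_t)) 2L else which.max(vapply(1:2, function(cl) mean(ms_t[cl_tumor == cl]), numeric(1)))
    subtype[is_tumor] <- ifelse(cl_tumor == b_cluster, "B", "A")
    pipeline_log(logcon, "cluster", "subtype labels derived from clustering (B = cluster %d)", b_cluster)
  }
  labels_out <- data.frame(sample_id = ann$sample_id,
                           cluster_all = cut_all[ann$sample_id],
                           cluster_tumor = NA_integer_, subtype = subtype)
  labels_out$cluster_tumor[is_tumor] <- cl_tumor[ann$sample_id[is_tumor]]
  utils::write.csv(labels_out, file.path(config$out_dir, "cluster_labels.csv"), row.names = FALSE)

  de_contrast <- function(cols, groups, name) {
    tab <- moderated_de(x[, cols, drop = FALSE], groups)
    n_sig <- sum(tab$q <= config$fdr_threshold)
    pipeline_log(logcon, "de", "%s: %d genes at q <= %g", name, n_sig, config$fdr_threshold)
    utils::write.table(tab, file.path(config$out_dir, paste0("de_", name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tab
  }
  de_tumor <- de_contrast(seq_len(ncol(x)),
                          ifelse(is_tumor, "tumor", "normal"), "tumor_vs_normal")
  de_subtype <- de_contrast(which(is_tumor), subtype[is_tumor], "B_vs_A")
  de_mvd <- if (length(unique(stats::na.omit(ann$mvd_class[is_tumor]))) == 2L) {
    keep <- is_tumor & !is.na(ann$mvd_class)
    de_contrast(which(keep), ann$mvd_class[keep], "high_vs_low_mvd")
  } else NULL

  ms <- tryCatch(marker_score(x, markers), error = function(e) {
    pipeline_log(logcon, "markers", "skipped: %s", conditionMessage(e)); NULL
  })
  if (!is.null(ms)) {
    utils::write.csv(data.frame(sample_id = names(ms), marker_score = as.numeric(ms)),
                     file.path(config$out_dir, "marker_scores.csv"), row.names = FALSE)
  }

  clin <- clinical_association(ifelse(is_tumor, subtype, NA), ann)
  utils::write.csv(clin, file.path(config$out_dir, "clinical_association.csv"), row.names = FALSE)
  pipeline_log(logcon, "clinical", "%d covariates tested", nrow(clin))

  cv <- loocv_run(x[, is_tumor, drop = FALSE], subtype[is_tumor],
                  ann$recurrence[is_tumor], k = config$k_predictor)
  pipeline_log(logcon, "predict", "nested LOOCV accuracy %.3f (Fisher p = %.4g)",
               cv$accuracy, cv$fisher_p)
  utils::write.csv(cv$folds, file.path(config$out_dir, "predictor_folds.csv"), row.names = FALSE)
  report <- list(accuracy = cv$accuracy, fisher_p = cv$fisher_p, k = cv$k,
                 confusion = as.data.frame(cv$confusion),
                 selected = cv$selected,
                 n_significant = list(
                   tumor_vs_normal = sum(de_tumor$q <= config$fdr_threshold),
                   B_vs_A = sum(de_subtype$q <= config$fdr_threshold),
                   high_vs_low_mvd = if (is.null(de_mvd)) NA else sum(de_mvd$q <= config$fdr_threshold)))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")

  resolved <- unclass(config)
  resolved$matrix <- if (is.character(config$matrix)) config$matrix else "<in-memory>"
  resolved$annotation <- if (is.character(config$annotation)) config$annotation else "<in-memory>"
  resolved$probe_map <- if (is.null(config$probe_map)) NULL else
    if (is.character(config$probe_map)) config$probe_map else "<in-memory>"
  yaml::write_yaml(resolved, file.path(config$out_dir, "config_resolved.yaml"))

  invisible(list(filtered = xf, tree_all = boot_all, tree_tumor = boot_tum,
                 subtype = subtype, de_tumor = de_tumor, de_subtype = de_subtype,
                 de_mvd = de_mvd, marker_scores = ms, clinical = clin, cv = cv))
}

## ---- command-line interface -------------------------------------------

cli_parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop_vt("unexpected argument: %s", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      flags[[key]] <- TRUE; i <- i + 1L
    } else {
      flags[[key]] <- args[i + 1L]; i <- i + 2L
    }
  }
  flags
}

cli_num <- function(flags, key, default) as.numeric(if (is.null(flags[[key]])) default else flags[[key]])

#' Command-line entry point
#'
#' Dispatches the `vasculotype` subcommands: `simulate`, `cluster`, `de`,
#' `markers`, `overlap`, `induce`, `predict`, `run`. Flags are `--key value`
#' pairs; see the shipped executable `exec/vasculotype` for usage.
#'
#' @param args Character vector of command-line arguments (subcommand
#'   first); defaults to [base::commandArgs()].
#' @return Invisibly, the subcommand's result.
#' @export
vasculotype_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) stop_vt("usage: vasculotype <simulate|cluster|de|markers|overlap|induce|predict|run> [--flags]")
  cmd <- args[1L]
  flags <- cli_parse_flags(args[-1L])
  need <- function(key) {
    if (is.null(flags[[key]])) stop_vt("missing required flag --%s for %s", key, cmd)
    flags[[key]]
  }
  res <- switch(cmd,
    simulate = {
      cfg_args <- if (!is.null(flags$config)) yaml::read_yaml(flags$config) else list()
      if (!is.null(flags$seed)) cfg_args$seed <- as.integer(cli_num(flags, "seed", 1))
      cohort <- generate_cohort(do.call(synth_config, cfg_args))
      write_cohort(cohort, need("out"))
      message(sprintf("wrote cohort (%d genes x %d samples) to %s",
                      nrow(cohort$matrix), ncol(cohort$matrix), flags$out))
      cohort
    },
    cluster = {
      x <- read_expression_matrix(need("matrix"))
      thr <- cli_num(flags, "iqr-threshold", 2)
      xf <- iqr_filter(x, thr)
      bs <- bootstrap_support(xf, n_boot = cli_num(flags, "boot", 10000),
                              seed = as.integer(cli_num(flags, "seed", 1)))
      out <- need("out"); dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write_newick(bs$tree, file.path(out, "tree.nwk"), bs$support)
      cl <- cut_k(bs$tree, as.integer(cli_num(flags, "k", 2)))
      utils::write.csv(data.frame(sample_id = names(cl), cluster = as.integer(cl)),
                       file.path(out, "clusters.csv"), row.names = FALSE)
      bs
    },
    de = {
      x <- read_expression_matrix(need("matrix"))
      ann <- read_sample_table(need("annot"))
      ann <- ann[match(colnames(x), ann$sample_id), ]
      contrast <- need("contrast")
      sel <- switch(contrast,
        tumor_vs_normal = list(cols = seq_len(ncol(x)),
                               groups = ifelse(ann$tissue == "tumor_vasculature", "tumor", "normal")),
        B_vs_A = {
          keep <- !is.na(ann$subtype); list(cols = which(keep), groups = ann$subtype[keep])
        },
        high_vs_low_mvd = {
          keep <- !is.na(ann$mvd_class); list(cols = which(keep), groups = ann$mvd_class[keep])
        },
        stop_vt("unknown contrast %s", contrast))
      tab <- moderated_de(x[, sel$cols, drop = FALSE], sel$groups)
      utils::write.table(tab, need("out"), sep = "\t", quote = FALSE, row.names = FALSE)
      tab
    },
    markers = {
      x <- read_expression_matrix(need("matrix"))
      genes <- strsplit(need("genes"), ",", fixed = TRUE)[[1L]]
      ms <- marker_score(x, genes)
      out <- need("out"); dir.create(out, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(data.frame(sample_id = names(ms), marker_score = as.numeric(ms)),
                       file.path(out, "marker_scores.csv"), row.names = FALSE)
      ms
    },
    overlap = {
      res <- signature_overlap(read_gene_set(need("a")), read_gene_set(need("b")),
                               read_gene_set(need("universe")))
      message(sprintf("overlap %d (expected %.2f), one-sided Fisher p = %.4g",
                      res$overlap, res$expected, res$p))
      res
    },
    induce = {
      x <- read_expression_matrix(need("matrix"))
      ann <- read_sample_table(need("annot"))
      ann <- ann[match(colnames(x), ann$sample_id), ]
      lab_col <- if (is.null(flags$labels)) "subtype" else flags$labels
      keep <- !is.na(ann[[lab_col]])
      res <- induced_segregation(x[, keep, drop = FALSE], read_gene_set(need("signature")),
                                 ann[[lab_col]][keep])
      message(sprintf("induced segregation: ARI %.3f, %d misassigned", res$ari, res$misassigned))
      res
    },
    predict = {
      x <- read_expression_matrix(need("matrix"))
      ann <- read_sample_table(need("annot"))
      ann <- ann[match(colnames(x), ann$sample_id), ]
      keep <- ann$tissue == "tumor_vasculature"
      xt <- x[, keep, drop = FALSE]
      cv <- loocv_run(xt, ann$subtype[keep], ann$recurrence[keep],
                      k = as.integer(cli_num(flags, "k", 6)),
                      adjust = is.null(flags[["no-adjust"]]),
                      strict_subtype = identical(flags[["strict-subtype"]], "true"))
      out <- need("out"); dir.create(out, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(cv$folds, file.path(out, "predictor_folds.csv"), row.names = FALSE)
      jsonlite::write_json(list(accuracy = cv$accuracy, fisher_p = cv$fisher_p, k = cv$k,
                                confusion = as.data.frame(cv$confusion)),
                           file.path(out, "cv_report.json"), auto_unbox = TRUE,
                           digits = NA, dataframe = "columns")
      if (!is.null(flags$scan)) {
        rng <- as.integer(strsplit(flags$scan, ":", fixed = TRUE)[[1L]])
        sc <- size_scan(xt, ann$subtype[keep], ann$recurrence[keep], k_range = rng[1L]:rng[2L])
        utils::write.csv(sc$accuracies, file.path(out, "size_scan.csv"), row.names = FALSE)
      }
      print(cv)
      cv
    },
    run = {
      cfg <- if (!is.null(flags$config))
        read_pipeline_config(flags$config, overrides = flags[setdiff(names(flags), "config")])
      else pipeline_config(matrix = need("matrix"), annotation = need("annot"),
                           out_dir = need("out"),
                           iqr_threshold = cli_num(flags, "iqr-threshold", 2),
                           n_boot = cli_num(flags, "boot", 10000),
                           k_predictor = cli_num(flags, "k", 6),
                           fdr_threshold = cli_num(flags, "fdr", 0.05),
                           seed = as.integer(cli_num(flags, "seed", 1)))
      run_full_pipeline(cfg)
    },
    stop_vt("unknown subcommand: %s", cmd))
  invisible(res)
}
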