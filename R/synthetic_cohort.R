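## Synthetic vasculature-cohort generator. Emulates the statistical design
## the downstream analyses assume: 15 normal-vasculature and 17
## tumor-vasculature samples, two planted tumor subtypes (9 "A" and 8 "B")
## separated by a large expression effect, a pericyte-marker block elevated
## in subtype B, microvessel-density class correlated with subtype, and a
## small recurrence effect (5 recurrent vs 12 nonrecurrent) whose carrier
## genes also vary with subtype so that the subtype signal masks the outcome
## signal -- the regime the subtype-adjusted predictor is designed to defeat.

#' Configuration for the synthetic cohort generator
#'
#' Default counts mirror the study design the package targets (15 normal,
#' 9 + 8 tumor samples, 5 recurrent of 17). Noise is Gaussian on the log2
#' scale with gene-specific variances drawn from a scaled inverse chi-square
#' prior with `var_prior_df` (d0) degrees of freedom and scale
#' `var_prior_scale` (s0^2), matching the hierarchical model behind the
#' moderated t-statistic so that estimator-recovery tests are meaningful.
#'
#' Subtype effects are planted symmetrically (A shifted by -e/2, B by +e/2)
#' so that the tumor-vs-normal contrast stays clean of subtype genes;
#' recurrence-effect genes additionally carry a full subtype shift, which is
#' what makes the outcome signal masked until the subtype adjustment is
#' applied.
#'
#' @param n_genes Number of genes.
#' @param n_normal,n_tumor_a,n_tumor_b Sample counts per group.
#' @param n_recurrent Number of recurrent tumor samples.
#' @param n_de_tumor Genes shifted in all tumor samples vs normal (default
#'   8\% of `n_genes`, i.e. 400 at the default size).
#' @param n_de_subtype Genes shifted between subtypes B and A, including the
#'   pericyte markers (default 12\% of `n_genes`, 600).
#' @param n_de_recur Genes shifted in recurrent tumor samples, which also
#'   carry a subtype shift -- see Details (default 1.2\% of `n_genes`, 60).
#' @param n_pericyte_markers Subset of the subtype genes, elevated in B
#'   (default 0.5\% of `n_genes`, 25).
#' @param effect_tumor,effect_subtype,effect_recur Planted effect sizes in
#'   log2 units.
#' @param baseline_mean,baseline_sd Per-gene baseline distribution (log2).
#' @param var_prior_df,var_prior_scale True d0 and s0^2 of the variance prior.
#' @param mvd_concordance Probability that a tumor sample's MVD class agrees
#'   with its subtype (B -> low, A -> high).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A validated `synth_config` object (a named list).
#' @export
synth_config <- function(n_genes = 5000L,
                         n_normal = 15L,
                         n_tumor_a = 9L,
                         n_tumor_b = 8L,
                         n_recurrent = 5L,
                         n_de_tumor = round(0.08 * n_genes),
                         n_de_subtype = round(0.12 * n_genes),
                         n_de_recur = round(0.012 * n_genes),
                         n_pericyte_markers = round(0.005 * n_genes),
                         effect_tumor = 2,
                         effect_subtype = 2,
                         effect_recur = 0.8,
                         baseline_mean = 8,
                         baseline_sd = 1.5,
                         var_prior_df = 4,
                         var_prior_scale = 0.1,
                         mvd_concordance = 0.9,
                         seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_normal = as.integer(n_normal),
    n_tumor_a = as.integer(n_tumor_a), n_tumor_b = as.integer(n_tumor_b),
    n_recurrent = as.integer(n_recurrent), n_de_tumor = as.integer(n_de_tumor),
    n_de_subtype = as.integer(n_de_subtype), n_de_recur = as.integer(n_de_recur),
    n_pericyte_markers = as.integer(n_pericyte_markers),
    effect_tumor = effect_tumor, effect_subtype = effect_subtype,
    effect_recur = effect_recur, baseline_mean = baseline_mean,
    baseline_sd = baseline_sd, var_prior_df = var_prior_df,
    var_prior_scale = var_prior_scale, mvd_concordance = mvd_concordance,
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  counts <- c("n_genes", "n_normal", "n_tumor_a", "n_tumor_b", "n_recurrent",
              "n_de_tumor", "n_de_subtype", "n_de_recur", "n_pericyte_markers")
  for (f in counts) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 0) stop_vt("invalid config field %s: must be a count >= 0", f)
  }
  n_tumor <- cfg$n_tumor_a + cfg$n_tumor_b
  if (cfg$n_genes < 1L) stop_vt("invalid config field n_genes: at least 1 gene required")
  if (cfg$n_recurrent > n_tumor) stop_vt("invalid config field n_recurrent: exceeds tumor sample count")
  if (cfg$n_pericyte_markers > cfg$n_de_subtype)
    stop_vt("invalid config field n_pericyte_markers: exceeds n_de_subtype")
  if (cfg$n_de_recur > cfg$n_genes) stop_vt("invalid config field n_de_recur: exceeds n_genes")
  if (cfg$n_de_tumor + cfg$n_de_subtype + cfg$n_de_recur > cfg$n_genes)
    stop_vt("invalid config: planted gene blocks exceed n_genes")
  for (f in c("effect_tumor", "effect_subtype", "effect_recur", "baseline_sd")) {
    if (cfg[[f]] < 0) stop_vt("invalid config field %s: must be >= 0", f)
  }
  if (cfg$var_prior_df <= 0) stop_vt("invalid config field var_prior_df: must be > 0")
  if (cfg$var_prior_scale <= 0) stop_vt("invalid config field var_prior_scale: must be > 0")
  if (cfg$mvd_concordance < 0 || cfg$mvd_concordance > 1)
    stop_vt("invalid config field mvd_concordance: must be a probability")
  invisible(cfg)
}

#' Generate a synthetic vasculature cohort
#'
#' Produces an expression matrix (genes x samples, log2 scale), a sample
#' annotation table, and a ground-truth object recording each gene's role
#' and planted shifts and each gene's true noise variance.
#'
#' Gene roles occupy consecutive blocks: `tumor_de` genes are shifted by
#' +/- `effect_tumor` in every tumor sample (half up, half down);
#' `subtype_de` genes are shifted by -s/2 in subtype A and +s/2 in subtype B
#' with s = +/- `effect_subtype` (the `pericyte_marker` subset always has
#' s > 0, i.e. is elevated in B); `recur_de` genes carry both a subtype shift
#' of the same form and an additional +/- `effect_recur` shift in recurrent
#' tumor samples. All remaining genes are `null` with exactly zero shift.
#'
#' @param config A [synth_config()] object.
#' @return A list of class `vasc_cohort` with elements `matrix` (expression),
#'   `samples` (annotation data.frame) and `truth` (gene roles, per-sample
#'   assignments, planted shift columns, true variances).
#' @export
generate_cohort <- function(config = synth_config()) {
  validate_synth_config(config)
  cfg <- config
  set.seed(cfg$seed)
  n_tumor <- cfg$n_tumor_a + cfg$n_tumor_b
  n_samp <- cfg$n_normal + n_tumor

  normal_ids <- sprintf("N%02d", seq_len(cfg$n_normal))
  tumor_ids <- sprintf("T%02d", seq_len(n_tumor))
  sample_ids <- c(normal_ids, tumor_ids)
  tissue <- rep(c("normal_vasculature", "tumor_vasculature"), c(cfg$n_normal, n_tumor))

  ## subtype assignment: random placement of the A/B split over tumor slots
  subtype_t <- rep(NA_character_, n_tumor)
  subtype_t[sample(n_tumor, cfg$n_tumor_b)] <- "B"
  subtype_t[is.na(subtype_t)] <- "A"
  recur_t <- rep("no", n_tumor)
  if (cfg$n_recurrent > 0) recur_t[sample(n_tumor, cfg$n_recurrent)] <- "yes"
  ## MVD class: B tumors are the more mature, lower-density vasculature
  concord <- stats::runif(n_tumor) < cfg$mvd_concordance
  mvd_t <- ifelse(subtype_t == "B", ifelse(concord, "low", "high"),
                  ifelse(concord, "high", "low"))
  ## clinical covariates independent of subtype, except tumor size which is
  ## modestly larger in subtype B (the subtypes are size-associated)
  er_t <- ifelse(stats::runif(n_tumor) < 0.6, "pos", "neg")
  her2_t <- ifelse(stats::runif(n_tumor) < 0.25, "pos", "neg")
  node_t <- ifelse(stats::runif(n_tumor) < 0.4, "pos", "neg")
  grade_t <- sample(1:3, n_tumor, replace = TRUE)
  size_t <- pmax(0.5, stats::rnorm(n_tumor, mean = ifelse(subtype_t == "B", 3.0, 2.2), sd = 0.6))

  samples <- data.frame(
    sample_id = sample_ids,
    tissue = tissue,
    mvd_class = c(rep(NA_character_, cfg$n_normal), mvd_t),
    subtype = c(rep(NA_character_, cfg$n_normal), subtype_t),
    recurrence = c(rep(NA_character_, cfg$n_normal), recur_t),
    er_status = c(rep(NA_character_, cfg$n_normal), er_t),
    her2_status = c(rep(NA_character_, cfg$n_normal), her2_t),
    node_status = c(rep(NA_character_, cfg$n_normal), node_t),
    grade = c(rep(NA_integer_, cfg$n_normal), grade_t),
    tumor_size = c(rep(NA_real_, cfg$n_normal), round(size_t, 2)),
    stringsAsFactors = FALSE
  )

  ## gene roles in consecutive blocks
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  role <- rep("null", cfg$n_genes)
  i_tumor <- seq_len(cfg$n_de_tumor)
  i_subtype <- cfg$n_de_tumor + seq_len(cfg$n_de_subtype)
  i_pericyte <- utils::head(i_subtype, cfg$n_pericyte_markers)
  i_recur <- cfg$n_de_tumor + cfg$n_de_subtype + seq_len(cfg$n_de_recur)
  role[i_tumor] <- "tumor_de"
  role[i_subtype] <- "subtype_de"
  role[i_pericyte] <- "pericyte_marker"
  role[i_recur] <- "recur_de"

  signs_half <- function(n) {
    if (n == 0) return(numeric(0))
    s <- rep(c(1, -1), length.out = n)
    s
  }
  shift_tumor <- numeric(cfg$n_genes)
  shift_tumor[i_tumor] <- signs_half(cfg$n_de_tumor) * cfg$effect_tumor
  shift_subtype <- numeric(cfg$n_genes)  # B minus A difference
  shift_subtype[i_pericyte] <- cfg$effect_subtype
  i_sub_rest <- setdiff(i_subtype, i_pericyte)
  shift_subtype[i_sub_rest] <- signs_half(length(i_sub_rest)) * cfg$effect_subtype
  shift_subtype[i_recur] <- signs_half(cfg$n_de_recur) * cfg$effect_subtype
  shift_recur <- numeric(cfg$n_genes)
  ## period-4 alternation keeps recurrence signs balanced and uncorrelated
  ## with the period-2 subtype signs on the same genes
  shift_recur[i_recur] <- rep(c(1, -1, -1, 1), length.out = cfg$n_de_recur) * cfg$effect_recur

  baseline <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
  true_var <- cfg$var_prior_df * cfg$var_prior_scale / stats::rchisq(cfg$n_genes, df = cfg$var_prior_df)

  is_tumor_s <- tissue == "tumor_vasculature"
  subtype_s <- samples$subtype
  recur_s <- samples$recurrence
  ## per-sample multipliers for each shift column
  m_tumor <- as.numeric(is_tumor_s)
  m_subtype <- ifelse(!is_tumor_s, 0, ifelse(subtype_s == "B", 0.5, -0.5))
  m_recur <- as.numeric(is_tumor_s & !is.na(recur_s) & recur_s == "yes")

  mean_mat <- baseline +
    outer(shift_tumor, m_tumor) +
    outer(shift_subtype, m_subtype) +
    outer(shift_recur, m_recur)
  noise <- matrix(stats::rnorm(cfg$n_genes * n_samp, sd = sqrt(true_var)),
                  nrow = cfg$n_genes, ncol = n_samp)
  x <- mean_mat + noise
  dimnames(x) <- list(gene_ids, sample_ids)

  truth <- list(
    gene_roles = data.frame(
      gene_id = gene_ids, role = role,
      shift_tumor = shift_tumor, shift_subtype = shift_subtype,
      shift_recur = shift_recur, true_variance = true_var,
      stringsAsFactors = FALSE
    ),
    sample_labels = samples[, c("sample_id", "tissue", "subtype", "recurrence", "mvd_class")],
    config = cfg
  )
  structure(list(matrix = x, samples = samples, truth = truth), class = "vasc_cohort")
}

#' Permute recurrence labels among tumor samples
#'
#' Supports permutation-null experiments: the recurrence column is permuted
#' among tumor samples only; every other field is untouched.
#'
#' @param table A sample annotation data.frame with `tissue` and `recurrence`.
#' @param seed Integer seed.
#' @return The table with permuted recurrence labels.
#' @export
permute_outcome <- function(table, seed) {
  if (!"recurrence" %in% names(table)) stop_vt("sample table lacks a recurrence column")
  is_tumor <- table$tissue == "tumor_vasculature"
  if (!any(is_tumor)) stop_vt("no tumor samples to permute")
  set.seed(as.integer(seed))
  idx <- which(is_tumor)
  table$recurrence[idx] <- table$recurrence[sample(idx)]
  table
}

#' Write a generated cohort to disk
#'
#' Writes the expression matrix as TSV, the annotation as CSV, and the
#' ground truth as a JSON sidecar.
#'
#' @param cohort A `vasc_cohort` object.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "vasc_cohort")) stop_vt("not a vasc_cohort object")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(cohort$matrix, file.path(dir, "expression.tsv"))
  write_sample_table(cohort$samples, file.path(dir, "samples.csv"))
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
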