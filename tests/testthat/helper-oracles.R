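## Independent oracles used across tests. These deliberately take different
## computational routes from the package implementations they check.

## Full-enumeration Wilcoxon rank-sum p: enumerate every assignment of group
## sizes over the pooled sample and tabulate the rank-sum of group 1.
enum_wilcoxon_p <- function(x, y, alternative = "two.sided") {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  W_obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(length(pooled), n1)
  W_all <- apply(sets, 2L, function(idx) sum(r[idx]))
  switch(alternative,
    two.sided = min(1, 2 * min(mean(W_all <= W_obs), mean(W_all >= W_obs))),
    greater = mean(W_all >= W_obs),
    less = mean(W_all <= W_obs))
}

## Hypergeometric enumeration of the Fisher 2x2 p via lchoose (no dhyper):
## probability of table with cell a given margins, summed by the
## probability-mass rule.
enum_fisher_p <- function(a, b, c, d, alternative = "two.sided") {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(N, c1)
  p <- exp(logp)
  obs <- p[match(a, support)]
  switch(alternative,
    two.sided = sum(p[p <= obs * (1 + 1e-7)]),
    greater = sum(p[support >= a]),
    less = sum(p[support <= a]))
}

## Small labeled random expression matrix for structural tests.
random_matrix <- function(n_genes, n_samples, seed = 1, sd = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples, sd = sd), n_genes, n_samples,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples))))
}

## Memoized default synthetic cohort shared by tests (seed fixed a priori).
.cohort_cache <- new.env(parent = emptyenv())
default_cohort <- function(seed = 101) {
  key <- paste0("s", seed)
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- generate_cohort(synth_config(seed = seed))
  .cohort_cache[[key]]
}

tumor_slice <- function(cohort) {
  tum <- cohort$samples$tissue == "tumor_vasculature"
  list(x = cohort$matrix[, tum, drop = FALSE],
       subtype = cohort$samples$subtype[tum],
       recurrence = cohort$samples$recurrence[tum],
       mvd = cohort$samples$mvd_class[tum],
       ann = cohort$samples[tum, ])
}
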