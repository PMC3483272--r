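# Normalize a genotype vector to logical "carries notA".
as_notA <- function(genotype, n = NULL) {
  g <- if (is.logical(genotype)) genotype
  else if (is.numeric(genotype)) {
    if (!all(genotype %in% c(0, 1))) stop("numeric genotypes must be 0/1 (1 = notA)")
    genotype == 1
  } else {
    genotype <- as.character(genotype)
    if (!all(genotype %in% c("A", "notA")))
      stop("genotype labels must be 'A' or 'notA'")
    genotype == "notA"
  }
  if (anyNA(g)) stop("genotype must be defined for every subject")
  if (!is.null(n) && length(g) != n)
    stop("genotype length does not match cohort size")
  g
}

#' Fisher exact association test on a (possibly weighted) cohort
#'
#' Builds the weighted phenotype-by-genotype 2x2 table (cells = summed subject
#' weights), rounds the cells to the nearest integer, and applies the
#' two-sided Fisher exact test. On a unit-weight cohort this is the ordinary
#' Fisher test of the count table; on a homogenized cohort the knocked-down
#' subjects contribute only their reduced weight.
#'
#' @param genotype Per-subject genotype: logical (TRUE = carries not-A),
#'   0/1 numeric, or `"A"`/`"notA"` labels.
#' @param cohort A [cohort()].
#' @param genotype_id Optional identifier carried into the result.
#' @param method Method label carried into the result.
#' @return One-row data frame: `genotype_id`, `method`, `effect` (Haldane
#'   log-OR of the rounded table), `p_value`.
#' @export
fisher_assoc <- function(genotype, cohort, genotype_id = NA_character_,
                         method = "fisher") {
  notA <- as_notA(genotype, length(cohort$ids))
  dis <- cohort$phenotype == "diseased"
  w <- cohort$weights
  tbl <- round_weighted_table(weighted_table(
    sum(w[dis & !notA]), sum(w[dis & notA]),
    sum(w[!dis & !notA]), sum(w[!dis & notA])))
  data.frame(genotype_id = genotype_id, method = method,
             effect = log(odds_ratio(tbl, haldane = TRUE)),
             p_value = fisher_exact_p(tbl), stringsAsFactors = FALSE)
}

#' Logistic-regression association test with PC covariates
#'
#' Fits `phenotype ~ genotype + PC1 + ... + PCn` by maximum likelihood and
#' reports the Wald test of the genotype coefficient (not-A coded 1). With
#' `use_weights = TRUE` the cohort weights enter as per-observation frequency
#' weights, so knocked-down subjects contribute a reduced share of the
#' likelihood. Perfect separation is reported at the boundary value with a
#' warning rather than an error.
#'
#' @inheritParams fisher_assoc
#' @param n_pcs Number of leading PC columns of the cohort coordinates to use
#'   as covariates.
#' @param use_weights Use the cohort weights in the fit.
#' @return One-row data frame: `genotype_id`, `method`, `effect` (genotype
#'   log-odds coefficient), `p_value`.
#' @export
logistic_pc_assoc <- function(genotype, cohort, n_pcs = 3, use_weights = FALSE,
                              genotype_id = NA_character_) {
  notA <- as_notA(genotype, length(cohort$ids))
  if (n_pcs < 0 || n_pcs > ncol(cohort$coords))
    stop("n_pcs exceeds the number of PC columns in the cohort")
  if (length(unique(cohort$phenotype)) < 2L)
    stop("both phenotypes must be present")
  if (length(unique(notA)) < 2L)
    stop("both genotype labels must be present")
  df <- data.frame(y = as.integer(cohort$phenotype == "diseased"),
                   g = as.numeric(notA))
  if (n_pcs > 0) df <- cbind(df, cohort$coords[, seq_len(n_pcs), drop = FALSE])
  w <- if (use_weights) cohort$weights else rep(1, nrow(df))
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., family = stats::binomial(), data = df, weights = w),
    warning = function(cnd) {
      msg <- conditionMessage(cnd)
      if (grepl("non-integer #successes", msg)) {
        invokeRestart("muffleWarning")      # expected with fractional weights
      } else if (grepl("fitted probabilities numerically 0 or 1", msg) ||
                 grepl("algorithm did not converge", msg)) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  cf <- summary(fit)$coefficients
  if (any(is.na(stats::coef(fit))) || !("g" %in% rownames(cf)))
    stop("rank-deficient design: genotype term is aliased with a covariate")
  if (any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8))
    separated <- TRUE                     # boundary fit: separation signature
  if (separated)
    warning("possible perfect separation; p-value reported at the boundary")
  data.frame(genotype_id = genotype_id,
             method = if (use_weights) "logistic_pc_weighted" else "logistic_pc",
             effect = cf["g", "Estimate"],
             p_value = min(max(cf["g", "Pr(>|z|)"], .Machine$double.xmin), 1),
             stringsAsFactors = FALSE)
}

.pvals <- function(x) {
  if (is.data.frame(x)) x <- x$p_value
  x <- as.numeric(x)
  if (length(x) == 0L || anyNA(x)) stop("p-value list must be nonempty and complete")
  x
}

#' ROC curve over p-value significance thresholds
#'
#' Sweeps the significance threshold over all observed p-values; at each
#' threshold TPR is the fraction of positive-class results called significant
#' (p <= threshold) and FPR the same for the negative class. The curve starts
#' at (0, 0), ends at (1, 1), and the AUC is the trapezoid area.
#'
#' @param results_positive,results_negative Numeric p-value vectors, or data
#'   frames with a `p_value` column (e.g. rows of [fisher_assoc()] output),
#'   for genotypes simulated with and without a true phenotype association.
#' @return A list: `points` (data frame `fpr`, `tpr`) and `auc`.
#' @export
roc_points <- function(results_positive, results_negative) {
  pos <- .pvals(results_positive)
  neg <- .pvals(results_negative)
  thr <- sort(unique(c(pos, neg)))
  tpr <- vapply(thr, function(t) mean(pos <= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg <= t), numeric(1))
  pts <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  n <- nrow(pts)
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-n]) / 2)
  list(points = pts, auc = auc)
}
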