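#' Specification of a structured synthetic cohort
#'
#' Defines a point cloud in PC ancestry space (a Gaussian mixture), an
#' axis-aligned box region, and the phenotype-assignment probabilities inside
#' and outside the box. The defaults emulate the confounding geometry of the
#' validation study the method was designed around: a 3-component mixture in
#' 3 dimensions forming a cloud that is continuous along PC1 and tightly
#' bimodal along PC2, with the box at the high-PC1 corner holding roughly a
#' quarter of the subjects (0.6/0.4 diseased/healthy chance inside it,
#' 0.5/0.5 outside), and a well-separated component below the PC2 = -2.68
#' line used by the false-negative genotype scheme. See the package vignette
#' for why these shapes were chosen.
#'
#' @param n_subjects Number of subjects.
#' @param components List of mixture components, each a list with `mean`
#'   (k-vector), `sigma` (k x k covariance) and `prop` (mixing proportion;
#'   proportions must sum to 1).
#' @param box Axis-aligned region: list with `min` and `max` k-vectors
#'   (infinite bounds allowed).
#' @param p_diseased_in_box,p_diseased_outside Probability of the diseased
#'   label inside/outside the box, in (0, 1).
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @return An object of class `cohort_spec`.
#' @export
structured_cohort_spec <- function(n_subjects = 4000,
                                   components = NULL,
                                   box = NULL,
                                   p_diseased_in_box = 0.6,
                                   p_diseased_outside = 0.5,
                                   seed = 20121029) {
  if (is.null(components))
    components <- list(
      list(mean = c(0, 0, 0),         sigma = diag(c(4, 0.64, 1.44)), prop = 0.50),
      list(mean = c(3.5, -1.2, 0),    sigma = diag(c(1, 0.36, 1)),    prop = 0.22),
      list(mean = c(-1.5, -6.0, 0.5), sigma = diag(c(1.44, 0.36, 1)), prop = 0.28))
  if (is.null(box))
    box <- list(min = c(2.2, -3.0, -Inf), max = c(6.5, 1.0, Inf))
  props <- vapply(components, `[[`, numeric(1), "prop")
  if (abs(sum(props) - 1) > 1e-8) stop("mixing proportions must sum to 1")
  for (p in c(p_diseased_in_box, p_diseased_outside))
    if (p <= 0 || p >= 1) stop("phenotype probabilities must lie in (0, 1)")
  if (length(box$min) != length(components[[1]]$mean) ||
      length(box$max) != length(box$min) || any(box$min >= box$max))
    stop("box bounds must be per-axis min < max vectors")
  structure(list(n_subjects = as.integer(n_subjects), components = components,
                 box = box, p_diseased_in_box = p_diseased_in_box,
                 p_diseased_outside = p_diseased_outside,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

.in_box <- function(coords, box) {
  inside <- rep(TRUE, nrow(coords))
  for (j in seq_len(ncol(coords)))
    inside <- inside & coords[, j] >= box$min[j] & coords[, j] <= box$max[j]
  inside
}

#' Draw a structured synthetic cohort
#'
#' Samples PC coordinates from the mixture and assigns the diseased label
#' with the in-box probability inside the box region, the outside probability
#' elsewhere. All weights start at 1. The box membership is kept on the
#' cohort (attribute `"in_box"`, plus the box itself as `"box"`) for the
#' genotype generators.
#'
#' @param spec A [structured_cohort_spec()].
#' @return A [cohort()].
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_subjects
    k <- length(spec$components[[1]]$mean)
    props <- vapply(spec$components, `[[`, numeric(1), "prop")
    comp <- sample.int(length(spec$components), n, replace = TRUE, prob = props)
    coords <- matrix(0, n, k)
    for (ci in seq_along(spec$components)) {
      rows <- which(comp == ci)
      if (!length(rows)) next
      cm <- spec$components[[ci]]
      z <- matrix(stats::rnorm(length(rows) * k), length(rows), k)
      coords[rows, ] <- sweep(z %*% chol(cm$sigma), 2, cm$mean, `+`)
    }
    inside <- .in_box(coords, spec$box)
    if (!any(inside)) warning("no subject falls inside the box region")
    p_dis <- ifelse(inside, spec$p_diseased_in_box, spec$p_diseased_outside)
    dis <- stats::rbinom(n, 1, p_dis) == 1
    co <- cohort(sprintf("S%05d", seq_len(n)),
                 ifelse(dis, "diseased", "healthy"), coords)
    attr(co, "in_box") <- inside
    attr(co, "box") <- spec$box
    co
  })
}

#' Population odds ratio implied by two carrier probabilities
#'
#' For a genotype assigned with probability `p_notA_diseased` to diseased and
#' `p_notA_healthy` to healthy subjects, the implied population OR is the
#' ratio of the two odds, `[p_d/(1-p_d)] / [p_h/(1-p_h)]`.
#'
#' @param p_notA_diseased,p_notA_healthy Carrier probabilities in (0, 1).
#' @return A positive odds ratio.
#' @examples
#' expected_or(0.15, 0.10)  # ~1.59
#' @export
expected_or <- function(p_notA_diseased, p_notA_healthy) {
  for (p in c(p_notA_diseased, p_notA_healthy))
    if (!is.numeric(p) || p <= 0 || p >= 1)
      stop("probabilities must lie strictly in (0, 1)")
  (p_notA_diseased / (1 - p_notA_diseased)) /
    (p_notA_healthy / (1 - p_notA_healthy))
}

.draw_genotypes <- function(pr, n_reps, seed) {
  withr::with_seed(seed, {
    n <- length(pr)
    g <- matrix(stats::runif(n * n_reps) < pr, n, n_reps)
    colnames(g) <- sprintf("rep%03d", seq_len(n_reps))
    g
  })
}

#' Genotype generators for the three association archetypes
#'
#' Each generator returns an n-subjects-by-n-replicates logical matrix
#' (TRUE = the subject carries the not-A genotype), drawn independently
#' across subjects and replicates.
#'
#' `gen_true_positive` assigns not-A with a phenotype-conditional probability:
#' the genotype is genuinely associated (population OR =
#' [expected_or()] of the two probabilities) and homogeneously distributed in
#' space, so structure does not distort its evaluation.
#'
#' `gen_false_positive` assigns not-A based only on box membership, never on
#' phenotype (population OR = 1 in each stratum); combined with the
#' diseased-enriched box it produces the classic stratification
#' false positive.
#'
#' `gen_false_negative` assigns not-A conditionally on (stratum, phenotype)
#' with the same within-stratum OR on both sides of a PC2 line, but opposite
#' carrier prevalence, so the pooled naive OR is dragged toward 1 and the
#' association is concealed.
#'
#' @param cohort A [cohort()] (for `gen_false_positive`, one carrying box
#'   membership, e.g. from [simulate_cohort()], unless `box` is given).
#' @param p_notA_diseased,p_notA_healthy Phenotype-conditional carrier
#'   probabilities in (0, 1).
#' @param n_reps Number of replicate genotypes.
#' @param seed Integer seed.
#' @return Logical n x n_reps matrix.
#' @export
gen_true_positive <- function(cohort, p_notA_diseased, p_notA_healthy,
                              n_reps = 500, seed = 1) {
  expected_or(p_notA_diseased, p_notA_healthy)  # validates the probabilities
  pr <- ifelse(cohort$phenotype == "diseased", p_notA_diseased, p_notA_healthy)
  .draw_genotypes(pr, n_reps, seed)
}

#' @rdname gen_true_positive
#' @param p_notA_in_box,p_notA_outside Carrier probabilities inside/outside
#'   the box, applied regardless of phenotype.
#' @param box Axis-aligned box region (list with `min`/`max`); defaults to
#'   the box stored on the cohort.
#' @export
gen_false_positive <- function(cohort, p_notA_in_box = 0.9,
                               p_notA_outside = 0.1, n_reps = 500, seed = 1,
                               box = attr(cohort, "box")) {
  for (p in c(p_notA_in_box, p_notA_outside))
    if (p <= 0 || p >= 1) stop("probabilities must lie strictly in (0, 1)")
  if (is.null(box)) stop("cohort carries no box region; supply `box`")
  inside <- .in_box(cohort$coords, box)
  pr <- ifelse(inside, p_notA_in_box, p_notA_outside)
  .draw_genotypes(pr, n_reps, seed)
}

#' @rdname gen_true_positive
#' @param probs Length-4 carrier probabilities, named or ordered as
#'   `below_diseased`, `below_healthy`, `above_diseased`, `above_healthy`.
#'   The default quadruple gives the same within-stratum OR (~1.65) on both
#'   sides of the line.
#' @param line Stratum rule: list with `axis` (coordinate column) and
#'   `threshold`; "below" means coordinate < threshold.
#' @export
gen_false_negative <- function(cohort,
                               probs = c(below_diseased = 0.08,
                                         below_healthy = 0.05,
                                         above_diseased = 0.95,
                                         above_healthy = 0.92),
                               n_reps = 500, seed = 1,
                               line = list(axis = 2, threshold = -2.68)) {
  stopifnot(length(probs) == 4L, all(probs > 0), all(probs < 1))
  below <- cohort$coords[, line$axis] < line$threshold
  if (!any(below) || all(below))
    stop("both strata of the line rule must be nonempty")
  dis <- cohort$phenotype == "diseased"
  pr <- ifelse(below,
               ifelse(dis, probs[[1]], probs[[2]]),
               ifelse(dis, probs[[3]], probs[[4]]))
  .draw_genotypes(pr, n_reps, seed)
}

#' Genotype-assignment schemes of the validation study
#'
#' The six named schemes: three true positives spanning a range of carrier
#' frequencies (implied ORs ~1.33, ~1.59, ~2.06), two box-driven false
#' positives (population OR = 1), and the line-stratified false negative
#' (within-stratum OR ~1.65 concealed by opposite carrier prevalence).
#'
#' @return Named list of `genotype_scheme` objects (fields: `kind`, `label`,
#'   `probs`, `implied_or`).
#' @export
scheme_presets <- function() {
  tp <- function(label, pd, ph)
    structure(list(kind = "true_positive", label = label,
                   probs = c(p_notA_diseased = pd, p_notA_healthy = ph),
                   implied_or = expected_or(pd, ph)),
              class = "genotype_scheme")
  fp <- function(label, pin, pout)
    structure(list(kind = "false_positive", label = label,
                   probs = c(p_notA_in_box = pin, p_notA_outside = pout),
                   implied_or = 1),
              class = "genotype_scheme")
  fn <- structure(list(kind = "false_negative", label = "fn_line",
                       probs = c(below_diseased = 0.08, below_healthy = 0.05,
                                 above_diseased = 0.95, above_healthy = 0.92),
                       line = list(axis = 2, threshold = -2.68),
                       implied_or = expected_or(0.08, 0.05)),
                  class = "genotype_scheme")
  list(tp_common = tp("tp_common", 0.57, 0.50),
       tp_mid    = tp("tp_mid", 0.15, 0.10),
       tp_rare   = tp("tp_rare", 0.06, 0.03),
       fp_strong = fp("fp_strong", 0.90, 0.10),
       fp_mild   = fp("fp_mild", 0.80, 0.20),
       fn_line   = fn)
}

#' @export
#' @method print genotype_scheme
print.genotype_scheme <- function(x, ...) {
  cat(sprintf("Genotype scheme '%s' (%s), implied OR %.3f\n",
              x$label, x$kind, x$implied_or))
  invisible(x)
}

generate_genotypes <- function(scheme, cohort, n_reps, seed) {
  switch(scheme$kind,
    true_positive = gen_true_positive(cohort, scheme$probs[[1]],
                                      scheme$probs[[2]], n_reps, seed),
    false_positive = gen_false_positive(cohort, scheme$probs[[1]],
                                        scheme$probs[[2]], n_reps, seed),
    false_negative = gen_false_negative(cohort, scheme$probs, n_reps, seed,
                                        line = scheme$line),
    stop("unknown scheme kind: ", scheme$kind))
}

# Hanley-McNeil standard error of an AUC estimate.
auc_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' Run the full simulation study
#'
#' Simulates the structured cohort, homogenizes it, evaluates every replicate
#' genotype of every scheme under the four association strategies (Fisher on
#' the original cohort, Fisher on the homogenized cohort, logistic regression
#' with the leading PCs, and weighted logistic regression with the
#' homogenized weights plus PCs), and builds the four ROC curves. Genotypes
#' from schemes with implied OR different from 1 (the true positives and the
#' concealed false negative) form the ROC positive class; the OR = 1 box
#' schemes form the negative class. Fully reproducible from `seed`.
#'
#' @param spec A [structured_cohort_spec()]; its seed is replaced by `seed`.
#' @param schemes List of schemes, e.g. [scheme_presets()].
#' @param homog_params [homogenization_params()]; the study default is a 9%
#'   weight reduction at sphere weight 30 and knocked-down weight 0.2.
#' @param n_reps Replicate genotypes per scheme.
#' @param seed Master seed for the cohort and all genotype draws.
#' @return An object of class `homog_study`: `results` (data frame `scheme`,
#'   `kind`, `rep`, `method`, `effect`, `p_value`), `roc` (per-method
#'   [roc_points()] output), `auc`, `auc_se`, plus the `cohort` and
#'   homogenization result `homog`.
#' @export
run_study <- function(spec = structured_cohort_spec(n_subjects = 2000),
                      schemes = scheme_presets(),
                      homog_params = homogenization_params(
                        sphere_weight = 30, knockdown_weight = 0.2,
                        weight_reduction = 0.09),
                      n_reps = 500, seed = 1) {
  spec$seed <- as.integer(seed)
  co <- simulate_cohort(spec)
  index <- build_neighbor_index(co)
  hres <- homogenize(co, homog_params, index)
  co_hom <- apply_weights(co, hres)
  methods <- c("fisher_original", "fisher_homogenized", "logistic_pc",
               "logistic_pc_weighted")
  out <- vector("list", length(schemes))
  for (si in seq_along(schemes)) {
    sch <- schemes[[si]]
    G <- generate_genotypes(sch, co, n_reps, seed + 1000L + si)
    rows <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      g <- G[, r]
      gid <- paste0(sch$label, "_", colnames(G)[r])
      res <- rbind(
        fisher_assoc(g, co, gid, "fisher_original"),
        fisher_assoc(g, co_hom, gid, "fisher_homogenized"),
        logistic_pc_assoc(g, co, n_pcs = 3, use_weights = FALSE,
                          genotype_id = gid),
        logistic_pc_assoc(g, co_hom, n_pcs = 3, use_weights = TRUE,
                          genotype_id = gid))
      res$method <- methods  # weighted fit labels itself; fix fisher labels
      rows[[r]] <- cbind(data.frame(scheme = sch$label, kind = sch$kind,
                                    rep = r, stringsAsFactors = FALSE), res)
    }
    out[[si]] <- do.call(rbind, rows)
  }
  results <- do.call(rbind, out)
  rownames(results) <- NULL
  pos_kinds <- c("true_positive", "false_negative")
  roc <- lapply(stats::setNames(methods, methods), function(m) {
    sub <- results[results$method == m, ]
    roc_points(sub$p_value[sub$kind %in% pos_kinds],
               sub$p_value[sub$kind == "false_positive"])
  })
  auc <- vapply(roc, `[[`, numeric(1), "auc")
  n_pos <- sum(results$method == methods[1] & results$kind %in% pos_kinds)
  n_neg <- sum(results$method == methods[1] & results$kind == "false_positive")
  structure(list(results = results, roc = roc, auc = auc,
                 auc_se = vapply(auc, auc_se, numeric(1),
                                 n_pos = n_pos, n_neg = n_neg),
                 cohort = co, homog = hres, params = homog_params,
                 n_reps = n_reps, seed = seed),
            class = "homog_study")
}

#' @export
#' @method print homog_study
print.homog_study <- function(x, ...) {
  cat(sprintf("Simulation study: %d subjects, %d schemes x %d replicates\n",
              length(x$cohort$ids), length(unique(x$results$scheme)),
              x$n_reps))
  cat("AUC by association strategy:\n")
  for (m in names(x$auc))
    cat(sprintf("  %-22s %.4f (se %.4f)\n", m, x$auc[[m]], x$auc_se[[m]]))
  invisible(x)
}
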