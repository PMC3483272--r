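test_that("cohort simulation is reproducible and honors the phenotype rates", {
  spec <- structured_cohort_spec(n_subjects = 300, seed = 99)
  co1 <- simulate_cohort(spec)
  co2 <- simulate_cohort(spec)
  expect_identical(co1, co2)
  co3 <- simulate_cohort(structured_cohort_spec(n_subjects = 300, seed = 100))
  expect_false(identical(co1$coords, co3$coords))
  expect_true(all(co1$weights == 1))

  # a flat 0.5/0.5 assignment gives ~half diseased
  flat <- simulate_cohort(structured_cohort_spec(
    n_subjects = 10000, p_diseased_in_box = 0.5,
    p_diseased_outside = 0.5, seed = 12))
  expect_lt(abs(mean(flat$phenotype == "diseased") - 0.5), 0.015)

  # the 0.6 in-box enrichment shows at the binomial rate
  big <- simulate_cohort(structured_cohort_spec(n_subjects = 50000, seed = 13))
  inside <- attr(big, "in_box")
  expect_gt(sum(inside), 10000)
  expect_lt(abs(mean(big$phenotype[inside] == "diseased") - 0.6), 0.015)
  expect_lt(abs(mean(big$phenotype[!inside] == "diseased") - 0.5), 0.015)
})

test_that("expected_or matches the odds-ratio identity", {
  expect_equal(round(expected_or(0.15, 0.10), 2), 1.59)
  expect_equal(round(expected_or(0.06, 0.03), 2), 2.06)
  expect_equal(expected_or(0.08, 0.05), expected_or(0.95, 0.92))
  expect_equal(round(expected_or(0.08, 0.05), 2), 1.65)
  expect_equal(expected_or(0.3, 0.3), 1)
  expect_error(expected_or(0, 0.5), "strictly")
  expect_error(expected_or(0.5, 1), "strictly")
})

test_that("genotype generators hit their assignment probabilities", {
  co <- simulate_cohort(structured_cohort_spec(n_subjects = 10000, seed = 21))
  dis <- co$phenotype == "diseased"
  se3 <- function(p, n) 3 * sqrt(p * (1 - p) / n)

  g_tp <- gen_true_positive(co, 0.57, 0.50, n_reps = 1, seed = 5)[, 1]
  expect_lt(abs(mean(g_tp[dis]) - 0.57), se3(0.57, sum(dis)))
  expect_lt(abs(mean(g_tp[!dis]) - 0.50), se3(0.50, sum(!dis)))

  inb <- attr(co, "in_box")
  g_fp <- gen_false_positive(co, 0.9, 0.1, n_reps = 1, seed = 5)[, 1]
  expect_lt(abs(mean(g_fp[inb]) - 0.9), se3(0.9, sum(inb)))
  expect_lt(abs(mean(g_fp[!inb]) - 0.1), se3(0.1, sum(!inb)))

  below <- co$coords[, 2] < -2.68
  g_fn <- gen_false_negative(co, n_reps = 1, seed = 5)[, 1]
  expect_lt(abs(mean(g_fn[below & dis]) - 0.08), se3(0.08, sum(below & dis)))
  expect_lt(abs(mean(g_fn[!below & !dis]) - 0.92), se3(0.92, sum(!below & !dis)))

  # replicate counts are honored exactly and draws are seed-stable
  expect_identical(dim(gen_true_positive(co, 0.15, 0.10, n_reps = 7, seed = 1)),
                   c(10000L, 7L))
  expect_identical(gen_true_positive(co, 0.15, 0.10, 3, seed = 2),
                   gen_true_positive(co, 0.15, 0.10, 3, seed = 2))
})

test_that("the pooled true-positive sample OR converges to the analytic OR", {
  co <- simulate_cohort(structured_cohort_spec(n_subjects = 2000, seed = 31))
  dis <- co$phenotype == "diseased"
  G <- gen_true_positive(co, 0.57, 0.50, n_reps = 100, seed = 8)
  cells <- c(a = as.numeric(sum(!G[dis, ])), b = as.numeric(sum(G[dis, ])),
             c = as.numeric(sum(!G[!dis, ])), d = as.numeric(sum(G[!dis, ])))
  pooled_or <- (cells[["b"]] * cells[["c"]]) / (cells[["a"]] * cells[["d"]])
  expect_lt(abs(pooled_or - expected_or(0.57, 0.50)), 0.05)
})

test_that("the false-positive scheme is null within strata but fools Fisher", {
  co <- simulate_cohort(structured_cohort_spec(n_subjects = 2000, seed = 32))
  inb <- attr(co, "in_box")
  dis <- co$phenotype == "diseased"
  G <- gen_false_positive(co, 0.9, 0.1, n_reps = 50, seed = 9)
  or_in <- (sum(G[inb & dis, ]) * sum(!G[inb & !dis, ])) /
    (sum(!G[inb & dis, ]) * sum(G[inb & !dis, ]))
  expect_lt(abs(or_in - 1), 0.05)
  p <- vapply(1:20, function(r) fisher_assoc(G[, r], co)$p_value, numeric(1))
  expect_lt(stats::median(p), 0.05)  # structure-driven false positive
})

test_that("the false-negative scheme conceals a real within-stratum OR", {
  co <- simulate_cohort(structured_cohort_spec(n_subjects = 4000, seed = 33))
  dis <- co$phenotype == "diseased"
  G <- gen_false_negative(co, n_reps = 50, seed = 10)
  pooled_or <- (as.numeric(sum(G[dis, ])) * as.numeric(sum(!G[!dis, ]))) /
    (as.numeric(sum(!G[dis, ])) * as.numeric(sum(G[!dis, ])))
  expect_lt(pooled_or, 1.3)          # far below the within-stratum 1.65
  expect_gt(pooled_or, 1 / 1.3)
  co_flat <- cohort(co$ids, co$phenotype,
                    matrix(5, length(co$ids), 2))  # single stratum
  expect_error(gen_false_negative(co_flat, n_reps = 1, seed = 1), "nonempty")
})

test_that("scheme presets carry the published probabilities and ORs", {
  pre <- scheme_presets()
  expect_named(pre, c("tp_common", "tp_mid", "tp_rare", "fp_strong",
                      "fp_mild", "fn_line"))
  expect_equal(round(pre$tp_mid$implied_or, 2), 1.59)
  expect_equal(round(pre$tp_rare$implied_or, 2), 2.06)
  expect_equal(round(pre$fn_line$implied_or, 2), 1.65)
  expect_equal(pre$fp_strong$implied_or, 1)
  expect_equal(unname(pre$fn_line$probs), c(0.08, 0.05, 0.95, 0.92))
  expect_equal(pre$fn_line$line$threshold, -2.68)
})

test_that("a reduced study run emits the four strategies and ROC curves", {
  st <- run_study(structured_cohort_spec(n_subjects = 600),
                  schemes = scheme_presets()[c("tp_mid", "fp_strong", "fn_line")],
                  homog_params = homogenization_params(30, 0.2, 0.05),
                  n_reps = 5, seed = 4)
  methods <- c("fisher_original", "fisher_homogenized", "logistic_pc",
               "logistic_pc_weighted")
  expect_named(st$roc, methods)
  expect_named(st$auc, methods)
  expect_identical(nrow(st$results), 3L * 5L * 4L)
  expect_true(all(st$results$p_value > 0 & st$results$p_value <= 1))
  expect_true(all(vapply(st$roc, function(r)
    all(r$points$fpr >= 0 & r$points$fpr <= 1), logical(1))))
  # deterministic given the seed
  st2 <- run_study(structured_cohort_spec(n_subjects = 600),
                   schemes = scheme_presets()[c("tp_mid", "fp_strong", "fn_line")],
                   homog_params = homogenization_params(30, 0.2, 0.05),
                   n_reps = 5, seed = 4)
  expect_identical(st$results, st2$results)
})
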