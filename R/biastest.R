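#' Potential p-value bias test
#'
#' A cohort-level diagnostic of how small a Fisher p-value population
#' structure alone could produce. For every sphere weight in the ladder and
#' every subject-centered sphere of that weight, the sphere contingency table
#' (an idealized genotype carried by everyone inside the sphere and no one
#' outside) is rounded to integer cells and tested with the two-sided Fisher
#' exact test. The reported value per weight is the smallest p over all
#' centers; the overall test value is the smallest over all weights. Larger
#' values mean less structure-driven false-positive potential.
#'
#' Requested weights exceeding the total cohort weight are skipped with a
#' warning so the default ladder also works on small cohorts.
#'
#' @param cohort A [cohort()].
#' @param sphere_weights Ladder of sphere weights to scan.
#' @param index Optional precomputed [build_neighbor_index()].
#' @return An object of class `bias_test_report`: `per_weight` (named numeric,
#'   minimum p per sphere weight), `overall` (minimum over weights), `argmin`
#'   (list with `sphere_weight` and `center` attaining the overall minimum;
#'   ties resolved toward the smaller weight, then the earlier subject).
#' @examples
#' co <- simulate_cohort(structured_cohort_spec(n_subjects = 300, seed = 11))
#' potential_pvalue_bias_test(co, sphere_weights = c(25, 50))
#' @export
potential_pvalue_bias_test <- function(cohort,
                                       sphere_weights = c(25, 50, 100, 200,
                                                          400, 800, 1600),
                                       index = NULL) {
  if (length(sphere_weights) == 0L) stop("sphere weight ladder is empty")
  if (any(sphere_weights <= 0)) stop("sphere weights must be positive")
  total <- total_weight(cohort)
  keep <- sphere_weights <= total
  if (!all(keep))
    warning(sprintf("skipping sphere weight(s) exceeding total cohort weight (%.6g): %s",
                    total, paste(sphere_weights[!keep], collapse = ", ")))
  sphere_weights <- sphere_weights[keep]
  if (length(sphere_weights) == 0L)
    stop("no requested sphere weight fits within the total cohort weight")
  index <- .check_index(cohort, index)
  sphere_weights <- sort(sphere_weights)

  per_weight <- stats::setNames(numeric(length(sphere_weights)),
                                as.character(sphere_weights))
  argmin_center <- character(length(sphere_weights))
  for (wi in seq_along(sphere_weights)) {
    sc <- sphere_scan(cohort, index, sphere_weights[wi])
    cells <- cbind(round_half_away(sc$a), round_half_away(sc$b),
                   round_half_away(sc$c), round_half_away(sc$d))
    key <- paste(cells[, 1], cells[, 2], cells[, 3], cells[, 4])
    first <- !duplicated(key)
    p_unique <- vapply(which(first), function(i) fisher_exact_p(cells[i, ]),
                       numeric(1))
    p <- p_unique[match(key, key[first])]
    imin <- which.min(p)            # earliest subject on ties
    per_weight[wi] <- p[imin]
    argmin_center[wi] <- cohort$ids[imin]
  }
  wmin <- which.min(per_weight)     # smallest weight on ties (sorted ladder)
  structure(list(per_weight = per_weight,
                 overall = unname(per_weight[wmin]),
                 argmin = list(sphere_weight = sphere_weights[wmin],
                               center = argmin_center[wmin])),
            class = "bias_test_report")
}

#' @export
#' @method print bias_test_report
print.bias_test_report <- function(x, ...) {
  cat("Potential p-value bias test\n")
  cat("  min Fisher p by sphere weight:\n")
  for (w in names(x$per_weight))
    cat(sprintf("    %6s : %.3g\n", w, x$per_weight[[w]]))
  cat(sprintf("  overall: %.3g (sphere weight %g, centered on %s)\n",
              x$overall, x$argmin$sphere_weight, x$argmin$center))
  invisible(x)
}

#' Weight-reduction parameter sweep
#'
#' The parameter-selection workflow for the weight-reduction fraction: the
#' cohort is homogenized once up to the largest requested fraction, weights
#' are snapshotted at the cycle count corresponding to each fraction (the
#' algorithm is deterministic, so the prefix of a longer run equals a shorter
#' run), and the potential p-value bias test is evaluated on each snapshot.
#' The fraction is chosen at the knee of the resulting curve, beyond which
#' further weight decrease buys only marginal bias improvement.
#'
#' @param cohort A [cohort()] with unit weights.
#' @param fractions Weight-reduction fractions to evaluate (0 allowed: the
#'   unhomogenized cohort).
#' @param params [homogenization_params()] supplying sphere and knocked-down
#'   weights (its `weight_reduction` is ignored in favor of `fractions`).
#' @param sphere_weights Bias-test ladder, passed to
#'   [potential_pvalue_bias_test()].
#' @param index Optional precomputed [build_neighbor_index()].
#' @return A data frame with columns `f`, `cycles` and `overall_p`.
#' @export
parameter_sweep <- function(cohort, fractions = seq(0, 0.1, by = 0.01),
                            params = homogenization_params(),
                            sphere_weights = c(25, 50, 100, 200, 400, 800, 1600),
                            index = NULL) {
  stopifnot(all(fractions >= 0), all(fractions < 1))
  index <- .check_index(cohort, index)
  w0 <- total_weight(cohort)
  cycles <- vapply(fractions,
                   function(f) num_cycles(w0, f, params$knockdown_weight),
                   integer(1))
  maxc <- max(cycles)
  snapshots <- vector("list", length(fractions))
  snapshots[cycles == 0L] <- list(cohort$weights)
  t <- 0L
  cur <- cohort
  while (t < maxc) {
    step <- knock_down_step(cur, params, index)
    if (inherits(step, "no_eligible")) {
      warning(sprintf("no eligible subject left after %d cycles", t))
      snapshots[cycles > t] <- list(cur$weights)
      break
    }
    cur <- step$cohort
    t <- t + 1L
    snapshots[cycles == t] <- list(cur$weights)
  }
  overall <- vapply(seq_along(fractions), function(i) {
    ci <- cohort
    ci$weights <- snapshots[[i]]
    potential_pvalue_bias_test(ci, sphere_weights, index)$overall
  }, numeric(1))
  data.frame(f = fractions, cycles = cycles, overall_p = overall)
}
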