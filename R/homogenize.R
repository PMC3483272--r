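#' Homogenization parameters
#'
#' The three tunables of the knock-down algorithm. Defaults are the values
#' selected by the potential p-value bias test on the Parkinson's cohort the
#' method was developed on: sphere weight 30, knocked-down weight 0.2 and a 7%
#' net cohort weight reduction.
#'
#' @param sphere_weight Cohort weight held by each candidate sphere (> 0).
#' @param knockdown_weight Weight assigned to knocked subjects, in (0, 1).
#' @param weight_reduction Requested net fractional decrease of the total
#'   cohort weight, in \[0, 1).
#' @return An object of class `homog_params`.
#' @export
homogenization_params <- function(sphere_weight = 30, knockdown_weight = 0.2,
                                  weight_reduction = 0.07) {
  if (!is.numeric(sphere_weight) || length(sphere_weight) != 1L || sphere_weight <= 0)
    stop("sphere_weight must be a positive number")
  if (!is.numeric(knockdown_weight) || length(knockdown_weight) != 1L ||
      knockdown_weight <= 0 || knockdown_weight >= 1)
    stop("knockdown_weight must lie in (0, 1)")
  if (!is.numeric(weight_reduction) || length(weight_reduction) != 1L ||
      weight_reduction < 0 || weight_reduction >= 1)
    stop("weight_reduction must lie in [0, 1)")
  structure(list(sphere_weight = sphere_weight,
                 knockdown_weight = knockdown_weight,
                 weight_reduction = weight_reduction),
            class = "homog_params")
}

#' @export
#' @method print homog_params
print.homog_params <- function(x, ...) {
  cat(sprintf(paste0("Homogenization parameters: sphere weight %g, ",
                     "knocked-down weight %g, weight reduction %g%%\n"),
              x$sphere_weight, x$knockdown_weight, 100 * x$weight_reduction))
  invisible(x)
}

#' Number of knock-down cycles for a requested weight reduction
#'
#' Each cycle removes `1 - w_kd` weight from the cohort, so the cycle count is
#' `round(total_weight * f / (1 - w_kd))` (halves away from zero), the count
#' that brings the achieved reduction closest to the requested fraction `f`.
#'
#' @param total_weight Initial total cohort weight.
#' @param f Requested fractional weight decrease in \[0, 1).
#' @param w_kd Knocked-down weight in (0, 1).
#' @return Nonnegative integer cycle count.
#' @examples
#' num_cycles(3986, 0.07, 0.2)  # 349
#' @export
num_cycles <- function(total_weight, f, w_kd) {
  stopifnot(total_weight > 0, f >= 0, f < 1, w_kd > 0, w_kd < 1)
  as.integer(round_half_away(total_weight * f / (1 - w_kd)))
}

#' Pick the sphere with the most extreme OR
#'
#' Maximizes [extremeness()] (so OR = 3 and OR = 1/3 compete equally); ties
#' are broken by subject input order.
#'
#' @param ors Per-subject sphere OR estimates (e.g. [all_sphere_ors()]).
#' @return The index (or name, if `ors` is named) of the selected center.
#' @export
select_extreme_sphere <- function(ors) {
  if (length(ors) == 0L) stop("no sphere ORs supplied")
  i <- which.max(extremeness(ors))
  if (!is.null(names(ors))) names(ors)[i] else i
}

# Phenotype to knock inside a sphere: the over-represented side. OR > 1 means
# too many diseased inside; at exactly 1 the side with larger inside weight is
# taken, diseased on a full tie.
.knock_target <- function(or, a_in, c_in) {
  if (or > 1) "diseased"
  else if (or < 1) "healthy"
  else if (a_in >= c_in) "diseased" else "healthy"
}

#' One knock-down cycle
#'
#' Estimates the Haldane OR of every subject-centered sphere of weight
#' `params$sphere_weight`, selects the most extreme one, and knocks down the
#' sphere member closest to the center that still has unit weight and the
#' over-represented phenotype. If the selected sphere holds no eligible
#' subject, the next-most-extreme sphere is tried; only when no sphere
#' anywhere yields an eligible subject is a `no_eligible` signal returned.
#'
#' @param cohort A [cohort()].
#' @param params A [homogenization_params()].
#' @param index Optional precomputed [build_neighbor_index()].
#' @return A list with the updated `cohort` and a one-row `record` data frame
#'   (`center`, `sphere_or`, `knocked`, `phenotype`), or an object of class
#'   `no_eligible`.
#' @export
knock_down_step <- function(cohort, params, index = NULL) {
  index <- .check_index(cohort, index)
  sc <- sphere_scan(cohort, index, params$sphere_weight)
  ext <- pmax(sc$or, 1 / sc$or)
  for (cen in order(-ext, seq_along(ext))) {
    target <- .knock_target(sc$or[cen], sc$a[cen], sc$c[cen])
    members <- index$order[cen, seq_len(sc$count[cen])]
    elig <- members[cohort$weights[members] == 1 &
                    cohort$phenotype[members] == target]
    if (length(elig)) {
      k <- elig[1L]  # members are in distance order: closest eligible wins
      cohort$weights[k] <- params$knockdown_weight
      rec <- data.frame(center = cohort$ids[cen], sphere_or = sc$or[cen],
                        knocked = cohort$ids[k], phenotype = target,
                        stringsAsFactors = FALSE)
      return(list(cohort = cohort, record = rec))
    }
  }
  structure(list(), class = "no_eligible")
}

#' Homogenize a cohort by iterative weight knock-down
#'
#' Runs [knock_down_step()] for the cycle count implied by the requested
#' weight reduction (see [num_cycles()]). Each cycle re-estimates every sphere
#' OR on the current weights, selects the sphere furthest from OR = 1 and
#' lowers one over-represented subject inside it from weight 1 to the
#' knocked-down weight. The run is deterministic given the cohort order and
#' parameters; it stops early only if no eligible subject remains anywhere
#' (logged as a warning).
#'
#' @param cohort A [cohort()] (typically all weights 1).
#' @param params A [homogenization_params()].
#' @param index Optional precomputed [build_neighbor_index()].
#' @return An object of class `homog_result`: `final_weights` (named by
#'   subject ID), `log` (one row per cycle: `cycle`, `center`, `sphere_or`,
#'   `knocked`, `phenotype`), `params`, `initial_weight`, `n_cycles_requested`
#'   plus the subject `ids`/`fid` needed to write the weights back out.
#' @examples
#' spec <- structured_cohort_spec(n_subjects = 300, seed = 7)
#' co <- simulate_cohort(spec)
#' hr <- homogenize(co, homogenization_params(weight_reduction = 0.02))
#' hr
#' @export
homogenize <- function(cohort, params = homogenization_params(), index = NULL) {
  stopifnot(inherits(params, "homog_params"))
  index <- .check_index(cohort, index)
  w0 <- total_weight(cohort)
  if (params$sphere_weight >= w0)
    stop("sphere weight must be smaller than the total cohort weight")
  if (!any(cohort$weights == 1))
    stop("cohort has no unit-weight subjects to knock down")
  ncyc <- num_cycles(w0, params$weight_reduction, params$knockdown_weight)
  recs <- vector("list", ncyc)
  t_done <- 0L
  while (t_done < ncyc) {
    step <- knock_down_step(cohort, params, index)
    if (inherits(step, "no_eligible")) {
      warning(sprintf("no eligible subject left after %d of %d cycles",
                      t_done, ncyc))
      break
    }
    cohort <- step$cohort
    t_done <- t_done + 1L
    recs[[t_done]] <- step$record
  }
  log <- if (t_done > 0L) {
    cbind(data.frame(cycle = seq_len(t_done)),
          do.call(rbind, recs[seq_len(t_done)]))
  } else {
    data.frame(cycle = integer(), center = character(),
               sphere_or = numeric(), knocked = character(),
               phenotype = character(), stringsAsFactors = FALSE)
  }
  structure(list(final_weights = stats::setNames(cohort$weights, cohort$ids),
                 log = log, params = params, initial_weight = w0,
                 n_cycles_requested = ncyc, ids = cohort$ids,
                 fid = cohort$fid),
            class = "homog_result")
}

#' @export
#' @method print homog_result
print.homog_result <- function(x, ...) {
  kd <- table(factor(x$log$phenotype, levels = PHENOTYPES))
  cat(sprintf(paste0("Homogenization: %d of %d requested knock-down cycles ",
                     "(%d diseased, %d healthy)\n"),
              nrow(x$log), x$n_cycles_requested, kd[["diseased"]],
              kd[["healthy"]]))
  cat(sprintf("Total cohort weight %.6g -> %.6g\n",
              x$initial_weight, sum(x$final_weights)))
  invisible(x)
}

#' Copy homogenized weights back onto a cohort
#'
#' @param cohort The cohort the result was computed from.
#' @param result A [homogenize()] result (or a named weight vector).
#' @return The cohort with updated weights.
#' @export
apply_weights <- function(cohort, result) {
  w <- if (inherits(result, "homog_result")) result$final_weights else result
  if (is.null(names(w))) stop("weights must be named by subject ID")
  i <- match(cohort$ids, names(w))
  if (anyNA(i)) stop("weights missing for some cohort subjects")
  cohort$weights <- unname(w[i])
  cohort
}
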