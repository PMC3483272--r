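PHENOTYPES <- c("diseased", "healthy")

#' Case-control cohort in PC ancestry space
#'
#' The mutable state of the homogenization algorithm: subject IDs, binary
#' phenotype labels, coordinates in a k-dimensional principal-component space
#' and per-subject statistical weights in (0, 1]. A fresh cohort has all
#' weights at 1; [homogenize()] lowers selected subjects to the knocked-down
#' weight.
#'
#' @param ids Character vector of unique subject IDs.
#' @param phenotype Per-subject label, `"diseased"` or `"healthy"`.
#' @param coords Numeric matrix, one row per subject, k >= 1 columns.
#' @param weights Per-subject weights in (0, 1]; default all 1.
#' @param fid Optional family IDs (PLINK FID); defaults to `ids`.
#' @return An object of class `cohort`.
#' @examples
#' co <- cohort(paste0("s", 1:4), c("diseased", "diseased", "healthy", "healthy"),
#'              matrix(c(0, 1, 2, 9), ncol = 1))
#' total_weight(co)
#' @export
cohort <- function(ids, phenotype, coords, weights = rep(1, length(ids)),
                   fid = NULL) {
  ids <- as.character(ids)
  n <- length(ids)
  if (anyDuplicated(ids)) stop("subject IDs must be unique")
  if (!is.matrix(coords)) coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) != n || ncol(coords) < 1L)
    stop("coords must be an n x k numeric matrix, k >= 1")
  if (any(!is.finite(coords))) stop("coords must be finite")
  phenotype <- as.character(phenotype)
  if (length(phenotype) != n || !all(phenotype %in% PHENOTYPES))
    stop("phenotype must be 'diseased' or 'healthy' for every subject")
  if (!all(PHENOTYPES %in% phenotype))
    warning("cohort does not contain both phenotype labels")
  weights <- as.double(weights)
  if (length(weights) != n || any(!is.finite(weights)) ||
      any(weights <= 0) || any(weights > 1))
    stop("weights must lie in (0, 1]")
  if (is.null(fid)) fid <- ids
  rownames(coords) <- ids
  if (is.null(colnames(coords))) colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  structure(list(ids = ids, phenotype = phenotype, coords = coords,
                 weights = weights, fid = as.character(fid)),
            class = "cohort")
}

#' @export
#' @method print cohort
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort: %d subjects (%d diseased, %d healthy), %d PC(s)\n",
              length(x$ids), sum(x$phenotype == "diseased"),
              sum(x$phenotype == "healthy"), ncol(x$coords)))
  cat(sprintf("Total weight %.6g; %d subject(s) below unit weight\n",
              total_weight(x), sum(x$weights < 1)))
  invisible(x)
}

#' @export
as.data.frame.cohort <- function(x, ...) {
  data.frame(FID = x$fid, IID = x$ids, phenotype = x$phenotype,
             x$coords, WEIGHT = x$weights, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Total statistical weight of a cohort
#' @param cohort A [cohort()].
#' @return Sum of subject weights.
#' @export
total_weight <- function(cohort) sum(cohort$weights)

.subject_index <- function(cohort, subject) {
  if (is.character(subject)) {
    i <- match(subject, cohort$ids)
    if (is.na(i)) stop("unknown subject ID: ", subject)
    return(i)
  }
  i <- as.integer(subject)
  if (is.na(i) || i < 1L || i > length(cohort$ids))
    stop("subject index out of range")
  i
}

#' Distance-sorted neighbor lists in PC space
#'
#' For every subject, all subjects sorted by nondecreasing Euclidean distance
#' from it (the subject itself first). Coordinates never change during
#' homogenization, so the index is built once and reused every knock-down
#' cycle; only the weights walked along the lists change. Distance ties are
#' broken by subject input order.
#'
#' @param cohort A [cohort()].
#' @return An object of class `neighbor_index` with elements `order`
#'   (n x n integer matrix, row i = subject indices sorted by distance from
#'   subject i) and `dmat` (the full Euclidean distance matrix).
#' @export
build_neighbor_index <- function(cohort) {
  dmat <- as.matrix(stats::dist(cohort$coords))
  dimnames(dmat) <- NULL
  n <- nrow(dmat)
  idx <- seq_len(n)
  ord <- matrix(0L, n, n)
  for (i in idx) ord[i, ] <- order(dmat[i, ], idx)
  structure(list(order = ord, dmat = dmat, ids = cohort$ids),
            class = "neighbor_index")
}

#' @export
#' @method print neighbor_index
print.neighbor_index <- function(x, ...) {
  cat(sprintf("Neighbor index over %d subjects\n", nrow(x$order)))
  invisible(x)
}

.check_index <- function(cohort, index) {
  if (is.null(index)) return(build_neighbor_index(cohort))
  if (!inherits(index, "neighbor_index") ||
      !identical(index$ids, cohort$ids))
    stop("neighbor index does not match this cohort")
  index
}

#' Smallest closed ball of a given cohort weight around a subject
#'
#' Walks the center's distance-sorted neighbor list, accumulating subject
#' weights until the running sum reaches the requested sphere weight `W`; all
#' subjects at exactly the final radius are then included, so membership does
#' not depend on input order. Spheres are characterized by the weight they
#' hold, not by spatial radius: the relevant statistical comparison is between
#' spheres holding the same weight.
#'
#' @param center Subject ID or index.
#' @param W Requested sphere weight, at most the total cohort weight.
#' @param cohort A [cohort()].
#' @param index Optional precomputed [build_neighbor_index()].
#' @return An object of class `sphere`: `center` (ID), `members` (IDs in
#'   distance order), `radius`, `cohort_weight` (total member weight).
#' @examples
#' co <- cohort(paste0("s", 0:3), rep(c("diseased", "healthy"), 2),
#'              matrix(c(0, 1, 2, 9), ncol = 1))
#' sphere_at("s0", 3, co)
#' @export
sphere_at <- function(center, W, cohort, index = NULL) {
  index <- .check_index(cohort, index)
  i <- .subject_index(cohort, center)
  n <- length(cohort$ids)
  ordi <- index$order[i, ]
  cw <- cumsum(cohort$weights[ordi])
  m <- which(cw >= W)[1L]
  if (is.na(m)) stop("sphere weight exceeds total cohort weight")
  r <- index$dmat[i, ordi[m]]
  while (m < n && index$dmat[i, ordi[m + 1L]] == r) m <- m + 1L  # tie shell
  structure(list(center = cohort$ids[i],
                 members = cohort$ids[ordi[seq_len(m)]],
                 radius = r, cohort_weight = cw[m]),
            class = "sphere")
}

#' @export
#' @method print sphere
print.sphere <- function(x, ...) {
  cat(sprintf("Sphere centered on %s: %d members, radius %.4g, weight %.6g\n",
              x$center, length(x$members), x$radius, x$cohort_weight))
  invisible(x)
}

#' Sphere contingency table
#'
#' The 2x2 table of the idealized genotype present in every subject inside the
#' sphere and in none outside: `a` = diseased weight inside, `b` = diseased
#' weight outside, `c` = healthy weight inside, `d` = healthy weight outside.
#' Outside cells are computed as (phenotype total - inside sum), so the row
#' margins equal the phenotype weight totals exactly.
#'
#' @param s A [sphere_at()] result.
#' @param cohort The cohort the sphere was built from.
#' @return A [weighted_table()].
#' @export
sphere_table <- function(s, cohort) {
  mi <- match(s$members, cohort$ids)
  if (anyNA(mi)) stop("sphere members not found in cohort")
  dis <- cohort$phenotype[mi] == "diseased"
  a <- sum(cohort$weights[mi][dis])
  cc <- sum(cohort$weights[mi][!dis])
  tot_d <- sum(cohort$weights[cohort$phenotype == "diseased"])
  tot_h <- sum(cohort$weights[cohort$phenotype == "healthy"])
  weighted_table(a, max(tot_d - a, 0), cc, max(tot_h - cc, 0))
}

# Vectorized sphere tables + Haldane ORs for all subject-centered spheres.
# Single fast path used by homogenize and the bias test.
sphere_scan <- function(cohort, index, W) {
  if (W > total_weight(cohort))
    stop("sphere weight exceeds total cohort weight")
  sc <- cpp_sphere_scan(index$order, index$dmat, cohort$weights,
                        cohort$phenotype == "diseased", W)
  tot_d <- sum(cohort$weights[cohort$phenotype == "diseased"])
  tot_h <- sum(cohort$weights[cohort$phenotype == "healthy"])
  b <- pmax(tot_d - sc$a_in, 0)
  d <- pmax(tot_h - sc$c_in, 0)
  or <- ((sc$a_in + 0.5) * (d + 0.5)) / ((b + 0.5) * (sc$c_in + 0.5))
  list(a = sc$a_in, b = b, c = sc$c_in, d = d, or = or,
       count = sc$count, radius = sc$radius, cohort_weight = sc$cohort_weight)
}

#' Haldane sphere-OR estimates for all subject-centered spheres
#'
#' One OR per subject: the Haldane-corrected odds ratio of the sphere table of
#' the weight-`W` sphere centered on that subject. Identical to calling
#' [sphere_at()], [sphere_table()] and [odds_ratio()] per subject, but
#' computed in a single pass.
#'
#' @param W Sphere weight.
#' @param cohort A [cohort()].
#' @param index Optional precomputed [build_neighbor_index()].
#' @return Named numeric vector of ORs (names = subject IDs).
#' @export
all_sphere_ors <- function(W, cohort, index = NULL) {
  index <- .check_index(cohort, index)
  stats::setNames(sphere_scan(cohort, index, W)$or, cohort$ids)
}
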