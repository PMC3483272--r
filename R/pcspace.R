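#' Genotype dosage matrix
#'
#' Subjects by SNPs additive dosages in \{0, 1, 2\}, with missing calls as
#' `NA` (never encoded as a dosage value). SNPs are assumed ordered by
#' genomic position.
#'
#' @param calls Numeric matrix (subjects x SNPs) of dosages 0/1/2 or `NA`.
#' @param subjects,snps Optional ID vectors; default to the dimnames.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, subjects = rownames(calls),
                            snps = colnames(calls)) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "double"
  if (is.null(subjects)) subjects <- sprintf("S%d", seq_len(nrow(calls)))
  if (is.null(snps)) snps <- sprintf("snp%d", seq_len(ncol(calls)))
  if (length(subjects) != nrow(calls) || length(snps) != ncol(calls))
    stop("ID lists do not match the call matrix dimensions")
  if (anyDuplicated(subjects) || anyDuplicated(snps))
    stop("subject and SNP IDs must be unique")
  ok <- calls[!is.na(calls)]
  if (any(ok < 0 | ok > 2))
    stop("dosages must lie in [0, 2] (missing calls as NA)")
  dimnames(calls) <- list(subjects, snps)
  structure(list(subjects = as.character(subjects), snps = as.character(snps),
                 calls = calls),
            class = "genotype_matrix")
}

#' @export
#' @method print genotype_matrix
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d subjects x %d SNPs (%.2f%% missing)\n",
              nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Sliding-window LD pruning
#'
#' Greedy pruning of SNPs in high linkage disequilibrium, so that the PCA
#' reflects genome-wide ancestry rather than a few dense LD blocks: within
#' each window of `window_snps` consecutive SNPs, whenever a retained pair
#' has squared Pearson dosage correlation above `r2_threshold` the later SNP
#' (in matrix order) is dropped; the window then slides by `step_snps`.
#' Removal is recursive across windows — a dropped SNP never blocks later
#' comparisons. Correlations use subjects non-missing for both SNPs;
#' monomorphic SNPs have undefined correlation, which is treated as 0 with a
#' warning.
#'
#' @param g A [genotype_matrix()] with SNPs in genomic order.
#' @param window_snps Window size in SNPs.
#' @param step_snps Window shift in SNPs (`0 < step_snps < window_snps`).
#' @param r2_threshold Squared-correlation threshold in (0, 1).
#' @return Character vector of retained SNP IDs, in input order.
#' @export
ld_prune <- function(g, window_snps = 50L, step_snps = 5L, r2_threshold = 0.1) {
  stopifnot(inherits(g, "genotype_matrix"),
            window_snps > step_snps, step_snps > 0,
            r2_threshold > 0, r2_threshold < 1)
  X <- g$calls
  m <- ncol(X)
  v <- apply(X, 2, stats::var, na.rm = TRUE)
  v[is.na(v)] <- 0
  if (any(v == 0))
    warning(sprintf("%d monomorphic SNP(s): correlations involving them treated as 0",
                    sum(v == 0)))
  keep <- rep(TRUE, m)
  for (start in seq(1L, m, by = step_snps)) {
    win <- start:min(start + window_snps - 1L, m)
    win <- win[keep[win] & v[win] > 0]
    if (length(win) < 2L) next
    r2 <- suppressWarnings(stats::cor(X[, win, drop = FALSE],
                                      use = "pairwise.complete.obs"))^2
    r2[is.na(r2)] <- 0
    for (ii in seq_along(win)) {
      if (!keep[win[ii]]) next
      for (jj in seq_along(win)) {
        if (jj > ii && keep[win[jj]] && r2[ii, jj] > r2_threshold)
          keep[win[jj]] <- FALSE   # drop the later SNP of the pair
      }
    }
  }
  g$snps[keep]
}

#' Principal components of the pruned genotype matrix
#'
#' Mean-imputes missing dosages per SNP, standardizes each SNP column to zero
#' mean and unit variance, and returns the leading principal-component
#' projections of the subjects. SNP columns that are entirely missing, or
#' monomorphic after imputation, are excluded with a warning. Each
#' component's sign is fixed by requiring its largest-magnitude SNP loading
#' to be positive, so outputs are reproducible across platforms.
#'
#' @param g A [genotype_matrix()].
#' @param retained SNP IDs to use (e.g. from [ld_prune()]).
#' @param k Number of components.
#' @return An object of class `pc_projection`: `subjects`, `coords`
#'   (subjects x k matrix, columns `PC1..PCk`), `explained_variance`
#'   (component variances, nonincreasing).
#' @export
compute_pcs <- function(g, retained = g$snps, k = 3) {
  stopifnot(inherits(g, "genotype_matrix"), k >= 1)
  sel <- match(retained, g$snps)
  if (anyNA(sel)) stop("retained SNP IDs not present in the genotype matrix")
  X <- g$calls[, sel, drop = FALSE]
  all_na <- colSums(!is.na(X)) == 0L
  if (any(all_na)) {
    warning(sprintf("excluding %d all-missing SNP column(s)", sum(all_na)))
    X <- X[, !all_na, drop = FALSE]
  }
  for (j in seq_len(ncol(X))) {          # per-SNP mean imputation
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("excluding %d monomorphic SNP column(s)", sum(sds == 0)))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) == 0L) stop("no variable SNP columns left (zero total variance)")
  if (k > ncol(X) || k > nrow(X)) stop("k exceeds the available dimensions")
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  if (k > sum(pc$sdev > 1e-8)) stop("k exceeds the rank of the genotype matrix")
  coords <- pc$x[, seq_len(k), drop = FALSE]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {               # sign convention
    lead <- which.max(abs(rot[, j]))
    if (rot[lead, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("PC", seq_len(k))
  rownames(coords) <- g$subjects
  structure(list(subjects = g$subjects, coords = coords,
                 explained_variance = pc$sdev[seq_len(k)]^2),
            class = "pc_projection")
}

#' @export
#' @method print pc_projection
print.pc_projection <- function(x, ...) {
  cat(sprintf("PC projection: %d subjects x %d components\n",
              nrow(x$coords), ncol(x$coords)))
  cat("  component variances:", format(x$explained_variance, digits = 4), "\n")
  invisible(x)
}
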