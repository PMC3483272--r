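#' Weighted 2x2 contingency table
#'
#' The central bookkeeping object of the method: a 2x2 phenotype-by-genotype
#' table whose cells are summed subject weights rather than counts. Cell roles
#' are fixed: `a` = diseased & A, `b` = diseased & not-A, `c` = healthy & A,
#' `d` = healthy & not-A. For sphere tables "A" means "inside the sphere".
#' A cohort of unit-weight subjects gives integer cells.
#'
#' @param a,b,c,d Nonnegative cell weights.
#' @return An object of class `weighted_table`.
#' @examples
#' weighted_table(10, 5, 5, 10)
#' @export
weighted_table <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (!is.numeric(cells) || length(cells) != 4L)
    stop("a, b, c, d must each be a single numeric value")
  if (any(!is.finite(cells)))
    stop("table cells must be finite")
  if (any(cells < 0))
    stop("table cells must be nonnegative")
  structure(list(a = a, b = b, c = c, d = d), class = "weighted_table")
}

# Accept a weighted_table, a length-4 numeric (a, b, c, d) or a 2x2 matrix.
as_cells <- function(x) {
  if (inherits(x, "weighted_table")) return(c(a = x$a, b = x$b, c = x$c, d = x$d))
  if (is.matrix(x) && all(dim(x) == 2L))
    return(c(a = x[1, 1], b = x[1, 2], c = x[2, 1], d = x[2, 2]))
  if (is.numeric(x) && length(x) == 4L)
    return(c(a = x[[1]], b = x[[2]], c = x[[3]], d = x[[4]]))
  stop("expected a weighted_table, a length-4 numeric or a 2x2 matrix")
}

#' @export
as.matrix.weighted_table <- function(x, ...) {
  matrix(c(x$a, x$b, x$c, x$d), nrow = 2, byrow = TRUE,
         dimnames = list(phenotype = c("diseased", "healthy"),
                         genotype = c("A", "notA")))
}

#' @export
#' @method print weighted_table
print.weighted_table <- function(x, ...) {
  cat("Weighted 2x2 contingency table\n")
  print(as.matrix(x))
  invisible(x)
}

#' Odds ratio of a 2x2 table
#'
#' `(a*d) / (b*c)`; with `haldane = TRUE` every cell gets +0.5 first, so the
#' estimate stays finite and positive for tables with empty cells. Sphere-OR
#' estimation always uses the Haldane form.
#'
#' @param table A [weighted_table()], length-4 numeric `(a, b, c, d)` or 2x2
#'   matrix.
#' @param haldane Apply the Haldane +0.5 continuity correction.
#' @return A single positive odds ratio (may be 0 when `a*d == 0` without the
#'   correction).
#' @examples
#' odds_ratio(weighted_table(10, 5, 5, 10))        # 4
#' odds_ratio(c(3, 0, 2, 5), haldane = TRUE)       # 15.4
#' @export
odds_ratio <- function(table, haldane = FALSE) {
  x <- as_cells(table)
  if (haldane) x <- x + 0.5
  if (x[["b"]] == 0 || x[["c"]] == 0) {
    zero <- names(x)[x == 0 & names(x) %in% c("b", "c")]
    stop("odds ratio undefined: zero cell(s) ", paste(zero, collapse = ", "),
         " (use haldane = TRUE)")
  }
  unname((x[["a"]] * x[["d"]]) / (x[["b"]] * x[["c"]]))
}

#' Distance of an odds ratio from unity
#'
#' The symmetric extremeness measure used to pick the sphere to correct:
#' `max(or, 1/or)`, so OR = 3 and OR = 1/3 are equally extreme and unity is
#' the minimum.
#'
#' @param or_value Positive odds ratio(s); vectorized.
#' @return Extremeness value(s), each >= 1.
#' @examples
#' extremeness(c(3, 1/3, 1, 0.25))  # 3 3 1 4
#' @export
extremeness <- function(or_value) {
  if (!is.numeric(or_value) || any(!is.finite(or_value)) || any(or_value <= 0))
    stop("odds ratios must be finite and positive")
  pmax(or_value, 1 / or_value)
}

# Nearest integer, halves away from zero (cells are nonnegative here, but the
# rule is implemented in full). R's round() does banker's rounding, which is
# not wanted.
round_half_away <- function(x) trunc(x + sign(x) * 0.5)

#' Round a weighted table to integer cells
#'
#' Each cell is independently rounded to the nearest integer (halves away from
#' zero) so the Fisher exact test can be applied to a weighted table.
#'
#' @param table A [weighted_table()] (or coercible form).
#' @return A `weighted_table` with integer cells.
#' @examples
#' round_weighted_table(weighted_table(2.4, 3.6, 1.0, 0.2))
#' @export
round_weighted_table <- function(table) {
  x <- round_half_away(as_cells(table))
  weighted_table(x[["a"]], x[["b"]], x[["c"]], x[["d"]])
}

#' Two-sided Fisher exact test p-value
#'
#' Minimum-likelihood two-sided convention: the sum of hypergeometric
#' probabilities, over all tables with the observed margins, of tables whose
#' point probability does not exceed that of the observed table. A table with
#' a zero row or column margin carries no evidence and returns 1. Weighted
#' tables must be rounded (see [round_weighted_table()]) first.
#'
#' @param table Integer-cell table (any form accepted by [odds_ratio()]).
#' @return p-value in (0, 1].
#' @examples
#' fisher_exact_p(weighted_table(5, 5, 5, 5))   # 1
#' fisher_exact_p(c(10, 0, 0, 10))              # ~1.08e-5
#' @export
fisher_exact_p <- function(table) {
  x <- as_cells(table)
  if (any(x != round(x)))
    stop("fisher_exact_p requires integer cells; apply round_weighted_table first")
  if ((x[["a"]] + x[["b"]]) == 0 || (x[["c"]] + x[["d"]]) == 0 ||
      (x[["a"]] + x[["c"]]) == 0 || (x[["b"]] + x[["d"]]) == 0)
    return(1)
  m <- matrix(x, nrow = 2, byrow = TRUE)
  min(stats::fisher.test(m)$p.value, 1)
}
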