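# Independent brute-force oracles, kept free of the package's code paths.

# Two-sided Fisher exact p by explicit enumeration over all tables with the
# observed margins: sum the hypergeometric point probabilities (computed from
# log-binomial coefficients) of tables no more probable than the observed one.
# The same relative tolerance as mainstream implementations is used when
# comparing point probabilities, so exact floating-point ties do not flip.
oracle_fisher_p <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- c + d
  n1 <- a + c
  if (m1 == 0 || m2 == 0 || n1 == 0 || (b + d) == 0) return(1)
  x <- max(0, n1 - m2):min(n1, m1)
  logp <- lchoose(m1, x) + lchoose(m2, n1 - x) - lchoose(m1 + m2, n1)
  p <- exp(logp)
  p_obs <- exp(lchoose(m1, a) + lchoose(m2, c) - lchoose(m1 + m2, n1))
  min(sum(p[p <= p_obs * (1 + 1e-7)]), 1)
}

# Naive sphere construction around one center: distances recomputed from the
# coordinates (same per-axis accumulation order as stats::dist), full sort,
# cumulative weight walk, closed-ball tie shell. Cell sums follow the member
# (distance) order. Used to cross-check the neighbor-index fast path.
naive_sphere <- function(cohort, center_i, W) {
  n <- length(cohort$ids)
  cp <- cohort$coords[center_i, ]
  d2 <- rep(0, n)
  for (k in seq_len(ncol(cohort$coords)))
    d2 <- d2 + (cohort$coords[, k] - cp[k])^2
  d <- unname(sqrt(d2))
  ord <- order(d, seq_len(n))
  cw <- cumsum(cohort$weights[ord])
  m <- which(cw >= W)[1L]
  if (is.na(m)) stop("W exceeds total weight")
  r <- d[ord[m]]
  while (m < n && d[ord[m + 1L]] == r) m <- m + 1L
  members <- ord[seq_len(m)]
  dis <- cohort$phenotype[members] == "diseased"
  a <- sum(cohort$weights[members][dis])
  cc <- sum(cohort$weights[members][!dis])
  tot_d <- sum(cohort$weights[cohort$phenotype == "diseased"])
  tot_h <- sum(cohort$weights[cohort$phenotype == "healthy"])
  list(members = members, radius = r, cohort_weight = cw[m],
       a = a, b = max(tot_d - a, 0), c = cc, d = max(tot_h - cc, 0))
}

# Random test cohort: n subjects, k-dimensional coordinates, a mix of unit,
# knocked-down and arbitrary weights.
random_cohort <- function(n, k = 3, weight_mode = c("mixed", "unit")) {
  weight_mode <- match.arg(weight_mode)
  w <- if (weight_mode == "unit") rep(1, n) else
    sample(c(1, 0.2, round(stats::runif(1), 3) + 1e-3), n,
           replace = TRUE, prob = c(0.6, 0.25, 0.15))
  cohort(sprintf("r%04d", seq_len(n)),
         sample(c("diseased", "healthy"), n, replace = TRUE),
         matrix(stats::rnorm(n * k), n, k),
         pmin(w, 1))
}

# Small structured cohort used across test files.
small_structured_cohort <- function(n = 500, seed = 42)
  simulate_cohort(structured_cohort_spec(n_subjects = n, seed = seed))
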