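#' Per-UMI read-count distribution
#'
#' Given normalized family size `F`, the read count of a UMI is
#' `C | F ~ Poisson(F * D)` where `D` is the mean sequencing depth in reads
#' per UMI. Marginally, `P(C = k)` is the Poisson mixture
#' `integral P(C = k | F = x) f_F(x; E) dx`, computed by the midpoint rule on
#' the density table's size grid.
#'
#' @param k Non-negative integer read counts (vectorised).
#' @param efficiency PCR efficiency E within the table's grid range.
#' @param depth Mean reads per UMI, D > 0.
#' @param table A [build_density_table()] object.
#' @return Probabilities `P(C = k)`, one per element of `k`.
#' @export
umi_read_pmf <- function(k, efficiency, depth, table) {
  stopifnot(all(k >= 0), all(k == round(k)), depth > 0)
  col <- fsd_column(table, efficiency)
  pmf_from_column(k, col, table$x, table$width, depth)
}

# Midpoint-rule mixture pmf from a pre-interpolated density column.
pmf_from_column <- function(k, col, x, width, depth) {
  wts <- col * width
  lam <- x * depth
  p <- vapply(k, function(ki) sum(stats::dpois(ki, lam) * wts), numeric(1))
  pmin(pmax(p, 0), 1)
}

#' Mean and variance of the per-UMI read count
#'
#' Closed form for the Poisson-mixture read count: `E(C) = D` and
#' `V(C) = D + D^2 (1-E)/(1+E)` — Poisson sampling noise plus the PCR
#' family-size dispersion. At E = 1 the distribution is exactly Poisson.
#'
#' @inheritParams umi_read_pmf
#' @return A list with elements `mean` and `variance`.
#' @export
umi_read_moments <- function(efficiency, depth) {
  stopifnot(depth > 0, efficiency > 0, efficiency <= 1)
  list(
    mean = depth,
    variance = depth + depth^2 * (1 - efficiency) / (1 + efficiency)
  )
}

#' Censored moments of the read count
#'
#' Mean and variance of `C` conditional on surviving the error-correction
#' threshold, `C >= T`. The infinite sums are rewritten as
#' `E(C) - sum_{k<T} k P(C=k)` (and similarly for the second moment) so only
#' the `T` head probabilities are needed. `threshold = 0` returns the
#' uncensored moments exactly.
#'
#' @inheritParams umi_read_pmf
#' @param threshold Minimum read count T (non-negative integer).
#' @return A list with `mean`, `variance` and `p_survive` = `P(C >= T)`.
#' @export
umi_censored_moments <- function(efficiency, depth, threshold, table) {
  check_count(threshold, "threshold")
  mom <- umi_read_moments(efficiency, depth)
  if (threshold == 0) {
    return(list(mean = mom$mean, variance = mom$variance, p_survive = 1))
  }
  col <- fsd_column(table, efficiency)
  censored_from_column(mom, col, table$x, table$width, depth, threshold)
}

# Censored moments from a pre-interpolated density column. Uses closed-form
# Poisson partial expectations per grid point,
#   E[C 1{C>=T} | F=x]   = lambda * Q(T-1, lambda)
#   E[C^2 1{C>=T} | F=x] = lambda^2 * Q(T-2, lambda) + lambda * Q(T-1, lambda)
# with lambda = x*D and Q(j, .) the Poisson upper tail, so that heavy
# censoring (loss near 1) involves no cancellation.
censored_from_column <- function(mom, col, x, width, depth, threshold) {
  if (threshold == 0) {
    return(list(mean = mom$mean, variance = mom$variance, p_survive = 1))
  }
  wts <- col * width
  lam <- x * depth
  upper_tail <- function(j) {
    if (j <= 0) rep(1, length(lam)) else stats::ppois(j - 1, lam, lower.tail = FALSE)
  }
  p_surv <- sum(upper_tail(threshold) * wts)
  if (p_surv < 1e-12) {
    stop("loss is numerically 1: P(C >= T) < 1e-12 for these parameters")
  }
  q1 <- upper_tail(threshold - 1)
  m1 <- sum(lam * q1 * wts) / p_surv
  m2 <- sum((lam^2 * upper_tail(threshold - 2) + lam * q1) * wts) / p_surv
  list(mean = m1, variance = max(m2 - m1^2, 0), p_survive = p_surv)
}

#' Expected loss under an error-correction threshold
#'
#' The loss is the probability that a true molecule's UMI gathers fewer than
#' `threshold` reads (including zero) and is therefore never observed or is
#' filtered out: `loss = P(C < T) = sum_{k<T} P(C=k)`.
#'
#' @inheritParams umi_censored_moments
#' @return The loss, a probability in \[0, 1).
#' @export
umi_loss <- function(efficiency, depth, threshold, table) {
  check_count(threshold, "threshold")
  if (threshold == 0) {
    return(0)
  }
  col <- fsd_column(table, efficiency)
  p <- sum(stats::ppois(threshold - 1, table$x * depth) * col * table$width)
  min(max(p, 0), 1 - 1e-15)
}

#' Truncated-Poisson loss baseline
#'
#' The naive loss estimate that ignores PCR family-size dispersion: assume
#' `C ~ Poisson(D)` (equivalent to 100% efficiency), fit `D` so that the
#' T-censored Poisson mean matches the observed censored mean, and report
#' `P(Poisson(D) < T)`. Because the Poisson model has no amplification
#' variance this systematically under-estimates the true loss whenever E < 1.
#'
#' @param mean_observed Observed mean read count among UMIs with at least
#'   `threshold` reads.
#' @param threshold Error-correction threshold T.
#' @return The baseline loss estimate, a probability.
#' @export
poisson_loss_baseline <- function(mean_observed, threshold) {
  check_count(threshold, "threshold")
  if (threshold == 0) {
    return(0)
  }
  if (mean_observed <= threshold - 1 + 1e-12) {
    stop("observed censored mean must exceed threshold - 1; no Poisson fit exists")
  }
  cens_mean <- function(lambda) {
    ks <- seq_len(threshold) - 1
    head_p <- stats::dpois(ks, lambda)
    p_surv <- 1 - sum(head_p)
    if (p_surv <= 0) {
      return(threshold) # lambda -> 0 limit: all surviving mass at k = T
    }
    (lambda - sum(ks * head_p)) / p_surv
  }
  f <- function(lambda) cens_mean(lambda) - mean_observed
  lo <- 1e-8
  hi <- max(mean_observed, 1)
  while (f(hi) < 0 && hi < 1e9) hi <- hi * 10
  if (f(lo) > 0 || f(hi) < 0) {
    stop("no truncated-Poisson depth matches the observed censored mean ", mean_observed)
  }
  lambda <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  stats::ppois(threshold - 1, lambda)
}
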