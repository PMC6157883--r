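# Shared fixtures, built once per test run.

# Reduced-replicate density table shared by all tests: 0.05-spaced efficiency
# grid, 1e5 branching-process draws per efficiency, fixed seed.
test_density_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_density_table(
        efficiencies = seq(0.05, 1, by = 0.05),
        replicates = 1e5, seed = 20240901
      )
    }
    cache
  }
})

# Exact distribution of the branching-process family size after two cycles:
# exhaustive enumeration over the first copy (success/failure) and the
# per-molecule copies of the second cycle.
enumerate_two_cycles <- function(efficiency) {
  e <- efficiency
  pmf <- numeric(4) # sizes 1..4
  # first cycle fails (M1 = 1): second cycle Binom(1, e)
  pmf[1] <- (1 - e) * (1 - e)
  pmf[2] <- (1 - e) * e
  # first cycle succeeds (M1 = 2): second cycle Binom(2, e)
  pmf[2] <- pmf[2] + e * (1 - e)^2
  pmf[3] <- e * 2 * e * (1 - e)
  pmf[4] <- e * e^2
  pmf
}

# Standard error of a sample variance from the empirical fourth moment.
var_se <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m4 <- mean((x - m)^4)
  sqrt((m4 - m2^2) / n)
}

# Scenario table for the abundance-tier simulation design.
tier_scenarios <- function(tiers = c(10, 30, 100, 300, 1000, 3000, 10000),
                           genes_per_tier = 30, depth = 6,
                           efficiency_range = c(0.25, 0.8)) {
  n <- length(tiers) * genes_per_tier
  tibble::tibble(
    gene = sprintf("g%05d", seq_len(n)),
    n_true = rep(tiers, each = genes_per_tier),
    efficiency = stats::runif(n, efficiency_range[1], efficiency_range[2]),
    depth = depth
  )
}

median_error_by_tier <- function(genes, scenarios, column = "n_corrected") {
  idx <- match(genes$gene, scenarios$gene)
  err <- (genes[[column]] - scenarios$n_true[idx]) / scenarios$n_true[idx]
  tapply(err, scenarios$n_true[idx], stats::median)
}
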