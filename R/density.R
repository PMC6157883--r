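#' Simulate Galton-Watson PCR family sizes
#'
#' PCR amplification is modelled as a Galton-Watson branching process: each
#' cycle, every molecule of a family is duplicated independently with
#' probability `efficiency`, so the family size follows
#' `M_0 = 1`, `M_i = M_{i-1} + Binom(M_{i-1}, E)`.
#'
#' @param n Number of independent families to simulate.
#' @param efficiency Per-cycle duplication probability E, in \[0, 1\].
#' @param cycles Number of PCR cycles (non-negative integer).
#' @param seed Optional integer seed; when given the draw is reproducible and
#'   the caller's RNG state is left untouched.
#'
#' @return Integer vector of length `n` with the family sizes after `cycles`
#'   cycles.
#'
#' @examples
#' simulate_family_sizes(5, efficiency = 1, cycles = 3)  # always 8
#' @export
simulate_family_sizes <- function(n, efficiency, cycles, seed = NULL) {
  check_probability(efficiency, "efficiency")
  stopifnot(cycles >= 0, n >= 0)
  with_seed_if(seed, {
    m <- rep(1L, n)
    for (i in seq_len(cycles)) {
      m <- m + stats::rbinom(n, m, efficiency)
    }
    m
  })
}

#' Mean and variance of the PCR family size
#'
#' Closed-form first two moments of the Galton-Watson family size `M_i`:
#' `E[M_i] = (1+E)^i` and
#' `V[M_i] = ((1-E)/(1+E)) * (1+E)^i * ((1+E)^i - 1)`, which vanishes for
#' E = 0 and E = 1 (fully deterministic amplification).
#'
#' @inheritParams simulate_family_sizes
#' @return A list with elements `mean` and `variance`.
#' @export
family_size_moments <- function(efficiency, cycles) {
  check_probability(efficiency, "efficiency")
  stopifnot(cycles >= 0)
  g <- (1 + efficiency)^cycles
  list(
    mean = g,
    variance = (1 - efficiency) / (1 + efficiency) * g * (g - 1)
  )
}

#' Variance of the normalized family size
#'
#' The normalized family size `F = lim M_i / (1+E)^i` has mean 1 and variance
#' `(1-E)/(1+E)`. The limit degenerates at E = 0 (the family never grows), so
#' zero efficiency is rejected.
#'
#' @param efficiency Per-cycle duplication probability E, in (0, 1\].
#' @return `(1-E)/(1+E)`, vectorised over `efficiency`.
#' @export
normalized_family_variance <- function(efficiency) {
  if (any(efficiency <= 0) || any(efficiency > 1)) {
    stop("`efficiency` must lie in (0, 1] (the normalized family size is degenerate at E = 0)")
  }
  (1 - efficiency) / (1 + efficiency)
}

# Cycle count needed so that the residual variance term (1+E)^(-i) of the
# normalized family size is below 1/size_target.
cycles_for_convergence <- function(efficiency, size_target = 1e4, max_cycles = 2000) {
  min(ceiling(log(size_target) / log1p(efficiency)), max_cycles)
}

#' Simulate the normalized family size F
#'
#' Runs the branching process until the expected family size `(1+E)^i`
#' reaches `size_target` (residual variance of the limit is then below
#' `1/size_target`) and returns `M_i / (1+E)^i`, a draw from the normalized
#' family-size distribution with mean 1 and variance `(1-E)/(1+E)`.
#'
#' @inheritParams simulate_family_sizes
#' @param efficiency Per-cycle duplication probability E, in (0, 1\].
#' @param size_target Expected family size at which the limit is considered
#'   converged (default `1e4`).
#' @param max_cycles Hard cap on the number of simulated cycles.
#' @return Numeric vector of length `n` of normalized family sizes.
#' @export
simulate_normalized_family <- function(n, efficiency, seed = NULL,
                                       size_target = 1e4, max_cycles = 2000) {
  if (efficiency <= 0 || efficiency > 1) {
    stop("`efficiency` must lie in (0, 1] (the normalized family size is degenerate at E = 0)")
  }
  cycles <- cycles_for_convergence(efficiency, size_target, max_cycles)
  m <- simulate_family_sizes(n, efficiency, cycles, seed = seed)
  m / (1 + efficiency)^cycles
}

#' Pre-compute the normalized family-size density table
#'
#' Builds the density `f_F(x; E)` of the normalized family size on a grid of
#' efficiencies and sizes by Monte-Carlo simulation of the branching process.
#' The x-axis uses bins of width `bin_width` up to `x_fine`, then widths
#' growing geometrically by `growth` until `x_max`; this resolves the narrow
#' bimodal structure near x = 0.5 and 1 at high efficiencies while keeping the
#' long right tail at low efficiencies cheap. Downstream read-count integrals
#' (midpoint rule) and inverse-CDF sampling both run on this grid.
#'
#' @param efficiencies Ordered vector of grid efficiencies in (0, 1\].
#' @param replicates Monte-Carlo draws per efficiency (at least `1e4`;
#'   default `1e6` for a production-quality table).
#' @param bin_width Width of the fine bins (default 0.01).
#' @param x_fine End of the fine-binned region (default 2).
#' @param growth Geometric growth factor of bin widths beyond `x_fine`.
#' @param x_max Upper end of the supported range of normalized sizes.
#' @param size_target,max_cycles Convergence control passed to
#'   [simulate_normalized_family()].
#' @param seed Optional integer seed, recorded in the table metadata.
#'
#' @return An object of class `family_size_density`: a list with the grid
#'   (`e`, `x` midpoints, `width`, `breaks`), the density matrix
#'   (`length(x)` rows by `length(e)` columns), and metadata (`replicates`,
#'   `size_target`, `seed`).
#' @export
build_density_table <- function(efficiencies = seq(0.02, 1, by = 0.02),
                                replicates = 1e6,
                                bin_width = 0.01, x_fine = 2, growth = 1.08,
                                x_max = 50, size_target = 1e4,
                                max_cycles = 2000, seed = NULL) {
  if (any(efficiencies <= 0) || any(efficiencies > 1)) {
    stop("`efficiencies` must lie in (0, 1]")
  }
  if (is.unsorted(efficiencies, strictly = TRUE)) {
    stop("`efficiencies` must be strictly increasing")
  }
  if (replicates < 1e4) {
    stop("`replicates` must be at least 1e4 to resolve the density grid")
  }
  # fine bins are centred on multiples of bin_width so that x = 1 (the whole
  # mass of F at E = 1) is a bin midpoint and the midpoint rule is exact there
  breaks <- c(0, seq(bin_width / 2, x_fine, by = bin_width))
  w <- bin_width
  while (max(breaks) < x_max) {
    w <- w * growth
    breaks <- c(breaks, max(breaks) + w)
  }
  widths <- diff(breaks)
  mids <- breaks[-1] - widths / 2

  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max - 1L, 1)
  }

  # Columns are driven by common random numbers: cycle i uses the same
  # uniforms for every efficiency (binomial draws by inverse transform), so
  # the tabulated densities -- and every functional interpolated from them --
  # vary smoothly with E instead of carrying independent Monte-Carlo noise
  # per column. This keeps moment inversion well-posed between grid nodes.
  cycle_uniforms <- function(i) {
    withr::with_seed(
      (seed + 7919 * i) %% (.Machine$integer.max - 1L),
      stats::runif(replicates)
    )
  }
  dens <- vapply(efficiencies, function(e) {
    cycles <- cycles_for_convergence(e, size_target, max_cycles)
    m <- rep(1, replicates)
    for (i in seq_len(cycles)) {
      m <- m + stats::qbinom(cycle_uniforms(i), m, e)
    }
    f <- m / (1 + e)^cycles
    counts <- tabulate(findInterval(f, breaks, rightmost.closed = TRUE),
      nbins = length(mids)
    )
    counts / (replicates * widths)
  }, numeric(length(mids)))

  structure(
    list(
      e = efficiencies, x = mids, width = widths, breaks = breaks,
      density = dens, replicates = replicates, size_target = size_target,
      seed = seed
    ),
    class = "family_size_density"
  )
}

#' @export
print.family_size_density <- function(x, ...) {
  cat(
    "<family_size_density>\n",
    sprintf("  efficiencies: %d values in [%g, %g]\n", length(x$e), min(x$e), max(x$e)),
    sprintf("  sizes: %d bins on [0, %g]\n", length(x$x), max(x$breaks)),
    sprintf(
      "  replicates per efficiency: %g; seed: %s\n", x$replicates,
      if (is.null(x$seed)) "none" else x$seed
    ),
    sep = ""
  )
  invisible(x)
}

# Density column at an arbitrary efficiency, linearly interpolated between the
# two bracketing grid columns, evaluated at the table's own x midpoints.
fsd_column <- function(table, efficiency) {
  e <- table$e
  if (efficiency < min(e) - 1e-12 || efficiency > max(e) + 1e-12) {
    stop(sprintf(
      "efficiency %.4g outside the density table's range [%g, %g]; no extrapolation",
      efficiency, min(e), max(e)
    ))
  }
  efficiency <- min(max(efficiency, min(e)), max(e))
  j <- findInterval(efficiency, e, all.inside = TRUE)
  wt <- (efficiency - e[j]) / (e[j + 1] - e[j])
  pmax((1 - wt) * table$density[, j] + wt * table$density[, j + 1], 0)
}

#' Evaluate the interpolated family-size density
#'
#' Interpolates `f_F(x; E)` from a pre-computed [build_density_table()] grid:
#' linear in x between bin midpoints and linear in E between grid columns,
#' clipped at zero. Efficiencies outside the grid range are an error (no
#' extrapolation); x beyond the grid support evaluates to 0.
#'
#' @param table A `family_size_density` object.
#' @param x Normalized family sizes (non-negative), vectorised.
#' @param efficiency A single efficiency within the table's grid range.
#' @return Non-negative density values, one per element of `x`.
#' @export
fsd_density <- function(table, x, efficiency) {
  stopifnot(inherits(table, "family_size_density"), all(x >= 0))
  col <- fsd_column(table, efficiency)
  out <- stats::approx(table$x, col, xout = x, rule = 2)$y
  out[x > max(table$breaks)] <- 0
  pmax(out, 0)
}

#' Write a density table to a self-describing TSV file
#'
#' The header (comment lines) records the efficiency grid, replicate count,
#' convergence target and seed; the body holds one row per size bin with the
#' bin bounds, midpoint and the density for every grid efficiency at full
#' double precision, so [read_density_table()] round-trips losslessly.
#'
#' @param table A `family_size_density` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_density_table <- function(table, path) {
  stopifnot(inherits(table, "family_size_density"))
  num <- function(x) sprintf("%.17g", x)
  header <- c(
    "# family_size_density v1",
    paste0("# efficiencies\t", paste(num(table$e), collapse = "\t")),
    paste0("# replicates\t", num(table$replicates)),
    paste0("# size_target\t", num(table$size_target)),
    paste0("# seed\t", if (is.null(table$seed)) "NA" else table$seed)
  )
  body <- cbind(
    break_lo = table$breaks[-length(table$breaks)],
    break_hi = table$breaks[-1],
    x = table$x,
    table$density
  )
  colnames(body) <- c(
    "break_lo", "break_hi", "x",
    sprintf("d_%s", format(table$e, trim = TRUE))
  )
  lines <- c(
    header,
    paste(colnames(body), collapse = "\t"),
    apply(body, 1, function(r) paste(num(r), collapse = "\t"))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a density table written by [write_density_table()]
#'
#' @param path File path.
#' @return A `family_size_density` object.
#' @export
read_density_table <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[[1]], "# family_size_density")) {
    stop("not a family_size_density file: ", path)
  }
  meta <- strsplit(sub("^# ", "", lines[2:5]), "\t", fixed = TRUE)
  names(meta) <- vapply(meta, `[[`, "", 1)
  e <- as.numeric(meta$efficiencies[-1])
  seed <- meta$seed[[2]]
  body <- utils::read.table(text = lines[-(1:5)], header = TRUE, sep = "\t")
  structure(
    list(
      e = e,
      x = body$x,
      width = body$break_hi - body$break_lo,
      breaks = c(body$break_lo[1], body$break_hi),
      density = as.matrix(body[, -(1:3), drop = FALSE], dimnames = NULL),
      replicates = as.numeric(meta$replicates[[2]]),
      size_target = as.numeric(meta$size_target[[2]]),
      seed = if (identical(seed, "NA")) NULL else as.integer(seed)
    ),
    class = "family_size_density"
  )
}
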