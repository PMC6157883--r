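#' Sample moments of observed per-UMI read counts
#'
#' @param reads Vector of read counts of the UMIs observed for one gene (all
#'   at least `threshold` — filtering happens upstream).
#' @param threshold Error-correction threshold the counts were filtered at.
#' @return A list with `n_obs`, `mean` and `variance` (unbiased); mean and
#'   variance are `NA` when they are undefined (`n_obs < 1` resp. `< 2`).
#' @export
umi_sample_moments <- function(reads, threshold = 0) {
  check_count(threshold, "threshold")
  if (length(reads) > 0 && any(reads < threshold)) {
    stop("`reads` contains counts below the threshold; filter before estimating")
  }
  list(
    n_obs = length(reads),
    mean = if (length(reads) >= 1) mean(reads) else NA_real_,
    variance = if (length(reads) >= 2) stats::var(reads) else NA_real_
  )
}

#' Fit the amplification model by the method of moments
#'
#' Finds efficiency `E` and depth `D` such that the model's censored mean and
#' variance of reads per UMI match the observed sample moments.
#'
#' With `threshold = 0` the fit is closed-form: `D = m` and
#' `E = (1 - v') / (1 + v')` with the normalized excess dispersion
#' `v' = (v - m) / m^2` clipped to \[0, 1\] (clipping is reported via
#' `at_boundary`). With `threshold > 0` the censored moment equations are
#' solved numerically by nested bracketed root-finding: for fixed `E` the
#' censored mean is strictly increasing in `D`, so `D(E)` is found by Brent's
#' method, and the outer search drives the censored-variance residual over
#' `E` in the density table's supported range. Moment pairs outside the
#' model's attainable region are clamped to the nearest boundary of the
#' search domain with `converged = FALSE`.
#'
#' @param mean,variance Sample mean and variance of reads per surviving UMI.
#' @param threshold Error-correction threshold T the data were filtered at.
#' @param table A [build_density_table()] object (required when
#'   `threshold > 0`).
#' @param depth_range Search interval for `D`.
#' @return A list with `efficiency`, `depth`, `converged`, `at_boundary`.
#' @export
fit_readcount_model <- function(mean, variance, threshold = 0, table = NULL,
                                depth_range = c(1e-4, 1e6)) {
  check_count(threshold, "threshold")
  if (!is.finite(mean) || mean <= 0) {
    stop("sample mean must be positive to fit the read-count model")
  }
  if (!is.finite(variance) || variance < 0) {
    stop("sample variance must be non-negative")
  }
  if (threshold == 0) {
    vprime <- (variance - mean) / mean^2
    at_boundary <- vprime < 0 || vprime > 1
    vprime <- min(max(vprime, 0), 1)
    return(list(
      efficiency = (1 - vprime) / (1 + vprime), depth = mean,
      converged = TRUE, at_boundary = at_boundary
    ))
  }
  if (is.null(table)) {
    stop("a density table is required to fit with threshold > 0")
  }
  if (mean <= threshold - 1) {
    stop("censored sample mean must exceed threshold - 1")
  }

  e_lo <- min(table$e)
  e_hi <- max(table$e)

  solve_depth <- function(e) {
    col <- fsd_column(table, e)
    cmean <- function(d) {
      mom <- umi_read_moments(e, d)
      censored_from_column(mom, col, table$x, table$width, d, threshold)$mean
    }
    f <- function(d) cmean(d) - mean
    # raise the lower bracket past depths where the loss is numerically 1
    lo <- depth_range[1]
    hi <- min(max(2 * mean, 1), depth_range[2])
    flo <- tryCatch(f(lo), error = function(err) NA_real_)
    while (!is.finite(flo) && lo < hi) {
      lo <- lo * 10
      flo <- tryCatch(f(lo), error = function(err) NA_real_)
    }
    if (!is.finite(flo) || flo > 0) {
      return(list(depth = lo, ok = FALSE, col = col))
    }
    while (f(hi) < 0 && hi < depth_range[2]) hi <- min(hi * 10, depth_range[2])
    if (f(hi) < 0) {
      return(list(depth = hi, ok = FALSE, col = col))
    }
    d <- stats::uniroot(f, c(lo, hi), tol = 1e-9 * max(1, mean))$root
    list(depth = d, ok = TRUE, col = col)
  }

  cvar_resid <- function(e) {
    fit <- solve_depth(e)
    mom <- umi_read_moments(e, fit$depth)
    cm <- censored_from_column(
      mom, fit$col, table$x, table$width,
      fit$depth, threshold
    )
    list(resid = cm$variance - variance, depth = fit$depth, depth_ok = fit$ok)
  }

  hi_fit <- cvar_resid(e_hi)
  if (!hi_fit$depth_ok || hi_fit$resid >= 0) {
    # under-dispersed relative to the (near-)Poisson limit: clamp E high
    return(list(
      efficiency = e_hi, depth = hi_fit$depth,
      converged = hi_fit$depth_ok && abs(hi_fit$resid) < 1e-6 * max(1, variance),
      at_boundary = TRUE
    ))
  }
  lo_fit <- cvar_resid(e_lo)
  if (!lo_fit$depth_ok || lo_fit$resid <= 0) {
    # more dispersed than the model can express: clamp E low
    return(list(
      efficiency = e_lo, depth = lo_fit$depth,
      converged = FALSE, at_boundary = TRUE
    ))
  }
  # The residual is monotone across the table's efficiency nodes but deep
  # censoring can make it wiggle between nodes (the interpolated tail there
  # rests on few Monte-Carlo draws). Scan the nodes first: an (essentially)
  # exact node root is returned as-is, otherwise Brent runs inside the single
  # bracketing inter-node interval.
  nodes <- c(e_lo, table$e[table$e > e_lo & table$e < e_hi], e_hi)
  fits <- vector("list", length(nodes))
  fits[[1]] <- lo_fit
  fits[[length(nodes)]] <- hi_fit
  for (i in seq(2, length(nodes) - 1)) fits[[i]] <- cvar_resid(nodes[i])
  ok <- vapply(fits, `[[`, logical(1), "depth_ok")
  resid <- vapply(fits, `[[`, numeric(1), "resid")

  zero_tol <- 1e-9 * max(1, variance)
  exact <- which(ok & abs(resid) < zero_tol)
  if (length(exact) > 0) {
    best <- exact[which.min(abs(resid[exact]))]
    return(list(
      efficiency = nodes[best], depth = fits[[best]]$depth,
      converged = TRUE, at_boundary = FALSE
    ))
  }
  # bracketing intervals between usable nodes; when deep-censoring noise
  # yields several crossings, take the steepest (largest residual drop)
  usable <- which(ok)
  li <- usable[-length(usable)]
  ri <- usable[-1]
  cross <- which(resid[li] > 0 & resid[ri] < 0)
  if (length(cross) == 0) {
    stop("no efficiency bracket found despite boundary sign change")
  }
  pick <- cross[which.max(resid[li][cross] - resid[ri][cross])]
  root <- stats::uniroot(function(e) cvar_resid(e)$resid,
    c(nodes[li[pick]], nodes[ri[pick]]),
    f.lower = resid[li[pick]], f.upper = resid[ri[pick]], tol = 1e-7
  )
  e_hat <- root$root
  d_hat <- solve_depth(e_hat)$depth
  list(efficiency = e_hat, depth = d_hat, converged = TRUE, at_boundary = FALSE)
}

#' Loss implied by a fitted read-count model
#'
#' @param fit A [fit_readcount_model()] result.
#' @inheritParams umi_censored_moments
#' @return The model loss `P(C < T)` at the fitted parameters.
#' @export
estimate_loss <- function(fit, threshold, table) {
  umi_loss(fit$efficiency, fit$depth, threshold, table)
}

#' Correct an observed UMI count for lost molecules
#'
#' Scales the observed number of surviving UMIs up by the estimated loss:
#' `n_total = n_obs / (1 - loss)`. The corrected count is real-valued; round
#' only for display.
#'
#' @param n_obs Observed UMIs after threshold filtering (vectorised).
#' @param loss Estimated loss in \[0, 1) (vectorised).
#' @return Estimated total molecule count(s), `n_obs / (1 - loss)`.
#' @export
correct_count <- function(n_obs, loss) {
  if (any(!is.finite(loss)) || any(loss < 0) || any(loss >= 1)) {
    stop("`loss` must lie in [0, 1)")
  }
  stopifnot(all(n_obs >= 0))
  n_obs / (1 - loss)
}
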