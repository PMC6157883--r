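#' Regression weight for the shrinkage prior fit
#'
#' Weight given to a gene with `n` observed UMIs in the weighted
#' least-squares fit of the shrinkage prior: `w(n) = n / (1 + n/100)`. The
#' weight grows linearly for small `n` and saturates at 100, which keeps the
#' fit focused on genes with a moderate number of observations — the ones
#' that actually benefit from shrinkage — rather than on the noisiest genes.
#'
#' @param n Number of observed UMIs (vectorised, non-negative).
#' @return Weights `n / (1 + n/100)`, in `[0, 100)`.
#' @export
shrinkage_weight <- function(n) {
  stopifnot(all(n >= 0))
  n / (1 + n / 100)
}

#' Fit the shrinkage prior (between-gene and estimator variance)
#'
#' Under the shrinkage model the expected squared deviation of a raw
#' gene-specific loss estimate from the mean raw loss decomposes as
#' `E(loss_raw - loss_bar)^2 = s + u / n_obs`: a between-gene variance `s`
#' of the true loss plus an estimator variance inversely proportional to the
#' number of observed UMIs. `s` and `u` are fitted by weighted least squares
#' with weights [shrinkage_weight()], constrained to be non-negative
#' (a negative unconstrained coordinate is pinned at zero and the other
#' coordinate re-solved).
#'
#' @param loss_raw Raw per-gene loss estimates (only genes with a valid raw
#'   fit).
#' @param n_obs Observed UMIs per gene, same length as `loss_raw`.
#' @param loss_all Library-wide loss estimate (stored in the prior for
#'   downstream shrinking).
#' @return A list of class `shrinkage_prior` with `loss_all`, `loss_bar`,
#'   `s`, `u`.
#' @export
fit_shrinkage_prior <- function(loss_raw, n_obs, loss_all) {
  stopifnot(length(loss_raw) == length(n_obs))
  keep <- is.finite(loss_raw) & is.finite(n_obs) & n_obs > 0
  loss_raw <- loss_raw[keep]
  n_obs <- n_obs[keep]
  if (length(loss_raw) < 2 || length(unique(n_obs)) < 2) {
    warning(
      "fewer than 2 genes with valid raw losses and distinct UMI counts; ",
      "falling back to pure library-wide shrinkage (s = 0)"
    )
    return(structure(
      list(
        loss_all = loss_all,
        loss_bar = if (length(loss_raw)) mean(loss_raw) else loss_all,
        s = 0, u = 0
      ),
      class = "shrinkage_prior"
    ))
  }
  loss_bar <- mean(loss_raw)
  y <- (loss_raw - loss_bar)^2
  w <- shrinkage_weight(n_obs)
  x <- 1 / n_obs

  wls <- function(fit_s, fit_u) {
    # solve min sum w (y - s - u x)^2 over the free coordinates
    if (fit_s && fit_u) {
      xm <- cbind(1, x)
      beta <- solve(crossprod(xm, w * xm), crossprod(xm, w * y))
      c(s = beta[1], u = beta[2])
    } else if (fit_s) {
      c(s = sum(w * y) / sum(w), u = 0)
    } else if (fit_u) {
      c(s = 0, u = sum(w * x * y) / sum(w * x^2))
    } else {
      c(s = 0, u = 0)
    }
  }
  beta <- wls(TRUE, TRUE)
  if (beta["s"] < 0) beta <- wls(FALSE, TRUE)
  if (beta["u"] < 0) beta <- wls(TRUE, FALSE)
  beta <- pmax(beta, 0)
  structure(
    list(
      loss_all = loss_all, loss_bar = loss_bar,
      s = unname(beta["s"]), u = unname(beta["u"])
    ),
    class = "shrinkage_prior"
  )
}

#' @export
print.shrinkage_prior <- function(x, ...) {
  cat(sprintf(
    "<shrinkage_prior> loss_all=%.4g loss_bar=%.4g s=%.4g u=%.4g\n",
    x$loss_all, x$loss_bar, x$s, x$u
  ))
  invisible(x)
}

#' Optimal shrinkage coefficient for a gene
#'
#' `lambda = s / (s + u / n)`: the fraction of weight the raw gene-specific
#' loss estimate receives. Genes with many observed UMIs (precise raw
#' estimates) get `lambda` near 1, poorly observed genes are shrunk towards
#' the library-wide loss. Defined as 0 when `s + u/n` vanishes.
#'
#' @param prior A [fit_shrinkage_prior()] object.
#' @param n Observed UMIs (vectorised, positive).
#' @return Shrinkage coefficients in `[0, 1]`.
#' @export
shrinkage_lambda <- function(prior, n) {
  stopifnot(inherits(prior, "shrinkage_prior"), all(n > 0))
  denom <- prior$s + prior$u / n
  ifelse(denom > 0, prior$s / denom, 0)
}

#' Shrink a raw loss estimate towards the library-wide loss
#'
#' The James-Stein-type combination
#' `loss_shr = lambda * loss_raw + (1 - lambda) * loss_all`, clamped to
#' `[0, 1)` so it can always be used in the count correction.
#'
#' @param loss_raw Raw gene-specific loss estimates.
#' @param loss_all Library-wide loss estimate.
#' @param lambda Shrinkage coefficients in `[0, 1]`.
#' @return Shrunken loss estimates.
#' @export
shrink_loss <- function(loss_raw, loss_all, lambda) {
  check_probability(lambda, "lambda")
  out <- lambda * loss_raw + (1 - lambda) * loss_all
  pmin(pmax(out, 0), 1 - 1e-12)
}
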