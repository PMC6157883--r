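#' Phantom-filter, estimate and loss-correct a UMI library
#'
#' The full correction pipeline: (1) filter UMIs below the error-correction
#' threshold; (2) fit the amplification/sequencing model (efficiency E, depth
#' D) to the pooled censored reads-per-UMI distribution and to each gene with
#' at least two surviving UMIs, derive the implied losses, and stabilise the
#' per-gene losses by James-Stein-type shrinkage towards the library-wide
#' value; (3) scale each gene's observed UMI count up by its shrunken loss,
#' `n_corrected = n_obs / (1 - loss_shr)`.
#'
#' Genes whose raw fit is unavailable (fewer than two surviving UMIs, or a
#' failed moment inversion) receive the library-wide loss (`lambda = 0`) and
#' are excluded from the shrinkage-prior regression; their number is
#' reported in the summary.
#'
#' @param table UMI table (columns `gene`, `umi`, `reads`), filtered or not.
#' @param threshold Error-correction threshold T (reads, non-negative
#'   integer). The choice is the user's; see [threshold_scan()] for
#'   diagnostics supporting it.
#' @param density_table A [build_density_table()] object covering the
#'   plausible efficiency range.
#' @param umis_per_molecule Divisor applied to corrected counts for
#'   protocols where each original template yields that many independently
#'   amplified UMI-carrying molecules (e.g. 2 when both strands of a
#'   double-stranded template are labelled); default 1.
#' @return An object of class `umi_fit` with components `genes` (per-gene
#'   tibble: `gene`, `n_obs`, `efficiency_raw`, `depth_raw`, `loss_raw`,
#'   `lambda`, `efficiency_shr`, `depth_shr`, `loss_shr`, `n_corrected`,
#'   `n_corrected_rounded`), `summary` (library-wide one-row tibble),
#'   `diagnostics` (observed vs predicted UMIs per read count) and `prior`
#'   (the fitted shrinkage prior). See [tidy.umi_fit()], [glance.umi_fit()]
#'   and [autoplot.umi_fit()].
#' @export
umi_correct <- function(table, threshold, density_table,
                        umis_per_molecule = 1) {
  check_count(threshold, "threshold")
  stopifnot(umis_per_molecule >= 1)
  filtered <- apply_read_threshold(table, threshold)
  if (nrow(filtered) == 0) {
    stop("no UMIs survive the threshold T = ", threshold)
  }

  lib <- umi_sample_moments(filtered$reads, threshold)
  lib_fit <- tryCatch(
    fit_readcount_model(lib$mean, lib$variance, threshold, density_table),
    error = function(e) {
      stop(
        "library-wide fit failed (n = ", lib$n_obs, ", mean = ",
        signif(lib$mean, 4), ", variance = ", signif(lib$variance, 4),
        "): ", conditionMessage(e)
      )
    }
  )
  loss_all <- estimate_loss(lib_fit, threshold, density_table)

  fit_one <- function(reads) {
    sm <- umi_sample_moments(reads, threshold)
    if (sm$n_obs < 2 || !is.finite(sm$variance)) {
      return(tibble::tibble(
        n_obs = sm$n_obs, efficiency_raw = NA_real_,
        depth_raw = NA_real_, loss_raw = NA_real_
      ))
    }
    fit <- tryCatch(
      fit_readcount_model(sm$mean, sm$variance, threshold, density_table),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(tibble::tibble(
        n_obs = sm$n_obs, efficiency_raw = NA_real_,
        depth_raw = NA_real_, loss_raw = NA_real_
      ))
    }
    tibble::tibble(
      n_obs = sm$n_obs, efficiency_raw = fit$efficiency,
      depth_raw = fit$depth,
      loss_raw = estimate_loss(fit, threshold, density_table)
    )
  }

  genes <- filtered |>
    dplyr::summarise(fit = list(fit_one(.data$reads)), .by = "gene") |>
    tidyr::unnest("fit")

  prior <- withCallingHandlers(
    fit_shrinkage_prior(genes$loss_raw, genes$n_obs, loss_all),
    warning = function(w) invokeRestart("muffleWarning")
  )
  genes <- genes |>
    dplyr::mutate(
      lambda = dplyr::if_else(
        is.finite(.data$loss_raw),
        shrinkage_lambda(prior, pmax(.data$n_obs, 1)),
        0
      ),
      loss_shr = dplyr::if_else(
        is.finite(.data$loss_raw),
        shrink_loss(.data$loss_raw, loss_all, .data$lambda),
        loss_all
      ),
      # the same lambda applied to E and D for reporting; the count
      # correction below uses loss_shr only
      efficiency_shr = dplyr::if_else(
        is.finite(.data$efficiency_raw),
        .data$lambda * .data$efficiency_raw + (1 - .data$lambda) * lib_fit$efficiency,
        lib_fit$efficiency
      ),
      depth_shr = dplyr::if_else(
        is.finite(.data$depth_raw),
        .data$lambda * .data$depth_raw + (1 - .data$lambda) * lib_fit$depth,
        lib_fit$depth
      ),
      n_corrected = correct_count(.data$n_obs, .data$loss_shr) / umis_per_molecule,
      n_corrected_rounded = round(.data$n_corrected)
    ) |>
    dplyr::select(
      "gene", "n_obs", "efficiency_raw", "depth_raw", "loss_raw",
      "lambda", "efficiency_shr", "depth_shr", "loss_shr",
      "n_corrected", "n_corrected_rounded"
    )

  diagnostics <- readcount_diagnostics(
    table, threshold, lib_fit, density_table
  )

  summary <- tibble::tibble(
    threshold = threshold,
    efficiency = lib_fit$efficiency,
    depth = lib_fit$depth,
    loss = loss_all,
    n_obs = lib$n_obs,
    n_total = correct_count(lib$n_obs, loss_all) / umis_per_molecule,
    n_genes = nrow(genes),
    n_genes_fallback = sum(!is.finite(genes$loss_raw)),
    at_boundary = lib_fit$at_boundary
  )

  structure(
    list(
      genes = genes, summary = summary, diagnostics = diagnostics,
      prior = prior, threshold = threshold
    ),
    class = "umi_fit"
  )
}

# Observed reads-per-UMI histogram (including counts below the threshold,
# for comparison) against the fitted model prediction scaled so that the
# predicted mass at k >= T matches the number of surviving UMIs.
readcount_diagnostics <- function(table, threshold, lib_fit, density_table) {
  k_max <- max(table$reads, threshold)
  k <- 0:k_max
  observed <- c(0, tabulate(table$reads, nbins = k_max))
  pmf <- umi_read_pmf(k, lib_fit$efficiency, lib_fit$depth, density_table)
  loss <- umi_loss(lib_fit$efficiency, lib_fit$depth, threshold, density_table)
  n_surviving <- sum(observed[k >= threshold])
  tibble::tibble(
    k = k, observed = observed,
    predicted = pmf * n_surviving / (1 - loss),
    below_threshold = k < threshold
  )
}

#' Library-wide fits across candidate thresholds
#'
#' Re-runs the library-wide model fit at each candidate error-correction
#' threshold and tabulates, per candidate, the fitted parameters, loss and
#' corrected total, plus observed-versus-predicted reads-per-UMI histograms.
#' The intended use mirrors how a threshold is chosen in practice: pick the
#' lowest T at which the observed distribution above T matches the
#' prediction, while counts below T (phantom territory) exceed it. The
#' choice itself stays with the user.
#'
#' @param table UMI table (columns `gene`, `umi`, `reads`).
#' @param thresholds Candidate thresholds (non-negative integers).
#' @param density_table A [build_density_table()] object.
#' @return An object of class `umi_threshold_scan`: list with `summary`
#'   (one row per candidate: `threshold`, `n_obs`, `efficiency`, `depth`,
#'   `loss`, `n_total`, `converged`) and `histograms` (per candidate and
#'   read count: `observed`, `predicted`, `below_threshold`). Per-candidate
#'   fit failures yield `NA` rows, not errors.
#' @export
threshold_scan <- function(table, thresholds, density_table) {
  stopifnot(length(thresholds) > 0)
  one <- function(threshold) {
    filtered <- apply_read_threshold(table, threshold)
    sm <- umi_sample_moments(filtered$reads, threshold)
    fit <- tryCatch(
      fit_readcount_model(sm$mean, sm$variance, threshold, density_table),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(list(
        summary = tibble::tibble(
          threshold = threshold, n_obs = sm$n_obs, efficiency = NA_real_,
          depth = NA_real_, loss = NA_real_, n_total = NA_real_,
          converged = FALSE
        ),
        histogram = NULL
      ))
    }
    loss <- estimate_loss(fit, threshold, density_table)
    list(
      summary = tibble::tibble(
        threshold = threshold, n_obs = sm$n_obs, efficiency = fit$efficiency,
        depth = fit$depth, loss = loss,
        n_total = correct_count(sm$n_obs, loss),
        converged = fit$converged
      ),
      histogram = dplyr::mutate(
        readcount_diagnostics(table, threshold, fit, density_table),
        threshold = threshold, .before = 1
      )
    )
  }
  scans <- purrr::map(sort(unique(thresholds)), one)
  structure(
    list(
      summary = purrr::list_rbind(purrr::map(scans, "summary")),
      histograms = purrr::list_rbind(purrr::compact(purrr::map(scans, "histogram")))
    ),
    class = "umi_threshold_scan"
  )
}

#' @export
print.umi_fit <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0(
      "<umi_fit> T=%d; library-wide E=%.3f, D=%.3f, loss=%.3f\n",
      "  %d UMIs over %d genes (%d without raw fit); corrected total %.1f\n"
    ),
    s$threshold, s$efficiency, s$depth, s$loss,
    s$n_obs, s$n_genes, s$n_genes_fallback, sum(x$genes$n_corrected)
  ))
  invisible(x)
}

#' @export
print.umi_threshold_scan <- function(x, ...) {
  cat("<umi_threshold_scan>\n")
  print(x$summary)
  invisible(x)
}

#' Per-gene results of a UMI correction fit
#'
#' @param x A [umi_correct()] result.
#' @param ... Unused.
#' @return The per-gene tibble (raw and shrunken parameter estimates,
#'   shrinkage coefficient, losses, corrected counts), one row per gene.
#' @export
tidy.umi_fit <- function(x, ...) {
  x$genes
}

#' One-row library-wide summary of a UMI correction fit
#'
#' @param x A [umi_correct()] result.
#' @param ... Unused.
#' @return A one-row tibble with the library-wide parameter estimates, loss,
#'   UMI counts and fallback diagnostics.
#' @export
glance.umi_fit <- function(x, ...) {
  x$summary
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
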