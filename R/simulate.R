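#' Draw normalized family sizes, fast, from a density table
#'
#' Inverse-CDF sampling on the piecewise-linear CDF implied by a
#' pre-computed density table — orders of magnitude faster than re-running
#' the branching process per molecule, and validated against it by
#' Kolmogorov-Smirnov distance in the test-suite.
#'
#' @param n Number of draws.
#' @param efficiency Efficiency within the table's grid range.
#' @param table A [build_density_table()] object; if `NULL` the branching
#'   process is simulated directly.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` normalized family sizes.
#' @export
sample_family_sizes <- function(n, efficiency, table = NULL, seed = NULL) {
  if (is.null(table)) {
    return(simulate_normalized_family(n, efficiency, seed = seed))
  }
  col <- fsd_column(table, efficiency)
  mass <- col * table$width
  cdf <- c(0, cumsum(mass)) / sum(mass)
  with_seed_if(seed, {
    u <- stats::runif(n)
    # invert the piecewise-linear CDF over the bin breaks
    stats::approx(cdf, table$breaks, xout = u, ties = "ordered", rule = 2)$y
  })
}

#' Simulate per-UMI read counts for one gene
#'
#' The generative model of the whole package: every one of `n_true`
#' molecules is amplified into a family with normalized size
#' `F ~ f_F(.; E)` and sequenced to a read count `C | F ~ Poisson(F * D)`.
#' Zero counts are included (those molecules would be unobserved).
#'
#' @param n_true True number of molecules.
#' @param efficiency PCR efficiency of the gene.
#' @param depth Mean reads per UMI of the gene.
#' @param table Optional density table for fast family-size sampling.
#' @param seed Optional integer seed.
#' @return Integer vector of `n_true` read counts (zeros included).
#' @export
simulate_gene_counts <- function(n_true, efficiency, depth, table = NULL,
                                 seed = NULL) {
  check_count(n_true, "n_true")
  stopifnot(depth > 0)
  with_seed_if(seed, {
    f <- sample_family_sizes(n_true, efficiency, table = table)
    stats::rpois(n_true, f * depth)
  })
}

#' Simulate a UMI library from per-gene scenarios
#'
#' Applies [simulate_gene_counts()] to every row of a scenario table and
#' emits the canonical per-UMI read-count table. UMIs with zero reads are
#' omitted (they are unobservable); optionally, phantom UMIs — artifacts
#' with no molecule of origin and characteristically low read counts — are
#' injected at `phantom_rate` expected phantoms per true molecule, with read
#' counts `1 + Geometric` with mean `phantom_mean_reads`. A `phantom` column
#' records the ground truth for evaluation; drop it to obtain the table a
#' real experiment would yield.
#'
#' @param scenarios Data frame with columns `gene`, `n_true`, `efficiency`,
#'   `depth` (one row per gene, unique gene ids).
#' @param phantom_rate Expected phantom UMIs per true molecule (default 0).
#' @param phantom_mean_reads Mean read count of a phantom UMI (at least 1).
#' @param table Optional density table for fast family-size sampling.
#' @param seed Optional integer seed; the whole library is reproduced
#'   bit-for-bit for a given seed.
#' @return A tibble with columns `gene`, `umi`, `reads`, `phantom`.
#' @export
simulate_umi_library <- function(scenarios, phantom_rate = 0,
                                 phantom_mean_reads = 1.5, table = NULL,
                                 seed = NULL) {
  stopifnot(
    is.data.frame(scenarios),
    all(c("gene", "n_true", "efficiency", "depth") %in% names(scenarios)),
    !anyDuplicated(scenarios$gene),
    all(scenarios$n_true >= 0),
    phantom_rate >= 0, phantom_mean_reads >= 1
  )
  with_seed_if(seed, {
    per_gene <- purrr::pmap(
      list(scenarios$gene, scenarios$n_true, scenarios$efficiency, scenarios$depth),
      function(gene, n_true, efficiency, depth) {
        reads <- simulate_gene_counts(n_true, efficiency, depth, table = table)
        n_phantom <- if (phantom_rate > 0) stats::rpois(1, phantom_rate * n_true) else 0L
        phantom_reads <- if (n_phantom > 0) {
          1L + stats::rgeom(n_phantom, prob = 1 / phantom_mean_reads)
        } else {
          integer(0)
        }
        umi <- c(
          sprintf("umi%06d", seq_along(reads)),
          sprintf("phantom%06d", seq_len(n_phantom))
        )
        is_phantom <- rep(c(FALSE, TRUE), c(length(reads), n_phantom))
        tibble::tibble(
          gene = gene, umi = umi,
          reads = c(reads, phantom_reads), phantom = is_phantom
        )
      }
    )
    dplyr::filter(purrr::list_rbind(per_gene), .data$reads >= 1)
  })
}

#' Rescale scenario depths to a target mean
#'
#' Multiplies every gene's depth by one common factor so that the unweighted
#' mean depth across genes equals `target_mean_depth` — the device used to
#' study behaviour at low sequencing depth (e.g. a library re-scaled to an
#' average of 1 read per molecule) while preserving relative depth
#' differences between genes.
#'
#' @param scenarios Scenario data frame (see [simulate_umi_library()]).
#' @param target_mean_depth Desired unweighted mean of the `depth` column.
#' @return The scenarios with rescaled `depth`.
#' @export
scale_depths <- function(scenarios, target_mean_depth) {
  stopifnot(nrow(scenarios) > 0, target_mean_depth > 0)
  m <- mean(scenarios$depth)
  if (m <= 0) {
    stop("mean depth is zero; cannot rescale")
  }
  dplyr::mutate(scenarios, depth = .data$depth * target_mean_depth / m)
}
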