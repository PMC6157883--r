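#' Read a per-UMI read-count table
#'
#' Two input layouts are supported. The canonical layout has one row per UMI
#' with columns `gene`, `umi`, `reads`; duplicated `(gene, umi)` pairs are
#' summed with a warning. The `umi-group` layout is the per-read table
#' emitted by UMI-grouping tools (one row per read, with a `gene` column and
#' the deduplicated UMI in `final_umi` or `umi`); rows are counted per
#' `(gene, umi)` pair.
#'
#' @param path Path to a tab-separated file with a header.
#' @param format `"canonical"` or `"umi-group"`.
#' @return A tibble with columns `gene`, `umi`, `reads` (reads >= 1).
#' @export
read_umi_table <- function(path, format = c("canonical", "umi-group")) {
  format <- match.arg(format)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tbl) == 0) {
    stop("empty UMI table: ", path)
  }
  if (format == "umi-group") {
    umi_col <- if ("final_umi" %in% names(tbl)) "final_umi" else "umi"
    missing <- setdiff(c("gene", umi_col), names(tbl))
    if (length(missing) > 0) {
      stop(path, ": missing column(s) ", paste(missing, collapse = ", "))
    }
    return(
      tbl |>
        dplyr::count(gene = .data$gene, umi = .data[[umi_col]], name = "reads") |>
        tibble::as_tibble()
    )
  }
  missing <- setdiff(c("gene", "umi", "reads"), names(tbl))
  if (length(missing) > 0) {
    stop(path, ": missing column(s) ", paste(missing, collapse = ", "))
  }
  bad <- which(!is.finite(tbl$reads) | tbl$reads < 1 | tbl$reads != round(tbl$reads))
  if (length(bad) > 0) {
    stop(sprintf(
      "%s: line %d: `reads` must be a positive integer (got %s)",
      path, bad[1] + 1L, tbl$reads[bad[1]]
    ))
  }
  if (anyDuplicated(tbl[c("gene", "umi")])) {
    warning("duplicate (gene, umi) rows in ", path, "; read counts summed")
    tbl <- dplyr::summarise(tbl,
      reads = sum(.data$reads),
      .by = c("gene", "umi")
    )
  }
  tibble::as_tibble(tbl[c("gene", "umi", "reads")])
}

#' Filter phantom UMIs by read-count threshold
#'
#' Removes every UMI with fewer than `threshold` reads — the error-correction
#' step that discards likely phantoms (which concentrate at low read counts)
#' at the price of also discarding some true UMIs; the loss model quantifies
#' and corrects that price. Thresholds 0 and 1 remove nothing, since UMIs
#' with zero reads are never observed in the first place.
#'
#' @param table A UMI table (columns `gene`, `umi`, `reads`).
#' @param threshold Minimum read count T (non-negative integer).
#' @return The filtered table.
#' @export
apply_read_threshold <- function(table, threshold) {
  check_count(threshold, "threshold")
  dplyr::filter(table, .data$reads >= threshold)
}

#' Write pipeline results to tab-separated files
#'
#' Emits the per-gene table, the library-wide summary and the reads-per-UMI
#' diagnostics of a [umi_correct()] fit, each as a TSV with a header and
#' doubles at 6 significant digits.
#'
#' @param fit A [umi_correct()] result.
#' @param genes_path,summary_path,diagnostics_path Output paths; `NULL`
#'   skips the corresponding file.
#' @return The fit, invisibly.
#' @export
write_umi_results <- function(fit, genes_path = NULL, summary_path = NULL,
                              diagnostics_path = NULL) {
  stopifnot(inherits(fit, "umi_fit"))
  emit <- function(tbl, path) {
    tbl <- dplyr::mutate(tbl, dplyr::across(dplyr::where(is.double), ~ signif(.x, 6)))
    tryCatch(
      readr::write_tsv(tbl, path, progress = FALSE),
      error = function(e) stop("failed to write ", path, ": ", conditionMessage(e))
    )
  }
  if (!is.null(genes_path)) emit(fit$genes, genes_path)
  if (!is.null(summary_path)) emit(fit$summary, summary_path)
  if (!is.null(diagnostics_path)) emit(fit$diagnostics, diagnostics_path)
  invisible(fit)
}
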