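#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-feature results of a pipeline run
#'
#' @param x A `glyco_pipeline` object.
#' @param branch `"glyco"` (default) or `"protein"`.
#' @param ... Unused.
#' @return The differential-result tibble of the requested branch, with
#'   occupancy calls joined in for the glyco branch when available.
#' @method tidy glyco_pipeline
#' @export
tidy.glyco_pipeline <- function(x, branch = c("glyco", "protein"), ...) {
  branch <- match.arg(branch)
  if (branch == "protein") {
    return(x$protein_results)
  }
  res <- x$glyco_results
  if (!is.null(x$crossref)) {
    res <- dplyr::left_join(
      res,
      x$crossref$calls[, c("feature_id", "call")],
      by = "feature_id"
    ) |>
      dplyr::rename(occupancy_call = "call")
  }
  res
}

#' One-row summary of a pipeline run
#'
#' @param x A `glyco_pipeline` object.
#' @param ... Unused.
#' @return A one-row tibble of the headline counts and statistics.
#' @method glance glyco_pipeline
#' @export
glance.glyco_pipeline <- function(x, ...) {
  pr <- x$protein_results
  gr <- x$glyco_results
  n_sig <- sum(gr$status %in% c("decreased", "increased"))
  e <- x$enrichment
  tibble(
    n_protein_features = x$n_protein_features,
    n_protein_tested = nrow(pr),
    n_dap = sum(pr$status != "unchanged"),
    n_dap_decreased = sum(pr$status == "decreased"),
    n_glyco_features = x$n_glyco_features,
    n_glyco_testable = sum(!gr$status %in%
                             c("exclusive_control", "exclusive_mutant")),
    n_glyco_decreased = sum(gr$status == "decreased"),
    n_glyco_increased = sum(gr$status == "increased"),
    n_exclusive_control = sum(gr$status == "exclusive_control"),
    n_exclusive_mutant = sum(gr$status == "exclusive_mutant"),
    decreased_fraction_of_significant =
      if (n_sig > 0) sum(gr$status == "decreased") / n_sig else NA_real_,
    n_reference_sites = nrow(x$reference),
    n_novel_sites = x$novel_summary$n_novel,
    glycoprotein_enrichment_fold =
      if (!is.null(e$glycoprotein_in_decreased))
        e$glycoprotein_in_decreased$fold_enrichment else NA_real_,
    glycoprotein_enrichment_p =
      if (!is.null(e$glycoprotein_in_decreased))
        e$glycoprotein_in_decreased$p_value else NA_real_,
    n_unoccupied_in_mutant =
      if (!is.null(x$crossref))
        sum(x$crossref$calls$call == "unoccupied_in_mutant") else NA_integer_
  )
}
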