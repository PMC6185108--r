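#' Cross-reference decreased glycosites against total-proteome evidence
#'
#' A decreased (or control-exclusive) glycosite whose unmodified counterpart
#' peptide is detected in at least `k` mutant samples but never in control
#' samples is called `unoccupied_in_mutant`: the site exists unmodified in the
#' mutant, so its loss of glyco signal reflects loss of occupancy, not loss of
#' the protein. If that pattern fails but the parent protein itself is
#' decreased in the total proteome, the site is `protein_level_change` (a
#' disambiguation category added here); otherwise the occupancy reduction is
#' `occupancy_reduced_unconfirmed`. Sites not decreased pass through as
#' `unchanged`.
#'
#' @param glyco_results Differential-result tibble from [glyco_site_test()].
#' @param unmodified_matrix An unmodified-peptide [quant_matrix()] keyed like
#'   the glycosite features (`"<protein_id>:<position>"`).
#' @param protein_results Differential-result tibble from
#'   [paired_protein_test()] (feature ids = protein ids). May be empty.
#' @param k Minimum mutant detections of the counterpart (default 3, the
#'   exclusive-detection convention).
#' @return A list: `calls` (per-site tibble with `call`, counterpart
#'   detections and parent-protein status) and `summary` (counts per call).
#' @export
crossref_occupancy <- function(glyco_results, unmodified_matrix,
                               protein_results, k = 3) {
  design <- qm_design(unmodified_matrix)
  if (!all(c("control", "mutant") %in% design$genotype)) {
    abort("Counterpart matrix design must contain both genotypes")
  }
  m <- qm_intensities(unmodified_matrix)
  ctrl <- design$sample_id[design$genotype == "control"]
  mut <- design$sample_id[design$genotype == "mutant"]
  cp_ctrl <- rowSums(!is.na(m[, ctrl, drop = FALSE]))
  cp_mut <- rowSums(!is.na(m[, mut, drop = FALSE]))

  idx <- match(glyco_results$feature_id, rownames(m))
  n_cp_ctrl <- ifelse(is.na(idx), 0L, cp_ctrl[idx])
  n_cp_mut <- ifelse(is.na(idx), 0L, cp_mut[idx])

  parent <- parse_site_ids(glyco_results$feature_id)$protein_id
  parent_status <- protein_results$status[
    match(parent, protein_results$feature_id)]
  parent_decreased <- !is.na(parent_status) & parent_status == "decreased"

  candidate <- glyco_results$status %in% c("decreased", "exclusive_control")
  call <- dplyr::case_when(
    !candidate ~ "unchanged",
    n_cp_mut >= k & n_cp_ctrl == 0L ~ "unoccupied_in_mutant",
    parent_decreased ~ "protein_level_change",
    TRUE ~ "occupancy_reduced_unconfirmed"
  )

  calls <- tibble(
    feature_id = glyco_results$feature_id,
    protein_id = parent,
    glyco_status = glyco_results$status,
    counterpart_detected_control = as.integer(n_cp_ctrl),
    counterpart_detected_mutant = as.integer(n_cp_mut),
    parent_protein_status = parent_status,
    call = call
  )
  summary <- calls |>
    dplyr::count(.data$call, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n))
  list(calls = calls, summary = summary)
}
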