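#' Scan protein sequences for canonical N-glycosylation sequons
#'
#' Finds every canonical sequon N-X-S/T (X != Pro) in each protein. Overlapping
#' sequons are all reported; an Asn whose +1/+2 window runs past the C-terminus
#' is not. Positions are 1-based and refer to the Asn residue itself.
#'
#' @param proteins A tibble with columns `protein_id` and `sequence`.
#' @return A site tibble (see [classify_site()]) with `evidence =
#'   "scanned_only"`; zero rows when no sequon exists.
#' @examples
#' scan_sequons(tibble::tibble(protein_id = "P1", sequence = "ANGTM"))
#' @export
scan_sequons <- function(proteins) {
  proteins <- as_tibble(proteins)
  hits <- purrr::map2(proteins$protein_id, proteins$sequence, function(id, seq) {
    m <- gregexpr("N(?=[^P][ST])", seq, perl = TRUE)[[1]]
    pos <- as.integer(m[m > 0])
    if (length(pos) == 0) return(NULL)
    tibble(protein_id = id, position = pos)
  })
  keys <- dplyr::bind_rows(hits)
  if (nrow(keys) == 0) {
    return(empty_site_table())
  }
  classify_site(proteins, keys, evidence = "scanned_only")
}

empty_site_table <- function() {
  tibble(
    protein_id = character(), position = integer(),
    sequon = character(), sequon_class = character(),
    minus2_residue = character(), minus2_aromatic = logical(),
    evidence = character()
  )
}

#' Classify the sequon context of Asn sites
#'
#' For each (protein, position) key, extracts the sequon (residues 0, +1, +2
#' with Asn at 0), assigns the sequon class, and records the -2 residue and
#' its aromaticity (aromatic = Phe, Tyr, His or Trp). Sites at positions 1-2
#' have no -2 context (`NA`); they are excluded only from -2-dependent
#' analyses downstream, not from anything else. Keys whose residue is not Asn
#' are rejected: they signal an evidence/sequence mismatch.
#'
#' Class rule: `NxT` iff the +2 residue is T and +1 is not P; `NxS` iff +2 is S
#' and +1 is not P; everything else (including windows truncated by the
#' C-terminus) is `non_canonical`.
#'
#' @param proteins A tibble with `protein_id`, `sequence`.
#' @param keys A tibble with `protein_id`, `position` (1-based Asn coordinate).
#' @param evidence Evidence label stamped on the returned rows.
#' @return A tibble with columns `protein_id`, `position`, `sequon`,
#'   `sequon_class`, `minus2_residue`, `minus2_aromatic`, `evidence`.
#' @export
classify_site <- function(proteins, keys, evidence = "scanned_only") {
  proteins <- as_tibble(proteins)
  keys <- as_tibble(keys)
  seq <- proteins$sequence[match(keys$protein_id, proteins$protein_id)]
  if (anyNA(seq)) {
    abort(paste0(
      "Site key(s) reference unknown protein(s): ",
      paste(unique(keys$protein_id[is.na(seq)]), collapse = ", ")
    ))
  }
  len <- nchar(seq)
  if (any(keys$position < 1L | keys$position > len)) {
    abort("Site position outside protein sequence")
  }
  res0 <- substr(seq, keys$position, keys$position)
  if (any(res0 != "N")) {
    bad <- which(res0 != "N")[1]
    abort(paste0(
      "Residue at ", keys$protein_id[bad], ":", keys$position[bad],
      " is '", res0[bad], "', not Asn — evidence/sequence mismatch"
    ))
  }
  plus1 <- ifelse(keys$position + 1L <= len,
                  substr(seq, keys$position + 1L, keys$position + 1L), "")
  plus2 <- ifelse(keys$position + 2L <= len,
                  substr(seq, keys$position + 2L, keys$position + 2L), "")
  sequon <- paste0("N", plus1, plus2)
  sequon_class <- dplyr::case_when(
    plus2 == "T" & plus1 != "P" & plus1 != "" ~ "NxT",
    plus2 == "S" & plus1 != "P" & plus1 != "" ~ "NxS",
    TRUE ~ "non_canonical"
  )
  minus2 <- ifelse(keys$position >= 3L,
                   substr(seq, keys$position - 2L, keys$position - 2L),
                   NA_character_)
  tibble(
    protein_id = keys$protein_id,
    position = as.integer(keys$position),
    sequon = sequon,
    sequon_class = sequon_class,
    minus2_residue = minus2,
    minus2_aromatic = ifelse(is.na(minus2), NA, minus2 %in% AROMATIC_RESIDUES),
    evidence = evidence
  )
}

#' Build the evidence-based reference glycoproteome
#'
#' A glycosite becomes part of the reference glycoproteome when its
#' deglycosylated-peptide feature is detected (non-missing) in at least
#' `min_control_detections` control samples; detections in mutant samples do
#' not count towards the criterion. Each retained site is classified from the
#' protein sequence.
#'
#' @param site_matrix A glycosite [quant_matrix()] whose feature ids parse as
#'   `"<protein_id>:<position>"`.
#' @param proteins A tibble with `protein_id`, `sequence`.
#' @param min_control_detections Minimum control detections (default 2).
#' @return A site tibble with `evidence = "reference"`, plus
#'   `n_detected_control` per site.
#' @export
build_reference_glycoproteome <- function(site_matrix, proteins,
                                          min_control_detections = 2) {
  design <- qm_design(site_matrix)
  n_ctrl <- sum(design$genotype == "control")
  if (n_ctrl < min_control_detections) {
    abort("Design has fewer control samples than min_control_detections")
  }
  m <- qm_intensities(site_matrix)
  ctrl_det <- rowSums(!is.na(m[, design$sample_id[design$genotype == "control"],
                               drop = FALSE]))
  keep <- ctrl_det >= min_control_detections
  if (!any(keep)) {
    out <- empty_site_table()
    out$n_detected_control <- integer()
    return(out)
  }
  keys <- parse_site_ids(site_matrix$feature_id[keep])
  sites <- classify_site(proteins, keys, evidence = "reference")
  sites$n_detected_control <- as.integer(ctrl_det[keep])
  sites
}

#' Call likely novel glycosylation sites
#'
#' Reference sites absent from the union of the supplied known-site lists are
#' relabelled `evidence = "novel"`; sites present in any list stay
#' `"reference"`.
#'
#' @param reference A reference site tibble
#'   (from [build_reference_glycoproteome()]).
#' @param known_site_lists A tibble with `protein_id`, `position`, or a list
#'   of such tibbles (e.g. a published atlas plus UniProt annotation).
#' @return The site tibble with updated `evidence`.
#' @seealso [novel_site_summary()]
#' @export
call_novel_sites <- function(reference, known_site_lists) {
  if (is.data.frame(known_site_lists)) {
    known_site_lists <- list(known_site_lists)
  }
  known <- unique(unlist(lapply(known_site_lists, function(k) {
    site_id(k$protein_id, k$position)
  })))
  ids <- site_id(reference$protein_id, reference$position)
  reference$evidence <- ifelse(ids %in% known, "reference", "novel")
  reference
}

#' Summarize novel-site calls
#'
#' @param sites A site tibble after [call_novel_sites()].
#' @return One-row tibble: reference size, novel count, novel fraction, and
#'   the non-canonical-sequon fraction among novel sites.
#' @export
novel_site_summary <- function(sites) {
  n_ref <- nrow(sites)
  novel <- sites[sites$evidence == "novel", , drop = FALSE]
  tibble(
    n_sites = n_ref,
    n_novel = nrow(novel),
    novel_fraction = if (n_ref > 0) nrow(novel) / n_ref else NA_real_,
    non_canonical_novel_fraction =
      if (nrow(novel) > 0) mean(novel$sequon_class == "non_canonical")
      else NA_real_
  )
}

#' Per-protein N-glycosylation multiplicity
#'
#' Multiplicity is the number of distinct reference-glycoproteome positions on
#' a protein; proteins with no reference site get 0 and count as
#' non-glycoproteins downstream. `scanned_multiplicity` (the count of canonical
#' sequons found by scanning the sequence) is reported alongside; enrichment
#' analyses use the evidence-based count.
#'
#' @param reference A reference site tibble.
#' @param proteins A tibble with `protein_id`, `sequence`.
#' @return A tibble with `protein_id`, `multiplicity`, `scanned_multiplicity`.
#' @export
multiplicity_profiles <- function(reference, proteins) {
  proteins <- as_tibble(proteins)
  ref_counts <- reference |>
    dplyr::distinct(.data$protein_id, .data$position) |>
    dplyr::count(.data$protein_id, name = "multiplicity")
  scanned <- scan_sequons(proteins) |>
    dplyr::count(.data$protein_id, name = "scanned_multiplicity")
  proteins |>
    dplyr::select("protein_id") |>
    dplyr::left_join(ref_counts, by = "protein_id") |>
    dplyr::left_join(scanned, by = "protein_id") |>
    dplyr::mutate(
      multiplicity = dplyr::coalesce(.data$multiplicity, 0L),
      scanned_multiplicity = dplyr::coalesce(.data$scanned_multiplicity, 0L)
    )
}
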