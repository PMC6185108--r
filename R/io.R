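#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly multi-line) FASTA file into a protein table. The
#' identifier is the first whitespace-delimited token of each header line;
#' sequences are upper-cased. Duplicate identifiers and empty sequences are
#' rejected.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `protein_id` and `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 demo", "MANG", "TML"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyNA(ids) || any(!nzchar(ids))) {
    bad <- which(!nzchar(ids) | is.na(ids))[1]
    abort(paste0("Malformed FASTA header for record ", bad))
  }
  seqs <- toupper(as.character(aa))
  if (any(!nzchar(seqs))) {
    abort(paste0(
      "Empty sequence for record(s): ",
      paste(ids[!nzchar(seqs)], collapse = ", ")
    ))
  }
  if (anyDuplicated(ids)) {
    abort(paste0(
      "Duplicate protein id(s) in FASTA: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  bad_chars <- grepl(paste0("[^", paste(c(AA_ALPHABET, "X"), collapse = ""), "]"), seqs)
  if (any(bad_chars)) {
    abort(paste0(
      "Non amino-acid characters in sequence(s): ",
      paste(ids[bad_chars], collapse = ", ")
    ))
  }
  tibble(protein_id = unname(ids), sequence = unname(seqs))
}

#' Read a sample-design table
#'
#' The design table is tab-separated with columns `sample_id`, `genotype`
#' (`control` or `mutant`) and `pair_id` (litter/batch pairing, integer >= 1).
#'
#' @param path Path to a TSV file.
#' @return A validated design tibble.
#' @export
read_sample_design <- function(path) {
  design <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    genotype = readr::col_character(),
    pair_id = readr::col_integer()
  ))
  validate_design(design)
}

#' Validate a sample design
#'
#' Checks identifier uniqueness, genotype levels, and (when `paired = TRUE`)
#' that every `pair_id` occurs exactly once per genotype.
#'
#' @param design A design tibble (`sample_id`, `genotype`, `pair_id`).
#' @param paired Require a complete pairing across genotypes?
#' @return The design, invisibly unchanged (columns coerced to standard types).
#' @export
validate_design <- function(design, paired = FALSE) {
  req <- c("sample_id", "genotype", "pair_id")
  if (!all(req %in% names(design))) {
    abort(paste0(
      "Design must have columns: ", paste(req, collapse = ", ")
    ))
  }
  design <- as_tibble(design)
  design$sample_id <- as.character(design$sample_id)
  design$genotype <- as.character(design$genotype)
  design$pair_id <- as.integer(design$pair_id)
  if (anyDuplicated(design$sample_id)) {
    abort("Duplicate sample_id in design")
  }
  if (!all(design$genotype %in% GENOTYPE_LEVELS)) {
    abort("genotype must be 'control' or 'mutant'")
  }
  if (any(is.na(design$pair_id)) || any(design$pair_id < 1L)) {
    abort("pair_id must be integers >= 1")
  }
  if (paired) {
    tab <- table(design$genotype, design$pair_id)
    if (!all(dim(tab) >= c(2L, 1L)) || any(tab != 1L)) {
      abort("Paired design requires each pair_id exactly once per genotype")
    }
  }
  design
}

#' Construct a quantification matrix
#'
#' A `quant_matrix` is a tibble whose first column is `feature_id` and whose
#' remaining columns (one per sample, in design order) hold raw-scale
#' intensities; `NA` encodes a missing (not detected) value, which is distinct
#' from 0 and is never imputed anywhere in the pipeline. The sample design and
#' the feature kind travel as attributes.
#'
#' @param values A data frame with a `feature_id` column and one numeric
#'   column per sample of `design`.
#' @param design A sample-design tibble (see [validate_design()]).
#' @param kind One of `"protein"`, `"glycosite"`, `"unmodified_peptide"`.
#' @return A `quant_matrix` tibble.
#' @export
quant_matrix <- function(values, design,
                         kind = c("protein", "glycosite", "unmodified_peptide")) {
  kind <- match.arg(kind)
  design <- validate_design(design)
  values <- as_tibble(values)
  if (names(values)[1] != "feature_id") {
    abort("First column of a quantification table must be 'feature_id'")
  }
  sample_cols <- setdiff(names(values), "feature_id")
  unknown <- setdiff(sample_cols, design$sample_id)
  if (length(unknown) > 0) {
    abort(paste0(
      "Sample column(s) not in design: ", paste(unknown, collapse = ", ")
    ))
  }
  missing_cols <- setdiff(design$sample_id, sample_cols)
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Design sample(s) absent from table: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  values <- values[, c("feature_id", design$sample_id)]
  if (anyDuplicated(values$feature_id)) {
    abort(paste0(
      "Duplicate feature id(s): ",
      paste(unique(values$feature_id[duplicated(values$feature_id)]),
            collapse = ", ")
    ))
  }
  for (s in design$sample_id) {
    x <- values[[s]]
    if (!is.numeric(x)) abort(paste0("Column ", s, " is not numeric"))
    if (any(!is.na(x) & (x < 0 | !is.finite(x)))) {
      abort(paste0("Negative or non-finite intensity in column ", s))
    }
  }
  structure(values,
    design = design, feature_kind = kind,
    class = c("quant_matrix", class(as_tibble(values)))
  )
}

#' @export
`[.quant_matrix` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && "feature_id" %in% names(out)) {
    attr(out, "design") <- attr(x, "design")
    attr(out, "feature_kind") <- attr(x, "feature_kind")
    class(out) <- class(x)
  }
  out
}

#' @rdname quant_matrix
#' @param x A `quant_matrix`.
#' @export
qm_design <- function(x) attr(x, "design")

#' @rdname quant_matrix
#' @export
qm_kind <- function(x) attr(x, "feature_kind")

#' Intensities of a quant matrix as a base matrix
#'
#' @param x A `quant_matrix`.
#' @return A numeric matrix (features x samples) with `NA` for missing cells,
#'   rownames from `feature_id`.
#' @export
qm_intensities <- function(x) {
  design <- qm_design(x)
  m <- as.matrix(as.data.frame(x)[, design$sample_id, drop = FALSE])
  rownames(m) <- x$feature_id
  m
}

# Subset a quant_matrix to a set of feature ids (order preserved as given).
qm_subset <- function(x, feature_ids) {
  keep <- x[match(feature_ids, x$feature_id), , drop = FALSE]
  quant_matrix(keep, qm_design(x), qm_kind(x))
}

#' Read a quantification table
#'
#' Tab-separated, first column the feature id, remaining columns matching the
#' design's `sample_id`s (any order; reordered to design order). Empty cells
#' and `NA` denote missing values and are preserved as `NA` — never as 0.
#'
#' @param path Path to a TSV file.
#' @inheritParams quant_matrix
#' @return A [quant_matrix()].
#' @export
read_quant_table <- function(path, design,
                             kind = c("protein", "glycosite", "unmodified_peptide")) {
  kind <- match.arg(kind)
  raw <- readr::read_tsv(path,
    na = c("", "NA"),
    col_types = readr::cols(
      .default = readr::col_double(),
      feature_id = readr::col_character()
    )
  )
  if (names(raw)[1] != "feature_id") {
    names(raw)[1] <- "feature_id"
    raw$feature_id <- as.character(raw$feature_id)
  }
  quant_matrix(raw, design, kind)
}

#' Write a result or quantification table
#'
#' Writes any pipeline table as tab-separated text with a header; missing
#' values are written as `NA` so tables round-trip through the matching
#' readers. Numeric values are written at full precision.
#'
#' @param results A data frame (any result table or `quant_matrix`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  readr::write_tsv(as_tibble(results), path, na = "NA")
  invisible(path)
}

#' Read a known-glycosite list
#'
#' Two-column TSV (`protein_id`, `position`, 1-based Asn coordinate), as
#' distilled from published site atlases or UniProt annotation.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `protein_id`, `position`.
#' @export
read_known_sites <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    position = readr::col_integer()
  ))
  if (any(is.na(x$position)) || any(x$position < 1L)) {
    abort("Known-site positions must be integers >= 1")
  }
  x
}

#' Parse glycosite feature ids
#'
#' Glycosite features in quantification tables are keyed
#' `"<protein_id>:<position>"` (1-based Asn coordinate). The position is taken
#' after the final colon, so protein ids containing colons are tolerated.
#'
#' @param feature_ids Character vector of feature ids.
#' @return A tibble with `feature_id`, `protein_id`, `position`.
#' @export
parse_site_ids <- function(feature_ids) {
  pos_txt <- sub("^.*:", "", feature_ids)
  prot <- sub(":[^:]*$", "", feature_ids)
  pos <- suppressWarnings(as.integer(pos_txt))
  bad <- is.na(pos) | pos < 1L | !nzchar(prot) | !grepl(":", feature_ids)
  if (any(bad)) {
    abort(paste0(
      "Feature id(s) not of the form '<protein_id>:<position>': ",
      paste(head(feature_ids[bad], 5), collapse = ", ")
    ))
  }
  tibble(feature_id = feature_ids, protein_id = prot, position = pos)
}

#' Compose glycosite feature ids from protein and position
#'
#' @param protein_id Character vector.
#' @param position Integer vector (1-based Asn coordinate).
#' @return Character vector `"<protein_id>:<position>"`.
#' @export
site_id <- function(protein_id, position) {
  paste0(protein_id, ":", position)
}
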