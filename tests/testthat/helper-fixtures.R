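# In-code fixture builders shared across test files.

toy_design <- function() {
  tibble::tibble(
    sample_id = c("C1", "C2", "C3", "C4", "M1", "M2", "M3", "M4"),
    genotype = rep(c("control", "mutant"), each = 4),
    pair_id = rep(1:4, 2)
  )
}

# rows: named list feature_id -> numeric vector of length 8 (NA = missing)
make_qm <- function(rows, design = toy_design(), kind = "glycosite") {
  m <- do.call(rbind, rows)
  df <- tibble::as_tibble(as.data.frame(m))
  names(df) <- design$sample_id
  quant_matrix(
    dplyr::bind_cols(tibble::tibble(feature_id = names(rows)), df),
    design, kind
  )
}

# detection-pattern row: first n_ctrl control and n_mut mutant cells detected
pattern_row <- function(n_ctrl, n_mut, base = 1000) {
  c(ifelse(seq_len(4) <= n_ctrl, base + seq_len(4), NA),
    ifelse(seq_len(4) <= n_mut, base + 100 + seq_len(4), NA))
}

extdata <- function(name) {
  system.file("extdata", name, package = "glycosens", mustWork = TRUE)
}
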