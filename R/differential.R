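#' Retain only features detected in every sample
#'
#' The total-proteome branch tests only proteins detected in all samples of
#' both genotypes, which avoids any data imputation.
#'
#' @param matrix A [quant_matrix()].
#' @return A list: `retained` (a `quant_matrix`) and `filtered_out`
#'   (character vector of feature ids with at least one missing cell).
#' @export
filter_complete_cases <- function(matrix) {
  m <- qm_intensities(matrix)
  complete <- rowSums(is.na(m)) == 0L
  list(
    retained = qm_subset(matrix, matrix$feature_id[complete]),
    filtered_out = matrix$feature_id[!complete]
  )
}

# Vectorized two-sided paired t on the rows of a difference matrix.
# Agreement with stats::t.test is asserted in the unit tests.
row_paired_t <- function(d) {
  n <- ncol(d)
  mean_d <- unname(rowMeans(d))
  sd_d <- unname(apply(d, 1, sd))
  flag <- rep(NA_character_, nrow(d))
  p <- numeric(nrow(d))
  zero_var <- sd_d == 0
  tstat <- ifelse(zero_var, NA_real_, mean_d / (sd_d / sqrt(n)))
  p <- 2 * pt(-abs(tstat), df = n - 1)
  # zero-variance differences are degenerate: p = 1 for a zero mean shift,
  # the smallest positive double for a perfectly consistent nonzero shift
  p[zero_var & mean_d == 0] <- 1
  p[zero_var & mean_d != 0] <- .Machine$double.xmin
  flag[zero_var] <- "degenerate"
  list(estimate = mean_d, p_value = p, flag = flag)
}

#' Paired differential test for the total proteome
#'
#' Log2-transforms a complete-case matrix, forms within-pair mutant minus
#' control differences, applies a two-sided paired t-test per feature, and
#' controls FDR with Benjamini-Hochberg. A feature is `decreased` /
#' `increased` when `q < alpha_q` with the corresponding sign, else
#' `unchanged`.
#'
#' @param matrix A complete-case [quant_matrix()] with a paired design.
#' @param alpha_q q-value threshold (default 0.05).
#' @return A differential-result tibble: `feature_id`, `log2_fold_change`
#'   (mutant minus control), `p_value`, `q_value`, `status`,
#'   `n_detected_control`, `n_detected_mutant`, `flag`.
#' @export
paired_protein_test <- function(matrix, alpha_q = 0.05) {
  design <- validate_design(qm_design(matrix), paired = TRUE)
  m <- qm_intensities(matrix)
  if (any(is.na(m))) {
    abort("paired_protein_test requires a complete-case matrix")
  }
  if (nrow(m) == 0) {
    return(empty_diff_table())
  }
  pairs <- sort(unique(design$pair_id))
  ctrl_cols <- design$sample_id[match(
    paste0("control", pairs), paste0(design$genotype, design$pair_id))]
  mut_cols <- design$sample_id[match(
    paste0("mutant", pairs), paste0(design$genotype, design$pair_id))]
  d <- log2(m[, mut_cols, drop = FALSE]) - log2(m[, ctrl_cols, drop = FALSE])
  fit <- row_paired_t(d)
  q <- p.adjust(fit$p_value, method = "BH")
  status <- dplyr::case_when(
    q < alpha_q & fit$estimate < 0 ~ "decreased",
    q < alpha_q & fit$estimate > 0 ~ "increased",
    TRUE ~ "unchanged"
  )
  tibble(
    feature_id = matrix$feature_id,
    log2_fold_change = fit$estimate,
    p_value = fit$p_value,
    q_value = q,
    status = status,
    n_detected_control = length(ctrl_cols),
    n_detected_mutant = length(mut_cols),
    flag = fit$flag
  )
}

empty_diff_table <- function() {
  tibble(
    feature_id = character(), log2_fold_change = numeric(),
    p_value = numeric(), q_value = numeric(), status = character(),
    n_detected_control = integer(), n_detected_mutant = integer(),
    flag = character()
  )
}

#' Detection-pattern filter for the glycosite branch
#'
#' Control-anchored filtering: a glycosite is testable when detected in at
#' least `min_control` control samples. Sites detected exclusively in one
#' genotype (zero detections in the other, at least `min_exclusive` in their
#' own) bypass the t-test and are handled by the exclusive-detection rule.
#' The four outcome sets partition the input features; exclusivity takes
#' precedence, so the sets are disjoint.
#'
#' @param matrix A glycosite [quant_matrix()].
#' @param min_control Minimum control detections to test (default 3).
#' @param min_exclusive Minimum same-genotype detections for an exclusive
#'   call (default 3).
#' @return A list: `testable` (a `quant_matrix`), and character vectors
#'   `exclusive_control`, `exclusive_mutant`, `filtered_out`.
#' @export
filter_glyco_sites <- function(matrix, min_control = 3, min_exclusive = 3) {
  design <- qm_design(matrix)
  m <- qm_intensities(matrix)
  ctrl <- design$sample_id[design$genotype == "control"]
  mut <- design$sample_id[design$genotype == "mutant"]
  n_ctrl <- rowSums(!is.na(m[, ctrl, drop = FALSE]))
  n_mut <- rowSums(!is.na(m[, mut, drop = FALSE]))
  excl_ctrl <- n_mut == 0L & n_ctrl >= min_exclusive
  excl_mut <- n_ctrl == 0L & n_mut >= min_exclusive
  testable <- !excl_ctrl & !excl_mut & n_ctrl >= min_control
  rest <- !excl_ctrl & !excl_mut & !testable
  list(
    testable = qm_subset(matrix, matrix$feature_id[testable]),
    exclusive_control = matrix$feature_id[excl_ctrl],
    exclusive_mutant = matrix$feature_id[excl_mut],
    filtered_out = matrix$feature_id[rest],
    detections = tibble(
      feature_id = matrix$feature_id,
      n_detected_control = as.integer(n_ctrl),
      n_detected_mutant = as.integer(n_mut)
    )
  )
}

# Vectorized two-sided two-sample t on log2 values with missing cells;
# Welch by default, pooled variance optionally. Cross-checked against
# stats::t.test in the unit tests.
row_two_sample_t <- function(x_mat, y_mat, var_equal = FALSE) {
  nx <- unname(rowSums(!is.na(x_mat)))
  ny <- unname(rowSums(!is.na(y_mat)))
  mx <- unname(rowMeans(x_mat, na.rm = TRUE))
  my <- unname(rowMeans(y_mat, na.rm = TRUE))
  vx <- unname(apply(x_mat, 1, var, na.rm = TRUE))
  vy <- unname(apply(y_mat, 1, var, na.rm = TRUE))
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  est <- mx - my
  tstat <- est / se
  p <- 2 * pt(-abs(tstat), df = df)
  zero_var <- se == 0 | is.na(se)
  flag <- rep(NA_character_, length(p))
  p[zero_var & est == 0] <- 1
  p[zero_var & est != 0] <- .Machine$double.xmin
  flag[zero_var] <- "degenerate"
  list(estimate = est, p_value = p, flag = flag)
}

#' Unpaired differential test for glycosites
#'
#' Tests each testable glycosite on its detected values only (log2 scale,
#' two-sided unpaired t-test; Welch by default), calling `decreased` /
#' `increased` at `p < alpha_p`. Features with fewer than two detected values
#' in either genotype are reported `unchanged` with a `low_coverage` flag.
#' Exclusive-detection features from [filter_glyco_sites()] are appended with
#' their own status — downstream they are treated as decreased-occupancy
#' candidates (exclusive to control) or the mirror. No q-value is computed in
#' this branch.
#'
#' @param filtered The list returned by [filter_glyco_sites()].
#' @param alpha_p p-value threshold (default 0.05).
#' @param var_equal Use the pooled-variance Student test instead of Welch
#'   (default `FALSE`).
#' @return A differential-result tibble (as [paired_protein_test()], with
#'   `q_value` all `NA`).
#' @export
glyco_site_test <- function(filtered, alpha_p = 0.05, var_equal = FALSE) {
  matrix <- filtered$testable
  design <- qm_design(matrix)
  m <- log2(qm_intensities(matrix))
  ctrl <- design$sample_id[design$genotype == "control"]
  mut <- design$sample_id[design$genotype == "mutant"]
  n_ctrl <- rowSums(!is.na(m[, ctrl, drop = FALSE]))
  n_mut <- rowSums(!is.na(m[, mut, drop = FALSE]))

  res <- empty_diff_table()
  if (nrow(m) > 0) {
    ok <- n_ctrl >= 2L & n_mut >= 2L
    est <- rep(NA_real_, nrow(m))
    p <- rep(NA_real_, nrow(m))
    flag <- rep(NA_character_, nrow(m))
    if (any(ok)) {
      fit <- row_two_sample_t(m[ok, mut, drop = FALSE],
                              m[ok, ctrl, drop = FALSE],
                              var_equal = var_equal)
      est[ok] <- fit$estimate
      p[ok] <- fit$p_value
      flag[ok] <- fit$flag
    }
    flag[!ok] <- "low_coverage"
    status <- dplyr::case_when(
      !ok ~ "unchanged",
      p < alpha_p & est < 0 ~ "decreased",
      p < alpha_p & est > 0 ~ "increased",
      TRUE ~ "unchanged"
    )
    res <- tibble(
      feature_id = matrix$feature_id,
      log2_fold_change = est,
      p_value = p,
      q_value = NA_real_,
      status = status,
      n_detected_control = as.integer(n_ctrl),
      n_detected_mutant = as.integer(n_mut),
      flag = flag
    )
  }

  excl <- dplyr::bind_rows(
    exclusive_rows(filtered, filtered$exclusive_control, "exclusive_control"),
    exclusive_rows(filtered, filtered$exclusive_mutant, "exclusive_mutant")
  )
  dplyr::bind_rows(res, excl)
}

exclusive_rows <- function(filtered, ids, status) {
  if (length(ids) == 0) return(empty_diff_table())
  det <- filtered$detections[match(ids, filtered$detections$feature_id), ]
  tibble(
    feature_id = ids,
    log2_fold_change = NA_real_,
    p_value = NA_real_,
    q_value = NA_real_,
    status = status,
    n_detected_control = det$n_detected_control,
    n_detected_mutant = det$n_detected_mutant,
    flag = NA_character_
  )
}
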