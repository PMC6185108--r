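test_that("fisher enrichment handles balance, separation and bad margins", {
  # perfectly balanced table: no association
  bal <- fisher_enrichment(5, 10, 10, 20)
  expect_equal(bal$fold_enrichment, 1)
  expect_equal(bal$p_value, 1)
  expect_equal(bal$odds_ratio, 1)

  # complete separation: p = 2 / C(20, 10)
  sep <- fisher_enrichment(10, 10, 10, 20)
  expect_equal(sep$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(sep$odds_ratio, Inf)

  expect_error(fisher_enrichment(0, 0, 5, 10), "positive")
  expect_error(fisher_enrichment(6, 5, 10, 20), "margins",
               ignore.case = TRUE)
  expect_error(fisher_enrichment(3, 5, 2, 20), "margins",
               ignore.case = TRUE)
})

test_that("fisher p agrees with hypergeometric enumeration on random tables", {
  set.seed(14)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    r1 <- sample(1:(n - 1), 1)
    c1 <- sample(1:(n - 1), 1)
    a <- sample(max(0, r1 + c1 - n):min(r1, c1), 1)
    got <- fisher_enrichment(a, r1, c1, n)$p_value
    expect_equal(got, fisher_oracle(a, r1 - a, c1 - a, n - r1 - c1 + a),
                 tolerance = 1e-9)
  }
})

test_that("Mann-Whitney exact branch matches labeling enumeration", {
  # complete separation of 4 vs 4: p = 2/70
  sep <- mann_whitney_test(1:4, 10:13)
  expect_equal(sep$p_value, 2 / choose(8, 4), tolerance = 1e-12)
  expect_equal(sep$method, "exact")

  # identical multisets: p = 1
  expect_equal(mann_whitney_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  tied <- mann_whitney_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(tied$p_value, 1)
  expect_equal(tied$mean_a, tied$mean_b)

  set.seed(15)
  for (i in 1:40) {
    x <- sample(1:5, sample(2:6, 1), replace = TRUE)  # heavy ties
    y <- sample(1:5, sample(2:6, 1), replace = TRUE)
    expect_equal(mann_whitney_test(x, y)$p_value, mw_enum_p(x, y),
                 tolerance = 1e-12)
  }
  expect_error(mann_whitney_test(numeric(), 1:3), "non-empty")
})

test_that("large groups fall back to the tie-corrected normal approximation", {
  set.seed(16)
  x <- sample(1:10, 60, TRUE)
  y <- sample(2:11, 60, TRUE)
  got <- mann_whitney_test(x, y)
  expect_equal(got$method, "normal_approx")
  expect_equal(got$p_value,
               stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("multiplicity enrichment anchors threshold 1 at fold 1", {
  set.seed(17)
  bg <- tibble::tibble(
    protein_id = paste0("P", 1:60),
    multiplicity = sample(0:8, 60, TRUE)
  )
  glyco <- bg$protein_id[bg$multiplicity >= 1]
  dec <- sample(glyco, 12)
  res <- multiplicity_enrichment(dec, bg)
  expect_equal(res$fold_enrichment[res$threshold == 1], 1)
  expect_equal(res$p_value[res$threshold == 1], 1)

  # all decreased at multiplicity >= 4 with a 50% background: fold 2 at k=4
  bg2 <- tibble::tibble(
    protein_id = paste0("Q", 1:20),
    multiplicity = rep(c(1L, 5L), each = 10)
  )
  dec2 <- paste0("Q", 11:15)
  res2 <- multiplicity_enrichment(dec2, bg2)
  k4 <- res2[res2$threshold == 4, ]
  expect_equal(k4$fold_enrichment, 2)
  expect_equal(k4$p_value, fisher_oracle(5, 0, 5, 10), tolerance = 1e-12)

  # all decreased are single-site proteins: fold 0 above threshold 1
  dec3 <- paste0("Q", 1:5)
  res3 <- multiplicity_enrichment(dec3, bg2)
  expect_equal(res3$fold_enrichment[res3$threshold >= 2], c(0, 0, 0))

  expect_error(multiplicity_enrichment(character(), bg2), "Empty")
  expect_error(multiplicity_enrichment("nope", bg2), "background")
})

test_that("motif enrichment recovers a constructed +2 Ser excess", {
  proteins <- tibble::tibble(
    protein_id = c("D", "U"),
    sequence = c(paste0("AAAFA", strrep("NGSAAAA", 6)),
                 paste0("AAAFA", strrep("NGTAAAA", 6)))
  )
  dec <- classify_site(proteins,
                       tibble::tibble(protein_id = "D",
                                      position = 6 + 7 * (0:5)))
  unc <- classify_site(proteins,
                       tibble::tibble(protein_id = "U",
                                      position = 6 + 7 * (0:5)))
  out <- sequon_position_enrichment(dec, unc, proteins)
  ser <- out$features[out$features$feature == "plus2_ser", ]
  expect_gt(ser$fold_enrichment, 1)
  expect_equal(ser$p_value, fisher_oracle(6, 0, 0, 6), tolerance = 1e-12)
  expect_equal(ser$n_decreased_hit, 6)
  expect_equal(ser$n_unchanged_hit, 0)

  # identical composition: every feature p = 1
  out2 <- sequon_position_enrichment(dec, dec, proteins)
  expect_true(all(out2$features$p_value == 1))

  expect_error(sequon_position_enrichment(dec[0, ], unc, proteins),
               "non-empty")
})

test_that("the -2 aromatic class uses F, Y, H, W and skips undefined context", {
  proteins <- tibble::tibble(
    protein_id = c("PH", "PL", "PN"),
    sequence = c("AAHANGSAA",   # H at -2: aromatic
                 "AALANGSAA",   # L at -2: non-aromatic
                 "NGSAAAAAA")   # site at 1: no -2 context
  )
  sites <- classify_site(
    proteins,
    tibble::tibble(protein_id = c("PH", "PL", "PN"), position = c(5, 5, 1))
  )
  dec <- sites[1:2, ]
  unc <- sites[c(3, 2), ]
  out <- sequon_position_enrichment(dec, unc, proteins)
  m2 <- out$features[out$features$feature == "minus2_nonaromatic", ]
  # undefined -2 rows are excluded from the -2 feature only
  expect_equal(m2$n_decreased, 2)
  expect_equal(m2$n_unchanged, 1)
  expect_equal(m2$n_decreased_hit, 1)  # only the Leu site is non-aromatic
})

test_that("logo matrix frequencies sum to one per series and position", {
  proteins <- tibble::tibble(
    protein_id = "P",
    sequence = paste0("AAAFA", strrep("NGSAAAA", 6))
  )
  sites <- classify_site(proteins,
                         tibble::tibble(protein_id = "P",
                                        position = 6 + 7 * (0:5)))
  out <- sequon_position_enrichment(sites[1:3, ], sites[4:6, ], proteins)
  sums <- out$logo |>
    dplyr::group_by(series, position) |>
    dplyr::summarise(s = sum(frequency), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
})

test_that("NxS-multiplicity correlation handles exact trends and degeneracy", {
  # decreased series: NxS% = 10 * multiplicity -> r = 1
  mk_sites <- function(mult, n_nxs, n_nxt, prefix) {
    ids <- paste0(prefix, mult, "_", seq_len(n_nxs + n_nxt))
    tibble::tibble(
      protein_id = ids, position = 5L,
      sequon = c(rep("NGS", n_nxs), rep("NGT", n_nxt)),
      sequon_class = c(rep("NxS", n_nxs), rep("NxT", n_nxt)),
      minus2_residue = "A", minus2_aromatic = FALSE, evidence = "reference"
    )
  }
  dec <- dplyr::bind_rows(
    mk_sites(1, 1, 9, "d"), mk_sites(2, 2, 8, "d"),
    mk_sites(3, 3, 7, "d"), mk_sites(4, 4, 6, "d")
  )
  unc <- dplyr::bind_rows(
    mk_sites(1, 5, 5, "u"), mk_sites(2, 5, 5, "u"),
    mk_sites(3, 5, 5, "u"), mk_sites(4, 5, 5, "u")
  )
  profiles <- tibble::tibble(
    protein_id = c(dec$protein_id, unc$protein_id),
    multiplicity = as.integer(sub("^[du]([0-9]+)_.*$", "\\1",
                                  c(dec$protein_id, unc$protein_id)))
  )
  out <- nxs_multiplicity_correlation(dec, unc, profiles)
  st <- out$stats
  expect_equal(st$r[st$series == "decreased"], 1, tolerance = 1e-9)
  # constant series -> r reported as 0 with p = 1
  expect_equal(st$r[st$series == "unchanged"], 0)
  expect_equal(st$p_value[st$series == "unchanged"], 1)

  # fewer than 3 usable bins is an error
  expect_error(
    nxs_multiplicity_correlation(dec[dec$protein_id %in%
                                       profiles$protein_id[
                                         profiles$multiplicity <= 2], ],
                                 unc, profiles),
    "3 usable"
  )
})

test_that("annotation-set enrichment reduces to the Fisher construction", {
  all_feats <- paste0("P", 1:20, ":5")
  dec_feats <- paste0("P", 1:10, ":5")
  # membership equal to the background: no enrichment possible
  res <- annotation_set_enrichment(dec_feats, all_feats, "everything",
                                   paste0("P", 1:20))
  expect_equal(res$fold_enrichment, 1)
  expect_equal(res$p_value, 1)

  # decreased all members, background half: fold 2
  res2 <- annotation_set_enrichment(dec_feats, all_feats, "setA",
                                    paste0("P", 1:10))
  expect_equal(res2$fold_enrichment, 2)
  expect_equal(res2$p_value, fisher_oracle(10, 0, 0, 10), tolerance = 1e-12)

  expect_error(
    annotation_set_enrichment(dec_feats, all_feats, "ghost", "Z9"),
    "no member"
  )
})
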