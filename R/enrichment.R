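#' Exact 2x2 enrichment of a hit class within a feature set
#'
#' Builds the 2x2 table (rows: in-set / not in-set; columns: hit / non-hit,
#' with the background including the set) and computes a two-sided Fisher
#' exact p (sum of hypergeometric probabilities no larger than the observed
#' table's). The headline effect size is fold enrichment — the hit fraction in
#' the set over the hit fraction in the whole background; the sample odds
#' ratio is reported alongside (infinite when a margin cell is empty).
#'
#' @param set_hits Hits inside the set.
#' @param set_total Set size (> 0).
#' @param bg_hits Hits in the whole background (including the set).
#' @param bg_total Background size (the set is a subset of the background).
#' @return One-row tibble: the four table cells (`in_set_hit`,
#'   `in_set_nonhit`, `out_set_hit`, `out_set_nonhit`), `fold_enrichment`,
#'   `odds_ratio`, `p_value`.
#' @examples
#' fisher_enrichment(8, 10, 20, 100)
#' @export
fisher_enrichment <- function(set_hits, set_total, bg_hits, bg_total) {
  if (set_total <= 0 || bg_total <= 0) {
    abort("set_total and bg_total must be positive")
  }
  if (set_hits < 0 || set_hits > set_total || bg_hits < 0 ||
      set_total > bg_total || set_hits > bg_hits ||
      (set_total - set_hits) > (bg_total - bg_hits)) {
    abort("Inconsistent 2x2 margins: the set must be a subset of the background")
  }
  a <- set_hits
  b <- set_total - set_hits
  cc <- bg_hits - set_hits
  d <- (bg_total - bg_hits) - b
  tab <- matrix(c(a, cc, b, d), nrow = 2)
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  or <- if (b * cc == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * cc)
  }
  tibble(
    in_set_hit = a, in_set_nonhit = b,
    out_set_hit = cc, out_set_nonhit = d,
    fold_enrichment = (a / set_total) / (bg_hits / bg_total),
    odds_ratio = or,
    p_value = p
  )
}

#' Multiplicity-threshold enrichment among decreased glycoproteins
#'
#' For each threshold `k`, tests whether glycoproteins with multiplicity at
#' least `k` are enriched among the decreased glycoproteins relative to all
#' glycoproteins. The background is restricted to glycoproteins (multiplicity
#' >= 1); at `k = 1` every glycoprotein is a hit, so the fold enrichment is 1
#' by construction (the no-enrichment anchor).
#'
#' @param decreased_proteins Character vector of decreased glycoprotein ids
#'   (must be non-empty and a subset of the background).
#' @param background A multiplicity-profile tibble
#'   (see [multiplicity_profiles()]); rows with multiplicity 0 are dropped.
#' @param thresholds Integer thresholds (default 1:4).
#' @return A tibble with one [fisher_enrichment()] row per threshold plus a
#'   `threshold` column.
#' @export
multiplicity_enrichment <- function(decreased_proteins, background,
                                    thresholds = 1:4) {
  bg <- background[background$multiplicity >= 1L, , drop = FALSE]
  decreased_proteins <- unique(decreased_proteins)
  if (length(decreased_proteins) == 0) {
    abort("Empty decreased set")
  }
  if (!all(decreased_proteins %in% bg$protein_id)) {
    abort("Decreased proteins must be glycoproteins present in the background")
  }
  dec_mult <- bg$multiplicity[match(decreased_proteins, bg$protein_id)]
  purrr::map_dfr(thresholds, function(k) {
    dplyr::bind_cols(
      tibble(threshold = as.integer(k)),
      fisher_enrichment(
        set_hits = sum(dec_mult >= k),
        set_total = length(dec_mult),
        bg_hits = sum(bg$multiplicity >= k),
        bg_total = nrow(bg)
      )
    )
  })
}

#' Compare multiplicity between two protein groups
#'
#' Mann-Whitney comparison of per-protein multiplicity (e.g. proteins with a
#' decreased glycopeptide versus unchanged glycoproteins, or an annotation set
#' versus the rest), with group means reported.
#'
#' @param group_a,group_b Multiplicity-profile tibbles (or numeric vectors of
#'   multiplicities). Must be non-empty.
#' @return One-row tibble from [mann_whitney_test()].
#' @export
multiplicity_group_test <- function(group_a, group_b) {
  pull_mult <- function(g) {
    if (is.data.frame(g)) g$multiplicity else g
  }
  mann_whitney_test(pull_mult(group_a), pull_mult(group_b))
}

site_context <- function(sites, proteins, positions) {
  seq <- proteins$sequence[match(sites$protein_id, proteins$protein_id)]
  len <- nchar(seq)
  purrr::map_dfr(positions, function(off) {
    at <- sites$position + off
    ok <- at >= 1L & at <= len
    tibble(
      position = off,
      residue = ifelse(ok, substr(seq, at, at), NA_character_)
    )
  })
}

#' Sequon-position motif enrichment between decreased and unchanged sites
#'
#' For every flanking position (Asn = 0 excluded) and residue observed there,
#' and for the two headline context features — a non-aromatic residue
#' (anything but Phe/Tyr/His/Trp) at -2 and a Ser at +2 (the NxS motif) —
#' builds the 2x2 decreased-vs-unchanged by feature-present/absent table and
#' computes a two-sided Fisher exact p. Sites whose window runs past a
#' terminus are excluded from that position only. The full per-position
#' residue count table (a logo matrix in long form) is returned alongside.
#'
#' @param decreased_sites,unchanged_sites Site tibbles (see
#'   [classify_site()]); both must be non-empty.
#' @param proteins A tibble with `protein_id`, `sequence` (for flanking
#'   residues beyond the sequon).
#' @param positions Flank offsets to scan (default -5:5, 0 skipped).
#' @return A list: `features` (one row per position x feature with counts,
#'   `fold_enrichment`, `odds_ratio`, `p_value`; headline rows have feature
#'   `minus2_nonaromatic` and `plus2_ser`) and `logo` (long residue-frequency
#'   table per series).
#' @export
sequon_position_enrichment <- function(decreased_sites, unchanged_sites,
                                       proteins, positions = -5:5) {
  if (nrow(decreased_sites) == 0 || nrow(unchanged_sites) == 0) {
    abort("Both site sets must be non-empty")
  }
  positions <- setdiff(positions, 0L)
  ctx <- function(sites, series) {
    site_context(sites, proteins, positions) |>
      dplyr::mutate(series = series)
  }
  both <- dplyr::bind_rows(ctx(decreased_sites, "decreased"),
                           ctx(unchanged_sites, "unchanged"))
  logo <- both |>
    dplyr::filter(!is.na(.data$residue)) |>
    dplyr::count(.data$series, .data$position, .data$residue, name = "n") |>
    dplyr::group_by(.data$series, .data$position) |>
    dplyr::mutate(frequency = .data$n / sum(.data$n)) |>
    dplyr::ungroup()

  one_feature <- function(pos, label, dec_hit, dec_tot, unc_hit, unc_tot) {
    n_dec <- dec_tot
    n_unc <- unc_tot
    fe <- fisher_enrichment(
      set_hits = dec_hit, set_total = n_dec,
      bg_hits = dec_hit + unc_hit, bg_total = n_dec + n_unc
    )
    dplyr::bind_cols(
      tibble(position = pos, feature = label,
             n_decreased_hit = dec_hit, n_decreased = n_dec,
             n_unchanged_hit = unc_hit, n_unchanged = n_unc),
      fe[, c("fold_enrichment", "odds_ratio", "p_value")]
    )
  }

  per_residue <- purrr::map_dfr(positions, function(pos) {
    d <- both[both$position == pos & both$series == "decreased" &
                !is.na(both$residue), ]
    u <- both[both$position == pos & both$series == "unchanged" &
                !is.na(both$residue), ]
    if (nrow(d) == 0 || nrow(u) == 0) return(NULL)
    residues <- sort(unique(c(d$residue, u$residue)))
    purrr::map_dfr(residues, function(res) {
      one_feature(pos, res,
                  sum(d$residue == res), nrow(d),
                  sum(u$residue == res), nrow(u))
    })
  })

  dec_m2 <- decreased_sites[!is.na(decreased_sites$minus2_aromatic), ]
  unc_m2 <- unchanged_sites[!is.na(unchanged_sites$minus2_aromatic), ]
  headline <- dplyr::bind_rows(
    if (nrow(dec_m2) > 0 && nrow(unc_m2) > 0) {
      one_feature(-2L, "minus2_nonaromatic",
                  sum(!dec_m2$minus2_aromatic), nrow(dec_m2),
                  sum(!unc_m2$minus2_aromatic), nrow(unc_m2))
    },
    one_feature(2L, "plus2_ser",
                sum(plus2_residue(decreased_sites) == "S", na.rm = TRUE),
                nrow(decreased_sites),
                sum(plus2_residue(unchanged_sites) == "S", na.rm = TRUE),
                nrow(unchanged_sites))
  )
  list(features = dplyr::bind_rows(headline, per_residue), logo = logo)
}

plus2_residue <- function(sites) {
  res <- substr(sites$sequon, 3, 3)
  ifelse(nzchar(res), res, NA_character_)
}

#' NxS fraction versus protein multiplicity
#'
#' Bins glycosites by their parent protein's multiplicity (singleton bins up
#' to `cap - 1`, everything at or above `cap` pooled), computes per bin and
#' per series (decreased / unchanged) the percentage of sites whose sequon
#' class is NxS, and fits a Pearson correlation of percentage against bin
#' multiplicity per series. Bins with fewer than `min_bin_size` sites in a
#' series are dropped for that series; at least 3 usable bins are required.
#' A series with constant percentages is reported with `r = 0`, `p = 1`.
#'
#' @param decreased_sites,unchanged_sites Site tibbles.
#' @param profiles Multiplicity-profile tibble (see
#'   [multiplicity_profiles()]).
#' @param min_bin_size Minimum sites per usable bin (default 3).
#' @param cap Pooling threshold for high multiplicities (default 8).
#' @return An `nxs_correlation` list: `points` (series, bin multiplicity, n,
#'   percentage NxS) and `stats` (per-series `r`, `p_value`, `n_bins`).
#' @export
nxs_multiplicity_correlation <- function(decreased_sites, unchanged_sites,
                                         profiles, min_bin_size = 3, cap = 8) {
  series_points <- function(sites, series) {
    if (nrow(sites) == 0) return(NULL)
    mult <- profiles$multiplicity[match(sites$protein_id,
                                        profiles$protein_id)]
    if (anyNA(mult)) {
      abort("Every site's protein must appear in the multiplicity profiles")
    }
    tibble(
      series = series,
      bin = pmin(mult, cap),
      is_nxs = sites$sequon_class == "NxS"
    ) |>
      dplyr::group_by(.data$series, .data$bin) |>
      dplyr::summarise(
        n = dplyr::n(),
        pct_nxs = 100 * mean(.data$is_nxs),
        .groups = "drop"
      ) |>
      dplyr::filter(.data$n >= min_bin_size)
  }
  points <- dplyr::bind_rows(
    series_points(decreased_sites, "decreased"),
    series_points(unchanged_sites, "unchanged")
  )
  for (s in c("decreased", "unchanged")) {
    if (sum(points$series == s) < 3) {
      abort(paste0("Fewer than 3 usable multiplicity bins for the ", s,
                   " series"))
    }
  }
  stats_tbl <- points |>
    dplyr::group_by(.data$series) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 3) {
        abort(paste0(
          "Fewer than 3 usable multiplicity bins for the ", key$series,
          " series"
        ))
      }
      if (sd(df$pct_nxs) == 0) {
        return(tibble(r = 0, p_value = 1, n_bins = nrow(df)))
      }
      ct <- cor.test(df$bin, df$pct_nxs, method = "pearson")
      tibble(r = unname(ct$estimate), p_value = ct$p.value, n_bins = nrow(df))
    }) |>
    dplyr::ungroup()
  structure(list(points = points, stats = stats_tbl),
            class = "nxs_correlation")
}

#' @export
print.nxs_correlation <- function(x, ...) {
  cat("NxS fraction vs protein multiplicity\n")
  print(x$stats)
  invisible(x)
}

#' Annotation-set enrichment among decreased glycopeptides
#'
#' Tests whether glycopeptide features whose parent protein belongs to a
#' user-supplied annotation set (e.g. an IgSF-CAM membership list) are
#' over-represented among the decreased features, against all analysed
#' features as background.
#'
#' @param decreased_features Character vector of decreased feature ids
#'   (`"<protein_id>:<position>"`); a subset of `all_features`.
#' @param all_features Character vector of background feature ids.
#' @param annotation Label for the set (carried into the result).
#' @param membership Character vector of member protein ids.
#' @return One-row tibble: `annotation` plus the [fisher_enrichment()]
#'   columns and the hit fraction within the decreased set.
#' @export
annotation_set_enrichment <- function(decreased_features, all_features,
                                      annotation, membership) {
  if (!all(decreased_features %in% all_features)) {
    abort("Decreased features must be a subset of the background features")
  }
  bg_prot <- parse_site_ids(all_features)$protein_id
  dec_prot <- parse_site_ids(decreased_features)$protein_id
  bg_hit <- bg_prot %in% membership
  if (!any(bg_hit)) {
    abort(paste0(
      "Annotation set '", annotation,
      "' has no member among the background features"
    ))
  }
  fe <- fisher_enrichment(
    set_hits = sum(dec_prot %in% membership),
    set_total = length(dec_prot),
    bg_hits = sum(bg_hit),
    bg_total = length(all_features)
  )
  dplyr::bind_cols(
    tibble(
      annotation = annotation,
      decreased_member_fraction = sum(dec_prot %in% membership) /
        length(dec_prot)
    ),
    fe
  )
}
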