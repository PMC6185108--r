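#' Configuration for the synthetic glycoproteome generator
#'
#' Encodes, as an explicit generative model, the mechanism under study: a
#' limited supply of lipid-linked oligosaccharide (a mild, global
#' N-glycosylation stress) lowers per-site occupancy most at inefficient
#' sequons, and the accumulated loss of occupancy across a protein's sites
#' drives its degradation — so sensitivity grows with N-glycan multiplicity.
#'
#' Per site with transfer efficiency `e` (from the sequon class, plus a small
#' bonus for an aromatic -2 residue): occupancy is `e` in control and
#' `e * max(0, 1 - kappa * stress * (1 - e))` in mutant. Per protein, the
#' expected increase in unoccupied sites is `delta_u = sum(o_ctrl - o_mut)`
#' and the mutant abundance multiplier is `r = exp(-lambda * delta_u)`.
#'
#' @param n_proteins Number of proteins (default 2000).
#' @param glycoprotein_fraction Fraction of proteins carrying sequons
#'   (default 0.4).
#' @param multiplicity_mean,multiplicity_dispersion Site count per
#'   glycoprotein is `1 + NegBinomial(mean, dispersion)` (defaults 1.8 and
#'   1.0), capped at `multiplicity_cap`.
#' @param multiplicity_cap Maximum sites per protein (default 16).
#' @param sequon_class_probs Named probabilities for NxT / NxS /
#'   non_canonical (defaults 0.45, 0.45, 0.10).
#' @param minus2_aromatic_prob Probability of an aromatic -2 residue
#'   (default 0.15).
#' @param efficiency Named per-class transfer efficiencies
#'   (NxT 0.98, NxS 0.92, non_canonical 0.70).
#' @param aromatic_bonus Efficiency bonus for aromatic -2 (default 0.02).
#' @param efficiency_cap Upper bound on efficiency (default 0.995).
#' @param stress Global stress `s` in \[0, 1\] (default 0.5); 0 = unstressed.
#' @param kappa Occupancy sensitivity `kappa >= 0` (default 3).
#' @param lambda Degradation rate `lambda >= 0` (default 1).
#' @param abundance_log2_mean,abundance_log2_sd Protein log2-abundance
#'   distribution (defaults 20 and 2).
#' @param replicate_sd Per-sample replicate noise sd, log2 (default 0.25).
#' @param pair_effect_sd Litter/pair effect sd, log2, shared by the two
#'   samples of a pair (default 0.3).
#' @param site_ionization_log2_sd Fixed per-peptide ionization offset sd
#'   (default 1).
#' @param detection_midpoint,detection_width Logistic detection model: a cell
#'   of log2 intensity `I` is observed with probability
#'   `plogis((I - midpoint) / width)` (defaults 18 and 1) — the
#'   missing-not-at-random regime of label-free MS.
#' @param annotated_fraction Fraction of glycoproteins tagged with the
#'   synthetic `"IgSF-CAM-like"` annotation, drawn preferentially from
#'   high-multiplicity proteins (default 0.1; 0 disables).
#' @param n_control,n_mutant Samples per genotype (defaults 4 and 4, paired).
#' @param seed Integer seed; every draw flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_proteins = 2000,
                       glycoprotein_fraction = 0.4,
                       multiplicity_mean = 1.8,
                       multiplicity_dispersion = 1.0,
                       multiplicity_cap = 16,
                       sequon_class_probs = c(NxT = 0.45, NxS = 0.45,
                                              non_canonical = 0.10),
                       minus2_aromatic_prob = 0.15,
                       efficiency = c(NxT = 0.98, NxS = 0.92,
                                      non_canonical = 0.70),
                       aromatic_bonus = 0.02,
                       efficiency_cap = 0.995,
                       stress = 0.5,
                       kappa = 3,
                       lambda = 1,
                       abundance_log2_mean = 20,
                       abundance_log2_sd = 2,
                       replicate_sd = 0.25,
                       pair_effect_sd = 0.3,
                       site_ionization_log2_sd = 1,
                       detection_midpoint = 18,
                       detection_width = 1,
                       annotated_fraction = 0.1,
                       n_control = 4,
                       n_mutant = 4,
                       seed = 1L) {
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    glycoprotein_fraction = glycoprotein_fraction,
    multiplicity_mean = multiplicity_mean,
    multiplicity_dispersion = multiplicity_dispersion,
    multiplicity_cap = as.integer(multiplicity_cap),
    sequon_class_probs = sequon_class_probs,
    minus2_aromatic_prob = minus2_aromatic_prob,
    efficiency = efficiency,
    aromatic_bonus = aromatic_bonus,
    efficiency_cap = efficiency_cap,
    stress = stress,
    kappa = kappa,
    lambda = lambda,
    abundance_log2_mean = abundance_log2_mean,
    abundance_log2_sd = abundance_log2_sd,
    replicate_sd = replicate_sd,
    pair_effect_sd = pair_effect_sd,
    site_ionization_log2_sd = site_ionization_log2_sd,
    detection_midpoint = detection_midpoint,
    detection_width = detection_width,
    annotated_fraction = annotated_fraction,
    n_control = as.integer(n_control),
    n_mutant = as.integer(n_mutant),
    seed = as.integer(seed)
  )
  probs <- c(cfg$glycoprotein_fraction, cfg$minus2_aromatic_prob,
             cfg$sequon_class_probs, cfg$annotated_fraction)
  if (any(probs < 0 | probs > 1)) abort("Probabilities must lie in [0, 1]")
  if (abs(sum(cfg$sequon_class_probs) - 1) > 1e-8) {
    abort("sequon_class_probs must sum to 1")
  }
  if (!setequal(names(cfg$sequon_class_probs), c("NxT", "NxS", "non_canonical")) ||
      !setequal(names(cfg$efficiency), c("NxT", "NxS", "non_canonical"))) {
    abort("sequon_class_probs and efficiency need names NxT, NxS, non_canonical")
  }
  if (cfg$stress < 0 || cfg$stress > 1) abort("stress must lie in [0, 1]")
  if (cfg$kappa < 0 || cfg$lambda < 0) abort("kappa and lambda must be >= 0")
  if (any(cfg$efficiency <= 0 | cfg$efficiency > 1)) {
    abort("efficiencies must lie in (0, 1]")
  }
  if (cfg$n_proteins < 1 || cfg$n_control < 1 || cfg$n_mutant < 1) {
    abort("n_proteins, n_control, n_mutant must be >= 1")
  }
  structure(cfg, class = "sim_config")
}

# Non-Asn backbone alphabet: the simulated sequon catalogue is then exactly
# the ground truth (no accidental sequons from backbone Asn).
backbone_alphabet <- function() setdiff(AA_ALPHABET, "N")

#' Generate a synthetic proteome with ground-truth occupancy and degradation
#'
#' Draws glycoprotein status, per-protein multiplicity, per-site sequon class
#' and -2 context, then builds random backbone sequences with each sequon
#' embedded at its recorded position (sites spaced so blocks never overlap).
#' Backbone residues exclude Asn, so scanning a simulated protein recovers
#' exactly its true canonical sites. Ground-truth occupancies and the
#' degradation multiplier follow the model described in [sim_config()].
#'
#' @param config A [sim_config()].
#' @return A `sim_proteome` list: `proteins` (protein_id, sequence,
#'   annotation), `sites` (per-site truth) and `protein_truth` (per-protein
#'   truth).
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  generate_proteome_impl(config)
}

generate_proteome_impl <- function(config) {
  n <- config$n_proteins
  protein_id <- sprintf("SP%04d", seq_len(n))
  is_glyco <- runif(n) < config$glycoprotein_fraction
  mult <- integer(n)
  mult[is_glyco] <- pmin(
    1L + rnbinom(sum(is_glyco),
                 size = config$multiplicity_dispersion,
                 mu = config$multiplicity_mean),
    config$multiplicity_cap
  )

  classes <- names(config$sequon_class_probs)
  site_protein <- rep(protein_id, mult)
  n_sites <- length(site_protein)
  site_index <- sequence(mult[mult > 0L])
  site_class <- if (n_sites > 0) {
    sample(classes, n_sites, replace = TRUE, prob = config$sequon_class_probs)
  } else character()
  site_arom <- runif(n_sites) < config$minus2_aromatic_prob

  e <- pmin(
    unname(config$efficiency[site_class]) +
      ifelse(site_arom, config$aromatic_bonus, 0),
    config$efficiency_cap
  )
  o_ctrl <- e
  o_mut <- e * pmax(0, 1 - config$kappa * config$stress * (1 - e))

  # Asn of site i sits at 8*i + 2; each site owns the 5-residue block
  # [-2, +2], so consecutive blocks never overlap.
  site_pos <- 8L * site_index + 2L
  sequences <- build_sequences(protein_id, mult, site_protein, site_pos,
                               site_class, site_arom)

  abundance_log2 <- rnorm(n, config$abundance_log2_mean,
                          config$abundance_log2_sd)
  delta_u <- rep(0, n)
  if (n_sites > 0) {
    loss <- tapply(o_ctrl - o_mut, factor(site_protein, levels = protein_id),
                   sum, default = 0)
    delta_u <- as.numeric(loss)
  }
  r <- exp(-config$lambda * delta_u)

  annotation <- rep(NA_character_, n)
  if (config$annotated_fraction > 0 && any(is_glyco)) {
    glyco_idx <- which(is_glyco)
    n_tag <- max(1L, round(config$annotated_fraction * length(glyco_idx)))
    # weight by multiplicity: the synthetic adhesion-molecule-like set is
    # biased towards highly glycosylated proteins
    w <- mult[glyco_idx]^2
    tagged <- glyco_idx[sample.int(length(glyco_idx),
                                   min(n_tag, length(glyco_idx)), prob = w)]
    annotation[tagged] <- "IgSF-CAM-like"
  }

  sites <- tibble(
    protein_id = site_protein,
    position = site_pos,
    sequon_class = site_class,
    minus2_aromatic = site_arom,
    efficiency = e,
    o_ctrl = o_ctrl,
    o_mut = o_mut
  )
  structure(list(
    proteins = tibble(protein_id = protein_id, sequence = sequences,
                      annotation = annotation),
    sites = sites,
    protein_truth = tibble(
      protein_id = protein_id,
      is_glycoprotein = is_glyco,
      multiplicity = mult,
      abundance_log2 = abundance_log2,
      delta_u = delta_u,
      r = r
    ),
    config = config
  ), class = "sim_proteome")
}

build_sequences <- function(protein_id, mult, site_protein, site_pos,
                            site_class, site_arom) {
  bb <- backbone_alphabet()
  non_arom <- setdiff(bb, AROMATIC_RESIDUES)
  plus1_pool <- setdiff(bb, "P")
  noncanon_plus2 <- setdiff(bb, c("S", "T", "P"))
  lengths <- 8L * mult + 20L
  n_sites <- length(site_pos)
  minus2 <- character(n_sites)
  minus2[site_arom] <- sample(AROMATIC_RESIDUES, sum(site_arom), replace = TRUE)
  minus2[!site_arom] <- sample(non_arom, sum(!site_arom), replace = TRUE)
  plus1 <- sample(plus1_pool, n_sites, replace = TRUE)
  plus2 <- character(n_sites)
  plus2[site_class == "NxT"] <- "T"
  plus2[site_class == "NxS"] <- "S"
  n_nc <- sum(site_class == "non_canonical")
  plus2[site_class == "non_canonical"] <- sample(noncanon_plus2, n_nc,
                                                 replace = TRUE)
  site_by_protein <- split(seq_len(n_sites),
                           factor(site_protein, levels = protein_id))
  vapply(seq_along(protein_id), function(i) {
    chars <- sample(bb, lengths[i], replace = TRUE)
    for (j in site_by_protein[[i]]) {
      p <- site_pos[j]
      chars[p - 2L] <- minus2[j]
      chars[p] <- "N"
      chars[p + 1L] <- plus1[j]
      chars[p + 2L] <- plus2[j]
    }
    paste(chars, collapse = "")
  }, character(1))
}

#' Simulate paired label-free quantification tables
#'
#' Per sample, a protein's log2 intensity is its abundance plus a pair effect
#' (shared between the two samples of a pair — the litter design that
#' justifies the paired test), plus replicate noise; mutant samples are
#' shifted by `log2(r)`. A glycosite feature adds `log2(occupancy)` and a
#' fixed per-peptide ionization offset to its protein's intensity in that
#' sample; the matching unmodified peptide uses `log2(1 - occupancy)` with its
#' own offset. Zero occupancy makes the species absent (missing), not
#' zero-intensity. Every cell is then observed with probability
#' `plogis((log2 I - midpoint) / width)`, otherwise missing.
#'
#' @param config A [sim_config()].
#' @param proteome A `sim_proteome` from [generate_proteome()].
#' @return A list: `design`, and [quant_matrix()] objects `protein_quant`,
#'   `glyco_quant`, `unmodified_quant` (raw-scale intensities, `NA` missing).
#' @export
simulate_quant <- function(config, proteome) {
  stopifnot(inherits(config, "sim_config"), inherits(proteome, "sim_proteome"))
  # derived stream: distinct from the proteome draw but still seed-determined
  set.seed((config$seed %% 1000000L) + 777L)
  simulate_quant_impl(config, proteome)
}

simulate_quant_impl <- function(config, proteome) {
  n_pairs <- max(config$n_control, config$n_mutant)
  design <- tibble(
    sample_id = c(sprintf("C%d", seq_len(config$n_control)),
                  sprintf("M%d", seq_len(config$n_mutant))),
    genotype = rep(c("control", "mutant"),
                   c(config$n_control, config$n_mutant)),
    pair_id = c(seq_len(config$n_control), seq_len(config$n_mutant))
  )
  truth <- proteome$protein_truth
  n_prot <- nrow(truth)
  n_smp <- nrow(design)

  shift <- outer(log2(truth$r), as.numeric(design$genotype == "mutant"))

  # Total-proteome cohort: littermate pairing, so the pair effect is shared
  # by the two samples of a pair (this is what justifies the paired test).
  pair_eff <- matrix(rnorm(n_prot * n_pairs, 0, config$pair_effect_sd),
                     n_prot, n_pairs)
  noise <- matrix(rnorm(n_prot * n_smp, 0, config$replicate_sd), n_prot, n_smp)
  prot_log2 <- truth$abundance_log2 + pair_eff[, design$pair_id, drop = FALSE] +
    noise + shift
  rownames(prot_log2) <- truth$protein_id

  # Glycoproteomics cohort: distinct animals (as in the study design), so
  # biological effects are independent per sample and the unpaired glyco
  # test is correctly calibrated.
  animal_eff <- matrix(rnorm(n_prot * n_smp, 0, config$pair_effect_sd),
                       n_prot, n_smp)
  noise_g <- matrix(rnorm(n_prot * n_smp, 0, config$replicate_sd),
                    n_prot, n_smp)
  prot_log2_glyco <- truth$abundance_log2 + animal_eff + noise_g + shift
  rownames(prot_log2_glyco) <- truth$protein_id

  sites <- proteome$sites
  n_sites <- nrow(sites)
  site_rows <- match(sites$protein_id, truth$protein_id)
  ion_glyco <- rnorm(n_sites, 0, config$site_ionization_log2_sd)
  ion_unmod <- rnorm(n_sites, 0, config$site_ionization_log2_sd)
  occ <- outer(sites$o_ctrl, rep(1, n_smp))
  occ[, design$genotype == "mutant"] <- sites$o_mut
  # glyco features live in the glyco cohort; the unmodified counterpart
  # peptides are observed in the total-proteomics experiment
  glyco_log2 <- prot_log2_glyco[site_rows, , drop = FALSE] + log2(occ) +
    ion_glyco
  unmod_log2 <- prot_log2[site_rows, , drop = FALSE] + log2(1 - occ) + ion_unmod

  observe <- function(log2_mat) {
    p <- plogis((log2_mat - config$detection_midpoint) / config$detection_width)
    p[!is.finite(log2_mat)] <- 0 # occupancy 0 or 1: species absent
    keep <- matrix(runif(length(p)) < p, nrow(p), ncol(p))
    out <- 2^log2_mat
    out[!keep] <- NA_real_
    out
  }

  to_qm <- function(m, ids, kind) {
    df <- as_tibble(as.data.frame(m))
    names(df) <- design$sample_id
    quant_matrix(dplyr::bind_cols(tibble(feature_id = ids), df), design, kind)
  }

  site_ids <- site_id(sites$protein_id, sites$position)
  list(
    design = design,
    protein_quant = to_qm(observe(prot_log2), truth$protein_id, "protein"),
    glyco_quant = to_qm(observe(glyco_log2), site_ids, "glycosite"),
    unmodified_quant = to_qm(observe(unmod_log2), site_ids,
                             "unmodified_peptide")
  )
}

#' Generate a complete synthetic glycoproteomics study
#'
#' Single entry point: seeds the generator once, draws the proteome and the
#' three quantification tables, and subsamples the true sites into a
#' known-site list (so novel-site calling is exercised).
#'
#' @param config A [sim_config()].
#' @param known_fraction Fraction of true sites put on the synthetic
#'   known-site list (default 0.8).
#' @return A `glyco_sim` list: `proteome`, `design`, `protein_quant`,
#'   `glyco_quant`, `unmodified_quant`, `known_sites`, `config`.
#' @export
simulate_glycoproteome <- function(config = sim_config(),
                                   known_fraction = 0.8) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  proteome <- generate_proteome_impl(config)
  quant <- simulate_quant_impl(config, proteome)
  sites <- proteome$sites
  n_known <- round(known_fraction * nrow(sites))
  known_idx <- sort(sample(nrow(sites), n_known))
  structure(c(
    list(
      proteome = proteome,
      known_sites = sites[known_idx, c("protein_id", "position")],
      config = config
    ),
    quant
  ), class = "glyco_sim")
}

#' @export
print.glyco_sim <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic glycoproteomics study\n")
  cat(sprintf("  %d proteins (%d glycoproteins), %d true sites\n",
              cfg$n_proteins, sum(x$proteome$protein_truth$is_glycoprotein),
              nrow(x$proteome$sites)))
  cat(sprintf("  stress s = %.2f, kappa = %.1f, lambda = %.1f, seed = %d\n",
              cfg$stress, cfg$kappa, cfg$lambda, cfg$seed))
  cat(sprintf("  %d control vs %d mutant samples (paired)\n",
              cfg$n_control, cfg$n_mutant))
  invisible(x)
}
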