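#' Run the full glycoproteomics analysis pipeline
#'
#' Orchestrates every stage: (optionally) simulate a synthetic study, build
#' the reference glycoproteome and call novel sites, compute multiplicity
#' profiles, run the paired total-proteome and unpaired glycosite differential
#' branches, cross-reference decreased glycosites against unmodified-peptide
#' evidence, and compute the susceptibility statistics (glycoprotein
#' enrichment among decreased proteins, multiplicity-threshold enrichment,
#' group multiplicity comparisons, sequon motif enrichment, the
#' NxS-versus-multiplicity correlation, and any annotation-set enrichments).
#'
#' When `data` is `NULL` a synthetic study is generated from `config`.
#' Otherwise `data` must be a list with `proteins` (tibble of `protein_id`,
#' `sequence`), `protein_quant`, `glyco_quant` (both [quant_matrix()]),
#' optionally `unmodified_quant`, `known_sites` and `annotation_sets` (a
#' named list of protein-id vectors).
#'
#' @param data Input data list, or `NULL` to simulate.
#' @param config A [sim_config()] used when simulating.
#' @param alpha_q q-value threshold for the total proteome (default 0.05).
#' @param alpha_p p-value threshold for glycosites (default 0.05).
#' @param min_reference_detections Control detections required for the
#'   reference glycoproteome (default 2).
#' @param min_control,min_exclusive Glyco-branch filter thresholds
#'   (defaults 3 and 3).
#' @param crossref_k Mutant detections of the unmodified counterpart required
#'   for an `unoccupied_in_mutant` call (default 3).
#' @param var_equal Pooled-variance glyco test instead of Welch
#'   (default `FALSE`).
#' @param out_dir If non-`NULL`, stage outputs, the resolved configuration
#'   (YAML) and a plain-text report are written there.
#' @param quiet Suppress stage messages on standard error (default `TRUE`).
#' @return A `glyco_pipeline` object; see [tidy.glyco_pipeline()],
#'   [glance.glyco_pipeline()], [autoplot.glyco_pipeline()].
#' @export
run_glyco_pipeline <- function(data = NULL,
                               config = sim_config(),
                               alpha_q = 0.05,
                               alpha_p = 0.05,
                               min_reference_detections = 2,
                               min_control = 3,
                               min_exclusive = 3,
                               crossref_k = 3,
                               var_equal = FALSE,
                               out_dir = NULL,
                               quiet = TRUE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  simulated <- is.null(data)
  if (simulated) {
    say("stage simulate: generating synthetic study (seed %d)", config$seed)
    sim <- simulate_glycoproteome(config)
    ann <- sim$proteome$proteins
    annotation_sets <- if (any(!is.na(ann$annotation))) {
      split(ann$protein_id, ann$annotation)
    } else {
      list()
    }
    data <- list(
      proteins = sim$proteome$proteins[, c("protein_id", "sequence")],
      protein_quant = sim$protein_quant,
      glyco_quant = sim$glyco_quant,
      unmodified_quant = sim$unmodified_quant,
      known_sites = sim$known_sites,
      annotation_sets = annotation_sets
    )
  } else {
    sim <- NULL
    for (needed in c("proteins", "protein_quant", "glyco_quant")) {
      if (is.null(data[[needed]])) {
        abort(paste0(
          "Input '", needed, "' is required when simulation is disabled"
        ))
      }
    }
    data$annotation_sets <- data$annotation_sets %||% list()
  }

  say("stage annotate: reference glycoproteome")
  reference <- build_reference_glycoproteome(
    data$glyco_quant, data$proteins,
    min_control_detections = min_reference_detections
  )
  if (!is.null(data$known_sites)) {
    reference <- call_novel_sites(reference, data$known_sites)
  }
  novel_summary <- novel_site_summary(reference)
  profiles <- multiplicity_profiles(reference, data$proteins)

  say("stage diff-proteome: complete-case paired test")
  cc <- filter_complete_cases(data$protein_quant)
  protein_results <- paired_protein_test(cc$retained, alpha_q = alpha_q)

  say("stage diff-glyco: control-anchored filter + unpaired test")
  fg <- filter_glyco_sites(data$glyco_quant,
                           min_control = min_control,
                           min_exclusive = min_exclusive)
  glyco_results <- glyco_site_test(fg, alpha_p = alpha_p,
                                   var_equal = var_equal)

  crossref <- NULL
  if (!is.null(data$unmodified_quant)) {
    say("stage crossref: occupancy calls")
    crossref <- crossref_occupancy(glyco_results, data$unmodified_quant,
                                   protein_results, k = crossref_k)
  }

  say("stage enrich: susceptibility statistics")
  enrichment <- pipeline_enrichments(
    protein_results, glyco_results, reference, profiles,
    data$proteins, data$annotation_sets
  )

  res <- structure(list(
    simulated = simulated,
    sim = sim,
    reference = reference,
    novel_summary = novel_summary,
    profiles = profiles,
    protein_filtered_out = cc$filtered_out,
    protein_results = protein_results,
    glyco_filter = fg[c("exclusive_control", "exclusive_mutant",
                        "filtered_out")],
    glyco_results = glyco_results,
    crossref = crossref,
    enrichment = enrichment,
    params = list(
      alpha_q = alpha_q, alpha_p = alpha_p,
      min_reference_detections = min_reference_detections,
      min_control = min_control, min_exclusive = min_exclusive,
      crossref_k = crossref_k, var_equal = var_equal,
      config = if (simulated) unclass(config) else NULL
    ),
    n_protein_features = nrow(data$protein_quant),
    n_glyco_features = nrow(data$glyco_quant)
  ), class = "glyco_pipeline")

  if (!is.null(out_dir)) {
    write_pipeline_outputs(res, out_dir)
  }
  say("done in %.1fs", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  res
}

# Decreased / unchanged site partitions used by the enrichment stage.
# "Unchanged" is the inclusive reading: every reference site not called
# decreased (or control-exclusive) and not called increased (or
# mutant-exclusive).
partition_sites <- function(glyco_results, reference) {
  ref_ids <- site_id(reference$protein_id, reference$position)
  status <- glyco_results$status[match(ref_ids, glyco_results$feature_id)]
  dec <- !is.na(status) & status %in% c("decreased", "exclusive_control")
  inc <- !is.na(status) & status %in% c("increased", "exclusive_mutant")
  list(
    decreased = reference[dec, , drop = FALSE],
    unchanged = reference[!dec & !inc, , drop = FALSE]
  )
}

pipeline_enrichments <- function(protein_results, glyco_results, reference,
                                 profiles, proteins, annotation_sets) {
  out <- list()
  tested <- profiles[profiles$protein_id %in% protein_results$feature_id, ]
  dec_prot <- protein_results$feature_id[protein_results$status == "decreased"]
  dec_glycoprot <- intersect(
    dec_prot, tested$protein_id[tested$multiplicity >= 1L])

  # glycoprotein enrichment among decreased proteins (all tested proteins as
  # background)
  out$glycoprotein_in_decreased <- if (length(dec_prot) > 0) {
    dec_mult <- tested$multiplicity[match(dec_prot, tested$protein_id)]
    fisher_enrichment(
      set_hits = sum(dec_mult >= 1L),
      set_total = length(dec_prot),
      bg_hits = sum(tested$multiplicity >= 1L),
      bg_total = nrow(tested)
    )
  }

  # multiplicity-threshold enrichment among decreased glycoproteins
  out$multiplicity_thresholds <- if (length(dec_glycoprot) > 0) {
    multiplicity_enrichment(dec_glycoprot, tested)
  }

  # mean multiplicity, decreased vs unchanged glycoproteins (total proteome)
  unch_glycoprot <- setdiff(
    tested$protein_id[tested$multiplicity >= 1L &
                        tested$protein_id %in%
                          protein_results$feature_id[
                            protein_results$status != "increased"]],
    dec_glycoprot
  )
  out$protein_multiplicity_groups <-
    if (length(dec_glycoprot) > 0 && length(unch_glycoprot) > 0) {
      multiplicity_group_test(
        tested[match(dec_glycoprot, tested$protein_id), ],
        tested[match(unch_glycoprot, tested$protein_id), ]
      )
    }

  parts <- partition_sites(glyco_results, reference)
  out$site_partition <- parts

  # per-protein view of the glyco branch: proteins with >= 1 decreased
  # glycopeptide vs the other reference glycoproteins
  dec_site_prot <- unique(parts$decreased$protein_id)
  other_prot <- setdiff(unique(reference$protein_id), dec_site_prot)
  out$glyco_multiplicity_groups <-
    if (length(dec_site_prot) > 0 && length(other_prot) > 0) {
      multiplicity_group_test(
        profiles[match(dec_site_prot, profiles$protein_id), ],
        profiles[match(other_prot, profiles$protein_id), ]
      )
    }

  out$motif <- if (nrow(parts$decreased) > 0 && nrow(parts$unchanged) > 0) {
    sequon_position_enrichment(parts$decreased, parts$unchanged, proteins)
  }

  out$nxs_correlation <- tryCatch(
    nxs_multiplicity_correlation(parts$decreased, parts$unchanged, profiles),
    error = function(e) NULL
  )

  analysed <- glyco_results$feature_id
  dec_features <- glyco_results$feature_id[
    glyco_results$status %in% c("decreased", "exclusive_control")]
  out$annotation <- purrr::imap_dfr(annotation_sets, function(members, label) {
    tryCatch(
      annotation_set_enrichment(dec_features, analysed, label, members),
      error = function(e) NULL
    )
  })
  out
}

#' @export
print.glyco_pipeline <- function(x, ...) {
  g <- generics::glance(x)
  cat("Glycoproteomics differential occupancy pipeline\n")
  cat(sprintf("  total proteome: %d features, %d complete-case, %d DAP (%d decreased)\n",
              x$n_protein_features, nrow(x$protein_results),
              g$n_dap, g$n_dap_decreased))
  cat(sprintf("  glyco branch:   %d features, %d testable, %d exclusive-control, %d exclusive-mutant\n",
              x$n_glyco_features,
              sum(!x$glyco_results$status %in%
                    c("exclusive_control", "exclusive_mutant")),
              length(x$glyco_filter$exclusive_control),
              length(x$glyco_filter$exclusive_mutant)))
  cat(sprintf("  reference glycoproteome: %d sites on %d proteins (%d novel)\n",
              nrow(x$reference), length(unique(x$reference$protein_id)),
              x$novel_summary$n_novel))
  cat(sprintf("  decreased glyco calls: %d (+%d exclusive-control), increased: %d\n",
              sum(x$glyco_results$status == "decreased"),
              sum(x$glyco_results$status == "exclusive_control"),
              sum(x$glyco_results$status == "increased")))
  if (!is.null(x$enrichment$glycoprotein_in_decreased)) {
    e <- x$enrichment$glycoprotein_in_decreased
    cat(sprintf("  glycoprotein enrichment among decreased DAP: fold %.2f, p = %.3g\n",
                e$fold_enrichment, e$p_value))
  }
  if (!is.null(x$crossref)) {
    n_un <- sum(x$crossref$calls$call == "unoccupied_in_mutant")
    cat(sprintf("  occupancy cross-reference: %d site(s) unoccupied in mutant\n",
                n_un))
  }
  invisible(x)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wp <- function(obj, name) write_results(obj, file.path(out_dir, name))
  wp(res$reference, "reference_sites.tsv")
  wp(res$profiles, "multiplicity_profiles.tsv")
  wp(res$protein_results, "protein_differential.tsv")
  wp(res$glyco_results, "glyco_differential.tsv")
  if (!is.null(res$crossref)) {
    wp(res$crossref$calls, "occupancy_calls.tsv")
  }
  if (!is.null(res$enrichment$multiplicity_thresholds)) {
    wp(res$enrichment$multiplicity_thresholds,
       "multiplicity_enrichment.tsv")
  }
  if (!is.null(res$enrichment$motif)) {
    wp(res$enrichment$motif$features, "motif_enrichment.tsv")
    wp(res$enrichment$motif$logo, "logo_matrix.tsv")
  }
  if (!is.null(res$enrichment$nxs_correlation)) {
    wp(res$enrichment$nxs_correlation$points, "nxs_correlation_points.tsv")
    wp(res$enrichment$nxs_correlation$stats, "nxs_correlation_stats.tsv")
  }
  if (!is.null(res$enrichment$annotation) &&
      nrow(res$enrichment$annotation) > 0) {
    wp(res$enrichment$annotation, "annotation_enrichment.tsv")
  }
  yaml::write_yaml(res$params, file.path(out_dir, "config.yaml"))
  writeLines(utils::capture.output(print(res)),
             file.path(out_dir, "report.txt"))
  invisible(out_dir)
}
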