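#' Dyad-level strain sharing analysis of a social cohort
#'
#' Computes joint presence and pairwise popANI comparisons for each listed
#' sample dyad, summarises sharing per dyad, and compares sharing rates
#' across dyad categories with both the Welch/Benjamini-Hochberg and the
#' Tukey HSD routes.
#'
#' @param profiles list of [allele_profile()]s.
#' @param dyads data.frame `sample_a`, `sample_b`, `category`.
#' @param min_depth,min_breadth,ani_threshold,min_count,min_freq thresholds
#'   as elsewhere.
#' @return Object of class `social_analysis`: `summaries`, `comparisons`,
#'   `presence`, `tests_welch`, `tests_tukey`, `thresholds`.
#' @export
social_sharing_analysis <- function(profiles, dyads,
                                    min_depth = 5L, min_breadth = 0.25,
                                    ani_threshold = 0.99999,
                                    min_count = 2L, min_freq = 0.05) {
  presence <- presence_table(profiles, min_depth, min_breadth)
  comparisons <- compare_cohort(profiles, dyads, presence,
                                min_depth, min_breadth, min_count, min_freq)
  summaries <- dyad_summaries(dyads, comparisons, presence, ani_threshold)
  has2 <- length(unique(summaries$category[!is.na(summaries$sharing_rate)])) >= 2L
  tw <- if (has2) compare_sharing_across_categories(summaries, "welch_bh") else NULL
  tk <- if (has2) compare_sharing_across_categories(summaries, "tukey") else NULL
  structure(list(summaries = summaries, comparisons = comparisons,
                 presence = presence, tests_welch = tw, tests_tukey = tk,
                 thresholds = list(min_depth = min_depth,
                                   min_breadth = min_breadth,
                                   ani_threshold = ani_threshold,
                                   min_count = min_count,
                                   min_freq = min_freq)),
            class = "social_analysis")
}

#' @export
print.social_analysis <- function(x, ...) {
  cat("Social-cohort strain sharing analysis\n")
  s <- x$summaries[!is.na(x$summaries$sharing_rate), , drop = FALSE]
  agg <- tapply(s$sharing_rate, s$category, mean)
  for (nm in names(agg))
    cat(sprintf("  %-18s n = %2d  mean sharing rate %5.1f%%\n",
                nm, sum(s$category == nm), 100 * agg[[nm]]))
  if (!is.null(x$tests_tukey)) {
    cat("  Tukey HSD adjusted p:\n")
    for (i in seq_len(nrow(x$tests_tukey)))
      cat(sprintf("    %s - %s: %s\n", x$tests_tukey$group1[i],
                  x$tests_tukey$group2[i],
                  format.pval(x$tests_tukey$p_adj[i], digits = 2)))
  }
  invisible(x)
}

#' @export
plot.social_analysis <- function(x, ...) {
  s <- x$summaries[!is.na(x$summaries$sharing_rate), , drop = FALSE]
  graphics::boxplot(sharing_rate ~ category, data = s,
                    xlab = "", ylab = "strain sharing rate", las = 2, ...)
  invisible(x)
}

#' Run the end-to-end pipeline on a simulated cohort
#'
#' Simulates a cohort under the configured design, then executes every
#' downstream stage in order — presence, comparison, dyad sharing, the
#' transmission-filter cascade and enrichment (transplant design) or
#' category tests and covariate regressions (social design) — logging the
#' count of items at each stage. Fully reproducible given the seeds.
#'
#' @param config a [pipeline_config()].
#' @param sim a [sim_config()] for the simulation stage.
#' @param out_dir optional directory to write TSV outputs into.
#' @param quiet suppress stage logging.
#' @return Object of class `strainshare_pipeline` with the cohort, the
#'   stage results and the stage-count `log` data.frame.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         sim = sim_config(seed = config$seed),
                         out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  note <- function(stage, count) {
    log[[length(log) + 1L]] <<- data.frame(stage = stage, count = count)
    if (!quiet) message(sprintf("[%s] %d", stage, count))
  }
  th <- config[c("min_depth", "min_breadth", "ani_threshold",
                 "min_count", "min_freq")]
  if (config$design == "fmt") {
    cohort <- simulate_fmt_cohort(sim, seed = config$seed)
    note("profiles", length(cohort$profiles))
    an <- fmt_strain_analysis(cohort$profiles, cohort$metadata,
                              min_depth = th$min_depth,
                              min_breadth = th$min_breadth,
                              ani_threshold = th$ani_threshold,
                              min_count = th$min_count,
                              min_freq = th$min_freq)
    note("species_detected",
         length(unique(an$presence$species_id[an$presence$present])))
    note("dyad_species_events", nrow(an$events))
    for (t in 0:3)
      note(paste0("shared_events_tier_", t),
           sum(an$events$shared & an$events$tier >= t))
    ann <- cohort$pool$annotations
    ev <- an$events[an$events$shared, , drop = FALSE]
    fam <- stats::setNames(ann$family, ann$species_id)
    enr <- NULL
    if (any(ev$matched) && any(!ev$matched)) {
      enr <- family_composition_test(fam[ev$species_id[ev$matched]],
                                     fam[ev$species_id[!ev$matched]],
                                     seed = config$seed)
    }
    oxy <- stats::setNames(ann$oxygen, ann$species_id)
    anaerobic <- oxy[ev$species_id] == "anaerobic"
    perm <- NULL
    sub <- which(ev$tier >= 2L & ev$matched)
    if (length(sub))
      perm <- permutation_trait_enrichment(anaerobic, sub,
                                           n_perm = config$n_perm,
                                           seed = config$seed)
    res <- list(cohort = cohort, analysis = an, family_test = enr,
                anaerobe_enrichment = perm)
  } else {
    cohort <- simulate_social_cohort(sim, seed = config$seed)
    note("profiles", length(cohort$profiles))
    an <- social_sharing_analysis(cohort$profiles, cohort$dyads,
                                  min_depth = th$min_depth,
                                  min_breadth = th$min_breadth,
                                  ani_threshold = th$ani_threshold,
                                  min_count = th$min_count,
                                  min_freq = th$min_freq)
    note("dyads_with_rate", sum(!is.na(an$summaries$sharing_rate)))
    covs <- cohort$dyads[c("diet_similarity", "month_distance",
                           "rainfall_total")]
    rep_ <- covariate_report(covs, an$summaries$sharing_rate)
    note("covariates_fit", sum(!is.na(rep_$slope)))
    res <- list(cohort = cohort, analysis = an, covariates = rep_)
  }
  res$log <- do.call(rbind, log)
  res$config <- config
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_allele_profiles(cohort$profiles,
                          file.path(out_dir, "profiles.tsv"),
                          file.path(out_dir, "genome_lengths.tsv"))
    utils::write.table(cohort$metadata, file.path(out_dir, "metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cohort$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (config$design == "fmt") {
      utils::write.table(res$analysis$events,
                         file.path(out_dir, "tiered_events.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      utils::write.table(res$analysis$summaries,
                         file.path(out_dir, "dyad_summaries.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(res$covariates,
                         file.path(out_dir, "covariate_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(res$log, file.path(out_dir, "stage_log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(res, class = "strainshare_pipeline")
}

#' @export
print.strainshare_pipeline <- function(x, ...) {
  cat(sprintf("<strainshare_pipeline> %s design\n", x$config$design))
  print(x$log, row.names = FALSE)
  invisible(x)
}
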