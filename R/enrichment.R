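#' Genus-level oxygen tolerance label
#'
#' Collapses per-entry oxygen phenotypes of a genus to a species label:
#' all obligate aerobes give `"aerobic"`, all obligate anaerobes
#' `"anaerobic"`, any mixture (including facultative entries) `"mixed"`,
#' and no entries `"unknown"`.
#'
#' @param genus_entries character vector of entry phenotypes; values
#'   containing "aerobe"/"anaerobe" are recognised, with "facultative"
#'   entries always producing a mixture.
#' @return One of `"aerobic"`, `"anaerobic"`, `"mixed"`, `"unknown"`.
#' @export
annotate_oxygen <- function(genus_entries) {
  e <- tolower(trimws(as.character(genus_entries)))
  e <- e[nzchar(e)]
  if (!length(e)) return("unknown")
  fac <- grepl("facultative", e)
  ana <- !fac & grepl("anaerobe", e)
  aer <- !fac & !ana & grepl("aerobe", e)
  if (all(aer)) return("aerobic")
  if (all(ana)) return("anaerobic")
  "mixed"
}

#' Genus-level host range label
#'
#' @param genus_entries character vector of reported host taxa for the
#'   genus entries.
#' @return `"single_host"` when exactly one distinct host is reported,
#'   `"multi_host"` for more than one, `"unknown"` for none.
#' @export
annotate_host_range <- function(genus_entries) {
  h <- unique(trimws(as.character(genus_entries)))
  h <- h[nzchar(h)]
  if (!length(h)) return("unknown")
  if (length(h) == 1L) "single_host" else "multi_host"
}

#' Family composition test between two event groups
#'
#' Tests whether two collections of sharing events involve different
#' bacterial families, via Fisher's exact test on the family x group
#' contingency table: exact for 2x2 tables, seeded Monte Carlo exact
#' (default 1e5 draws) for larger tables.
#'
#' @param families_a,families_b character vectors of family labels of the
#'   events in each group (at least one event each).
#' @param b_monte Monte Carlo draws for tables larger than 2x2.
#' @param seed seed for the Monte Carlo test.
#' @return List with `p`, `method` and the contingency `table`.
#' @export
family_composition_test <- function(families_a, families_b,
                                    b_monte = 1e5, seed = NULL) {
  if (!length(families_a) || !length(families_b))
    stop("need at least one event per group")
  fam <- factor(c(families_a, families_b))
  grp <- factor(rep(c("a", "b"), c(length(families_a), length(families_b))))
  tab <- table(fam, grp)
  if (nrow(tab) < 2L)
    return(list(p = 1, method = "single family (not testable)", table = tab))
  if (nrow(tab) == 2L) {
    ft <- stats::fisher.test(tab)
    return(list(p = ft$p.value, method = "Fisher exact (2x2)", table = tab))
  }
  ft <- with_seed(seed,
                  stats::fisher.test(tab, simulate.p.value = TRUE, B = b_monte))
  list(p = ft$p.value, method = sprintf("Fisher Monte Carlo (B = %g)", b_monte),
       table = tab)
}

#' Log2 odds ratio of a family between two event groups
#'
#' Odds of an event belonging to the given family in group a versus group
#' b, on the log2 scale, with a Haldane-Anscombe correction (+0.5 to every
#' cell) when any cell is zero, and a Woolf 95% confidence interval.
#'
#' @param families_a,families_b family labels per event in each group.
#' @param family the family to test.
#' @return List with `log2_or`, `ci_lower`, `ci_upper` and the 2x2 counts.
#' @export
family_log_odds <- function(families_a, families_b, family) {
  a_in <- sum(families_a == family); a_out <- length(families_a) - a_in
  b_in <- sum(families_b == family); b_out <- length(families_b) - b_in
  cells <- c(a_in, a_out, b_in, b_out)
  if (any(cells == 0)) cells <- cells + 0.5
  lor <- log2((cells[1L] * cells[4L]) / (cells[2L] * cells[3L]))
  se_ln <- sqrt(sum(1 / cells))
  half <- 1.96 * se_ln / log(2)
  list(log2_or = lor, ci_lower = lor - half, ci_upper = lor + half,
       counts = c(a_in = a_in, a_out = a_out, b_in = b_in, b_out = b_out))
}

#' Baseline prevalence of event species, compared between dyad types
#'
#' Annotates each sharing event with the number of baseline samples in
#' which its species passes presence (e.g. donors and/or pre-transplant
#' recipients) and compares matched versus mismatched event prevalences
#' with a Welch t-test.
#'
#' @param events data.frame with `species_id` and logical `matched`.
#' @param presence a [presence_table()].
#' @param baseline_samples character vector of baseline sample ids
#'   (non-empty).
#' @return List with `events` (input plus `prevalence`), and `t`, `df`,
#'   `p` of the matched-vs-mismatched Welch comparison (`NA` when a group
#'   has fewer than two events).
#' @export
prevalence_of_events <- function(events, presence, baseline_samples) {
  if (!length(baseline_samples)) stop("baseline_samples must be non-empty")
  base <- presence[presence$present &
                   presence$sample_id %in% baseline_samples, , drop = FALSE]
  prev <- table(factor(base$species_id))
  events$prevalence <- as.integer(prev[events$species_id])
  events$prevalence[is.na(events$prevalence)] <- 0L
  pm <- events$prevalence[events$matched]
  pu <- events$prevalence[!events$matched]
  if (length(pm) >= 2L && length(pu) >= 2L &&
      (stats::sd(pm) > 0 || stats::sd(pu) > 0)) {
    tt <- stats::t.test(pm, pu, var.equal = FALSE)
    list(events = events, t = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value)
  } else {
    t_ <- if (length(pm) >= 2L && length(pu) >= 2L) 0 else NA_real_
    list(events = events, t = t_, df = NA_real_,
         p = if (identical(t_, 0)) 1 else NA_real_)
  }
}

#' Permutation test for trait enrichment in a filtered event subset
#'
#' The cumulative filters produce subsets of the full list of sharing
#' events, so a filtered subset's trait proportion cannot be compared to
#' the full list with an independence test. Instead, `n_perm` subsets of
#' the observed size are drawn from the full list without replacement and
#' the p-value is the proportion of draws whose trait proportion is as or
#' more extreme than the observed one — at or above for `"greater"`
#' (enrichment, the default), at or below for `"less"`, or as far from the
#' full-list proportion in absolute value for `"two.sided"`. The raw
#' proportion of draws is reported, so the smallest attainable p is
#' `1/n_perm`. Events with unknown trait are excluded from the full list
#' and the subset alike, with a message.
#'
#' @param trait logical vector over all events (NA = unknown).
#' @param subset logical vector or integer indices marking the observed
#'   subset within `trait` (non-empty after unknown removal).
#' @param n_perm number of permutations (default 1000).
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @param seed seed for reproducibility.
#' @return List with `p`, `observed` (subset trait proportion),
#'   `background` (full-list proportion), `subset_size`, `n_perm`.
#' @export
permutation_trait_enrichment <- function(trait, subset, n_perm = 1000L,
                                         alternative = c("greater", "less",
                                                         "two.sided"),
                                         seed = NULL) {
  alternative <- match.arg(alternative)
  trait <- as.logical(trait)
  if (is.logical(subset)) {
    if (length(subset) != length(trait))
      stop("logical subset must match trait length")
    subset <- which(subset)
  }
  subset <- as.integer(subset)
  if (any(subset < 1L | subset > length(trait)))
    stop("subset indices out of range")
  known <- !is.na(trait)
  if (!all(known)) {
    message(sum(!known), " event(s) with unknown trait excluded")
    keep <- which(known)
    subset <- match(intersect(subset, keep), keep)
    trait <- trait[keep]
  }
  n <- length(trait)
  k <- length(subset)
  if (k == 0L) stop("observed subset is empty")
  if (k > n) stop("subset larger than the event list")
  obs <- mean(trait[subset])
  bg <- mean(trait)
  eps <- 1e-9
  with_seed(seed, {
    draws <- vapply(seq_len(n_perm),
                    function(i) mean(trait[sample.int(n, k)]), 0)
    p <- switch(alternative,
                greater = mean(draws >= obs - eps),
                less = mean(draws <= obs + eps),
                two.sided = mean(abs(draws - bg) >= abs(obs - bg) - eps))
    list(p = p, observed = obs, background = bg,
         subset_size = k, n_perm = n_perm, alternative = alternative)
  })
}
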