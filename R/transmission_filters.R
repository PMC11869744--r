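#' Was the strain absent from the recipient before the transplant?
#'
#' First rung of the cumulative transmission-filter cascade: a sharing
#' event can only be transmission if the recipient did not already share
#' the strain with the donor before the transplant. True when the species
#' fails joint presence in the pre-transplant sample (`donor_vs_pre =
#' NULL`) or when the donor/pre comparison falls below the sharing
#' threshold; a comparison with no comparable sites never counts as
#' sharing.
#'
#' @param donor_vs_pre `pairwise_comparison` of the donor against the
#'   recipient's pre-transplant sample, or `NULL` when the species is not
#'   jointly present there.
#' @param ani_threshold popANI sharing threshold.
#' @param has_pre_sample set FALSE when the recipient has no
#'   pre-transplant sample at all; the cascade then stops with an error.
#' @return Logical flag.
#' @export
strain_absent_pre <- function(donor_vs_pre = NULL, ani_threshold = 0.99999,
                              has_pre_sample = TRUE) {
  if (!isTRUE(has_pre_sample))
    stop("transmission cascade requires the recipient's pre-transplant sample")
  if (is.null(donor_vs_pre)) return(TRUE)
  stopifnot(inherits(donor_vs_pre, "pairwise_comparison"))
  !(isTRUE(donor_vs_pre$evaluable) && donor_vs_pre$popANI >= ani_threshold)
}

#' Is the strain unique to the focal donor?
#'
#' Second rung: strains detected in more than one donor before the
#' transplant are excluded, because widespread strains can be acquired from
#' sources other than the designated donor. Divergent conspecific strains
#' in other donors (below the threshold) do not disqualify the event —
#' uniqueness is at the strain level, not the species level.
#'
#' @param cross_comparisons list of `pairwise_comparison`s of the focal
#'   donor against every other donor in which the species passes presence
#'   (possibly empty).
#' @param ani_threshold popANI sharing threshold.
#' @return Logical: TRUE iff no other donor shares the strain.
#' @export
strain_unique_to_donor <- function(cross_comparisons,
                                   ani_threshold = 0.99999) {
  !any(vapply(cross_comparisons, function(cmp) {
    stopifnot(inherits(cmp, "pairwise_comparison"))
    isTRUE(cmp$evaluable) && cmp$popANI >= ani_threshold
  }, TRUE))
}

#' Is the strain unique to the focal recipient?
#'
#' Third rung: strains detected in more than one recipient after the
#' transplant are excluded, reducing the possibility that recipients
#' exchanged the strain with each other independently of the transplant.
#'
#' @param cross_comparisons list of `pairwise_comparison`s of the focal
#'   recipient's post-transplant sample against every other recipient's
#'   post-transplant sample where the species passes presence.
#' @param ani_threshold popANI sharing threshold.
#' @return Logical: TRUE iff no other recipient shares the strain.
#' @export
strain_unique_to_recipient <- function(cross_comparisons,
                                       ani_threshold = 0.99999) {
  strain_unique_to_donor(cross_comparisons, ani_threshold)
}

#' Assign cumulative transmission tiers to sharing events
#'
#' Tier 0 is any strain-sharing event; tier 1 additionally requires the
#' strain to have been absent from the recipient pre-transplant; tier 2
#' additionally requires uniqueness to one donor; tier 3 additionally
#' requires uniqueness to one recipient. The criteria are cumulative, so
#' tier sets are nested by construction: an event's tier is the highest
#' rung whose predicates all hold.
#'
#' @param events data.frame with logical columns `absent_pre`,
#'   `unique_donor`, `unique_recipient`.
#' @return The events with an integer `tier` column (0-3) appended.
#' @export
assign_tiers <- function(events) {
  need <- c("absent_pre", "unique_donor", "unique_recipient")
  if (!all(need %in% names(events)))
    stop("events must have columns ", paste(need, collapse = ", "))
  e1 <- events$absent_pre
  e2 <- e1 & events$unique_donor
  e3 <- e2 & events$unique_recipient
  events$tier <- e1 + e2 + e3
  events
}

#' Full transmission-filter analysis of a transplant cohort
#'
#' Runs the whole cascade over every donor x recipient dyad (matched pairs
#' — recipients with their designated donor — and mismatched pairs alike):
#' joint presence, pairwise popANI/conANI comparison, sharing calls, the
#' three cumulative filters, per-dyad sharing rates at each tier, and Welch
#' t tests of matched versus mismatched rates with Benjamini-Hochberg
#' adjustment across tiers.
#'
#' At tier t, a dyad's sharing rate is the fraction of its jointly present,
#' tier-t-eligible species whose comparison meets the sharing threshold;
#' species with non-evaluable comparisons are excluded throughout.
#'
#' @param profiles list of [allele_profile()]s covering the cohort.
#' @param metadata sample metadata with columns `sample_id`, `host_id`,
#'   `role` (`donor`/`recipient`), `timepoint` (`pre`/`post`/`none`) and
#'   `designated_donor` (donor host for each recipient).
#' @param min_depth,min_breadth presence thresholds.
#' @param ani_threshold popANI sharing threshold (one global threshold for
#'   dyad sharing and cross-cohort strain identity).
#' @param min_count,min_freq allele detection thresholds.
#' @param donor_scope `"donors"` evaluates donor-uniqueness against the
#'   other donors only (the default); `"all_pre"` against all other
#'   pre-transplant samples including recipients'.
#' @param pre_mode how "shared prior to transplant" is operationalised:
#'   `"donor_vs_pre"` (default) compares the donor with the recipient's
#'   pre sample; `"pre_vs_post"` compares the recipient's own pre and post
#'   samples.
#' @return An object of class `fmt_analysis`: `events` (one row per dyad x
#'   jointly present species with sharing flag, filter flags and tier),
#'   `dyad_rates` (per dyad: `matched`, `rate_0`..`rate_3`,
#'   `n_eligible_0`..`n_eligible_3`), `tests` (Welch/BH per tier),
#'   `presence`, and the thresholds used.
#' @export
fmt_strain_analysis <- function(profiles, metadata,
                                min_depth = 5L, min_breadth = 0.25,
                                ani_threshold = 0.99999,
                                min_count = 2L, min_freq = 0.05,
                                donor_scope = c("donors", "all_pre"),
                                pre_mode = c("donor_vs_pre", "pre_vs_post")) {
  donor_scope <- match.arg(donor_scope)
  pre_mode <- match.arg(pre_mode)
  idx <- profile_index(profiles)
  presence <- presence_table(profiles, min_depth, min_breadth)
  pres <- presence[presence$present, , drop = FALSE]
  by_sample <- split(pres$species_id, pres$sample_id)
  sp_in <- function(s) by_sample[[s]] %||% character(0)

  md <- metadata
  donors <- md[md$role == "donor", , drop = FALSE]
  rec <- md[md$role == "recipient", , drop = FALSE]
  rhosts <- unique(rec$host_id)
  pre_of <- post_of <- designated <- character(0)
  for (h in rhosts) {
    pre <- rec$sample_id[rec$host_id == h & rec$timepoint == "pre"]
    post <- rec$sample_id[rec$host_id == h & rec$timepoint == "post"]
    if (length(post) != 1L)
      stop("recipient ", h, " must have exactly one post-transplant sample")
    if (length(pre) != 1L)
      stop("recipient ", h, " lacks a pre-transplant sample; ",
           "the cascade requires the pre timepoint")
    pre_of[h] <- pre; post_of[h] <- post
    designated[h] <- rec$designated_donor[rec$host_id == h][1L]
  }
  donor_sample <- stats::setNames(donors$sample_id, donors$host_id)

  cache <- new.env(parent = emptyenv())
  cmp <- function(sa, sb, sp) {
    k <- paste(sort(c(sa, sb))[1L], sort(c(sa, sb))[2L], sp, sep = "\x1f")
    v <- cache[[k]]
    if (is.null(v)) {
      v <- compare_profiles(idx[[.pkey(sa, sp)]], idx[[.pkey(sb, sp)]],
                            min_depth, min_count, min_freq)
      cache[[k]] <- v
    }
    v
  }
  shares <- function(sa, sb, sp) {
    c0 <- cmp(sa, sb, sp)
    isTRUE(c0$evaluable) && c0$popANI >= ani_threshold
  }

  rows <- list()
  for (dh in names(donor_sample)) {
    d <- donor_sample[[dh]]
    for (rh in rhosts) {
      p <- post_of[[rh]]; q <- pre_of[[rh]]
      for (sp in intersect(sp_in(d), sp_in(p))) {
        c0 <- cmp(d, p, sp)
        if (!c0$evaluable) next
        shared <- c0$popANI >= ani_threshold
        absent_pre <- if (pre_mode == "donor_vs_pre") {
          strain_absent_pre(if (sp %in% sp_in(q)) cmp(d, q, sp) else NULL,
                            ani_threshold)
        } else {
          strain_absent_pre(if (sp %in% sp_in(q) && sp %in% sp_in(p))
            cmp(q, p, sp) else NULL, ani_threshold)
        }
        dscope <- setdiff(unname(donor_sample), d)
        if (donor_scope == "all_pre")
          dscope <- c(dscope, unname(pre_of[setdiff(rhosts, rh)]))
        dscope <- dscope[vapply(dscope, function(s) sp %in% sp_in(s), TRUE)]
        unique_donor <- strain_unique_to_donor(
          lapply(dscope, cmp, sb = d, sp = sp), ani_threshold)
        rscope <- unname(post_of[setdiff(rhosts, rh)])
        rscope <- rscope[vapply(rscope, function(s) sp %in% sp_in(s), TRUE)]
        unique_recipient <- strain_unique_to_recipient(
          lapply(rscope, cmp, sb = p, sp = sp), ani_threshold)
        rows[[length(rows) + 1L]] <- data.frame(
          donor_sample = d, recipient_sample = p, donor_host = dh,
          recipient_host = rh, matched = identical(designated[[rh]], dh),
          species_id = sp, popANI = c0$popANI, conANI = c0$conANI,
          shared = shared, absent_pre = absent_pre,
          unique_donor = unique_donor, unique_recipient = unique_recipient,
          stringsAsFactors = FALSE)
      }
    }
  }
  events <- do.call(rbind, rows)
  if (is.null(events)) stop("no jointly present species in any dyad")
  events <- assign_tiers(events)
  rownames(events) <- NULL

  dy <- unique(events[c("donor_sample", "recipient_sample", "matched")])
  rate_cols <- paste0("rate_", 0:3)
  n_cols <- paste0("n_eligible_", 0:3)
  for (cn in c(rate_cols, n_cols)) dy[[cn]] <- NA_real_
  for (i in seq_len(nrow(dy))) {
    ev <- events[events$donor_sample == dy$donor_sample[i] &
                 events$recipient_sample == dy$recipient_sample[i], , drop = FALSE]
    # eligibility at tier t is the cumulative filter applied to all jointly
    # present species, shared or not
    elig <- cbind(rep(TRUE, nrow(ev)),
                  ev$absent_pre,
                  ev$absent_pre & ev$unique_donor,
                  ev$absent_pre & ev$unique_donor & ev$unique_recipient)
    for (t in 0:3) {
      n <- sum(elig[, t + 1L])
      dy[[n_cols[t + 1L]]][i] <- n
      dy[[rate_cols[t + 1L]]][i] <-
        if (n > 0) sum(ev$shared & elig[, t + 1L]) / n else NA_real_
    }
  }
  rownames(dy) <- NULL

  tests <- data.frame(tier = 0:3, statistic = NA_real_, df = NA_real_,
                      p = NA_real_, p_adj = NA_real_,
                      mean_matched = NA_real_, mean_mismatched = NA_real_)
  for (t in 0:3) {
    rm_ <- dy[[rate_cols[t + 1L]]][dy$matched]
    ru <- dy[[rate_cols[t + 1L]]][!dy$matched]
    rm_ <- rm_[!is.na(rm_)]; ru <- ru[!is.na(ru)]
    tests$mean_matched[t + 1L] <- mean(rm_)
    tests$mean_mismatched[t + 1L] <- mean(ru)
    if (length(rm_) >= 2L && length(ru) >= 2L &&
        (stats::sd(rm_) > 0 || stats::sd(ru) > 0)) {
      tt <- stats::t.test(rm_, ru, var.equal = FALSE)
      tests$statistic[t + 1L] <- unname(tt$statistic)
      tests$df[t + 1L] <- unname(tt$parameter)
      tests$p[t + 1L] <- tt$p.value
    }
  }
  ok <- !is.na(tests$p)
  tests$p_adj[ok] <- stats::p.adjust(tests$p[ok], "BH")

  structure(list(events = events, dyad_rates = dy, tests = tests,
                 presence = presence,
                 thresholds = list(min_depth = min_depth,
                                   min_breadth = min_breadth,
                                   ani_threshold = ani_threshold,
                                   min_count = min_count,
                                   min_freq = min_freq,
                                   donor_scope = donor_scope,
                                   pre_mode = pre_mode)),
            class = "fmt_analysis")
}

#' @export
print.fmt_analysis <- function(x, ...) {
  cat("Transplant strain-sharing analysis\n")
  cat(sprintf("  %d dyads (%d matched), %d dyad x species events, %d shared\n",
              nrow(x$dyad_rates), sum(x$dyad_rates$matched),
              nrow(x$events), sum(x$events$shared)))
  cat("  mean sharing rate by cumulative filter tier:\n")
  for (t in 0:3)
    cat(sprintf("    tier %d: matched %5.1f%%  mismatched %5.1f%%  (BH p = %s)\n",
                t, 100 * x$tests$mean_matched[t + 1L],
                100 * x$tests$mean_mismatched[t + 1L],
                format.pval(x$tests$p_adj[t + 1L], digits = 2)))
  invisible(x)
}

#' @export
summary.fmt_analysis <- function(object, ...) {
  out <- list(tests = object$tests,
              tier_counts = vapply(0:3, function(t)
                sum(object$events$shared & object$events$tier >= t), 0L))
  class(out) <- "summary.fmt_analysis"
  out
}

#' @export
print.summary.fmt_analysis <- function(x, ...) {
  cat("Shared events surviving each cumulative tier:\n")
  print(stats::setNames(x$tier_counts, paste0("tier_", 0:3)))
  cat("\nMatched vs mismatched Welch tests (BH across tiers):\n")
  print(x$tests, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.fmt_analysis <- function(x, ...) {
  dy <- x$dyad_rates
  long <- do.call(rbind, lapply(0:3, function(t)
    data.frame(tier = factor(t), matched = dy$matched,
               rate = dy[[paste0("rate_", t)]])))
  graphics::boxplot(rate ~ matched + tier, data = long,
                    col = c("indianred", "steelblue"),
                    names = paste(rep(0:3, each = 2), c("mm", "m")),
                    xlab = "cumulative filter tier", ylab = "sharing rate", ...)
  invisible(x)
}

#' Score cascade events against simulation ground truth
#'
#' Joins the shared events of an [fmt_strain_analysis()] with a simulator
#' truth table and reports, for each cumulative tier, the precision of
#' matched-pair events: the fraction of surviving sharing events that are
#' generatively transmitted donor-to-recipient transfers.
#'
#' @param analysis an `fmt_analysis`.
#' @param truth truth table with `sample_id`, `species_id`, `origin`,
#'   `source_sample` (as emitted by [simulate_fmt_cohort()]).
#' @return data.frame `tier`, `n_events`, `n_true`, `precision` (matched
#'   pairs only; `NA` precision when no event survives a tier).
#' @export
score_transmission_events <- function(analysis, truth) {
  stopifnot(inherits(analysis, "fmt_analysis"))
  ev <- analysis$events
  ev <- ev[ev$shared & ev$matched, , drop = FALSE]
  key <- paste(truth$sample_id, truth$species_id,
               truth$origin, truth$source_sample, sep = "\x1f")
  ev$true_transmission <- paste(ev$recipient_sample, ev$species_id,
                                "transmitted", ev$donor_sample,
                                sep = "\x1f") %in% key
  out <- data.frame(tier = 0:3, n_events = NA_integer_,
                    n_true = NA_integer_, precision = NA_real_)
  for (t in 0:3) {
    sub <- ev[ev$tier >= t, , drop = FALSE]
    out$n_events[t + 1L] <- nrow(sub)
    out$n_true[t + 1L] <- sum(sub$true_transmission)
    out$precision[t + 1L] <-
      if (nrow(sub)) mean(sub$true_transmission) else NA_real_
  }
  out
}
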