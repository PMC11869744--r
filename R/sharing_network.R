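#' Summarise strain sharing for one sample dyad
#'
#' Among the species jointly present in the two samples, counts how many
#' meet the strain-identity threshold and reports the sharing rate
#' (shared strains / shared species). Species whose comparison has no
#' comparable sites are excluded from numerator and denominator alike.
#'
#' @param sample_a,sample_b sample identifiers.
#' @param comparisons data.frame of pairwise comparisons as produced by
#'   [compare_cohort()] (must cover the dyad's jointly present species).
#' @param presence a [presence_table()].
#' @param ani_threshold popANI strain-identity threshold (default 0.99999).
#' @param category optional dyad category label carried through.
#' @return One-row data.frame: `sample_a`, `sample_b`, `category`,
#'   `n_shared_species`, `n_shared_strains`, `sharing_rate` (`NA` when no
#'   species is jointly present; such dyads are excluded from category
#'   statistics with a warning there).
#' @export
summarize_dyad <- function(sample_a, sample_b, comparisons, presence,
                           ani_threshold = 0.99999, category = NA_character_) {
  pa <- presence$species_id[presence$present & presence$sample_id == sample_a]
  pb <- presence$species_id[presence$present & presence$sample_id == sample_b]
  joint <- intersect(pa, pb)
  sel <- (comparisons$sample_a == sample_a & comparisons$sample_b == sample_b) |
         (comparisons$sample_a == sample_b & comparisons$sample_b == sample_a)
  cmp <- comparisons[sel & comparisons$species_id %in% joint, , drop = FALSE]
  cmp <- cmp[cmp$evaluable, , drop = FALSE]
  n_sp <- nrow(cmp)
  n_st <- sum(cmp$popANI >= ani_threshold)
  data.frame(sample_a = sample_a, sample_b = sample_b, category = category,
             n_shared_species = n_sp, n_shared_strains = n_st,
             sharing_rate = if (n_sp > 0) n_st / n_sp else NA_real_,
             stringsAsFactors = FALSE)
}

#' Dyad summaries for a set of sample pairs
#'
#' @param dyads data.frame with columns `sample_a`, `sample_b` and
#'   optionally `category`.
#' @inheritParams summarize_dyad
#' @return data.frame of [summarize_dyad()] rows.
#' @export
dyad_summaries <- function(dyads, comparisons, presence,
                           ani_threshold = 0.99999) {
  cats <- if ("category" %in% names(dyads)) dyads$category else NA_character_
  rows <- lapply(seq_len(nrow(dyads)), function(i)
    summarize_dyad(dyads$sample_a[i], dyads$sample_b[i], comparisons,
                   presence, ani_threshold,
                   category = if (length(cats) > 1L) cats[i] else cats))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Categorise a sample dyad from host metadata
#'
#' Applies the field-study dyad definitions: longitudinal self-pairs are
#' repeat samples of one host 120-150 days apart; pairs of hosts whose
#' lifespans never intersect are `never_overlapped`; contemporaneous hosts
#' in different social groups sampled less than 150 days apart are
#' `different_groups`; hosts in the same group sampled at most 4 days apart
#' (and, when a close-partner list is supplied, designated as close
#' partners) are `close_partners`. Dyads matching no definition are
#' `uncategorized` and excluded from category statistics.
#'
#' @param a,b one-row data.frames (or lists) with `sample_id`, `host_id`,
#'   `date` (Date) and `group`.
#' @param lifespans data.frame `host_id`, `birth`, `death` (Dates; `death`
#'   may be `NA` for animals still alive).
#' @param close_partners optional data.frame of host pairs (`host_a`,
#'   `host_b`) designated as close social partners; when `NULL`, any
#'   same-group pair within the window qualifies.
#' @return Category string.
#' @export
categorize_dyad <- function(a, b, lifespans, close_partners = NULL) {
  da <- as.Date(a$date); db <- as.Date(b$date)
  gap <- abs(as.numeric(db - da))
  if (identical(a$host_id, b$host_id))
    return(if (gap >= 120 && gap <= 150) "longitudinal" else "uncategorized")
  la <- lifespans[lifespans$host_id == a$host_id, , drop = FALSE]
  lb <- lifespans[lifespans$host_id == b$host_id, , drop = FALSE]
  if (nrow(la) != 1L || nrow(lb) != 1L)
    stop("lifespans must contain exactly one row per host")
  ea <- if (is.na(la$death)) as.Date("9999-12-31") else as.Date(la$death)
  eb <- if (is.na(lb$death)) as.Date("9999-12-31") else as.Date(lb$death)
  never <- ea < as.Date(lb$birth) || eb < as.Date(la$birth)
  if (never) return("never_overlapped")
  same_group <- !is.na(a$group) && !is.na(b$group) && a$group == b$group
  if (same_group) {
    if (gap > 4) return("uncategorized")
    if (!is.null(close_partners)) {
      hit <- any((close_partners$host_a == a$host_id & close_partners$host_b == b$host_id) |
                 (close_partners$host_a == b$host_id & close_partners$host_b == a$host_id))
      if (!hit) return("uncategorized")
    }
    return("close_partners")
  }
  if (gap < 150) return("different_groups")
  "uncategorized"
}

#' Compare sharing rates across dyad categories
#'
#' Either all pairwise Welch t-tests with Benjamini-Hochberg adjustment
#' across the family of category pairs, or a one-way Tukey HSD. Dyads with
#' undefined sharing rates are dropped with a warning; category pairs where
#' either side has fewer than two defined rates are flagged not computable.
#'
#' @param summaries data.frame from [dyad_summaries()] with `category` and
#'   `sharing_rate`.
#' @param method `"welch_bh"` or `"tukey"`.
#' @return data.frame with `group1`, `group2`, `estimate` (mean difference
#'   group2 - group1), `statistic` (Welch t; `NA` for Tukey), `df`, `p`
#'   (raw; for Tukey the adjusted p is also reported here), `p_adj` and
#'   `computable`.
#' @export
compare_sharing_across_categories <- function(summaries,
                                              method = c("welch_bh", "tukey")) {
  method <- match.arg(method)
  s <- summaries[!is.na(summaries$category) &
                 summaries$category != "uncategorized", , drop = FALSE]
  if (anyNA(s$sharing_rate)) {
    warning(sum(is.na(s$sharing_rate)),
            " dyad(s) with undefined sharing rate excluded")
    s <- s[!is.na(s$sharing_rate), , drop = FALSE]
  }
  rates <- split(s$sharing_rate, s$category)
  cats <- names(rates)
  if (length(cats) < 2L) stop("need at least two categories")
  prs <- utils::combn(cats, 2L)
  out <- data.frame(group1 = prs[1L, ], group2 = prs[2L, ],
                    estimate = NA_real_, statistic = NA_real_, df = NA_real_,
                    p = NA_real_, p_adj = NA_real_,
                    computable = TRUE, stringsAsFactors = FALSE)
  ok_cat <- vapply(rates, function(r) length(r) >= 2L, TRUE)
  out$computable <- ok_cat[out$group1] & ok_cat[out$group2]
  if (method == "welch_bh") {
    for (i in which(out$computable)) {
      tt <- stats::t.test(rates[[out$group2[i]]], rates[[out$group1[i]]],
                          var.equal = FALSE)
      out$estimate[i] <- unname(diff(rev(tt$estimate)))
      out$statistic[i] <- unname(tt$statistic)
      out$df[i] <- unname(tt$parameter)
      out$p[i] <- tt$p.value
    }
    out$p_adj[out$computable] <- stats::p.adjust(out$p[out$computable], "BH")
  } else {
    keep <- s$category %in% cats[ok_cat]
    if (sum(ok_cat) >= 2L) {
      fit <- stats::aov(sharing_rate ~ category, data = s[keep, , drop = FALSE])
      tk <- stats::TukeyHSD(fit)$category
      nm <- strsplit(rownames(tk), "-", fixed = TRUE)
      for (j in seq_along(nm)) {
        i <- which((out$group1 == nm[[j]][2L] & out$group2 == nm[[j]][1L]) |
                   (out$group1 == nm[[j]][1L] & out$group2 == nm[[j]][2L]))
        sgn <- if (out$group2[i] == nm[[j]][1L]) 1 else -1
        out$estimate[i] <- sgn * tk[j, "diff"]
        out$df[i] <- fit$df.residual
        out$p[i] <- out$p_adj[i] <- tk[j, "p adj"]
      }
    }
  }
  out
}

#' Downsampling robustness of category comparisons
#'
#' Re-runs the Tukey HSD category comparison on datasets downsampled so
#' that no host contributes more than one sampling unit: each host's units
#' are its single samples, plus each of its longitudinal self-pairs taken
#' as one unit (so the longitudinal category can survive downsampling); one
#' unit per host is retained per iteration and only dyads whose two samples
#' are both retained are kept.
#'
#' @param summaries [dyad_summaries()] output with categories.
#' @param host_map named character vector mapping sample_id to host_id.
#' @param n_iter number of downsampling iterations (default 100).
#' @param seed seed for reproducibility.
#' @return data.frame with `iter`, `group1`, `group2`, `p_adj`,
#'   `computable`; pairs that cannot be tested in an iteration are present
#'   with `computable = FALSE` rather than silently dropped.
#' @export
downsample_robustness <- function(summaries, host_map, n_iter = 100L,
                                  seed = NULL) {
  s <- summaries[!is.na(summaries$sharing_rate) &
                 summaries$category != "uncategorized", , drop = FALSE]
  miss <- setdiff(unique(c(s$sample_a, s$sample_b)), names(host_map))
  if (length(miss))
    stop("host_map does not cover samples: ", paste(miss, collapse = ", "))
  cats <- sort(unique(s$category))
  prs <- if (length(cats) >= 2L) utils::combn(cats, 2L) else
    matrix(character(0), 2L)
  units <- list()  # per host: list of character vectors of sample ids
  for (h in unique(host_map)) {
    smp <- names(host_map)[host_map == h]
    u <- as.list(smp)
    lon <- s[s$category == "longitudinal" &
             host_map[s$sample_a] == h & host_map[s$sample_b] == h, , drop = FALSE]
    if (nrow(lon))
      u <- c(u, lapply(seq_len(nrow(lon)),
                       function(i) c(lon$sample_a[i], lon$sample_b[i])))
    units[[h]] <- u
  }
  with_seed(seed, {
    res <- vector("list", n_iter)
    for (it in seq_len(n_iter)) {
      kept <- unlist(lapply(units, function(u) u[[sample.int(length(u), 1L)]]))
      sub <- s[s$sample_a %in% kept & s$sample_b %in% kept, , drop = FALSE]
      row <- data.frame(iter = it, group1 = prs[1L, ], group2 = prs[2L, ],
                        p_adj = NA_real_, computable = FALSE,
                        stringsAsFactors = FALSE)
      tab <- table(sub$category)
      if (sum(tab >= 2L) >= 2L) {
        tk <- tryCatch(
          compare_sharing_across_categories(sub, method = "tukey"),
          error = function(e) NULL)
        if (!is.null(tk)) {
          m <- match(paste(row$group1, row$group2),
                     paste(tk$group1, tk$group2))
          row$p_adj <- tk$p_adj[m]
          row$computable <- !is.na(row$p_adj)
        }
      }
      res[[it]] <- row
    }
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
  })
}

#' Strain sharing flags from a phylogenetic distance matrix
#'
#' A lightweight marker-gene alternative to the ANI route: pairwise
#' phylogenetic distances for one species are normalised and pairs at or
#' below the threshold are flagged as sharing a strain. `mode = "max_norm"`
#' divides by the species' maximum pairwise distance (a fixed normalised
#' cutoff, default 0.1); `mode = "quantile"` instead uses the given
#' quantile of the off-diagonal distances as the cutoff. Flags are
#' invariant to global rescaling of the matrix in both modes.
#'
#' @param distances square symmetric non-negative matrix with zero
#'   diagonal and sample labels as dimnames.
#' @param threshold normalised cutoff (max_norm) or quantile (quantile
#'   mode); default 0.1.
#' @param mode `"max_norm"` or `"quantile"`.
#' @return Logical matrix of sharing flags (diagonal `TRUE`).
#' @export
phylo_share <- function(distances, threshold = 0.1,
                        mode = c("max_norm", "quantile")) {
  mode <- match.arg(mode)
  d <- as.matrix(distances)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12) || any(d < 0) ||
      any(abs(diag(d)) > 1e-12))
    stop("distances must be square, symmetric, non-negative with zero diagonal")
  if (max(d) == 0) {
    warning("all distances are zero; every pair flagged as sharing")
    return(matrix(TRUE, nrow(d), ncol(d), dimnames = dimnames(d)))
  }
  cut <- if (mode == "max_norm") threshold * max(d) else
    stats::quantile(d[lower.tri(d)], threshold, names = FALSE)
  shared <- d <= cut
  diag(shared) <- TRUE
  shared
}
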