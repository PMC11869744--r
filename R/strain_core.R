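#' Construct an allele profile
#'
#' An allele profile is the per-sample, per-species record of read evidence:
#' for every covered genome position, the counts of A, C, G and T observed
#' in the pileup. It is the atomic input to presence calls and to all
#' pairwise strain comparisons.
#'
#' @param sample_id,species_id identifiers.
#' @param genome_length genome length in bp (concatenated scaffolds).
#' @param pos integer vector of 0-based genome positions (unique).
#' @param counts integer matrix with `length(pos)` rows and four columns
#'   (A, C, G, T) of non-negative base counts.
#' @return An object of class `allele_profile`: a list with fields
#'   `sample_id`, `species_id`, `genome_length`, `pos` (sorted) and `counts`.
#' @examples
#' p <- allele_profile("s1", "sp1", 100,
#'                     pos = c(0, 5), counts = rbind(c(8, 0, 0, 0), c(0, 6, 2, 0)))
#' p
#' @export
allele_profile <- function(sample_id, species_id, genome_length, pos, counts) {
  genome_length <- as.integer(genome_length)
  if (length(genome_length) != 1L || is.na(genome_length) || genome_length <= 0L)
    stop("genome_length must be a single positive integer")
  pos <- as.integer(pos)
  if (is.null(dim(counts))) counts <- matrix(as.integer(counts), ncol = 4L)
  counts <- matrix(as.integer(counts), ncol = 4L,
                   dimnames = list(NULL, BASES))
  if (length(pos) != nrow(counts))
    stop("pos and counts disagree in length")
  if (anyDuplicated(pos)) stop("duplicate positions in profile")
  if (length(pos) && (min(pos) < 0L || max(pos) >= genome_length))
    stop("positions must lie in [0, genome_length)")
  if (length(counts) && min(counts) < 0L) stop("negative base counts")
  o <- order(pos)
  structure(list(sample_id = as.character(sample_id),
                 species_id = as.character(species_id),
                 genome_length = genome_length,
                 pos = pos[o],
                 counts = counts[o, , drop = FALSE]),
            class = "allele_profile")
}

#' @export
print.allele_profile <- function(x, ...) {
  cat(sprintf("<allele_profile> sample %s, species %s: %d covered sites of %d bp\n",
              x$sample_id, x$species_id, length(x$pos), x$genome_length))
  invisible(x)
}

#' Detect alleles at a single site
#'
#' A base is called as a detected allele when it is supported by at least
#' `min_count` reads and makes up at least `min_freq` of the site's depth.
#' Both the major (consensus) and minor alleles that pass are returned, which
#' is what makes the downstream popANI comparison microdiversity-aware.
#'
#' @param counts numeric vector of length 4 (counts of A, C, G, T).
#' @param min_count minimum reads supporting an allele (default 2).
#' @param min_freq minimum within-site frequency (default 0.05).
#' @return Character vector of detected bases (possibly empty at depth 0).
#' @examples
#' detect_alleles(c(8, 2, 0, 0))            # major and minor allele
#' detect_alleles(c(9, 1, 0, 0))            # minor fails min_count
#' @export
detect_alleles <- function(counts, min_count = 2L, min_freq = 0.05) {
  counts <- as.numeric(counts)
  if (length(counts) != 4L) stop("counts must have length 4 (A, C, G, T)")
  depth <- sum(counts)
  if (depth <= 0) return(character(0))
  BASES[counts >= min_count & counts / depth >= min_freq]
}

# Vectorised allele mask: logical n x 4, TRUE where the base is a detected
# allele under the single-site rule.
.allele_mask <- function(counts, depth, min_count, min_freq) {
  counts >= min_count & counts >= depth * min_freq
}

#' Call species presence from an allele profile
#'
#' A species is present in a sample when at least a fraction `min_breadth`
#' of its genome is covered at depth `min_depth` or more. The defaults (25%
#' breadth at 5x) retain rare, low-abundance strains while controlling
#' false positives.
#'
#' @param profile an [allele_profile()].
#' @param min_depth minimum per-site depth counted toward breadth (default 5).
#' @param min_breadth minimum covered fraction of the genome (default 0.25).
#' @return A list of class `presence_call` with `sample_id`, `species_id`,
#'   `breadth`, `mean_depth` (genome-wide) and the logical `present`.
#' @export
presence_call <- function(profile, min_depth = 5L, min_breadth = 0.25) {
  stopifnot(inherits(profile, "allele_profile"))
  depth <- rowSums(profile$counts)
  breadth <- sum(depth >= min_depth) / profile$genome_length
  structure(list(sample_id = profile$sample_id,
                 species_id = profile$species_id,
                 breadth = breadth,
                 mean_depth = sum(depth) / profile$genome_length,
                 present = breadth >= min_breadth),
            class = "presence_call")
}

#' @export
print.presence_call <- function(x, ...) {
  cat(sprintf("<presence_call> %s / %s: breadth %.3f, mean depth %.1f -> %s\n",
              x$sample_id, x$species_id, x$breadth, x$mean_depth,
              if (x$present) "present" else "absent"))
  invisible(x)
}

#' Presence table for a collection of profiles
#'
#' @param profiles list of [allele_profile()] objects.
#' @inheritParams presence_call
#' @return data.frame with one row per profile: `sample_id`, `species_id`,
#'   `breadth`, `mean_depth`, `present`.
#' @export
presence_table <- function(profiles, min_depth = 5L, min_breadth = 0.25) {
  rows <- lapply(profiles, function(p) {
    pc <- presence_call(p, min_depth, min_breadth)
    data.frame(sample_id = pc$sample_id, species_id = pc$species_id,
               breadth = pc$breadth, mean_depth = pc$mean_depth,
               present = pc$present, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sample_id = character(), species_id = character(),
                      breadth = numeric(), mean_depth = numeric(),
                      present = logical())
  rownames(out) <- NULL
  out
}

#' Compare two allele profiles (popANI and conANI)
#'
#' Comparison is restricted to sites covered at depth `min_depth` or more in
#' both samples. A site is a population-level (popANI) substitution only when
#' the two samples' detected allele sets are disjoint, i.e. they share no
#' allele, major or minor; it is a consensus-level (conANI) substitution when
#' the majority bases differ (consensus ties broken alphabetically,
#' A < C < G < T). popANI is therefore never below conANI.
#'
#' @param a,b [allele_profile()] objects for the same species and genome.
#' @param min_depth minimum depth in both samples for a site to be compared.
#' @param min_count,min_freq allele detection thresholds, see
#'   [detect_alleles()].
#' @return A list of class `pairwise_comparison` with fields `sample_a`,
#'   `sample_b`, `species_id`, `n_compared`, `n_pop_subs`, `n_con_subs`,
#'   `popANI`, `conANI` and `evaluable`. When no site is comparable the
#'   comparison is flagged non-evaluable and the ANI fields are `NA`; a
#'   non-evaluable comparison never counts as sharing.
#' @examples
#' a <- allele_profile("x", "sp", 10, 0:9, matrix(rep(c(10L,0L,0L,0L), 10), 10, byrow = TRUE))
#' compare_profiles(a, a)
#' @export
compare_profiles <- function(a, b, min_depth = 5L, min_count = 2L, min_freq = 0.05) {
  stopifnot(inherits(a, "allele_profile"), inherits(b, "allele_profile"))
  if (a$species_id != b$species_id)
    stop(sprintf("species mismatch: %s vs %s", a$species_id, b$species_id))
  if (a$genome_length != b$genome_length)
    stop("profiles disagree on genome length")
  ia <- match(b$pos, a$pos)
  keepb <- which(!is.na(ia))
  ca <- a$counts[ia[keepb], , drop = FALSE]
  cb <- b$counts[keepb, , drop = FALSE]
  da <- rowSums(ca)
  db <- rowSums(cb)
  ok <- da >= min_depth & db >= min_depth
  n_compared <- sum(ok)
  out <- list(sample_a = a$sample_id, sample_b = b$sample_id,
              species_id = a$species_id, n_compared = n_compared,
              n_pop_subs = NA_integer_, n_con_subs = NA_integer_,
              popANI = NA_real_, conANI = NA_real_, evaluable = FALSE)
  if (n_compared == 0L) return(structure(out, class = "pairwise_comparison"))
  ca <- ca[ok, , drop = FALSE]; cb <- cb[ok, , drop = FALSE]
  da <- da[ok]; db <- db[ok]
  ma <- .allele_mask(ca, da, min_count, min_freq)
  mb <- .allele_mask(cb, db, min_count, min_freq)
  n_pop <- sum(rowSums(ma & mb) == 0L)
  # max.col with ties.method "first" realises the A < C < G < T tie-break
  n_con <- sum(max.col(ca, ties.method = "first") !=
               max.col(cb, ties.method = "first"))
  out$n_pop_subs <- n_pop
  out$n_con_subs <- n_con
  out$popANI <- 1 - n_pop / n_compared
  out$conANI <- 1 - n_con / n_compared
  out$evaluable <- TRUE
  structure(out, class = "pairwise_comparison")
}

#' @export
print.pairwise_comparison <- function(x, ...) {
  if (!x$evaluable) {
    cat(sprintf("<pairwise_comparison> %s vs %s / %s: no comparable sites\n",
                x$sample_a, x$sample_b, x$species_id))
  } else {
    cat(sprintf(
      "<pairwise_comparison> %s vs %s / %s: %d sites, popANI %.6f, conANI %.6f\n",
      x$sample_a, x$sample_b, x$species_id, x$n_compared, x$popANI, x$conANI))
  }
  invisible(x)
}

#' @export
as.data.frame.pairwise_comparison <- function(x, ...) {
  data.frame(sample_a = x$sample_a, sample_b = x$sample_b,
             species_id = x$species_id, n_compared = x$n_compared,
             n_pop_subs = x$n_pop_subs, n_con_subs = x$n_con_subs,
             popANI = x$popANI, conANI = x$conANI, evaluable = x$evaluable,
             stringsAsFactors = FALSE)
}

#' Decide whether two samples share a strain
#'
#' Two samples share a strain of a species when their population ANI meets
#' the strain-identity threshold, 99.999% by default (roughly the identity
#' expected for lineages that diverged within the last couple of years in
#' the human gut).
#'
#' @param comparison a `pairwise_comparison` from [compare_profiles()].
#' @param ani_threshold popANI threshold in [0, 1] (default 0.99999).
#' @return Logical flag.
#' @export
is_strain_shared <- function(comparison, ani_threshold = 0.99999) {
  stopifnot(inherits(comparison, "pairwise_comparison"))
  if (!isTRUE(comparison$evaluable))
    stop("comparison is not evaluable (no comparable sites)")
  comparison$popANI >= ani_threshold
}

#' Pairwise comparison table over a sample cohort
#'
#' Computes `pairwise_comparison` rows for the requested sample pairs over
#' the species jointly *present* in each pair (joint presence under the
#' breadth/depth criterion); species failing joint presence are excluded
#' from every downstream numerator and denominator.
#'
#' @param profiles list of [allele_profile()] objects.
#' @param pairs data.frame with columns `sample_a`, `sample_b`.
#' @param presence optional precomputed [presence_table()]; computed from
#'   `profiles` when missing.
#' @inheritParams compare_profiles
#' @param min_breadth presence breadth threshold used when `presence` is
#'   computed here.
#' @return data.frame with one row per pair x jointly present species and
#'   the `pairwise_comparison` fields.
#' @export
compare_cohort <- function(profiles, pairs, presence = NULL,
                           min_depth = 5L, min_breadth = 0.25,
                           min_count = 2L, min_freq = 0.05) {
  idx <- profile_index(profiles)
  if (is.null(presence))
    presence <- presence_table(profiles, min_depth, min_breadth)
  pres <- presence[presence$present, , drop = FALSE]
  by_sample <- split(pres$species_id, pres$sample_id)
  rows <- vector("list", 0L)
  for (i in seq_len(nrow(pairs))) {
    sa <- pairs$sample_a[i]; sb <- pairs$sample_b[i]
    sp <- intersect(by_sample[[sa]] %||% character(0),
                    by_sample[[sb]] %||% character(0))
    for (s in sp) {
      cmp <- compare_profiles(idx[[.pkey(sa, s)]], idx[[.pkey(sb, s)]],
                              min_depth, min_count, min_freq)
      rows[[length(rows) + 1L]] <- as.data.frame(cmp)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sample_a = character(), sample_b = character(),
                      species_id = character(), n_compared = integer(),
                      n_pop_subs = integer(), n_con_subs = integer(),
                      popANI = numeric(), conANI = numeric(),
                      evaluable = logical())
  rownames(out) <- NULL
  out
}

# Named lookup sample x species -> profile.
profile_index <- function(profiles) {
  keys <- vapply(profiles, function(p) .pkey(p$sample_id, p$species_id), "")
  if (anyDuplicated(keys)) stop("duplicate (sample, species) profile")
  stats::setNames(profiles, keys)
}
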