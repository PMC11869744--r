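#' Simulation configuration
#'
#' Bundles every knob of the forward simulator. Defaults describe a
#' desk-scale cohort: 80 species with 10 kb observed genomes, six haplotypes
#' per species separated by at least 10 private substitutions each (so
#' distinct haplotypes always fall below the 99.999% popANI sharing
#' threshold, while exact transmitted copies sit at it), geometric species
#' prevalence across hosts, mean sequencing depth 20x with a 0.1% per-read
#' error rate, and the transplant parameters used throughout validation
#' (engraftment probability 0.8, environmental acquisition 0.05).
#'
#' @param n_species number of species in the pool.
#' @param n_haplotypes haplotypes per species.
#' @param sites_per_genome observed genome length in bp.
#' @param divergence private substitutions carried by each haplotype;
#'   pairwise haplotype Hamming distance is at least `2 * divergence`.
#' @param prevalence_prob geometric parameter for carriers per species
#'   (carriers = 1 + geometric draws, capped at the cohort size).
#' @param minor_haplotype_prob probability a carrier harbours a second,
#'   minor haplotype (microdiversity); its within-host frequency is
#'   `minor_freq`.
#' @param minor_freq minor haplotype frequency.
#' @param mutation_rate per-site substitution probability applied to each
#'   transferred (transmitted/engrafted) haplotype copy; 0 keeps copies
#'   exact so the popANI threshold is unambiguous.
#' @param engraftment_prob probability a donor strain engrafts in its
#'   designated recipient.
#' @param depletion_survival probability a recipient's pre-transplant strain
#'   survives the antibiotic depletion.
#' @param environmental_rate per-species probability that a transplant
#'   recipient independently acquires the environmental haplotype.
#' @param unique_host_haplotypes if TRUE, carriers of a species all receive
#'   distinct haplotypes (and microdiversity is disabled), giving strictly
#'   per-host strain pools.
#' @param mean_depth mean sequencing depth (reads per site).
#' @param abundance_sdlog lognormal sd of the per sample x species depth
#'   multiplier; creates realistic presence/absence at the breadth filter.
#' @param error_rate per-read sequencing error probability.
#' @param breadth_target fraction of the genome exposed to sequencing
#'   (optional breadth masking; 1 = whole genome).
#' @param persistence probability a strain persists within a host between
#'   two longitudinal samples.
#' @param turnover per-species probability of a new acquisition at the
#'   second longitudinal timepoint.
#' @param base_carriage baseline per-host, per-species carriage scale in
#'   the social design.
#' @param social_env_rate per-species probability that a social dyad's
#'   shared environment offers the environmental haplotype.
#' @param env_base baseline probability that both members of a dyad pick up
#'   an offered environmental haplotype, before any covariate coupling.
#' @param diet_effect,season_effect,rain_effect weights of diet similarity,
#'   seasonal proximity and rainfall added to `env_base` in the joint
#'   acquisition probability.
#' @param social_transmission_prob per-species probability that close
#'   social partners exchange a carried strain.
#' @param seed default seed used by the simulators when none is passed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 80L,
                       n_haplotypes = 6L,
                       sites_per_genome = 10000L,
                       divergence = 10L,
                       prevalence_prob = 0.35,
                       minor_haplotype_prob = 0.15,
                       minor_freq = 0.2,
                       mutation_rate = 0,
                       engraftment_prob = 0.8,
                       depletion_survival = 0.2,
                       environmental_rate = 0.05,
                       unique_host_haplotypes = FALSE,
                       mean_depth = 20,
                       abundance_sdlog = 0.5,
                       error_rate = 0.001,
                       breadth_target = 1,
                       persistence = 0.9,
                       turnover = 0.05,
                       base_carriage = 0.25,
                       social_env_rate = 0.15,
                       env_base = 0.2,
                       diet_effect = 0.5,
                       season_effect = 0.25,
                       rain_effect = 0.25,
                       social_transmission_prob = 0.1,
                       seed = NULL) {
  cfg <- list(n_species = as.integer(n_species),
              n_haplotypes = as.integer(n_haplotypes),
              sites_per_genome = as.integer(sites_per_genome),
              divergence = as.integer(divergence),
              prevalence_prob = prevalence_prob,
              minor_haplotype_prob = minor_haplotype_prob,
              minor_freq = minor_freq,
              mutation_rate = mutation_rate,
              engraftment_prob = engraftment_prob,
              depletion_survival = depletion_survival,
              environmental_rate = environmental_rate,
              unique_host_haplotypes = isTRUE(unique_host_haplotypes),
              mean_depth = mean_depth,
              abundance_sdlog = abundance_sdlog,
              error_rate = error_rate,
              breadth_target = breadth_target,
              persistence = persistence,
              turnover = turnover,
              base_carriage = base_carriage,
              social_env_rate = social_env_rate,
              env_base = env_base,
              diet_effect = diet_effect,
              season_effect = season_effect,
              rain_effect = rain_effect,
              social_transmission_prob = social_transmission_prob,
              seed = seed)
  probs <- cfg[c("prevalence_prob", "minor_haplotype_prob", "minor_freq",
                 "mutation_rate", "engraftment_prob", "depletion_survival",
                 "environmental_rate", "error_rate", "breadth_target",
                 "persistence", "turnover", "social_env_rate", "env_base",
                 "social_transmission_prob")]
  if (any(unlist(probs) < 0 | unlist(probs) > 1))
    stop("probabilities must lie in [0, 1]")
  if (cfg$n_species < 1L || cfg$n_haplotypes < 1L || cfg$sites_per_genome < 1L)
    stop("counts must be positive")
  if (cfg$divergence < 1L)
    stop("divergence must be at least 1 substitution")
  if (cfg$n_haplotypes * cfg$divergence > cfg$sites_per_genome)
    stop("divergence infeasible: haplotype private sites exceed genome length")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d species x %d haplotypes, %d bp, ",
                     "divergence %d, depth %gx, error %g\n"),
              x$n_species, x$n_haplotypes, x$sites_per_genome, x$divergence,
              x$mean_depth, x$error_rate))
  invisible(x)
}

#' Simulate a species pool with divergent haplotypes
#'
#' Each species receives a random reference genome and `n_haplotypes`
#' haplotypes, each carrying `divergence` private substitutions at sites
#' disjoint from every other haplotype's, so any two haplotypes differ at
#' `2 * divergence` sites. Species prevalence weights (expected carriers)
#' are drawn from a geometric distribution, producing the rare-versus-
#' widespread contrast the transmission filters exploit. Species are also
#' annotated with plausible family/genus labels, oxygen tolerance and host
#' range for the enrichment analyses.
#'
#' @param config a [sim_config()].
#' @param seed optional seed (defaults to `config$seed`).
#' @param n_haplotypes optional override of `config$n_haplotypes`.
#' @return A list of class `species_pool` with elements `species` (named
#'   list; each entry holds `species_id`, `length`, `ref`, `haps`,
#'   `prevalence_weight`), `annotations` (data.frame) and `lengths`
#'   (data.frame `species_id`, `scaffold`, `length`).
#' @export
simulate_species_pool <- function(config, seed = config$seed,
                                  n_haplotypes = config$n_haplotypes) {
  stopifnot(inherits(config, "sim_config"))
  K <- as.integer(n_haplotypes)
  L <- config$sites_per_genome
  d <- config$divergence
  if (K * d > L) stop("divergence infeasible: haplotype private sites exceed genome length")
  families <- c("Lachnospiraceae", "Ruminococcaceae", "Bacteroidaceae",
                "Prevotellaceae", "Erysipelotrichaceae", "Bifidobacteriaceae",
                "Enterobacteriaceae", "Oscillospiraceae")
  with_seed(seed, {
    species <- vector("list", config$n_species)
    ann <- vector("list", config$n_species)
    for (i in seq_len(config$n_species)) {
      sid <- sprintf("sp%03d", i)
      ref <- sample.int(4L, L, replace = TRUE)
      vp <- sample.int(L, K * d)
      haps <- vector("list", K)
      for (k in seq_len(K)) {
        pos <- sort(vp[((k - 1L) * d + 1L):(k * d)])
        base <- vapply(pos, function(p) sample((1:4)[-ref[p]], 1L), 0L)
        haps[[k]] <- list(pos = pos, base = base)
      }
      fam <- sample(families, 1L, prob = c(3, 3, 2, 2, 1, 1, 1, 2))
      species[[i]] <- list(species_id = sid, length = L, ref = ref,
                           haps = haps,
                           prevalence_weight = 1L + stats::rgeom(1L, config$prevalence_prob))
      ann[[i]] <- data.frame(
        species_id = sid, family = fam,
        genus = paste0(sub("aceae$", "", fam), "_g", sample.int(6L, 1L)),
        oxygen = sample(c("anaerobic", "aerobic", "mixed"), 1L,
                        prob = c(0.65, 0.1, 0.25)),
        host_range = sample(c("single_host", "multi_host"), 1L,
                            prob = c(0.4, 0.6)),
        stringsAsFactors = FALSE)
    }
    names(species) <- vapply(species, `[[`, "", "species_id")
    structure(list(species = species,
                   annotations = do.call(rbind, ann),
                   lengths = data.frame(
                     species_id = names(species), scaffold = "genome",
                     length = L, stringsAsFactors = FALSE),
                   config = config),
              class = "species_pool")
  })
}

# Integer genotype (1..4 per site) of haplotype h of one pool species.
.hap_genotype <- function(sp, h) {
  g <- sp$ref
  hv <- sp$haps[[h]]
  g[hv$pos] <- hv$base
  g
}

#' Hamming distance between two haplotypes of a pool species
#'
#' @param pool a [simulate_species_pool()] result.
#' @param species_id species identifier.
#' @param i,j haplotype indices.
#' @return Integer count of differing sites.
#' @export
haplotype_distance <- function(pool, species_id, i, j) {
  sp <- pool$species[[species_id]]
  if (is.null(sp)) stop("unknown species: ", species_id)
  sum(.hap_genotype(sp, i) != .hap_genotype(sp, j))
}

# Copy haplotype h for a transfer; with mutation_rate > 0 the copy picks up
# new substitutions and is appended to the (locally mutated) pool species.
.transfer_hap <- function(poolenv, species_id, h, rate) {
  if (rate <= 0) return(h)
  sp <- poolenv$species[[species_id]]
  nmut <- stats::rbinom(1L, sp$length, rate)
  if (nmut == 0L) return(h)
  g <- .hap_genotype(sp, h)
  mpos <- sample.int(sp$length, nmut)
  g[mpos] <- vapply(mpos, function(p) sample((1:4)[-g[p]], 1L), 0L)
  diff <- which(g != sp$ref)
  sp$haps[[length(sp$haps) + 1L]] <- list(pos = diff, base = g[diff])
  poolenv$species[[species_id]] <- sp
  length(sp$haps)
}

#' Sequence allele profiles from genotype assignments
#'
#' Turns per-sample haplotype mixtures into read-level allele count
#' profiles: per-site depth is Poisson around the entry's mean depth, reads
#' are allocated to haplotypes multinomially by frequency, and each read is
#' misread to one of the three other bases with probability `error_rate`.
#'
#' @param genotypes list of entries, each a list with `sample_id`,
#'   `species_id`, `haps` (haplotype indices), `freqs` (summing to 1) and
#'   `d_mean` (mean depth for this sample x species).
#' @param pool a [simulate_species_pool()] result.
#' @param config a [sim_config()].
#' @param seed optional seed.
#' @return List of [allele_profile()] objects (entries with no covered
#'   sites are dropped).
#' @export
sequence_profiles <- function(genotypes, pool, config, seed = NULL) {
  with_seed(seed, {
    out <- vector("list", length(genotypes))
    for (i in seq_along(genotypes)) {
      g <- genotypes[[i]]
      if (abs(sum(g$freqs) - 1) > 1e-8)
        stop("haplotype frequencies must sum to 1 (sample ",
             g$sample_id, ", species ", g$species_id, ")")
      out[[i]] <- .sequence_one(g, pool$species[[g$species_id]], config)
    }
    out[!vapply(out, is.null, TRUE)]
  })
}

.sequence_one <- function(g, sp, config) {
  L <- sp$length
  depth <- stats::rpois(L, g$d_mean)
  if (config$breadth_target < 1)
    depth[stats::runif(L) > config$breadth_target] <- 0L
  cov <- which(depth > 0L)
  if (!length(cov)) return(NULL)
  dcov <- depth[cov]
  counts <- matrix(0L, length(cov), 4L, dimnames = list(NULL, BASES))
  counts[cbind(seq_along(cov), sp$ref[cov])] <- dcov
  vpos <- sort(unique(unlist(lapply(sp$haps[g$haps], `[[`, "pos"))))
  vcov <- vpos[depth[vpos] > 0L]
  if (length(vcov) && length(g$haps) >= 1L) {
    rowi <- match(vcov, cov)
    bmat <- matrix(0L, length(vcov), length(g$haps))
    for (k in seq_along(g$haps)) {
      hb <- sp$ref[vcov]
      hv <- sp$haps[[g$haps[k]]]
      m <- match(hv$pos, vcov)
      sel <- which(!is.na(m))
      hb[m[sel]] <- hv$base[sel]
      bmat[, k] <- hb
    }
    for (j in seq_along(vcov)) {
      alloc <- as.integer(stats::rmultinom(1L, depth[vcov[j]], g$freqs))
      cnt <- integer(4L)
      for (k in seq_along(g$haps))
        cnt[bmat[j, k]] <- cnt[bmat[j, k]] + alloc[k]
      counts[rowi[j], ] <- cnt
    }
  }
  if (config$error_rate > 0) {
    nerr <- stats::rbinom(length(cov), dcov, config$error_rate)
    ei <- which(nerr > 0L)
    if (length(ei)) {
      # misreads leave the site's majority base for one of the other three;
      # at realistic error rates attributing the source read to the majority
      # allele is an adequate approximation
      src <- max.col(counts[ei, , drop = FALSE], ties.method = "first")
      k <- pmin(nerr[ei], counts[cbind(ei, src)] - 1L)
      use <- k > 0L
      if (any(use)) {
        ei <- ei[use]; src <- src[use]; k <- k[use]
        counts[cbind(ei, src)] <- counts[cbind(ei, src)] - k
        site <- rep.int(ei, k)
        dest <- (rep.int(src, k) - 1L + sample.int(3L, sum(k), replace = TRUE)) %% 4L + 1L
        idx <- (dest - 1L) * length(cov) + site
        ui <- unique(idx)
        counts[ui] <- counts[ui] + tabulate(match(idx, ui), length(ui))
      }
    }
  }
  # sites are sorted, in range and non-negative by construction
  structure(list(sample_id = g$sample_id, species_id = g$species_id,
                 genome_length = L, pos = cov - 1L, counts = counts),
            class = "allele_profile")
}

.draw_depth <- function(config, n = 1L) {
  s <- config$abundance_sdlog
  config$mean_depth * stats::rlnorm(n, -s^2 / 2, s)
}

#' Simulate a fecal microbiota transplant cohort
#'
#' Emulates the transplant design used for validation: `n_donors` healthy
#' donors sampled once, `n_recipients` recipients sampled immediately before
#' and 15-30 days after a single-donor transplant. Recipients' pre-transplant
#' communities are depleted (each strain survives with probability
#' `depletion_survival`), every designated-donor strain engrafts with
#' probability `engraftment_prob`, and recipients independently acquire the
#' environmental haplotype of a species with probability
#' `environmental_rate`. The generative origin of every post-transplant
#' strain is recorded in the truth table.
#'
#' @param config a [sim_config()].
#' @param n_donors,n_recipients cohort sizes (defaults 5 and 8).
#' @param pool optional pre-built [simulate_species_pool()].
#' @param seed optional seed (defaults to `config$seed`).
#' @return A list of class `fmt_cohort`: `profiles`, `metadata`,
#'   `truth` (sample_id, species_id, haplotype, origin, source_sample),
#'   `pool`, `config`.
#' @export
simulate_fmt_cohort <- function(config, n_donors = 5L, n_recipients = 8L,
                                pool = NULL, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    n_hosts <- n_donors + n_recipients
    K <- if (config$unique_host_haplotypes)
      max(config$n_haplotypes, n_hosts) else config$n_haplotypes
    if (is.null(pool))
      pool <- simulate_species_pool(config, seed = NULL, n_haplotypes = K)
    poolenv <- new.env(parent = emptyenv())
    poolenv$species <- pool$species
    donors <- sprintf("D%d", seq_len(n_donors))
    recips <- sprintf("R%d", seq_len(n_recipients))
    designated <- sample(rep(donors, length.out = n_recipients))
    names(designated) <- recips

    # community[[host]][[species]] = list(haps, freqs)
    community <- stats::setNames(
      replicate(n_hosts, list(), simplify = FALSE), c(donors, recips))
    for (sid in names(pool$species)) {
      sp <- pool$species[[sid]]
      ncar <- min(sp$prevalence_weight, n_hosts)
      carriers <- sample(c(donors, recips), ncar)
      if (config$unique_host_haplotypes) {
        hs <- sample.int(length(sp$haps), ncar)
        for (j in seq_len(ncar))
          community[[carriers[j]]][[sid]] <- list(haps = hs[j], freqs = 1)
      } else {
        for (h in carriers) {
          major <- sample.int(length(sp$haps), 1L)
          if (stats::runif(1) < config$minor_haplotype_prob && length(sp$haps) > 1L) {
            minor <- sample(setdiff(seq_along(sp$haps), major), 1L)
            community[[h]][[sid]] <- list(
              haps = c(major, minor),
              freqs = c(1 - config$minor_freq, config$minor_freq))
          } else {
            community[[h]][[sid]] <- list(haps = major, freqs = 1)
          }
        }
      }
    }

    fmt_day <- as.Date("2020-06-01")
    genotypes <- list()
    truth <- list()
    meta <- list()
    add_sample <- function(sample_id, host, role, timepoint, date, strains) {
      meta[[length(meta) + 1L]] <<- data.frame(
        sample_id = sample_id, host_id = host, date = as.character(date),
        group = NA_character_, role = role, timepoint = timepoint,
        designated_donor = if (role == "recipient") designated[[host]] else NA_character_,
        stringsAsFactors = FALSE)
      for (sid in names(strains)) {
        st <- strains[[sid]]
        w <- st$freqs / sum(st$freqs)
        genotypes[[length(genotypes) + 1L]] <<- list(
          sample_id = sample_id, species_id = sid, haps = st$haps,
          freqs = w, d_mean = .draw_depth(config))
        truth[[length(truth) + 1L]] <<- data.frame(
          sample_id = sample_id, species_id = sid, haplotype = st$haps,
          origin = st$origin, source_sample = st$source,
          stringsAsFactors = FALSE)
      }
    }
    as_resident <- function(com) {
      lapply(com, function(st) {
        st$origin <- rep("pre_existing", length(st$haps))
        st$source <- rep(NA_character_, length(st$haps))
        st
      })
    }

    for (d in donors)
      add_sample(d, d, "donor", "none", fmt_day - 1L, as_resident(community[[d]]))
    for (r in recips)
      add_sample(paste0(r, "_pre"), r, "recipient", "pre", fmt_day - 1L,
                 as_resident(community[[r]]))

    for (r in recips) {
      don <- designated[[r]]
      post <- list()
      # surviving pre-transplant strains
      for (sid in names(community[[r]])) {
        st <- community[[r]][[sid]]
        keep <- stats::runif(length(st$haps)) < config$depletion_survival
        if (any(keep))
          post[[sid]] <- list(haps = st$haps[keep], freqs = st$freqs[keep],
                              origin = rep("pre_existing", sum(keep)),
                              source = rep(NA_character_, sum(keep)))
      }
      # engraftment from the designated donor
      for (sid in names(community[[don]])) {
        st <- community[[don]][[sid]]
        eng <- stats::runif(length(st$haps)) < config$engraftment_prob
        if (!any(eng)) next
        haps <- vapply(st$haps[eng], function(h)
          .transfer_hap(poolenv, sid, h, config$mutation_rate), 0L)
        cur <- post[[sid]] %||% list(haps = integer(), freqs = numeric(),
                                     origin = character(), source = character())
        new <- !(haps %in% cur$haps)
        post[[sid]] <- list(haps = c(cur$haps, haps[new]),
                            freqs = c(cur$freqs, st$freqs[eng][new]),
                            origin = c(cur$origin, rep("transmitted", sum(new))),
                            source = c(cur$source, rep(don, sum(new))))
      }
      # independent environmental acquisition (haplotype 1 = environmental)
      for (sid in names(pool$species)) {
        if (stats::runif(1) >= config$environmental_rate) next
        cur <- post[[sid]] %||% list(haps = integer(), freqs = numeric(),
                                     origin = character(), source = character())
        if (1L %in% cur$haps) next
        post[[sid]] <- list(haps = c(cur$haps, 1L),
                            freqs = c(cur$freqs, 0.3),
                            origin = c(cur$origin, "environmental"),
                            source = c(cur$source, NA_character_))
      }
      post <- lapply(post, function(st) { st$freqs <- st$freqs / sum(st$freqs); st })
      add_sample(paste0(r, "_post"), r, "recipient", "post",
                 fmt_day + sample(15:30, 1L), post)
    }

    pool$species <- poolenv$species
    metadata <- do.call(rbind, meta)
    metadata$date <- as.Date(metadata$date)
    profiles <- sequence_profiles(genotypes, pool, config)
    structure(list(profiles = profiles, metadata = metadata,
                   truth = do.call(rbind, truth), pool = pool,
                   config = config),
              class = "fmt_cohort")
  })
}

#' @export
print.fmt_cohort <- function(x, ...) {
  cat(sprintf("<fmt_cohort> %d samples, %d profiles, %d species pool\n",
              nrow(x$metadata), length(x$profiles), length(x$pool$species)))
  invisible(x)
}

#' Simulate a social (field-study) cohort of sample dyads
#'
#' Emulates the observational dyad design used to probe strain sharing in a
#' wild population: pairs of hosts whose lives never overlapped, pairs alive
#' at the same time but in different social groups (sampled < 150 days
#' apart), close social partners in one group (sampled < 4 days apart), and
#' longitudinal self-pairs (120-150 days apart). Each host carries a
#' personal strain pool (haplotypes distinct within a dyad); a shared
#' environmental haplotype is offered to each dyad per species with
#' probability `social_env_rate` and is acquired *jointly* with a
#' probability that increases with diet similarity, seasonal proximity and
#' rainfall (weights `diet_effect`, `season_effect`, `rain_effect`).
#' Longitudinal second samples retain each strain with probability
#' `persistence`; close partners additionally exchange carried strains with
#' probability `social_transmission_prob`.
#'
#' @param config a [sim_config()].
#' @param design named integer vector of dyad counts per category; default
#'   is the field design (20 never_overlapped, 23 different_groups, 26
#'   close_partners, 22 longitudinal).
#' @param pool optional pre-built pool.
#' @param seed optional seed.
#' @return A list of class `social_cohort`: `profiles`, `metadata`, `hosts`
#'   (host_id, birth, death, group), `dyads` (sample_a, sample_b, category),
#'   `diet` (group, year, food_type, proportion), `rainfall` (date, mm),
#'   `truth`, `pool`, `config`.
#' @export
simulate_social_cohort <- function(config,
                                   design = c(never_overlapped = 20L,
                                              different_groups = 23L,
                                              close_partners = 26L,
                                              longitudinal = 22L),
                                   pool = NULL, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  bad <- setdiff(names(design), c("never_overlapped", "different_groups",
                                  "close_partners", "longitudinal"))
  if (length(bad)) stop("unknown dyad categories: ", paste(bad, collapse = ", "))
  with_seed(seed, {
    if (is.null(pool)) {
      K <- max(config$n_haplotypes, 3L)  # env haplotype + two personal
      pool <- simulate_species_pool(config, seed = NULL, n_haplotypes = K)
    }
    poolenv <- new.env(parent = emptyenv())
    poolenv$species <- pool$species
    # daily rainfall 2008-2017 with a June-October dry season
    days <- seq(as.Date("2008-01-01"), as.Date("2017-12-31"), by = "day")
    mo <- as.integer(format(days, "%m"))
    wet <- !(mo %in% 6:10)
    rain <- ifelse(wet, stats::rgamma(length(days), 0.35, rate = 0.12),
                   stats::rgamma(length(days), 0.05, rate = 0.25))
    rainfall <- data.frame(date = days, mm = round(rain, 2))
    mkey <- format(days, "%Y-%m")
    month_sum <- tapply(rainfall$mm, mkey, sum)
    max_month <- max(month_sum)
    foods <- sprintf("food_%02d", 1:15)
    rdirichlet1 <- function(alpha) { g <- stats::rgamma(length(alpha), alpha); g / sum(g) }

    species_ids <- names(pool$species)
    weights <- vapply(pool$species, `[[`, 0L, "prevalence_weight")
    p_carry <- pmin(0.8, weights * config$base_carriage / 3)

    genotypes <- list(); truth <- list(); meta <- list()
    hosts <- list(); dyads <- list(); diet_rows <- list()
    d_idx <- 0L
    depth_of <- new.env(parent = emptyenv())  # per host x species, persistent
    host_depth <- function(host, sid) {
      k <- .pkey(host, sid)
      if (is.null(depth_of[[k]])) depth_of[[k]] <- .draw_depth(config)
      depth_of[[k]]
    }
    emit_sample <- function(sample_id, host, date, group, strains) {
      meta[[length(meta) + 1L]] <<- data.frame(
        sample_id = sample_id, host_id = host, date = as.character(date),
        group = group, role = "none", timepoint = "none",
        designated_donor = NA_character_, stringsAsFactors = FALSE)
      for (sid in names(strains)) {
        st <- strains[[sid]]
        genotypes[[length(genotypes) + 1L]] <<- list(
          sample_id = sample_id, species_id = sid, haps = st$haps,
          freqs = st$freqs / sum(st$freqs), d_mean = host_depth(host, sid))
        truth[[length(truth) + 1L]] <<- data.frame(
          sample_id = sample_id, species_id = sid, haplotype = st$haps,
          origin = st$origin, source_sample = st$source,
          stringsAsFactors = FALSE)
      }
    }
    strain <- function(h, origin, source = NA_character_)
      list(haps = h, freqs = rep(1 / length(h), length(h)),
           origin = rep(origin, length(h)), source = rep(source, length(h)))
    add_strain <- function(strains, sid, h, origin, source = NA_character_) {
      cur <- strains[[sid]]
      if (is.null(cur)) {
        strains[[sid]] <- list(haps = h, freqs = 1, origin = origin, source = source)
      } else if (!(h %in% cur$haps)) {
        n <- length(cur$haps) + 1L
        strains[[sid]] <- list(haps = c(cur$haps, h),
                               freqs = rep(1 / n, n),
                               origin = c(cur$origin, origin),
                               source = c(cur$source, source))
      }
      strains
    }

    for (cat in names(design)) for (k in seq_len(design[[cat]])) {
      d_idx <- d_idx + 1L
      tag <- sprintf("d%03d", d_idx)
      # never-overlapped pairs start early so the second host's sampling
      # date stays inside the rainfall record
      date_a <- as.Date("2010-06-01") +
        sample.int(if (cat == "never_overlapped") 900L else 2500L, 1L)
      gap <- switch(cat,
                    longitudinal = sample(120:150, 1L),
                    close_partners = sample(0:3, 1L),
                    different_groups = sample(0:149, 1L),
                    never_overlapped = sample(400:1500, 1L))
      date_b <- date_a + gap
      same_host <- cat == "longitudinal"
      same_group <- cat %in% c("close_partners", "longitudinal")
      g1 <- paste0(tag, "_g1")
      g2 <- if (same_group) g1 else paste0(tag, "_g2")
      ha <- paste0(tag, "_hA")
      hb <- if (same_host) ha else paste0(tag, "_hB")
      if (cat == "never_overlapped") {
        death_a <- date_a + sample(30:200, 1L)
        birth_b <- death_a + sample(30:150, 1L)
        if (date_b <= birth_b) date_b <- birth_b + sample(365:1200, 1L)
        hosts[[length(hosts) + 1L]] <- data.frame(
          host_id = c(ha, hb), birth = as.character(c(date_a - 3000L, birth_b)),
          death = as.character(c(death_a, date_b + 2000L)),
          group = c(g1, g2), stringsAsFactors = FALSE)
      } else {
        hh <- unique(c(ha, hb))
        hosts[[length(hosts) + 1L]] <- data.frame(
          host_id = hh, birth = as.character(rep(date_a - 3000L, length(hh))),
          death = as.character(rep(date_b + 2000L, length(hh))),
          group = if (same_host) g1 else c(g1, g2), stringsAsFactors = FALSE)
      }
      # group diets in the years of sampling; similarity varies across dyads
      diet_a <- rdirichlet1(rep(0.8, length(foods)))
      wmix <- stats::runif(1)
      diet_b <- if (same_group && format(date_a, "%Y") == format(date_b, "%Y"))
        diet_a else wmix * diet_a + (1 - wmix) * rdirichlet1(rep(0.8, length(foods)))
      diet_b <- diet_b / sum(diet_b)
      diet_rows[[length(diet_rows) + 1L]] <- data.frame(
        group = g1, year = format(date_a, "%Y"), food_type = foods,
        proportion = diet_a, stringsAsFactors = FALSE)
      if (!(same_group && format(date_a, "%Y") == format(date_b, "%Y")))
        diet_rows[[length(diet_rows) + 1L]] <- data.frame(
          group = g2, year = format(date_b, "%Y"), food_type = foods,
          proportion = diet_b, stringsAsFactors = FALSE)
      diet_sim <- 1 - sum(abs(diet_a - diet_b)) / sum(diet_a + diet_b)
      m1 <- as.integer(format(date_a, "%m")); m2 <- as.integer(format(date_b, "%m"))
      mdist <- min(abs(m1 - m2), 12L - abs(m1 - m2))
      rain_tot <- month_sum[[format(date_a, "%Y-%m")]] +
        month_sum[[format(date_b, "%Y-%m")]]
      overlap <- min(1, max(0, config$env_base +
                                 config$diet_effect * diet_sim +
                                 config$season_effect * (1 - mdist / 6) +
                                 config$rain_effect * rain_tot / (2 * max_month)))

      # personal pools: distinct haplotypes within the dyad, never the
      # environmental haplotype (index 1)
      sA <- list(); sB <- list()
      for (i in seq_along(species_ids)) {
        sid <- species_ids[i]
        nh <- length(pool$species[[sid]]$haps)
        pers <- sample(2:nh, 2L)
        if (stats::runif(1) < p_carry[i]) sA[[sid]] <- strain(pers[1L], "pre_existing")
        if (!same_host && stats::runif(1) < p_carry[i])
          sB[[sid]] <- strain(pers[2L], "pre_existing")
        if (stats::runif(1) < config$social_env_rate) {
          if (stats::runif(1) < overlap) {
            sA <- add_strain(sA, sid, 1L, "environmental")
            if (!same_host) sB <- add_strain(sB, sid, 1L, "environmental")
          } else if (stats::runif(1) < 0.5) {
            sA <- add_strain(sA, sid, 1L, "environmental")
          } else if (!same_host) {
            sB <- add_strain(sB, sid, 1L, "environmental")
          }
        }
      }
      sam_a <- paste0(tag, "_a"); sam_b <- paste0(tag, "_b")
      if (same_host) {
        # second sample: persistence + turnover
        sB <- list()
        for (sid in names(sA)) {
          st <- sA[[sid]]
          keep <- stats::runif(length(st$haps)) < config$persistence
          if (any(keep))
            sB[[sid]] <- list(haps = st$haps[keep], freqs = st$freqs[keep],
                              origin = rep("pre_existing", sum(keep)),
                              source = rep(sam_a, sum(keep)))
        }
        for (i in seq_along(species_ids)) {
          sid <- species_ids[i]
          if (stats::runif(1) < config$turnover) {
            nh <- length(pool$species[[sid]]$haps)
            sB <- add_strain(sB, sid, sample(2:nh, 1L), "environmental")
          }
        }
      } else if (cat == "close_partners" && config$social_transmission_prob > 0) {
        for (sid in names(sA)) {
          if (stats::runif(1) < config$social_transmission_prob) {
            h <- .transfer_hap(poolenv, sid, sA[[sid]]$haps[1L], config$mutation_rate)
            sB <- add_strain(sB, sid, h, "transmitted", sam_a)
          }
        }
        for (sid in names(sB)) {
          if (sB[[sid]]$origin[1L] != "pre_existing") next
          if (stats::runif(1) < config$social_transmission_prob) {
            h <- .transfer_hap(poolenv, sid, sB[[sid]]$haps[1L], config$mutation_rate)
            sA <- add_strain(sA, sid, h, "transmitted", sam_b)
          }
        }
      }
      emit_sample(sam_a, ha, date_a, g1, sA)
      emit_sample(sam_b, hb, date_b, g2, sB)
      dyads[[length(dyads) + 1L]] <- data.frame(
        sample_a = sam_a, sample_b = sam_b, category = cat,
        diet_similarity = diet_sim, month_distance = mdist,
        rainfall_total = rain_tot, stringsAsFactors = FALSE)
    }

    pool$species <- poolenv$species
    metadata <- do.call(rbind, meta); metadata$date <- as.Date(metadata$date)
    hosts <- do.call(rbind, hosts)
    hosts$birth <- as.Date(hosts$birth); hosts$death <- as.Date(hosts$death)
    profiles <- sequence_profiles(genotypes, pool, config)
    structure(list(profiles = profiles, metadata = metadata, hosts = hosts,
                   dyads = do.call(rbind, dyads),
                   diet = do.call(rbind, diet_rows), rainfall = rainfall,
                   truth = do.call(rbind, truth), pool = pool,
                   config = config),
              class = "social_cohort")
  })
}

#' @export
print.social_cohort <- function(x, ...) {
  cat(sprintf("<social_cohort> %d dyads (%s), %d samples, %d profiles\n",
              nrow(x$dyads),
              paste(names(table(x$dyads$category)), table(x$dyads$category),
                    sep = ":", collapse = ", "),
              nrow(x$metadata), length(x$profiles)))
  invisible(x)
}
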