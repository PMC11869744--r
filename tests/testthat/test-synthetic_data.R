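small_cfg <- function(...) {
  sim_config(n_species = 8L, n_haplotypes = 3L, sites_per_genome = 500L,
             divergence = 5L, ...)
}

test_that("species pools keep haplotypes divergent and are seed-stable", {
  cfg <- sim_config(n_species = 5L, n_haplotypes = 2L,
                    sites_per_genome = 10000L, divergence = 10L)
  pool <- simulate_species_pool(cfg, seed = 1L)
  for (sid in names(pool$species)) {
    d <- haplotype_distance(pool, sid, 1, 2)
    expect_gte(d, 10L)
    # distinct haplotypes sit safely below the popANI sharing threshold
    expect_lte(1 - d / 10000, 0.999)
  }
  pool2 <- simulate_species_pool(cfg, seed = 1L)
  expect_identical(pool, pool2)
  expect_error(sim_config(n_haplotypes = 100L, sites_per_genome = 100L,
                          divergence = 10L), "infeasible")
})

test_that("sequencing without error reproduces the genotype consensus", {
  cfg <- small_cfg(error_rate = 0, seed = 5L)
  pool <- simulate_species_pool(cfg, seed = 5L)
  g <- list(sample_id = "s", species_id = "sp001", haps = 2L, freqs = 1,
            d_mean = 30)
  prof <- sequence_profiles(list(g), pool, cfg, seed = 6L)[[1]]
  geno <- strainshare:::.hap_genotype(pool$species[["sp001"]], 2L)
  cons <- max.col(prof$counts, ties.method = "first")
  expect_equal(cons, geno[prof$pos + 1L])
})

test_that("zero depth drops the species entirely", {
  cfg <- small_cfg(seed = 5L)
  pool <- simulate_species_pool(cfg, seed = 5L)
  g <- list(sample_id = "s", species_id = "sp001", haps = 1L, freqs = 1,
            d_mean = 0)
  expect_length(sequence_profiles(list(g), pool, cfg, seed = 1L), 0L)
})

test_that("a 50/50 haplotype mixture exposes both alleles at variant sites", {
  cfg <- small_cfg(error_rate = 0, seed = 9L)
  pool <- simulate_species_pool(cfg, seed = 9L)
  sp <- pool$species[["sp002"]]
  g <- list(sample_id = "s", species_id = "sp002", haps = c(1L, 2L),
            freqs = c(0.5, 0.5), d_mean = 40)
  prof <- sequence_profiles(list(g), pool, cfg, seed = 10L)[[1]]
  g1 <- strainshare:::.hap_genotype(sp, 1L)
  g2 <- strainshare:::.hap_genotype(sp, 2L)
  vsite <- which(g1 != g2)
  hits <- 0L
  for (v in vsite) {
    i <- match(v - 1L, prof$pos)
    det <- detect_alleles(prof$counts[i, ])
    if (all(c("A", "C", "G", "T")[c(g1[v], g2[v])] %in% det))
      hits <- hits + 1L
  }
  expect_gte(hits / length(vsite), 0.9)
})

test_that("transplant simulation is deterministic given config and seed", {
  cfg <- small_cfg(seed = 77L)
  a <- simulate_fmt_cohort(cfg, n_donors = 2L, n_recipients = 3L)
  b <- simulate_fmt_cohort(cfg, n_donors = 2L, n_recipients = 3L)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth, b$truth)
  expect_identical(a$profiles, b$profiles)
})

test_that("transplant truth labels every strain instance exactly once", {
  cfg <- small_cfg(seed = 31L)
  coh <- simulate_fmt_cohort(cfg, n_donors = 3L, n_recipients = 4L)
  expect_true(all(coh$truth$origin %in%
                  c("transmitted", "pre_existing", "environmental")))
  key <- paste(coh$truth$sample_id, coh$truth$species_id, coh$truth$haplotype)
  expect_false(anyDuplicated(key) > 0)
  # transmitted strains name their source donor
  tr <- coh$truth[coh$truth$origin == "transmitted", ]
  expect_true(all(tr$source_sample %in%
                  coh$metadata$sample_id[coh$metadata$role == "donor"]))
})

test_that("full engraftment with no acquisition transfers every donor strain", {
  cfg <- small_cfg(engraftment_prob = 1, environmental_rate = 0,
                   depletion_survival = 0, minor_haplotype_prob = 0,
                   error_rate = 0, seed = 13L)
  coh <- simulate_fmt_cohort(cfg, n_donors = 2L, n_recipients = 2L)
  md <- coh$metadata
  for (r in md$host_id[md$role == "recipient" & md$timepoint == "post"]) {
    don <- md$designated_donor[md$host_id == r][1]
    post <- coh$truth[coh$truth$sample_id == paste0(r, "_post"), ]
    donor_strains <- coh$truth[coh$truth$sample_id == don, ]
    expect_setequal(paste(post$species_id, post$haplotype),
                    paste(donor_strains$species_id, donor_strains$haplotype))
    expect_true(all(post$origin == "transmitted"))
  }
})

test_that("social cohorts respect the dyad design and label origins", {
  cfg <- small_cfg(seed = 55L)
  des <- c(never_overlapped = 2L, different_groups = 2L,
           close_partners = 2L, longitudinal = 2L)
  coh <- simulate_social_cohort(cfg, design = des)
  expect_equal(as.vector(table(coh$dyads$category)[names(des)]),
               unname(as.integer(des)))
  # recover categories from the emitted metadata and lifespans
  md <- coh$metadata
  ls <- coh$hosts[c("host_id", "birth", "death")]
  for (i in seq_len(nrow(coh$dyads))) {
    a <- md[md$sample_id == coh$dyads$sample_a[i], ]
    b <- md[md$sample_id == coh$dyads$sample_b[i], ]
    expect_equal(categorize_dyad(a, b, ls), coh$dyads$category[i],
                 info = coh$dyads$category[i])
  }
  expect_true(all(coh$truth$origin %in%
                  c("transmitted", "pre_existing", "environmental")))
  expect_error(simulate_social_cohort(cfg, design = c(bogus = 2L)), "unknown")
})

test_that("full persistence makes longitudinal self-dyads share everything", {
  cfg <- small_cfg(persistence = 1, turnover = 0, error_rate = 0,
                   social_env_rate = 0, seed = 91L)
  coh <- simulate_social_cohort(cfg, design = c(longitudinal = 4L))
  an <- social_sharing_analysis(coh$profiles, coh$dyads)
  rates <- an$summaries$sharing_rate
  expect_true(all(rates[!is.na(rates)] == 1))
})

test_that("disjoint personal pools leave cross-host sharing near zero", {
  cfg <- small_cfg(social_env_rate = 0, social_transmission_prob = 0,
                   seed = 14L)
  coh <- simulate_social_cohort(cfg, design = c(different_groups = 6L))
  an <- social_sharing_analysis(coh$profiles, coh$dyads)
  rates <- an$summaries$sharing_rate
  expect_true(all(rates[!is.na(rates)] == 0))
})
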