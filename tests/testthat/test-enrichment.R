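test_that("oxygen and host-range annotation follow the genus rules", {
  expect_equal(annotate_oxygen(rep("obligate anaerobe", 3)), "anaerobic")
  expect_equal(annotate_oxygen(rep("obligate aerobe", 2)), "aerobic")
  expect_equal(annotate_oxygen(c("obligate aerobe", "obligate anaerobe")),
               "mixed")
  expect_equal(annotate_oxygen(c("obligate anaerobe", "facultative anaerobe")),
               "mixed")
  expect_equal(annotate_oxygen(character(0)), "unknown")
  expect_equal(annotate_host_range("Homo sapiens"), "single_host")
  expect_equal(annotate_host_range(c("Homo sapiens", "Sus scrofa")),
               "multi_host")
  expect_equal(annotate_host_range(character(0)), "unknown")
})

test_that("family composition test matches hypergeometric enumeration on 2x2", {
  # 10/0 vs 0/10 with equal margins: p = 2 / C(20, 10)
  fa <- rep(c("F1", "F2"), c(10, 0))
  fb <- rep(c("F1", "F2"), c(0, 10))
  got <- family_composition_test(fa, fb)
  expect_equal(got$p, 2 / choose(20, 10), tolerance = 1e-10)
  expect_equal(got$p, 1.08e-5, tolerance = 1e-2)

  # identical distributions: p ~ 1
  fa <- rep(c("F1", "F2"), c(5, 5))
  expect_gt(family_composition_test(fa, fa)$p, 0.99)

  # single family is not testable
  expect_equal(family_composition_test(rep("F1", 4), rep("F1", 6))$p, 1)

  # r x 2 Monte Carlo route is seeded and reproducible
  fa <- sample(paste0("F", 1:4), 30, replace = TRUE)
  fb <- sample(paste0("F", 1:4), 25, replace = TRUE)
  p1 <- family_composition_test(fa, fb, b_monte = 1e4, seed = 5)$p
  p2 <- family_composition_test(fa, fb, b_monte = 1e4, seed = 5)$p
  expect_identical(p1, p2)
})

test_that("family log odds ratios are exact, corrected, and antisymmetric", {
  fa <- rep(c("F", "o"), c(5, 5)); fb <- rep(c("F", "o"), c(5, 5))
  expect_equal(family_log_odds(fa, fb, "F")$log2_or, 0)

  fa <- rep(c("F", "o"), c(20, 5)); fb <- rep(c("F", "o"), c(5, 20))
  lo <- family_log_odds(fa, fb, "F")
  expect_equal(lo$log2_or, 4)  # log2(16)
  expect_true(lo$ci_lower < 4 && lo$ci_upper > 4)

  # zero cell stays finite under the Haldane-Anscombe correction
  fa <- rep("F", 8); fb <- rep(c("F", "o"), c(2, 6))
  lo <- family_log_odds(fa, fb, "F")
  expect_true(is.finite(lo$log2_or) && is.finite(lo$ci_upper))

  # antisymmetry under group swap
  set.seed(8)
  fa <- sample(c("F", "o"), 20, replace = TRUE)
  fb <- sample(c("F", "o"), 15, replace = TRUE)
  expect_equal(family_log_odds(fa, fb, "F")$log2_or,
               -family_log_odds(fb, fa, "F")$log2_or, tolerance = 1e-12)
})

test_that("event prevalence counts baseline carriers and compares groups", {
  profiles <- list()
  for (s in paste0("b", 1:13))
    profiles <- c(profiles, list(flat_profile(s, "spAll", 100L, 0:99)))
  profiles <- c(profiles, list(flat_profile("b1", "spRare", 100L, 0:99)))
  presence <- presence_table(profiles)
  events <- data.frame(species_id = c("spAll", "spRare", "spNone"),
                       matched = c(TRUE, FALSE, TRUE))
  got <- prevalence_of_events(events, presence, paste0("b", 1:13))
  expect_equal(got$events$prevalence, c(13L, 1L, 0L))
  expect_error(prevalence_of_events(events, presence, character(0)),
               "non-empty")
  # identical prevalence vectors give t = 0
  ev2 <- data.frame(species_id = rep("spAll", 6),
                    matched = rep(c(TRUE, FALSE), 3))
  got2 <- prevalence_of_events(ev2, presence, paste0("b", 1:13))
  expect_equal(got2$t, 0)
})

test_that("permutation enrichment matches its exact hypergeometric oracle", {
  # 20 events, 10 with trait, observed subset of 5 all carrying the trait:
  # exact tail = C(10,5)/C(20,5)
  trait <- rep(c(TRUE, FALSE), each = 10)
  subset <- 1:5
  exact <- choose(10, 5) / choose(20, 5)
  got <- permutation_trait_enrichment(trait, subset, n_perm = 1e4, seed = 17)
  se <- sqrt(exact * (1 - exact) / 1e4)
  expect_lt(abs(got$p - exact), 3 * se)
  expect_equal(got$observed, 1)
})

test_that("permutation enrichment degenerate cases give p = 1", {
  trait <- rep(c(TRUE, FALSE), each = 10)
  whole <- permutation_trait_enrichment(trait, seq_along(trait),
                                        n_perm = 200, seed = 1)
  expect_equal(whole$p, 1)
  all_trait <- permutation_trait_enrichment(rep(TRUE, 15), 1:4,
                                            n_perm = 200, seed = 1)
  expect_equal(all_trait$p, 1)
  expect_error(permutation_trait_enrichment(trait, integer(0)), "empty")
})

test_that("unknown traits are excluded from observed and permuted sets", {
  trait <- c(rep(TRUE, 5), rep(FALSE, 5), NA, NA)
  expect_message(
    got <- permutation_trait_enrichment(trait, c(1:3, 11L), n_perm = 500,
                                        seed = 2),
    "unknown")
  expect_equal(got$subset_size, 3L)   # the NA event dropped from the subset
  expect_equal(got$background, 0.5)
})

test_that("depletion direction and determinism behave", {
  trait <- rep(c(TRUE, FALSE), each = 10)
  lo <- permutation_trait_enrichment(trait, 11:15, n_perm = 2000,
                                     alternative = "less", seed = 3)
  exact <- choose(10, 5) / choose(20, 5)
  expect_lt(abs(lo$p - exact), 0.02)
  a <- permutation_trait_enrichment(trait, 1:4, n_perm = 500, seed = 9)
  b <- permutation_trait_enrichment(trait, 1:4, n_perm = 500, seed = 9)
  expect_identical(a, b)
})
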