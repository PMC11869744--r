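# Small hand-built cohort: 3 samples, 12 species, controlled sharing.
build_cohort <- function() {
  gl <- 200L
  mk <- function(s, sp, base) flat_profile(s, sp, gl, pos = 0:149, base = base)
  profiles <- list()
  # s1/s2 jointly carry sp01..sp10; 4 of those identical, 6 divergent
  for (i in 1:10) {
    b2 <- if (i <= 4) "A" else "C"
    profiles <- c(profiles, list(mk("s1", sprintf("sp%02d", i), "A"),
                                 mk("s2", sprintf("sp%02d", i), b2)))
  }
  # sp11 only in s1, sp12 only in s2
  profiles <- c(profiles, list(mk("s1", "sp11", "A"), mk("s2", "sp12", "G")))
  profiles
}

test_that("dyad summaries count shared species and strains correctly", {
  profiles <- build_cohort()
  presence <- presence_table(profiles)
  dyads <- data.frame(sample_a = "s1", sample_b = "s2", category = "pair")
  cmp <- compare_cohort(profiles, dyads, presence)
  s <- summarize_dyad("s1", "s2", cmp, presence)
  expect_equal(s$n_shared_species, 10L)
  expect_equal(s$n_shared_strains, 4L)
  expect_equal(s$sharing_rate, 0.4)

  # identity dyad
  self <- summarize_dyad("s1", "s1",
                         compare_cohort(profiles,
                                        data.frame(sample_a = "s1",
                                                   sample_b = "s1"),
                                        presence),
                         presence)
  expect_equal(self$sharing_rate, 1)

  # disjoint species sets give an undefined rate
  p2 <- list(flat_profile("x", "spA", 100L, 0:99),
             flat_profile("y", "spB", 100L, 0:99))
  pres2 <- presence_table(p2)
  s2 <- summarize_dyad("x", "y",
                       compare_cohort(p2, data.frame(sample_a = "x",
                                                     sample_b = "y"), pres2),
                       pres2)
  expect_equal(s2$n_shared_species, 0L)
  expect_true(is.na(s2$sharing_rate))
})

test_that("dyad categorisation applies the study windows", {
  lifespans <- data.frame(
    host_id = c("h1", "h2", "h3", "h4"),
    birth = as.Date(c("2000-01-01", "2000-01-01", "2010-06-01", "2000-01-01")),
    death = as.Date(c("2005-01-01", NA, NA, NA)))
  rec <- function(s, h, d, g) list(sample_id = s, host_id = h,
                                   date = as.Date(d), group = g)
  # same host, 130 days apart
  expect_equal(categorize_dyad(rec("a", "h2", "2012-01-01", "g1"),
                               rec("b", "h2", "2012-05-10", "g1"), lifespans),
               "longitudinal")
  # same host, 200 days apart: outside the window
  expect_equal(categorize_dyad(rec("a", "h2", "2012-01-01", "g1"),
                               rec("b", "h2", "2012-07-19", "g1"), lifespans),
               "uncategorized")
  # h1 died 2005, h3 born 2010
  expect_equal(categorize_dyad(rec("a", "h1", "2004-01-01", "g1"),
                               rec("b", "h3", "2012-01-01", "g2"), lifespans),
               "never_overlapped")
  # contemporaries in different groups within 150 days
  expect_equal(categorize_dyad(rec("a", "h2", "2012-01-01", "g1"),
                               rec("b", "h4", "2012-03-01", "g2"), lifespans),
               "different_groups")
  # same group within 4 days
  expect_equal(categorize_dyad(rec("a", "h2", "2012-01-01", "g1"),
                               rec("b", "h4", "2012-01-03", "g1"), lifespans),
               "close_partners")
  # same group but 30 days apart matches nothing
  expect_equal(categorize_dyad(rec("a", "h2", "2012-01-01", "g1"),
                               rec("b", "h4", "2012-01-31", "g1"), lifespans),
               "uncategorized")
  # close-partner designation restricts the same-group window
  cp <- data.frame(host_a = "h2", host_b = "h9")
  expect_equal(categorize_dyad(rec("a", "h2", "2012-01-01", "g1"),
                               rec("b", "h4", "2012-01-03", "g1"), lifespans,
                               close_partners = cp),
               "uncategorized")
})

test_that("category comparisons match Welch and BH oracles", {
  set.seed(31)
  s <- data.frame(
    sample_a = paste0("a", 1:30), sample_b = paste0("b", 1:30),
    category = rep(c("x", "y", "z"), each = 10),
    sharing_rate = c(rnorm(10, 0.2, 0.05), rnorm(10, 0.4, 0.05),
                     rnorm(10, 0.41, 0.05)))
  got <- compare_sharing_across_categories(s, "welch_bh")
  for (i in seq_len(nrow(got))) {
    x <- s$sharing_rate[s$category == got$group2[i]]
    y <- s$sharing_rate[s$category == got$group1[i]]
    w <- oracle_welch(x, y)
    expect_equal(got$statistic[i], w$t, tolerance = 1e-10)
    expect_equal(got$df[i], w$df, tolerance = 1e-10)
    expect_equal(got$p[i], w$p, tolerance = 1e-10)
  }
  expect_equal(got$p_adj, oracle_bh(got$p), tolerance = 1e-12)

  tk <- compare_sharing_across_categories(s, "tukey")
  want <- oracle_tukey(s$sharing_rate, s$category)
  m <- match(paste(tk$group1, tk$group2), paste(want$group1, want$group2))
  expect_equal(tk$p_adj, want$p_adj[m], tolerance = 1e-8)
})

test_that("identical rate vectors give t = 0 and adjusted p = 1", {
  s <- data.frame(sample_a = paste0("a", 1:8), sample_b = paste0("b", 1:8),
                  category = rep(c("x", "y"), each = 4),
                  sharing_rate = rep(c(0.1, 0.2, 0.3, 0.4), 2))
  got <- compare_sharing_across_categories(s, "welch_bh")
  expect_equal(got$statistic, 0)
  expect_equal(got$p_adj, 1)
})

test_that("BH example and monotonicity properties hold", {
  expect_equal(oracle_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(3:8, 1))
    adj <- p.adjust(p, "BH")
    expect_true(all(adj >= p - 1e-15))
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("Welch/BH detects a 0.1 mean difference at sd 0.02, n = 20", {
  set.seed(77)
  hits <- 0L
  for (i in 1:20) {
    s <- data.frame(sample_a = paste0("a", 1:40), sample_b = paste0("b", 1:40),
                    category = rep(c("x", "y"), each = 20),
                    sharing_rate = c(rnorm(20, 0.3, 0.02),
                                     rnorm(20, 0.4, 0.02)))
    got <- compare_sharing_across_categories(s, "welch_bh")
    if (got$p_adj < 0.001) hits <- hits + 1L
  }
  expect_gte(hits / 20, 0.95)
})

test_that("undersized categories are flagged, not dropped silently", {
  s <- data.frame(sample_a = paste0("a", 1:5), sample_b = paste0("b", 1:5),
                  category = c("x", "x", "y", "y", "z"),
                  sharing_rate = c(0.1, 0.2, 0.3, 0.4, 0.5))
  got <- compare_sharing_across_categories(s, "welch_bh")
  expect_false(got$computable[got$group1 == "x" & got$group2 == "z"])
  expect_true(got$computable[got$group1 == "x" & got$group2 == "y"])
})

test_that("downsampling is deterministic, preserves one unit per host", {
  set.seed(7)
  n <- 40
  s <- data.frame(sample_a = paste0("s", 1:n, "_a"),
                  sample_b = paste0("s", 1:n, "_b"),
                  category = rep(c("w", "x", "y", "z"), each = 10),
                  sharing_rate = c(rnorm(10, .5, .05), rnorm(10, .2, .05),
                                   rnorm(10, .2, .05), rnorm(10, .2, .05)))
  host_map <- setNames(paste0("h", 1:(2 * n)), c(s$sample_a, s$sample_b))
  r1 <- downsample_robustness(s, host_map, n_iter = 5, seed = 99)
  r2 <- downsample_robustness(s, host_map, n_iter = 5, seed = 99)
  expect_identical(r1, r2)
  # one sample per host already: every iteration equals the full analysis
  full <- compare_sharing_across_categories(s, "tukey")
  m <- match(paste(r1$group1, r1$group2), paste(full$group1, full$group2))
  expect_equal(r1$p_adj, full$p_adj[m], tolerance = 1e-12)
})

test_that("downsampling keeps longitudinal pairs as single host units", {
  # two samples per host, all dyads longitudinal: downsampling must keep them
  s <- data.frame(sample_a = paste0("h", 1:6, "_t1"),
                  sample_b = paste0("h", 1:6, "_t2"),
                  category = rep(c("longitudinal", "other"), each = 3),
                  sharing_rate = c(0.9, 0.95, 0.85, 0.2, 0.25, 0.22))
  host_map <- setNames(rep(paste0("h", 1:6), 2), c(s$sample_a, s$sample_b))
  # non-longitudinal two-sample dyads can be lost; longitudinal ones survive
  r <- downsample_robustness(s, host_map, n_iter = 10, seed = 1)
  expect_true(all(c("longitudinal", "other") %in% c(r$group1, r$group2)))
})

test_that("phylogenetic sharing flags are scale invariant", {
  d <- matrix(c(0, 0.05, 1.0,
                0.05, 0, 0.9,
                1.0, 0.9, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  f <- phylo_share(d, 0.1)
  expect_true(f["a", "b"])
  expect_false(f["a", "c"])
  expect_identical(phylo_share(d * 37.5, 0.1), f)
  expect_true(all(diag(f)))
  expect_warning(ps0 <- phylo_share(matrix(0, 2, 2)), "zero")
  expect_true(all(ps0))
  # quantile mode flags the requested fraction of pairs
  set.seed(2)
  n <- 20
  m <- matrix(runif(n * n), n)
  m <- (m + t(m)) / 2; diag(m) <- 0
  q <- phylo_share(m, 0.1, mode = "quantile")
  frac <- mean(q[lower.tri(q)])
  expect_gte(frac, 0.05)
  expect_lte(frac, 0.2)
  expect_error(phylo_share(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})
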