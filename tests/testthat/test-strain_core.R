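test_that("allele detection applies count and frequency thresholds", {
  expect_equal(detect_alleles(c(10, 0, 0, 0)), "A")
  expect_equal(detect_alleles(c(9, 1, 0, 0)), "A")   # C fails min_count
  expect_equal(detect_alleles(c(8, 2, 0, 0)), c("A", "C"))
  expect_equal(detect_alleles(c(0, 0, 0, 0)), character(0))
  # frequency threshold: 2 reads of 100 is below 5%
  expect_equal(detect_alleles(c(98, 2, 0, 0)), "A")
  # consensus base always qualifies when depth >= min_count
  set.seed(42)
  for (i in 1:20) {
    cnt <- tabulate(sample.int(4L, 8, replace = TRUE), 4L)
    cons <- c("A", "C", "G", "T")[which.max(cnt)]
    expect_true(cons %in% detect_alleles(cnt))
  }
})

test_that("presence calls follow the breadth-at-depth rule", {
  gl <- 100L
  p <- flat_profile("s", "sp", gl, pos = 0:29, depth = 6L)
  pc <- presence_call(p)
  expect_equal(pc$breadth, 0.30)
  expect_true(pc$present)

  p <- flat_profile("s", "sp", gl, pos = 0:23, depth = 10L)
  pc <- presence_call(p)
  expect_equal(pc$breadth, 0.24)
  expect_false(pc$present)

  # depth below the 5x threshold contributes nothing to breadth
  p <- flat_profile("s", "sp", gl, pos = 0:29, depth = 4L)
  pc <- presence_call(p)
  expect_equal(pc$breadth, 0)
  expect_false(pc$present)

  empty <- allele_profile("s", "sp", gl, integer(0),
                          matrix(integer(0), 0, 4))
  expect_false(presence_call(empty)$present)
  expect_equal(presence_call(empty)$breadth, 0)
})

test_that("popANI counts only sites with fully disjoint allele sets", {
  gl <- 1000L
  a <- flat_profile("a", "sp", gl, pos = 0:999, depth = 10L)
  self <- compare_profiles(a, a)
  expect_equal(self$popANI, 1)
  expect_equal(self$conANI, 1)
  expect_equal(self$n_compared, 1000L)

  # 10 comparable sites, one disjoint
  a <- flat_profile("a", "sp", 10L, pos = 0:9, base = "A")
  cb <- matrix(0L, 10, 4); cb[, 1] <- 10L
  cb[1, ] <- c(0L, 10L, 0L, 0L)  # site 0: pure C vs pure A
  b <- allele_profile("b", "sp", 10L, 0:9, cb)
  cmp <- compare_profiles(a, b)
  expect_equal(cmp$n_pop_subs, 1L)
  expect_equal(cmp$popANI, 0.9)

  # shared minor allele suppresses the popANI substitution but not conANI
  cb[1, ] <- c(4L, 6L, 0L, 0L)   # consensus C, minor A shared with a
  b <- allele_profile("b", "sp", 10L, 0:9, cb)
  cmp <- compare_profiles(a, b)
  expect_equal(cmp$n_pop_subs, 0L)
  expect_equal(cmp$n_con_subs, 1L)
  expect_equal(cmp$popANI, 1)
  expect_equal(cmp$conANI, 0.9)
})

test_that("comparison is symmetric and popANI >= conANI on random profiles", {
  set.seed(11)
  for (i in 1:50) {
    a <- random_profile("a")
    b <- random_profile("b")
    ab <- compare_profiles(a, b)
    ba <- compare_profiles(b, a)
    expect_equal(ab$n_compared, ba$n_compared)
    expect_equal(ab$popANI, ba$popANI)
    expect_equal(ab$conANI, ba$conANI)
    if (ab$evaluable) expect_gte(ab$popANI, ab$conANI)
  }
})

test_that("comparison matches the brute-force site enumeration", {
  set.seed(12)
  for (i in 1:200) {
    a <- random_profile("a")
    b <- random_profile("b")
    got <- compare_profiles(a, b)
    want <- oracle_compare(a, b)
    expect_identical(got$n_compared, want$n_compared)
    expect_identical(got$n_pop_subs,
                     if (got$evaluable) want$n_pop_subs else NA_integer_)
    expect_identical(got$n_con_subs,
                     if (got$evaluable) want$n_con_subs else NA_integer_)
  }
})

test_that("self-comparison of any profile with comparable sites is identity", {
  set.seed(13)
  for (i in 1:20) {
    a <- random_profile("a", max_depth = 20L)
    cmp <- compare_profiles(a, a)
    if (cmp$evaluable) {
      expect_equal(cmp$popANI, 1)
      expect_equal(cmp$conANI, 1)
    }
  }
})

test_that("degenerate comparisons are flagged, never shared", {
  a <- flat_profile("a", "sp", 100L, pos = 0:9, depth = 3L)  # below min_depth
  cmp <- compare_profiles(a, a)
  expect_false(cmp$evaluable)
  expect_true(is.na(cmp$popANI))
  expect_error(is_strain_shared(cmp), "not evaluable")
  b <- flat_profile("b", "spOther", 100L, pos = 0:9)
  a2 <- flat_profile("a", "sp", 100L, pos = 0:9)
  expect_error(compare_profiles(a2, b), "species mismatch")
})

test_that("strain sharing threshold is exact at 99.999%", {
  mk <- function(n_sub) {
    structure(list(sample_a = "a", sample_b = "b", species_id = "sp",
                   n_compared = 50000L, n_pop_subs = n_sub,
                   n_con_subs = n_sub, popANI = 1 - n_sub / 50000,
                   conANI = 1 - n_sub / 50000, evaluable = TRUE),
              class = "pairwise_comparison")
  }
  expect_true(is_strain_shared(mk(0L)))
  expect_false(is_strain_shared(mk(1L)))  # 0.99998 < 0.99999
})

test_that("profile construction validates its invariants", {
  expect_error(allele_profile("s", "sp", 10, c(0, 10),
                              matrix(1L, 2, 4)), "positions")
  expect_error(allele_profile("s", "sp", 10, c(0, 0),
                              matrix(1L, 2, 4)), "duplicate")
  expect_error(allele_profile("s", "sp", 10, 0,
                              matrix(-1L, 1, 4)), "negative")
})
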