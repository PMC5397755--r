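test_that("the site quota is the smaller period total", {
  expect_identical(site_quota(186, 147), 147L)
  expect_identical(site_quota(133, 72), 72L)
  expect_identical(site_quota(50, 50), 50L)
  expect_identical(site_quota(0, 10), 0L)
})

test_that("site subsampling is exhaustive at full quota, empty at zero,
           bounded, and rejects impossible quotas", {
  counts <- c(A = 12, B = 0, C = 5)
  expect_identical(resample_site(counts, 17), c(A = 12L, B = 0L, C = 5L))
  expect_identical(resample_site(counts, 0), c(A = 0L, B = 0L, C = 0L))
  expect_error(resample_site(counts, 18), "exceeds")
  set.seed(4)
  for (i in 1:25) {
    r <- resample_site(counts, 9)
    expect_identical(sum(r), 9L)
    expect_true(all(r <= counts))
  }
})

test_that("subsampled species counts are multivariate hypergeometric", {
  counts <- c(A = 30, B = 10)
  set.seed(99)
  draws <- replicate(10000, resample_site(counts, 20)[["A"]])
  # closed-form hypergeometric mean and variance: k*K/N, k*(K/N)(1-K/N)(N-k)/(N-1)
  ev <- 20 * 30 / 40
  v <- 20 * 0.75 * 0.25 * (40 - 20) / (40 - 1)
  expect_lt(abs(mean(draws) - ev), 3 * sqrt(v / 10000))
  expect_lt(abs(var(draws) - v) / v, 0.1)
})

test_that("identical periods with exhaustive quotas give all-zero shifts", {
  m <- named_matrix(c(4, 6, 2,
                      0, 3, 9), c("A", "B"), c("s1", "s2", "s3"))
  ds <- matrix_dataset(m, m)
  dist <- replicate_shifts(ds, c("A", "B"), R = 20, seed = 1)
  expect_identical(nrow(dist$replicates), 20L * 2L * 3L)
  expect_true(all(dist$replicates$diff_m == 0))
})

test_that("a single-site species has zero shift in every replicate", {
  mh <- named_matrix(c(0, 8, 0,
                       10, 20, 30), c("solo", "bg"), c("s1", "s2", "s3"))
  mm <- named_matrix(c(0, 5, 0,
                       20, 10, 30), c("solo", "bg"), c("s1", "s2", "s3"))
  ds <- matrix_dataset(mh, mm)
  dist <- replicate_shifts(ds, c("solo", "bg"), R = 30, seed = 2)
  solo <- dist$replicates[dist$replicates$species == "solo", ]
  expect_true(all(solo$diff_m == 0))
})

test_that("replicate shifts are reproducible and stream-stable in R", {
  ds <- generate_survey(recovery_scenario(300, seed = 10))
  sp <- c("focal", "background")
  d1 <- replicate_shifts(ds, sp, R = 5, seed = 42)
  d2 <- replicate_shifts(ds, sp, R = 5, seed = 42)
  expect_identical(d1$replicates, d2$replicates)
  d3 <- replicate_shifts(ds, sp, R = 3, seed = 42)
  expect_identical(d3$replicates,
                   d1$replicates[d1$replicates$replicate <= 3, ])
  d4 <- replicate_shifts(ds, sp, R = 5, seed = 43)
  expect_false(identical(d4$replicates, d1$replicates))
})

test_that("species lost from a resampled period are excluded and logged", {
  # 'rare' has 1 of the 40 individuals at s1; quota 20 of 40 means it is
  # absent from roughly half the resamples of the historical period.
  mh <- named_matrix(c(1, 0,
                       39, 30), c("rare", "bg"), c("s1", "s2"))
  mm <- named_matrix(c(2, 0,
                       18, 30), c("rare", "bg"), c("s1", "s2"))
  ds <- matrix_dataset(mh, mm)
  dist <- replicate_shifts(ds, c("rare", "bg"), R = 100, seed = 9)
  nv <- dist$n_valid$n_valid[dist$n_valid$species == "rare"]
  expect_true(all(nv == nv[1]))
  n_excl <- sum(dist$exclusions$species == "rare")
  expect_identical(nv[1] + n_excl, 100L)
  expect_gt(n_excl, 0L)
  expect_identical(nrow(dist$replicates), sum(dist$n_valid$n_valid))
  # the replicate table only contains surviving replicate indices
  rare_rows <- dist$replicates[dist$replicates$species == "rare", ]
  expect_false(any(rare_rows$replicate %in% dist$exclusions$replicate[
    dist$exclusions$species == "rare"]))
})

test_that("the one-sample t test matches the closed form and flags
           degenerate samples", {
  r <- one_sample_t(c(1, 2, 3, 4, 5))
  expect_equal(r$t_stat, 3 / (sqrt(2.5) / sqrt(5)), tolerance = 1e-10)
  expect_equal(r$t_stat, 4.242640687, tolerance = 1e-8)
  expect_equal(r$p_value, 2 * pt(-abs(r$t_stat), df = 4))
  expect_equal(r$p_value, 0.0132, tolerance = 1e-2)

  sym <- one_sample_t(c(-1, 1, -1, 1))
  expect_equal(sym$t_stat, 0)
  expect_equal(sym$p_value, 1)

  deg <- one_sample_t(c(5, 5, 5, 5))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p_value))
  expect_equal(deg$mean, 5)
})

test_that("direction classification applies the sign rule with a dead zone", {
  expect_identical(classify_direction(0), "stasis")
  expect_identical(classify_direction(204), "upslope")
  expect_identical(classify_direction(-259), "downslope")
  expect_identical(classify_direction(-40, epsilon_m = 50), "stasis")
  expect_identical(classify_direction(c(-60, 10, 60), epsilon_m = 50),
                   c("downslope", "stasis", "upslope"))
})

test_that("the signed-rank Z and p agree with enumeration and wilcox.test", {
  # symmetric sample: Z = 0, p = 1
  sym <- community_wilcoxon(c(-3, 3, -8, 8))
  expect_equal(sym$z_stat, 0)
  expect_equal(sym$p_value, 1)

  # all-positive ranks 1..8: most extreme statistic, exact p = 2/256
  allpos <- community_wilcoxon(1:8, exact = TRUE)
  expect_equal(allpos$statistic, 36)
  expect_equal(allpos$p_value, 2 / 256)

  # n = 6 distinct values: the continuity-corrected normal approximation
  # is within 0.05 of the exact enumeration over all 2^6 sign assignments
  x <- c(-1.2, 2.5, 3.1, -4.7, 5.3, 6.8)
  appr <- community_wilcoxon(x, exact = FALSE)
  appr_cc <- community_wilcoxon(x, exact = FALSE, correct = TRUE)
  exact <- community_wilcoxon(x, exact = TRUE)
  expect_lt(abs(appr_cc$p_value - exact$p_value), 0.05)

  # cross-check both routes against the reference implementation
  wt <- suppressWarnings(stats::wilcox.test(x, exact = TRUE))
  expect_equal(exact$p_value, wt$p.value)
  wt2 <- suppressWarnings(stats::wilcox.test(x, exact = FALSE,
                                             correct = FALSE))
  expect_equal(appr$p_value, wt2$p.value)

  expect_error(community_wilcoxon(c(0, 0)), class = "elevshift_no_data")
})

test_that("Pratt zero handling matches the hand-worked example", {
  # x = (0, 2, -3, 5): ranks of |x| are 1..4 with the zero ranked first;
  # W+ = 2 + 4 = 6, E = (4*5 - 1*2)/4 = 4.5,
  # Var = (4*5*9 - 1*2*3)/24 = 7.25
  pr <- community_wilcoxon(c(0, 2, -3, 5), zero_policy = "pratt")
  expect_equal(pr$statistic, 6)
  expect_equal(pr$z_stat, (6 - 4.5) / sqrt(7.25))
  expect_identical(pr$n_used, 4L)
})

test_that("direction summaries report counts and magnitude moments", {
  res <- data.frame(
    species = c("a", "b", "c"), range_point = "centre",
    n_valid = 100, mean_shift_m = c(100, 300, -250),
    t_stat = 1, p_value = 0.5,
    direction = c("upslope", "upslope", "downslope"),
    significant = FALSE,
    direction_strict = "stasis")
  s <- direction_summary(res)
  up <- s[s$direction == "upslope", ]
  expect_identical(up$n_species, 2L)
  expect_equal(up$mean_abs_shift_m, 200)
  expect_equal(up$se_abs_shift_m, 100)
  down <- s[s$direction == "downslope", ]
  expect_identical(down$n_species, 1L)
  expect_equal(down$mean_abs_shift_m, 250)
  expect_true(is.na(down$se_abs_shift_m))
  expect_identical(s$n_species[s$direction == "stasis"], 0L)

  all_stasis <- transform(res, direction = "stasis")
  s2 <- direction_summary(all_stasis)
  expect_identical(s2$n_species,
                   ifelse(s2$direction == "stasis", 3L, 0L))
  expect_true(all(is.na(s2$mean_abs_shift_m)))
})
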