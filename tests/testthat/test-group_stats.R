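test_that("replicate CVs follow the sample-statistic definition", {
  pm <- make_pm(rbind(c(10, 10, 10), c(1, 2, 3), c(100, 100, 100)))
  cv <- replicate_cv(pm)
  expect_equal(cv$cv[1], 0)
  expect_equal(cv$cv[2], 50)  # mean 2, sd 1
  # the row with the largest mean sits at rel_log_intensity 0
  expect_equal(cv$rel_log_intensity[which.max(c(10, 2, 100))], 0)
  expect_true(all(cv$rel_log_intensity <= 0))

  one_sample <- make_pm(matrix(1:3, ncol = 1))
  expect_error(replicate_cv(one_sample), "2 samples")
})

test_that("multiplicative noise yields a flat CV-vs-intensity profile, an
           additive floor bends it upward", {
  set.seed(61)
  n <- 600
  base <- 10^runif(n, 2, 6)
  # lognormal with 10% CV over 10 replicates; the sample CV then centers
  # close to 10% in every intensity bin
  mult <- sapply(base, function(b) b * exp(rnorm(10, 0, 0.0998)))
  pm <- make_pm(t(mult))
  prof <- cv_vs_intensity_profile(replicate_cv(pm))
  well_filled <- prof$n >= 10
  expect_true(any(well_filled))
  expect_true(all(abs(prof$median_cv[well_filled] - 10) < 3))

  # additive noise floor dominates small intensities: CV rises monotonically
  # below the floor-dominated intensity
  floor_sd <- 300
  base2 <- 10^runif(n, 3, 6)
  addv <- sapply(base2, function(b) pmax(b + rnorm(3, 0, floor_sd), 1))
  pm2 <- make_pm(t(addv))
  prof2 <- cv_vs_intensity_profile(replicate_cv(pm2))
  expect_gt(prof2$median_cv[1], prof2$median_cv[nrow(prof2)] + 10)

  # empty bins are absent, not zero
  expect_true(all(prof$n > 0))
})

test_that("the rank-sum test matches its exact landmarks", {
  expect_equal(wmw_test(c(5, 5, 5), c(5, 5, 5))$p, 1)
  r <- wmw_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)  # 2 extreme assignments / choose(6,3)
  expect_equal(r$direction, "B")
})

test_that("exact p equals brute-force enumeration over all label assignments", {
  set.seed(62)
  for (trial in 1:20) {
    xs <- round(rlnorm(5, 8, 1), 1)
    ys <- round(rlnorm(5, 8, 1), 1)
    got <- wmw_test(xs, ys)$p
    # oracle: recompute the U statistic (pairwise wins + half-ties) for every
    # assignment of the pooled values to group A
    pool <- c(xs, ys)
    ustat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    u_obs <- ustat(xs, ys)
    combs <- combn(10, 5)
    u_all <- apply(combs, 2, function(ix) ustat(pool[ix], pool[-ix]))
    p_oracle <- mean(abs(u_all - 12.5) >= abs(u_obs - 12.5) - 1e-9)
    expect_equal(got, p_oracle)
  }
})

test_that("exact and approximate p agree for tie-free samples, and match
           wilcox.test", {
  set.seed(63)
  for (trial in 1:10) {
    xs <- rlnorm(6, 8, 1); ys <- rlnorm(6, 8, 1)
    p_exact <- wmw_test(xs, ys)$p
    p_approx <- wmw_test(xs, ys, exact_limit = 0)$p
    expect_lt(abs(p_exact - p_approx), 0.01 + 0.05 * p_exact)
    # independent reference implementation
    expect_equal(p_exact, wilcox.test(xs, ys, exact = TRUE)$p.value)
  }
})

test_that("swapping the groups preserves p and flips the direction", {
  set.seed(64)
  for (trial in 1:10) {
    xs <- rlnorm(4, 8, 1); ys <- rlnorm(7, 8, 2)
    a <- wmw_test(xs, ys); b <- wmw_test(ys, xs)
    expect_equal(a$p, b$p)
    if (a$direction != "tie") {
      expect_equal(sort(c(a$direction, b$direction)), c("A", "B"))
    }
  }
})

test_that("group profiling bins every row once and respects direction", {
  set.seed(65)
  ints <- matrix(rlnorm(100 * 10, 8, 1), nrow = 100)
  pm <- make_pm(ints)
  gp <- group_profile(pm, 1:5, 6:10)
  expect_equal(nrow(gp$results), 100)
  expect_equal(sum(gp$histogram$n_total), 100)
  expect_true(all(gp$histogram$n_a + gp$histogram$n_b <=
                    gp$histogram$n_total))

  # single row, identical groups -> highest-p bin
  pm1 <- make_pm(matrix(rep(7, 10), nrow = 1))
  gp1 <- group_profile(pm1, 1:5, 6:10)
  expect_equal(gp1$histogram$n_total[nrow(gp1$histogram)], 1L)

  expect_error(group_profile(pm, c("bad"), 6:10), "unknown")
})

test_that("a four-fold shift is detected in most rows at p < 0.05", {
  set.seed(66)
  n_rows <- 100
  a <- matrix(rlnorm(n_rows * 10, 8, 0.5), nrow = n_rows)
  b <- matrix(rlnorm(n_rows * 10, 8, 0.5), nrow = n_rows) * 4
  pm <- make_pm(cbind(a, b))
  gp <- group_profile(pm, 1:10, 11:20)
  expect_gte(mean(gp$results$p < 0.05), 0.8)
  # direction: group B predominates
  expect_true(all(gp$results$direction[gp$results$p < 0.05] == "B"))
})

test_that("the randomization baseline is reproducible and tracks the observed
           null histogram", {
  set.seed(67)
  pm <- make_pm(matrix(rlnorm(300 * 10, 8, 1), nrow = 300))
  b1 <- randomization_baseline(pm, 5, 5, n_rounds = 5, seed = 99)
  b2 <- randomization_baseline(pm, 5, 5, n_rounds = 5, seed = 99)
  expect_identical(b1$mean_counts, b2$mean_counts)
  expect_equal(sum(b1$mean_counts), 300)

  obs <- group_profile(pm, 1:5, 6:10)$histogram
  # both are null; per-bin difference within Monte-Carlo error
  ph <- (obs$n_total + b1$mean_counts) / (2 * 300)
  bound <- 3 * sqrt(300 * ph * (1 - ph)) + 3
  expect_true(all(abs(obs$n_total - b1$mean_counts) <= bound))

  expect_error(randomization_baseline(pm, 4, 5, seed = 1), "inconsistent")
})

test_that("true signal lifts the low-p bin above the baseline", {
  set.seed(68)
  a <- matrix(rlnorm(150 * 5, 8, 0.4), nrow = 150)
  b <- cbind(matrix(rlnorm(150 * 5, 8, 0.4), nrow = 150))
  b[1:75, ] <- b[1:75, ] * 5
  pm <- make_pm(cbind(a, b))
  obs <- group_profile(pm, 1:5, 6:10)$histogram
  base <- randomization_baseline(pm, 5, 5, n_rounds = 10, seed = 7)
  expect_gt(obs$n_total[1], base$mean_counts[1])
})
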