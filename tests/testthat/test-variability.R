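test_that("nine permutations cover all ordered basal/apical combinations", {
  nine <- nine_permutations(c(-5, -5, -5), c(9, 10, 11), d = 4.4)
  expect_length(nine, 9)
  expect_equal(sort(unique(round(nine, 6))),
               round(c(14, 15, 16) / 4.4, 6))
  expect_equal(as.vector(table(round(nine, 6))), c(3, 3, 3))
  # identical twists everywhere -> nine identical torsions
  same <- nine_permutations(c(-5, -5, -5), c(10, 10, 10), d = 4.4)
  expect_equal(unname(same), rep(15 / 4.4, 9))
  expect_error(nine_permutations(c(1, 2), c(1, 2, 3), d = 4.4))
  # twist-curve input goes through torsion_curve
  b <- lapply(c(-5, -5, -5), make_twist, plane = 22, label = "basal")
  a <- lapply(c(9, 10, 11), function(v) make_twist(v, 66, "apical", 2L))
  nine2 <- nine_permutations(b, a)
  expect_equal(sort(unname(nine2)), sort(unname(nine)))
})

test_that("duplicate-pair RMSE is |diff|/sqrt(2)", {
  expect_equal(rmse_consistent(c(3.4, 3.4)), 0)
  expect_equal(rmse_consistent(c(3.2, 3.6)), 0.4 / sqrt(2))
  for (c_ in c(2, -0.5)) {
    expect_equal(rmse_consistent(c_ * c(3.2, 3.6)),
                 abs(c_) * rmse_consistent(c(3.2, 3.6)))
  }
})

test_that("permutation RMSE averages the two per-reference MSEs", {
  expect_equal(rmse_permutations(rep(3, 9), c(3, 3)), 0)
  expect_equal(rmse_permutations(rep(3, 9), c(3, 3.2)), sqrt(0.04 / 2))
  set.seed(1)
  nine <- rnorm(9, 3.4, 0.3)
  refs <- c(3.3, 3.5)
  expect_equal(rmse_permutations(nine, refs),
               rmse_permutations(sample(nine), refs))
  expect_gte(rmse_permutations(nine, refs), 0)
})

test_that("limits of agreement are 1.96 standard deviations", {
  d <- c(0.1, -0.3, 0.5, 0.0, -0.2)
  expect_equal(limits_of_agreement(d), 1.96 * sd(d))
  expect_equal(limits_of_agreement(rep(0.2, 4)), 0)
  expect_equal(limits_of_agreement(3 * d), 3 * limits_of_agreement(d))
  expect_error(limits_of_agreement(0.1))
})

test_that("binomial coverage test matches direct pmf summation", {
  allin <- binomial_within_limits(rep(3.4, 10), 3.4, 0.5)
  expect_equal(allin$k, 10)
  expect_equal(allin$p_value, 1)
  # frozen oracle: sum of choose(144, j) 0.95^j 0.05^(144-j) for j <= 116
  vals <- c(rep(0, 116), rep(10, 28))  # 116 of 144 within the limits
  bt <- binomial_within_limits(vals, 0, 1)
  expect_equal(bt$k, 116)
  expect_equal(bt$n, 144)
  expect_equal(bt$p_value, 6.578185944e-10, tolerance = 1e-6)
  # coverage above expectation -> p above 0.5
  hi <- binomial_within_limits(c(rep(0, 99), 10), 0, 1)
  expect_gt(hi$p_value, 0.5)
})

test_that("consecutive pairing yields 2n pairings by temporal proximity", {
  pr <- consecutive_pairing(10)
  expect_equal(nrow(pr), 20)
  pr2 <- consecutive_pairing(2)
  expect_equal(nrow(pr2), 4)
  # interior basal k (slot 2k-1) pairs with apicals k-1 (slot 2k-2) and
  # k (slot 2k); the first basal pairs with the two nearest available
  expect_equal(pr$apical[pr$basal == 5], c(4, 5))
  expect_equal(pr$apical[pr$basal == 1], c(1, 2))
  expect_equal(pr$apical[pr$basal == 10], c(9, 10))
  # via twist curves, with alternation enforced
  tw <- list()
  for (i in 1:4) {
    lab <- if (i %% 2 == 1) "basal" else "apical"
    tw[[i]] <- make_twist(c(0, i), if (lab == "basal") 22 else 66, lab, i)
  }
  pt <- pair_torsions(tw)
  expect_equal(nrow(pt), 4)
  expect_equal(pt$slot_apical, c(2, 4, 2, 4))
  tw_bad <- tw[c(2, 1, 3, 4)]
  expect_error(pair_torsions(tw_bad), "alternate")
})

test_that("protocol SD comparison is a paired t-test with safe degeneracy", {
  expect_warning(res <- protocol_sd_comparison(c(1, 2, 3), c(1, 2, 3)),
                 "zero variance")
  expect_equal(res$p_value, 1)
  # frozen closed form: diffs (0.3, 0.5, 0.1, 0.4, 0.2) -> t = 4.2426,
  # p = 2 * P(T_4 < -4.2426) = 0.0132356
  b <- c(1.3, 1.5, 1.1, 1.4, 1.2)
  a <- rep(1, 5)
  res2 <- protocol_sd_comparison(b, a)
  expect_equal(res2$t, 4.242641, tolerance = 1e-6)
  expect_equal(res2$p_value, 0.01323560, tolerance = 1e-7)
  expect_equal(res2$estimate, 0.3)
  expect_error(protocol_sd_comparison(1:3, 1:4), "same subjects")
})

test_that("pearson correlation reports the analytic two-sided p", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate(x, 2 * x)$r, 1)
  # r = 0.5 at n = 16: t = r sqrt(n-2)/sqrt(1-r^2) = 2.1602, p = 0.0486
  set.seed(42)
  repeat {  # construct a sample with r exactly 0.5 by orthogonalization
    x16 <- rnorm(16)
    e <- rnorm(16)
    e <- residuals(lm(e ~ x16))
    y16 <- 0.5 * scale(x16) + sqrt(1 - 0.25) * scale(e)
    if (abs(cor(x16, y16) - 0.5) < 1e-10) break
  }
  res <- correlate(x16, as.numeric(y16))
  expect_equal(res$r, 0.5, tolerance = 1e-9)
  expect_equal(res$p_value, 0.048580, tolerance = 1e-4)
  flip <- correlate(x16, -as.numeric(y16))
  expect_equal(flip$r, -0.5, tolerance = 1e-9)
  expect_equal(flip$p_value, res$p_value)
  expect_error(correlate(x, rep(1, 5)), "zero variance")
})

test_that("experiment-1 analysis aggregates per-subject RMSEs and coverage", {
  set.seed(9)
  subj <- lapply(1:6, function(i) {
    ref <- 3.4 + rnorm(2, 0, 0.15)
    list(nine = 3.4 + rnorm(9, 0, 0.4), ref_pair = ref,
         scout_range = runif(1, 5, 15))
  })
  names(subj) <- paste0("S", 1:6)
  rep1 <- analyze_experiment1(subj)
  expect_s3_class(rep1, "variability_report")
  expect_equal(nrow(rep1$per_subject), 6)
  expect_equal(rep1$binomial$n, 54)
  expect_true(rep1$loa_halfwidth >= 0)
  expect_equal(rep1$rmse_permutations_mean,
               mean(vapply(subj, function(s) rmse_permutations(s$nine, s$ref_pair),
                           numeric(1))))
})

test_that("experiment-2 analysis compares protocols and computes LoA", {
  set.seed(10)
  mk <- function(subject, protocol, sd) {
    data.frame(subject = subject, protocol = protocol, order = 1:20,
               peak_torsion = 3.5 + rnorm(20, 0, sd))
  }
  tor <- do.call(rbind, c(
    lapply(1:8, function(i) mk(paste0("S", i), "breath_hold", 0.35)),
    lapply(1:8, function(i) mk(paste0("S", i), "navigator", 0.15))))
  rep2 <- analyze_experiment2(tor)
  expect_gt(rep2$sd_breathhold_mean, rep2$sd_navigator_mean)
  expect_lt(rep2$sd_ttest$p_value, 0.05)
  expect_gt(rep2$loa_halfwidth[["breath_hold"]], rep2$loa_halfwidth[["navigator"]])
  # disjoint-pair flavor gives n differences per subject, still positive
  rep2d <- analyze_experiment2(tor, loa_flavor = "disjoint")
  expect_true(all(rep2d$loa_halfwidth > 0))
  # mismatched subject sets are rejected
  tor_bad <- tor[!(tor$subject == "S8" & tor$protocol == "navigator"), ]
  expect_error(analyze_experiment2(tor_bad), "different subject sets")
})
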