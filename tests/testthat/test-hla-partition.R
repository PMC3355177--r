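test_that("DQ profiles count effective copies, including in-trans DQ2.5", {
  p <- dq_profile(c("DQ2.5", "DQ2.2", "DQ8", "DQ2.2"),
                  c("DQ2.5", "DQ7", "X", "DQ2.2"))
  expect_identical(p$n_dq25, c(2L, 1L, 0L, 0L))
  expect_identical(p$n_dq8, c(0L, 0L, 1L, 0L))
  # the trans pair contributes no DQ2.2/DQ7 copies in the effective encoding
  expect_identical(p$n_dq22[2], 0L)
  expect_identical(p$n_dq7[2], 0L)
  expect_identical(p$n_dq22[4], 2L)
  expect_error(dq_profile("DQ9", "X"), "unknown haplotype")
  # order of the pair never matters
  expect_identical(dq_profile("DQ2.2", "DQ7"), dq_profile("DQ7", "DQ2.2"))
})

test_that("independence test matches Pearson chi-square and handles degeneracy", {
  expect_identical(independence_test(rep(1, 50), rbinom(50, 1, .5))$p_value, 1)
  expect_identical(
    independence_test(factor(rep(c("a", "b"), each = 100)),
                      rep(c(1, 0), 100))$p_value, 1)

  # printed 2x2 from the reference stratum table vs stats::chisq.test
  x <- factor(rep(c("hom", "ref"), times = c(279, 470)))
  y <- c(rep(1, 266), rep(0, 13), rep(1, 212), rep(0, 258))
  got <- independence_test(x, y)
  expect_equal(got$p_value, oracle_chisq_p(table(x, y)), tolerance = 1e-10)

  # ordinal trend form agrees with the Cochran-Armitage statistic
  x <- rep(0:2, times = c(100, 60, 40))
  y <- rbinom(200, 1, 0.2 + 0.2 * x / 2)
  got <- independence_test(x, y)
  ca <- suppressWarnings(stats::prop.trend.test(tapply(y, x, sum), table(x)))
  expect_equal(got$statistic, unname(ca$statistic), tolerance = 1e-10)
  expect_equal(got$p_value, ca$p.value, tolerance = 1e-10)
})

test_that("best binary split equals the exhaustive-partition oracle", {
  # forced k = 2 case
  x <- factor(rep(c("a", "b"), each = 30))
  y <- rep(c(1, 0, 1, 1), times = c(20, 10, 25, 5))
  sp <- best_binary_split(x, y, min_node = 1)
  expect_identical(sort(sp$left_values), "a")

  # k = 3 with rates (0.9, 0.9, 0.1) isolates the deviant level
  set.seed(7)
  x <- factor(rep(c("a", "b", "c"), each = 60))
  y <- c(rbinom(60, 1, .9), rbinom(60, 1, .9), rbinom(60, 1, .1))
  sp <- best_binary_split(x, y, min_node = 1)
  expect_identical(sort(sp$left_values), c("a", "b"))

  # random factors with k in 3..5 vs brute force
  for (s in 1:20) {
    set.seed(s)
    k <- sample(3:5, 1)
    x <- factor(sample(letters[1:k], 150, replace = TRUE))
    y <- rbinom(150, 1, stats::plogis(as.integer(x) / 2 - 1))
    if (length(unique(y)) < 2) next
    sp <- best_binary_split(x, y, min_node = 1)
    or <- oracle_best_split(x, y)
    expect_equal(sp$statistic, or$statistic, tolerance = 1e-10,
                 info = paste("seed", s))
  }

  # perfectly symmetric outcome: no admissible informative split
  x <- factor(rep(c("a", "b"), each = 40))
  y <- rep(c(1, 0), 40)
  expect_null(best_binary_split(x, y, min_node = 1))

  # ordinal cutpoint search
  x <- rep(0:2, times = c(50, 30, 20))
  y <- c(rbinom(80, 1, 0.2), rbinom(20, 1, 0.9))
  sp <- best_binary_split(x, y, min_node = 1)
  expect_identical(sp$cut, 1)
})

test_that("the reference cohort yields the published five-node tree", {
  rc <- dq_reference_cohort()
  tree <- fit_ctree(rc$profiles, rc$y)
  expect_identical(tree$n_terminal, 5L)
  ps <- tree_split_pvalues(tree)
  expect_identical(length(ps), 4L)
  expect_true(all(ps < 0.003))

  strata <- assign_strata(tree, rc$profiles)
  tab <- table(strata, rc$y)
  # each fitted stratum matches one reference stratum exactly
  ref <- dq_stratum_counts()
  got <- apply(tab[, c("1", "0")], 1, paste, collapse = "/")
  want <- apply(ref, 1, paste, collapse = "/")
  expect_setequal(unname(got), unname(want))
  expect_identical(stratum_agreement(strata, rc$stratum), 1)

  # permuting sample order permutes assignments
  perm <- sample(length(rc$y))
  expect_identical(assign_strata(tree, rc$profiles[perm, ]),
                   strata[perm], ignore_attr = TRUE)
})

test_that("decreasing alpha never increases the number of terminal nodes", {
  rc <- dq_reference_cohort()
  sizes <- vapply(c(0.5, 0.05, 0.01, 1e-3, 1e-5, 1e-150), function(a) {
    fit_ctree(rc$profiles, rc$y, tree_params(alpha = a))$n_terminal
  }, 0L)
  expect_true(all(diff(sizes) <= 0))
  expect_identical(sizes[length(sizes)], 1L)
})

test_that("the stopping rule holds its size under the null", {
  # outcome independent of both ordinal predictors
  splits <- 0L
  n_rep <- 40
  for (s in seq_len(n_rep)) {
    set.seed(300 + s)
    prof <- data.frame(n_dq25 = sample(0:2, 600, TRUE),
                       n_dq8 = sample(0:2, 600, TRUE))
    y <- rbinom(600, 1, 0.6)
    tree <- fit_ctree(prof, y)
    splits <- splits + (tree$n_terminal > 1L)
  }
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lte(splits / n_rep, 0.05 + 3 * se)
})

test_that("routing errors on unrepresentable profiles, not on unseen ones", {
  rc <- dq_reference_cohort()
  tree <- fit_ctree(rc$profiles, rc$y)
  # a value never seen at a split routes by cutpoint membership
  got <- assign_strata(tree, data.frame(n_dq25 = 0L, n_dq8 = 2L))
  expect_identical(as.integer(got),
                   as.integer(assign_strata(tree, data.frame(n_dq25 = 0L,
                                                             n_dq8 = 1L))))
  expect_error(assign_strata(tree, data.frame(n_dq25 = NA, n_dq8 = 0L)),
               "missing predictor")
  expect_error(assign_strata(tree, data.frame(n_dq25 = 1L)), "lack predictor")
})
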