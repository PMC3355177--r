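test_that("IRLS logistic fit matches closed forms and glm", {
  # intercept only: logit of the case fraction
  y <- rep(c(1, 0), times = c(40, 60))
  fit <- fit_logistic(matrix(1, 100, 1, dimnames = list(NULL, "b0")), y)
  expect_equal(unname(fit$coefficients), log(40 / 60), tolerance = 1e-10)

  # single binary covariate from the printed 2x2 (DQ2.5-hom vs non/non)
  x <- rep(c(1, 0), times = c(279, 470))
  y <- c(rep(1, 266), rep(0, 13), rep(1, 212), rep(0, 258))
  fit <- fit_logistic(cbind(b0 = 1, x = x), y)
  want <- oracle_2x2(266, 13, 212, 258)
  expect_equal(unname(fit$coefficients["x"]), want$beta, tolerance = 1e-8)
  expect_equal(sqrt(fit$covariance["x", "x"]), want$se, tolerance = 1e-8)

  # multi-covariate fit against stats::glm
  set.seed(13)
  X <- cbind(1, matrix(rnorm(200 * 3), 200, 3))
  colnames(X) <- c("b0", "x1", "x2", "x3")
  yy <- rbinom(200, 1, stats::plogis(X %*% c(-0.5, 1, 0, -0.7)))
  fit <- fit_logistic(X, yy)
  ref <- stats::glm(yy ~ X[, -1], family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12))
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(fit$covariance))),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  expect_true(fit$diagnostics$converged)
  expect_lt(fit$diagnostics$max_abs_score, 1e-8)
})

test_that("deviance is non-increasing and separation is flagged", {
  set.seed(21)
  X <- cbind(1, rnorm(80))
  y <- rbinom(80, 1, stats::plogis(2 * X[, 2]))
  fit <- fit_logistic(X, y)
  expect_true(all(diff(fit$diagnostics$deviance) <= 1e-8))

  # perfect separation
  xs <- c(-(5:1), 1:5)
  ys <- as.integer(xs > 0)
  fit <- fit_logistic(cbind(1, xs), ys)
  expect_true(fit$diagnostics$separation_flag)
  expect_true(all(!is.finite(fit$covariance) | is.na(fit$covariance)))

  expect_error(fit_logistic(cbind(b0 = 1, a = xs, dup = xs), ys),
               "collinear.*dup")
})

test_that("allele-coding flip negates beta and preserves the p-value", {
  spec <- xmhc_sim_spec(n_cases = 300, n_controls = 200, n_blocks = 2,
                        snps_per_block = 3, planted_or = 1.8, seed = 41)
  sim <- simulate_cohort(spec)
  res <- assoc_scan(sim$genotypes, sim$samples)
  flipped <- sim$genotypes
  flipped$calls <- 2L - flipped$calls
  res_f <- assoc_scan(flipped, sim$samples)
  expect_equal(res_f$beta, -res$beta, tolerance = 1e-6)
  expect_equal(res_f$wald_p, res$wald_p, tolerance = 1e-6)
})

test_that("scan handles missingness, monomorphic SNPs and the covariate SNP", {
  set.seed(19)
  calls <- matrix(rbinom(200 * 4, 2, 0.3), 200, 4)
  calls[1:10, 2] <- NA
  calls[, 3] <- 0L
  gm <- make_gm(calls)
  samples <- make_samples(rep(c("case", "control"), 100))
  res <- assoc_scan(gm, samples)
  expect_identical(res$n_used[res$snp_id == "rs002"], 190L)
  expect_identical(res$reason[res$snp_id == "rs003"], "monomorphic")
  expect_true(all(is.na(res$beta[res$snp_id == "rs003"])))

  # covariate SNP is modeled but never tested against itself
  res_c <- assoc_scan(gm, samples, covariate_snp = "rs001")
  expect_false("rs001" %in% res_c$snp_id)
  expect_identical(nrow(res_c), nrow(res) - 1L)
})

test_that("stratum adjustment removes signal that is confounding-only", {
  # genotype correlated with the risk stratum but with no direct effect
  set.seed(101)
  spec <- xmhc_sim_spec(n_cases = 1400, n_controls = 600, n_blocks = 2,
                        snps_per_block = 2, planted_or = numeric(0), seed = 51)
  sim <- simulate_cohort(spec)
  high <- sim$truth$strata$stratum %in%
    c("DQ2.5 homozygote", "DQ2.5/non-DQ8 heterozygote")
  n <- length(high)
  flip <- runif(n) < 0.15
  g_conf <- as.integer(ifelse(flip, rbinom(n, 1, 0.5), high))
  expect_gt(cor(g_conf, high)^2, 0.4)
  gm <- genotype_matrix(
    cbind(sim$genotypes$calls, conf = g_conf),
    rbind(sim$genotypes$variants,
          data.frame(snp_id = "conf", chrom = "6", pos_bp = 34000001L,
                     allele_minor = "A", allele_major = "G")),
    sim$genotypes$sample_ids)
  strata <- sim$truth$strata$stratum
  simple <- assoc_scan(gm, sim$samples)
  adjusted <- assoc_scan(gm, sim$samples, strata = strata)
  expect_lt(simple$wald_p[simple$snp_id == "conf"], 1e-6)
  expect_gt(adjusted$wald_p[adjusted$snp_id == "conf"], 0.01)
})

test_that("joint fits agree with marginal fits for independent SNPs", {
  spec <- xmhc_sim_spec(n_cases = 1000, n_controls = 500, n_blocks = 8,
                        snps_per_block = 3, planted_or = c(1.8, 2.0), seed = 61)
  sim <- simulate_cohort(spec)
  planted <- sim$truth$planted$snp_id
  marg <- assoc_scan(sim$genotypes, sim$samples)
  jt <- joint_fit(sim$genotypes, sim$samples, planted)
  for (s in planted) {
    b_m <- marg$beta[marg$snp_id == s]
    se_m <- marg$se[marg$snp_id == s]
    b_j <- jt$beta[jt$snp_id == s]
    expect_lt(abs(b_j - b_m), 2 * se_m)
  }
  expect_error(joint_fit(sim$genotypes, sim$samples, rep(planted[1], 2)),
               "collinear|duplicate")
})

test_that("a strata-only model reproduces the contingency odds ratios", {
  rc <- dq_reference_cohort()
  tree <- fit_ctree(rc$profiles, rc$y)
  strata <- factor(assign_strata(tree, rc$profiles))
  # reference level = most frequent stratum, as in the scan design
  ref_lev <- names(which.max(table(strata)))
  strata <- stats::relevel(strata, ref_lev)
  X <- stats::model.matrix(~strata)
  fit <- fit_logistic(X, rc$y)
  tab <- table(strata, rc$y)
  odds <- tab[, "1"] / tab[, "0"]
  for (lv in levels(strata)[-1]) {
    want <- log(odds[lv] / odds[ref_lev])
    expect_equal(unname(fit$coefficients[paste0("strata", lv)]),
                 unname(want), tolerance = 1e-6)
  }
})
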