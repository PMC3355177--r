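test_that("haplotype generator hits its LD targets at the limits", {
  blocks <- list(block_spec(4, 1000, target_r2 = 0, maf_range = c(0.2, 0.4)))
  h <- simulate_haplotypes(blocks, 20000, seed = 1)$haplotypes
  for (j in 2:4) expect_lt(cor(h[, j - 1], h[, j])^2, 0.02)

  blocks <- list(block_spec(3, 1000, target_r2 = 1, maf_range = c(0.3, 0.3)))
  h <- simulate_haplotypes(blocks, 500, seed = 2)$haplotypes
  expect_identical(h[, 1], h[, 2])
  expect_identical(h[, 1], h[, 3])

  blocks <- list(block_spec(2, 1000, target_r2 = 0.5, maf_range = c(0.3, 0.3)))
  h <- simulate_haplotypes(blocks, 50000, seed = 3)$haplotypes
  expect_lt(abs(cor(h[, 1], h[, 2])^2 - 0.5), 0.03)
})

test_that("infeasible LD targets raise a parameter error with the bound", {
  blocks <- list(block_spec(10, 1000, target_r2 = 0.6,
                            maf_range = c(0.05, 0.5)))
  expect_error(simulate_haplotypes(blocks, 10, seed = 1),
               "infeasible.*feasible r2")
})

test_that("blocks are LD-independent across hotspot boundaries", {
  blocks <- list(block_spec(3, 1000, target_r2 = 0.8, maf_range = c(0.36, 0.4)),
                 block_spec(3, 50000, target_r2 = 0.8, maf_range = c(0.36, 0.4)))
  h <- simulate_haplotypes(blocks, 20000, seed = 4)$haplotypes
  for (i in 1:3) for (j in 4:6) expect_lt(cor(h[, i], h[, j])^2, 0.02)
  # within blocks the LD is there
  expect_gt(cor(h[, 1], h[, 2])^2, 0.5)
})

test_that("cohort simulation is deterministic and fills quotas exactly", {
  spec <- xmhc_sim_spec(n_cases = 120, n_controls = 60, n_blocks = 3,
                        snps_per_block = 4, planted_or = 2.0, seed = 9)
  sim1 <- simulate_cohort(spec)
  sim2 <- simulate_cohort(spec)
  expect_identical(sim1, sim2)
  expect_identical(sum(sim1$samples$status == "case"), 120L)
  expect_identical(sum(sim1$samples$status == "control"), 60L)
  expect_identical(nrow(sim1$genotypes$variants), 12L)
  # a different seed gives a different cohort
  spec_b <- xmhc_sim_spec(n_cases = 120, n_controls = 60, n_blocks = 3,
                          snps_per_block = 4, planted_or = 2.0, seed = 10)
  expect_false(identical(simulate_cohort(spec_b)$genotypes$calls,
                         sim1$genotypes$calls))
})

test_that("an effect-free cohort shows no case-control frequency signal", {
  spec <- xmhc_sim_spec(n_cases = 1000, n_controls = 1000, n_blocks = 10,
                        snps_per_block = 4, planted_or = numeric(0), seed = 5)
  spec$stratum_log_odds[] <- 0
  sim <- simulate_cohort(spec)
  g <- sim$genotypes$calls
  case <- sim$samples$status == "case"
  z <- apply(g, 2, function(col) {
    (mean(col[case]) - mean(col[!case])) /
      sqrt(var(col) * (1 / sum(case) + 1 / sum(!case)))
  })
  expect_true(all(abs(z) < 4))
})

test_that("stratum risk calibration reproduces the reference table", {
  spec <- xmhc_sim_spec(planted_or = numeric(0), n_blocks = 2,
                        snps_per_block = 2, seed = 21)
  sim <- simulate_cohort(spec)
  tab <- table(factor(sim$truth$strata$stratum, dq_stratum_levels()),
               sim$samples$status)
  prop <- prop.table(tab, 2)
  ref <- dq_stratum_counts()
  refp <- sweep(ref, 2, colSums(ref), "/")
  expect_lt(max(abs(prop[, "case"] - refp[, "cases"])), 0.03)
  expect_lt(max(abs(prop[, "control"] - refp[, "controls"])), 0.03)
})

test_that("a planted OR-2 SNP is detected and estimated without bias", {
  # 100 seeded replicates of a 1500/500 cohort with one MAF-0.3 SNP of
  # per-allele OR 2 and no other risk factors; power at 5e-7 is checked
  # against an analytic score calculation and the log-OR estimate for bias
  n_rep <- 100
  hits <- 0L
  betas <- numeric(n_rep)
  zero_strata <- default_stratum_log_odds()
  zero_strata[] <- 0
  for (r in seq_len(n_rep)) {
    spec <- cohort_spec(1500, 500,
                        list(block_spec(1, 1000, maf_range = c(0.3, 0.3))),
                        stratum_log_odds = zero_strata,
                        planted = data.frame(snp_index = 1L, beta = log(2)),
                        seed = 1000 + r)
    sim <- simulate_cohort(spec)
    res <- assoc_scan(sim$genotypes, sim$samples)
    hits <- hits + (res$wald_p[1] < 5e-7)
    betas[r] <- res$beta[1]
  }
  pow <- oracle_trend_power(2, 0.3, 1500, 500,
                            stratum_log_odds = zero_strata)
  expect_gte(hits, 90L)
  expect_lte(abs(hits - n_rep * pow), 3 * sqrt(n_rep * pow * (1 - pow)) + 1)
  expect_lt(abs(mean(betas) - log(2)), 3 * sd(betas) / sqrt(n_rep))
})
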