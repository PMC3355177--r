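test_that("EM r2 matches identity, independence and phased truth", {
  set.seed(3)
  g <- rbinom(5000, 2, 0.3)
  expect_equal(r2_em(g, g), 1, tolerance = 1e-9)

  g2 <- rbinom(5000, 2, 0.3)
  expect_lt(r2_em(g, g2), 0.01)

  expect_true(is.na(r2_em(rep(0L, 100), rbinom(100, 2, 0.3))))
  expect_identical(attr(r2_em(rep(0L, 100), g2[1:100]), "reason"),
                   "monomorphic")

  # phased-truth check: haplotypes with target r2 = 0.5, paired into
  # 5000 diploids. The EM estimate must equal the genotype-likelihood ML
  # estimate (independent 1-D optimization) and sit within the phase-
  # information loss band (~0.005 at this n) of the direct phased count.
  hs <- simulate_haplotypes(
    list(block_spec(2, 1000, target_r2 = 0.5, maf_range = c(0.3, 0.3))),
    10000, seed = 8)
  h <- hs$haplotypes
  g1 <- h[seq(1, 9999, 2), 1] + h[seq(2, 10000, 2), 1]
  g2 <- h[seq(1, 9999, 2), 2] + h[seq(2, 10000, 2), 2]
  r2_phased <- cor(h[, 1], h[, 2])^2
  expect_equal(r2_em(g1, g2), oracle_r2_ml(g1, g2), tolerance = 1e-6)
  expect_equal(r2_em(g1, g2), r2_phased, tolerance = 0.02)

  # missing calls are dropped pairwise
  g1[1:50] <- NA
  expect_equal(r2_em(g1, g2), oracle_r2_ml(g1, g2), tolerance = 1e-6)
})

# shared LD panel for the clumping tests: 4 blocks of 3 SNPs
ld_panel <- local({
  spec <- xmhc_sim_spec(n_cases = 200, n_controls = 200, n_blocks = 4,
                        snps_per_block = 3, target_r2 = 0.7,
                        planted_or = numeric(0), seed = 71)
  simulate_cohort(spec)
})

test_that("greedy clumping matches hand-worked and brute-force oracles", {
  gm <- ld_panel$genotypes
  ids <- gm$variants$snp_id
  pos <- gm$variants$pos_bp

  # no SNP below p1 -> empty clump list
  res <- data.frame(snp_id = ids, wald_p = runif(12, 0.2, 1))
  expect_length(clump(res, gm), 0)

  # 3 correlated SNPs (one block), p = 1e-9, 1e-8, 1e-3: one clump,
  # most significant SNP is the index, both others secondary
  res <- data.frame(snp_id = ids[1:3], wald_p = c(1e-9, 1e-8, 1e-3))
  cl <- clump(res, subset_genotypes(gm, variants = ids[1:3]),
              clump_params(p1 = 5e-7, p2 = 0.01, max_kb = 3000, r2_min = 0.1))
  expect_length(cl, 1)
  expect_identical(cl[[1]]$index_snp, ids[1])
  expect_setequal(cl[[1]]$secondary$snp_id, ids[2:3])

  # full oracle equivalence over a parameter grid
  set.seed(72)
  p <- 10^-runif(12, 0, 10)
  res <- data.frame(snp_id = ids, wald_p = p)
  r2mat <- outer(seq_along(ids), seq_along(ids), Vectorize(function(i, j) {
    if (i == j) 1 else r2_em(gm$calls[, i], gm$calls[, j])
  }))
  for (p1 in c(1e-6, 1e-4)) {
    for (p2 in c(0.01, 0.05)) {
      for (r2min in c(0.05, 0.3, 0.8)) {
        for (kb in c(50, 250, 2000)) {
          got <- clump(res, gm, clump_params(p1, p2, kb, r2min))
          want <- oracle_clump(ids, pos, p, r2mat, p1, p2, kb, r2min)
          expect_identical(length(got), length(want))
          for (k in seq_along(got)) {
            expect_identical(got[[k]]$index_snp, want[[k]]$index)
            expect_setequal(got[[k]]$secondary$snp_id, want[[k]]$secondary)
          }
        }
      }
    }
  }

  # a barred SNP can be secondary but never index
  res <- data.frame(snp_id = ids[1:3], wald_p = c(1e-9, 1e-8, 1e-3))
  cl <- clump(res, gm, clump_params(max_kb = 3000), barred_index = ids[1])
  expect_identical(cl[[1]]$index_snp, ids[2])
  expect_true(ids[1] %in% cl[[1]]$secondary$snp_id)
})

test_that("clump outputs satisfy the membership invariants", {
  spec <- xmhc_sim_spec(n_cases = 1200, n_controls = 500, n_blocks = 6,
                        snps_per_block = 5, planted_or = c(2.0, 2.2),
                        seed = 73)
  sim <- simulate_cohort(spec)
  res <- assoc_scan(sim$genotypes, sim$samples)
  params <- clump_params(max_kb = 1000)
  cl <- clump(res, sim$genotypes, params)
  expect_gt(length(cl), 0)
  all_members <- unlist(lapply(cl, function(x) c(x$index_snp,
                                                 x$secondary$snp_id)))
  expect_identical(anyDuplicated(all_members), 0L)
  pos <- sim$genotypes$variants$pos_bp
  ids <- sim$genotypes$variants$snp_id
  for (x in cl) {
    expect_lt(x$index_p, params$p1)
    if (nrow(x$secondary)) {
      expect_true(all(x$secondary$r2_with_index >= params$r2_min))
      expect_true(all(x$secondary$p_value < params$p2))
      expect_true(all(x$secondary$p_value >= x$index_p))
      d <- abs(pos[match(x$secondary$snp_id, ids)] - x$index_pos)
      expect_true(all(d <= params$max_kb * 1000))
    }
  }
})

test_that("two planted independent loci become two clump indices", {
  hits <- 0L
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    spec <- xmhc_sim_spec(n_cases = 1500, n_controls = 500, n_blocks = 4,
                          snps_per_block = 3, planted_or = c(2.2, 2.2),
                          seed = 7000 + r)
    sim <- simulate_cohort(spec)
    res <- assoc_scan(sim$genotypes, sim$samples)
    cl <- clump(res, sim$genotypes, clump_params(max_kb = 3000))
    idx <- vapply(unclass(cl), `[[`, "", "index_snp")
    planted <- sim$truth$planted$snp_id
    blk <- (match(planted, sim$genotypes$variants$snp_id) - 1) %/% 3
    iblk <- (match(idx, sim$genotypes$variants$snp_id) - 1) %/% 3
    hits <- hits + (length(idx) == 2 && setequal(iblk, blk))
  }
  expect_gte(hits, 18L)
})

test_that("the sensitivity sweep follows the expected qualitative shape", {
  gm <- ld_panel$genotypes
  ids <- gm$variants$snp_id
  # a single isolated significant SNP: invariant to every parameter
  res <- data.frame(snp_id = ids, wald_p = c(1e-9, rep(0.5, 11)))
  sw <- sensitivity_sweep(res, gm, r2_grid = c(0.05, 0.5, 0.95),
                          p1_grid = 10^-(4:8))
  expect_true(all(sw$n_index_snps == 1L))

  # raising the index threshold above the best SNP zeroes the count
  sw <- sensitivity_sweep(res, gm, r2_grid = 0.1, p1_grid = c(1e-8, 1e-10))
  expect_identical(sw$n_index_snps[sw$parameter == "p1" & sw$value == 1e-10],
                   0L)
})
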