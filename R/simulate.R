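# Synthetic case-control cohort generator.
#
# Haplotypes are built block-by-block as a first-order Markov chain over
# biallelic loci: within a block each adjacent pair of SNPs is given the
# disequilibrium coefficient D that produces the requested r-squared at the
# realized allele frequencies, and blocks are mutually independent, which is
# the idealized picture of haplotype blocks separated by recombination
# hotspots. Disease status follows a logistic model whose linear predictor
# sums a baseline, an HLA-DQ risk-stratum effect, and per-allele effects of
# planted risk SNPs; the case-control design is realized by explicit
# rejection sampling until both quotas are filled.

#' Specification of one haplotype block
#'
#' @param n_snps Number of SNPs in the block (>= 1).
#' @param start_bp 1-based position of the first SNP.
#' @param snp_spacing_bp Distance between adjacent SNPs in bp.
#' @param target_r2 Target r-squared between adjacent SNPs within the block,
#'   in `[0, 1]`. Blocks are independent of each other (hotspot boundaries).
#' @param maf_range Length-2 numeric, low and high bound of the uniform
#'   distribution the per-SNP minor allele frequencies are drawn from;
#'   bounds in `(0, 0.5]`.
#' @return An object of class `block_spec`.
#' @export
block_spec <- function(n_snps, start_bp, snp_spacing_bp = 4000,
                       target_r2 = 0.6, maf_range = c(0.05, 0.5)) {
  stopifnot(n_snps >= 1, start_bp > 0, snp_spacing_bp > 0)
  if (target_r2 < 0 || target_r2 > 1) stop("target_r2 must be in [0, 1]")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be (low, high) within (0, 0.5]")
  }
  structure(list(n_snps = as.integer(n_snps), start_bp = as.integer(start_bp),
                 snp_spacing_bp = as.integer(snp_spacing_bp),
                 target_r2 = target_r2, maf_range = maf_range),
            class = "block_spec")
}

# Realize per-SNP allele frequencies and adjacent-pair haplotype frequencies
# for a block list; consumes RNG. Errors when the requested r2 is infeasible
# at the drawn frequencies (|D| bounded by the allele frequencies).
.realize_blocks <- function(blocks) {
  out <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    bl <- blocks[[b]]
    maf <- stats::runif(bl$n_snps, bl$maf_range[1], bl$maf_range[2])
    p11 <- rep(NA_real_, bl$n_snps)        # P(minor at j-1, minor at j)
    if (bl$n_snps > 1) {
      for (j in 2:bl$n_snps) {
        pa <- maf[j - 1]; pb <- maf[j]
        d_max <- min(pa * (1 - pb), pb * (1 - pa))
        d <- sqrt(bl$target_r2 * pa * (1 - pa) * pb * (1 - pb))
        if (d > d_max + 1e-12) {
          r2_max <- d_max^2 / (pa * (1 - pa) * pb * (1 - pb))
          stop(sprintf(
            "target_r2 = %.3f infeasible for adjacent MAFs (%.3f, %.3f); feasible r2 <= %.3f",
            bl$target_r2, pa, pb, r2_max))
        }
        p11[j] <- pa * pb + min(d, d_max)
      }
    }
    pos <- bl$start_bp + (seq_len(bl$n_snps) - 1L) * bl$snp_spacing_bp
    out[[b]] <- list(maf = maf, p11 = p11, pos = pos)
  }
  out
}

# Draw n haplotypes (rows) from realized block parameters; Markov within
# blocks, independent across blocks. Returns 0/1 matrix, 1 = minor allele.
.draw_haplotypes <- function(par, n) {
  cols <- lapply(par, function(bp) {
    m <- matrix(0L, n, length(bp$maf))
    m[, 1] <- stats::rbinom(n, 1L, bp$maf[1])
    if (length(bp$maf) > 1) {
      for (j in 2:length(bp$maf)) {
        pa <- bp$maf[j - 1]
        p_given1 <- bp$p11[j] / pa
        p_given0 <- (bp$maf[j] - bp$p11[j]) / (1 - pa)
        pr <- ifelse(m[, j - 1] == 1L, p_given1, p_given0)
        m[, j] <- stats::rbinom(n, 1L, pr)
      }
    }
    m
  })
  do.call(cbind, cols)
}

#' Simulate phased haplotypes with block LD structure
#'
#' @param blocks List of [block_spec()] objects.
#' @param n_haplotypes Number of haplotypes (rows) to draw.
#' @param seed Integer seed; the result is a deterministic function of
#'   `(blocks, n_haplotypes, seed)`.
#' @return List: `haplotypes` (0/1 matrix, 1 = minor allele), `variants`
#'   (data frame as in [genotype_matrix()]), `block` (block index per SNP),
#'   `maf` (design minor allele frequency per SNP).
#' @export
simulate_haplotypes <- function(blocks, n_haplotypes, seed) {
  .with_seed(seed, {
    par <- .realize_blocks(blocks)
    hap <- .draw_haplotypes(par, n_haplotypes)
    list(haplotypes = hap,
         variants = .block_variant_table(par),
         block = rep(seq_along(par), vapply(par, function(b) length(b$maf), 0L)),
         maf = unlist(lapply(par, `[[`, "maf")))
  })
}

# Widest relative band w such that any MAF pair in
# [a(1-w), min(0.5, a(1+w))] can reach target_r2 (|D| is bounded by the
# allele-frequency mismatch). Capped at +/-15%.
.feasible_band_width <- function(anchor, target_r2, cap = 0.15) {
  if (target_r2 <= 0) return(cap)
  ok <- function(w) {
    lo <- max(0.01, (1 - w) * anchor)
    hi <- min(0.5, (1 + w) * anchor)
    lo * (1 - hi) / ((1 - lo) * hi) >= target_r2
  }
  if (ok(cap)) return(cap)
  lo_w <- 0; hi_w <- cap
  for (i in 1:40) {
    mid <- (lo_w + hi_w) / 2
    if (ok(mid)) lo_w <- mid else hi_w <- mid
  }
  0.95 * lo_w
}

.block_variant_table <- function(par) {
  pos <- unlist(lapply(par, `[[`, "pos"))
  data.frame(snp_id = sprintf("snp%05d", seq_along(pos)),
             chrom = "6", pos_bp = as.integer(pos),
             allele_minor = "A", allele_major = "G",
             stringsAsFactors = FALSE)
}

#' Five-level HLA-DQ risk-stratum labels
#'
#' The five genotype categories the risk model distinguishes, in fixed order.
#' @return Character vector of length 5.
#' @export
dq_stratum_levels <- function() {
  c("DQ2.5 homozygote",
    "DQ2.5/DQ8 heterozygote",
    "DQ2.5/non-DQ8 heterozygote",
    "1 or 2 copies of DQ8",
    "non-DQ2.5/non-DQ8")
}

# Map effective copy counts to the five-level stratum label.
.stratum_from_counts <- function(n_dq25, n_dq8) {
  lv <- dq_stratum_levels()
  out <- rep(lv[5], length(n_dq25))
  out[n_dq25 == 0 & n_dq8 >= 1] <- lv[4]
  out[n_dq25 == 1 & n_dq8 == 0] <- lv[3]
  out[n_dq25 == 1 & n_dq8 >= 1] <- lv[2]
  out[n_dq25 == 2] <- lv[1]
  factor(out, levels = lv)
}

#' Default stratum log odds calibrated to the published five-level table
#'
#' Each stratum's disease odds are taken from the case/control counts of the
#' reference celiac cohort ([dq_stratum_counts()]) relative to the
#' non-DQ2.5/non-DQ8 stratum.
#' @return Named numeric vector, one log odds ratio per stratum (reference
#'   stratum = 0).
#' @export
default_stratum_log_odds <- function() {
  cnt <- dq_stratum_counts()
  odds <- cnt[, "cases"] / cnt[, "controls"]
  log(odds / odds["non-DQ2.5/non-DQ8"])
}

#' Default HLA haplotype-class frequencies
#'
#' Calibrated so that, under the default risk model, the expected stratum
#' composition of sampled cases and controls reproduces the reference
#' cohort's five-level table to within 0.006 per cell.
#' @return Named numeric vector over DQ2.5, DQ2.2, DQ7, DQ8, X; sums to 1.
#' @export
default_hla_freqs <- function() {
  f <- c("DQ2.5" = 0.3643, "DQ2.2" = 0.1737, "DQ7" = 0.2621,
         "DQ8" = 0.0852, "X" = 0.1147)
  f / sum(f)
}

#' Cohort simulation specification
#'
#' @param n_cases,n_controls Positive integer quotas.
#' @param blocks List of [block_spec()] objects describing the SNP panel.
#' @param stratum_log_odds Named numeric, log odds of disease added for each
#'   of the five strata ([dq_stratum_levels()]).
#' @param planted Data frame with columns `snp_index` (column index into the
#'   simulated panel) and `beta` (per-minor-allele log odds ratio); may have
#'   zero rows.
#' @param baseline_log_odds Baseline log odds of disease (applies to the
#'   reference stratum with genotype 0 at all planted SNPs).
#' @param hla_freqs Named numeric haplotype-class frequencies over
#'   DQ2.5, DQ2.2, DQ7, DQ8, X; must sum to 1 (tolerance 1e-6).
#' @param seed Integer seed; the simulated cohort is a deterministic function
#'   of the full specification.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases, n_controls, blocks,
                        stratum_log_odds = default_stratum_log_odds(),
                        planted = data.frame(snp_index = integer(),
                                             beta = numeric()),
                        baseline_log_odds = log(212 / 258),
                        hla_freqs = default_hla_freqs(),
                        seed = 1L) {
  stopifnot(n_cases >= 1, n_controls >= 1, length(blocks) >= 1)
  lv <- dq_stratum_levels()
  if (!all(lv %in% names(stratum_log_odds))) {
    stop("stratum_log_odds must name every stratum: ",
         paste(lv, collapse = "; "))
  }
  cls <- c("DQ2.5", "DQ2.2", "DQ7", "DQ8", "X")
  if (!all(cls %in% names(hla_freqs)) ||
      abs(sum(hla_freqs[cls]) - 1) > 1e-6 || any(hla_freqs[cls] < 0)) {
    stop("hla_freqs must be non-negative over ", paste(cls, collapse = ", "),
         " and sum to 1")
  }
  n_snps <- sum(vapply(blocks, function(b) b$n_snps, 0L))
  if (nrow(planted)) {
    stopifnot(all(c("snp_index", "beta") %in% names(planted)))
    if (any(planted$snp_index < 1 | planted$snp_index > n_snps)) {
      stop("planted snp_index outside the simulated panel (1..", n_snps, ")")
    }
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 blocks = blocks,
                 stratum_log_odds = stratum_log_odds[lv],
                 planted = planted,
                 baseline_log_odds = baseline_log_odds,
                 hla_freqs = hla_freqs[cls],
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default chr6 xMHC-scale simulation specification
#'
#' A cohort of 1668 cases and 517 controls typed at 1900 SNPs in 95
#' independent 20-SNP haplotype blocks spanning positions
#' 26,000,508-33,544,122, with the default HLA-DQ stratum risk model and
#' four planted independent risk SNPs in widely separated blocks.
#'
#' @param n_cases,n_controls Cohort quotas.
#' @param n_blocks,snps_per_block Panel layout.
#' @param target_r2 Within-block adjacent-SNP r-squared.
#' @param planted_or Per-allele odds ratios of the planted risk SNPs; their
#'   count sets the number of planted loci (0 for a null panel).
#' @param seed Integer seed (drives both the block MAF anchors realized
#'   here and the cohort draw in [simulate_cohort()]).
#' @details SNPs in strong LD necessarily have similar allele frequencies
#'   (`r2` between two biallelic loci is bounded by their frequency
#'   mismatch), so each block draws its SNP MAFs from a narrow band
#'   (+/- 15%) around a block-level anchor frequency; anchors are uniform
#'   on (0.15, 0.45) for background blocks and (0.32, 0.42) for planted
#'   blocks, keeping the planted ORs well powered.
#' @return A [cohort_spec()].
#' @export
xmhc_sim_spec <- function(n_cases = 1668, n_controls = 517,
                          n_blocks = 95, snps_per_block = 20,
                          target_r2 = 0.6,
                          planted_or = c(1.7, 1.9, 2.0, 2.2),
                          seed = 1L) {
  region <- c(26000508L, 33544122L)
  n_snps <- n_blocks * snps_per_block
  spacing <- floor((region[2] - region[1]) / (n_snps - 1))
  n_pl <- length(planted_or)
  pl_blocks <- if (n_pl) {
    round(seq(1, n_blocks, length.out = n_pl + 2))[2:(n_pl + 1)]
  } else integer()
  anchors <- .with_seed(seed, {
    a <- stats::runif(n_blocks, 0.15, 0.45)
    a[pl_blocks] <- stats::runif(length(pl_blocks), 0.32, 0.42)
    a
  })
  blocks <- lapply(seq_len(n_blocks), function(b) {
    w <- .feasible_band_width(anchors[b], target_r2)
    block_spec(snps_per_block,
               start_bp = region[1] + (b - 1L) * snps_per_block * spacing,
               snp_spacing_bp = spacing,
               target_r2 = target_r2,
               maf_range = c(max(0.02, (1 - w) * anchors[b]),
                             min(0.5, (1 + w) * anchors[b])))
  })
  planted <- data.frame(
    snp_index = as.integer((pl_blocks - 1) * snps_per_block +
                             ceiling(snps_per_block / 2)),
    beta = log(planted_or))
  cohort_spec(n_cases, n_controls, blocks, planted = planted, seed = seed)
}

#' Simulate a case-control cohort
#'
#' Individuals are drawn one batch at a time: two haplotypes from the block
#' model and an independent unordered HLA-DQ class pair; disease is Bernoulli
#' with logit equal to baseline + stratum effect + planted-SNP terms.
#' Individuals are accepted in draw order until the case and control quotas
#' are both exactly filled (rejection sampling).
#'
#' @param spec A [cohort_spec()].
#' @return List: `genotypes` ([genotype_matrix()]), `samples` (data frame
#'   `sample_id`, `status`), `hla` (data frame `sample_id`, `hap1`, `hap2`),
#'   `truth` (list with `strata` — data frame `sample_id`, `stratum` — and
#'   `planted` — data frame `snp_id`, `beta`, `odds_ratio`).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  .with_seed(spec$seed, .simulate_cohort_impl(spec))
}

.simulate_cohort_impl <- function(spec) {
  par <- .realize_blocks(spec$blocks)
  variants <- .block_variant_table(par)
  cls <- names(spec$hla_freqs)
  b_str <- spec$stratum_log_odds

  need_ca <- spec$n_cases
  need_co <- spec$n_controls
  acc_calls <- vector("list", 0L)
  acc_h1 <- acc_h2 <- acc_stratum <- character(0)
  acc_status <- character(0)

  for (round in 1:1000) {
    if (need_ca <= 0 && need_co <= 0) break
    nb <- max(200L, ceiling(1.6 * (need_ca + need_co)))
    h1 <- sample(cls, nb, replace = TRUE, prob = spec$hla_freqs)
    h2 <- sample(cls, nb, replace = TRUE, prob = spec$hla_freqs)
    prof <- dq_profile(h1, h2)
    stratum <- .stratum_from_counts(prof$n_dq25, prof$n_dq8)
    g <- .draw_haplotypes(par, nb) + .draw_haplotypes(par, nb)
    eta <- spec$baseline_log_odds + b_str[as.integer(stratum)]
    if (nrow(spec$planted)) {
      eta <- eta + g[, spec$planted$snp_index, drop = FALSE] %*% spec$planted$beta
    }
    eta <- as.numeric(eta)
    if (any(!is.finite(eta))) {
      stop("parameter error: non-finite linear predictor in disease model")
    }
    d <- stats::rbinom(nb, 1L, stats::plogis(eta))
    take_ca <- which(d == 1L)[seq_len(min(need_ca, sum(d == 1L)))]
    take_co <- which(d == 0L)[seq_len(min(need_co, sum(d == 0L)))]
    take <- sort(c(take_ca, take_co))
    if (length(take)) {
      acc_calls[[length(acc_calls) + 1L]] <- g[take, , drop = FALSE]
      acc_h1 <- c(acc_h1, h1[take]); acc_h2 <- c(acc_h2, h2[take])
      acc_stratum <- c(acc_stratum, as.character(stratum[take]))
      acc_status <- c(acc_status, ifelse(d[take] == 1L, "case", "control"))
      need_ca <- need_ca - length(take_ca)
      need_co <- need_co - length(take_co)
    }
  }
  if (need_ca > 0 || need_co > 0) {
    stop("rejection sampling failed to fill quotas; disease model too extreme")
  }

  calls <- do.call(rbind, acc_calls)
  ids <- sprintf("S%05d", seq_along(acc_status))
  swap <- acc_h1 > acc_h2
  hap1 <- ifelse(swap, acc_h2, acc_h1)
  hap2 <- ifelse(swap, acc_h1, acc_h2)
  planted_truth <- data.frame(
    snp_id = variants$snp_id[spec$planted$snp_index],
    beta = spec$planted$beta,
    odds_ratio = exp(spec$planted$beta),
    stringsAsFactors = FALSE)

  list(genotypes = genotype_matrix(calls, variants, ids),
       samples = data.frame(sample_id = ids, status = acc_status,
                            stringsAsFactors = FALSE),
       hla = data.frame(sample_id = ids, hap1 = hap1, hap2 = hap2,
                        stringsAsFactors = FALSE),
       truth = list(strata = data.frame(sample_id = ids,
                                        stratum = acc_stratum,
                                        stringsAsFactors = FALSE),
                    planted = planted_truth))
}

# Evaluate expr with a locally seeded RNG, restoring global state after.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
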