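# Independent oracles used to check the package's own implementations.
# Each is deliberately coded along a different route than the code it checks.

# Pearson chi-square p-value via the stats implementation.
oracle_chisq_p <- function(tab) {
  suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
}

# Exact HWE p by direct full enumeration of the conditional distribution
# P(het = h | n, minor allele count) via the closed-form ratio of binomial
# coefficients (no recurrence, no normalization trick).
oracle_hwe <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  n_minor <- 2 * min(n_hom1, n_hom2) + n_het
  if (n_minor == 0) return(1)
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  lp <- sapply(hets, function(h) {
    a <- (n_minor - h) / 2          # rare homozygotes
    b <- n - h - a                  # common homozygotes
    lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1) +
      h * log(2) - (lchoose(2 * n, n_minor))
  })
  pr <- exp(lp)
  sum(pr[pr <= pr[hets == n_het] * (1 + 1e-10)])
}

# Closed-form 2x2 logistic coefficients: exposed vs unexposed binary
# predictor with cells a,b = cases/controls exposed, c,d unexposed.
oracle_2x2 <- function(a, b, c, d) {
  list(beta = log((a * d) / (b * c)),
       se = sqrt(1 / a + 1 / b + 1 / c + 1 / d))
}

# Exhaustive best binary split for a factor predictor: enumerate every
# two-set partition of the observed levels with combn.
oracle_best_split <- function(x, y, min_node = 1) {
  lev <- sort(unique(as.character(x)))
  k <- length(lev)
  best <- NULL
  for (m in 1:floor(k / 2)) {
    for (cols in seq_len(ncol(utils::combn(lev, m)))) {
      left <- utils::combn(lev, m)[, cols]
      if (m == k / 2 && !(lev[1] %in% left)) next  # skip mirror duplicates
      inl <- as.character(x) %in% left
      if (sum(inl) < min_node || sum(!inl) < min_node) next
      tab <- table(factor(inl, c(FALSE, TRUE)), y)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      stat <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
      if (is.null(best) || stat > best$statistic) {
        best <- list(left = sort(left), statistic = unname(stat))
      }
    }
  }
  best
}

# Independently coded greedy clumping: repeatedly take the unassigned SNP
# with the smallest p-value (ties: position, then id) and sweep candidates.
oracle_clump <- function(snp_id, pos, p, r2mat, p1, p2, max_kb, r2_min,
                        barred = character()) {
  assigned <- rep(FALSE, length(p))
  out <- list()
  repeat {
    avail <- which(!assigned & !(snp_id %in% barred))
    if (!length(avail)) break
    o <- avail[order(p[avail], pos[avail], snp_id[avail])][1]
    if (p[o] >= p1) break
    assigned[o] <- TRUE
    members <- character()
    cand <- which(!assigned & p < p2 & abs(pos - pos[o]) <= max_kb * 1000)
    cand <- cand[order(p[cand], pos[cand], snp_id[cand])]
    for (j in cand) {
      if (!is.na(r2mat[o, j]) && r2mat[o, j] >= r2_min) {
        assigned[j] <- TRUE
        members <- c(members, snp_id[j])
      }
    }
    out[[length(out) + 1]] <- list(index = snp_id[o], secondary = members)
  }
  out
}

# Analytic power of the per-SNP association test for a planted additive
# effect under the cohort generator's risk model: exact case/control
# genotype distributions give the two-sample score z, whose square is the
# noncentrality of the 1-df Wald chi-square.
oracle_trend_power <- function(or, maf, n_case, n_ctrl,
                               alpha = 5e-7,
                               stratum_log_odds = default_stratum_log_odds(),
                               hla_freqs = default_hla_freqs(),
                               baseline = log(212 / 258)) {
  g <- 0:2
  pg <- stats::dbinom(g, 2, maf)
  # stratum distribution implied by random haplotype-class pairs
  f <- hla_freqs
  pr_pair <- outer(f, f)
  pairs <- expand.grid(h1 = names(f), h2 = names(f), stringsAsFactors = FALSE)
  prof <- dq_profile(pairs$h1, pairs$h2)
  lab <- xmhcscan:::.stratum_from_counts(prof$n_dq25, prof$n_dq8)
  ps <- tapply(as.vector(pr_pair), lab, sum)
  bs <- stratum_log_odds[names(ps)]
  p_case_g <- sapply(g, function(gg) {
    sum(ps * stats::plogis(baseline + bs + log(or) * gg))
  })
  p_case <- sum(pg * p_case_g)
  pg_case <- pg * p_case_g / p_case
  pg_ctrl <- pg * (1 - p_case_g) / (1 - p_case)
  m1 <- sum(g * pg_case); m0 <- sum(g * pg_ctrl)
  v1 <- sum(g^2 * pg_case) - m1^2; v0 <- sum(g^2 * pg_ctrl) - m0^2
  z2 <- (m1 - m0)^2 / (v1 / n_case + v0 / n_ctrl)
  stats::pchisq(stats::qchisq(1 - alpha, 1), 1, ncp = z2, lower.tail = FALSE)
}

# Two-locus haplotype-frequency ML by direct 1-D likelihood optimization
# over h11 (independent of the EM route).
oracle_r2_ml <- function(g1, g2) {
  cc <- !is.na(g1) & !is.na(g2)
  g1 <- g1[cc]; g2 <- g2[cc]
  tab <- table(factor(g1, 0:2), factor(g2, 0:2))
  pA <- mean(g1) / 2; pB <- mean(g2) / 2
  ll <- function(h11) {
    h <- c(`00` = 1 - pA - pB + h11, `01` = pB - h11,
           `10` = pA - h11, `11` = h11)
    if (min(h) <= 0) return(-Inf)
    P <- matrix(0, 3, 3)
    for (i in 0:2) for (j in 0:2) {
      s <- 0
      for (a1 in 0:1) for (b1 in 0:1) {
        a2 <- i - a1; b2 <- j - b1
        if (a2 < 0 || a2 > 1 || b2 < 0 || b2 > 1) next
        s <- s + h[paste0(a1, b1)] * h[paste0(a2, b2)]
      }
      P[i + 1, j + 1] <- s
    }
    sum(tab * log(P + 1e-300))
  }
  o <- stats::optimize(ll, c(max(0, pA + pB - 1) + 1e-9, min(pA, pB) - 1e-9),
                       maximum = TRUE, tol = 1e-12)
  (o$maximum - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# Small deterministic genotype matrix for IO/QC fixtures.
make_gm <- function(calls, pos = NULL, chrom = "6") {
  n_var <- ncol(calls)
  if (is.null(pos)) pos <- seq(1000, by = 1000, length.out = n_var)
  genotype_matrix(
    calls,
    data.frame(snp_id = sprintf("rs%03d", seq_len(n_var)), chrom = chrom,
               pos_bp = pos, allele_minor = "A", allele_major = "G"),
    sprintf("S%02d", seq_len(nrow(calls))))
}

make_samples <- function(status) {
  data.frame(sample_id = sprintf("S%02d", seq_along(status)), status = status,
             stringsAsFactors = FALSE)
}

# Fraction of samples whose fitted stratum maps (by majority vote) to their
# true stratum label.
stratum_agreement <- function(fitted, truth) {
  maj <- tapply(as.character(truth), fitted,
                function(z) names(which.max(table(z))))
  mean(maj[as.character(fitted)] == as.character(truth))
}
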