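# LD estimation from unphased genotypes and greedy LD-based grouping of
# association signals into independent loci ("clumps"), plus the parameter
# sensitivity sweep.

#' Two-locus r-squared by EM over unphased genotypes
#'
#' Estimates the four two-locus haplotype frequencies by
#' expectation-maximization over the double-heterozygote phase ambiguity and
#' returns `r2 = D^2 / (pA qA pB qB)`. Complete cases only.
#'
#' @param g1,g2 Aligned additive-coded genotype vectors (0/1/2/NA).
#' @param max_iter,tol EM iteration control.
#' @return r-squared in `[0, 1]`, or `NA` (with a `reason` attribute) when
#'   either SNP is monomorphic in the complete-case subset.
#' @export
r2_em <- function(g1, g2, max_iter = 200L, tol = 1e-12) {
  cc <- !is.na(g1) & !is.na(g2)
  g1 <- g1[cc]; g2 <- g2[cc]
  n <- length(g1)
  if (n == 0 || length(unique(g1)) < 2 || length(unique(g2)) < 2) {
    return(structure(NA_real_, reason = "monomorphic"))
  }
  pA <- mean(g1) / 2                       # minor-allele freq, locus 1
  pB <- mean(g2) / 2
  # genotype cell counts; cell (1,1) is the phase-ambiguous double het
  tab <- table(factor(g1, 0:2), factor(g2, 0:2))
  # haplotype freqs h[ab], a/b = 1 for the minor allele
  h <- c(h11 = pA * pB, h10 = pA * (1 - pB), h01 = (1 - pA) * pB,
         h00 = (1 - pA) * (1 - pB))
  ndh <- tab[2, 2]                         # double heterozygotes
  for (it in seq_len(max_iter)) {
    # expected count of each haplotype among the 2n resolved chromosomes
    w <- h["h11"] * h["h00"] /
      (h["h11"] * h["h00"] + h["h10"] * h["h01"] + 1e-300)
    c11 <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3] + ndh * w
    c10 <- 2 * tab[3, 1] + tab[3, 2] + tab[2, 1] + ndh * (1 - w)
    c01 <- 2 * tab[1, 3] + tab[2, 3] + tab[1, 2] + ndh * (1 - w)
    c00 <- 2 * tab[1, 1] + tab[2, 1] + tab[1, 2] + ndh * w
    h_new <- c(c11, c10, c01, c00) / (2 * n)
    names(h_new) <- names(h)
    if (max(abs(h_new - h)) < tol) {
      h <- h_new
      break
    }
    h <- h_new
  }
  d <- h["h11"] - pA * pB
  r2 <- d^2 / (pA * (1 - pA) * pB * (1 - pB))
  unname(min(max(r2, 0), 1))
}

#' Clumping parameters
#'
#' @param p1 Index-SNP significance threshold.
#' @param p2 Secondary-SNP significance threshold (`p1 <= p2`).
#' @param max_kb Maximum distance (kb) of a secondary SNP from the index.
#' @param r2_min Minimum r-squared of a secondary SNP with the index.
#' @return An object of class `clump_params`.
#' @export
clump_params <- function(p1 = 5e-7, p2 = 0.01, max_kb = 250, r2_min = 0.1) {
  stopifnot(p1 > 0, p2 > 0, p1 <= p2, max_kb > 0, r2_min >= 0, r2_min <= 1)
  structure(list(p1 = p1, p2 = p2, max_kb = max_kb, r2_min = r2_min),
            class = "clump_params")
}

#' Greedy LD-based SNP grouping
#'
#' Iterates SNPs by ascending p-value (ties broken by ascending position,
#' then snp id). Each not-yet-assigned SNP with `p < p1` becomes the index
#' of a new clump; every still-unassigned SNP with `p < p2`, on the same
#' chromosome within `max_kb` of the index, and with `r2 >= r2_min` to the
#' index joins that clump. Assignment is exclusive: each SNP belongs to at
#' most one clump.
#'
#' @param results [assoc_scan()]-style data frame (needs `snp_id`, `wald_p`;
#'   positions are taken from `gm`).
#' @param gm The QC-passed [genotype_matrix()] LD is computed in (full
#'   cohort, cases and controls pooled).
#' @param params A [clump_params()].
#' @param barred_index Optional snp ids never allowed to become an index
#'   (e.g. a known covariate SNP); they remain eligible as secondaries.
#' @return List of clumps (class `clump_set`); each clump is a list with
#'   `index_snp`, `index_p`, `secondary` (data frame `snp_id`,
#'   `r2_with_index`, `p_value`), `span_bp`.
#' @export
clump <- function(results, gm, params = clump_params(), barred_index = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(params, "clump_params"))
  res <- results[!is.na(results$wald_p), , drop = FALSE]
  vi <- match(res$snp_id, gm$variants$snp_id)
  if (any(is.na(vi) & res$wald_p < params$p1)) {
    stop("missing genotypes/position for significant SNP: ",
         paste(res$snp_id[is.na(vi) & res$wald_p < params$p1], collapse = ", "))
  }
  keep <- !is.na(vi)
  res <- res[keep, , drop = FALSE]
  vi <- vi[keep]
  pos <- gm$variants$pos_bp[vi]
  chrom <- gm$variants$chrom[vi]

  ord <- order(res$wald_p, pos, res$snp_id)
  assigned <- rep(FALSE, nrow(res))
  clumps <- list()
  for (i in ord) {
    if (res$wald_p[i] >= params$p1) break   # sorted: nothing further qualifies
    if (assigned[i]) next
    if (res$snp_id[i] %in% barred_index) next
    assigned[i] <- TRUE
    cand <- which(!assigned &
                    res$wald_p < params$p2 &
                    chrom == chrom[i] &
                    abs(pos - pos[i]) <= params$max_kb * 1000)
    sec <- list()
    g_index <- gm$calls[, vi[i]]
    for (j in cand[order(res$wald_p[cand], pos[cand], res$snp_id[cand])]) {
      r2 <- r2_em(g_index, gm$calls[, vi[j]])
      if (!is.na(r2) && r2 >= params$r2_min) {
        assigned[j] <- TRUE
        sec[[length(sec) + 1L]] <- data.frame(
          snp_id = res$snp_id[j], r2_with_index = r2,
          p_value = res$wald_p[j], stringsAsFactors = FALSE)
      }
    }
    secondary <- if (length(sec)) do.call(rbind, sec) else
      data.frame(snp_id = character(), r2_with_index = numeric(),
                 p_value = numeric(), stringsAsFactors = FALSE)
    member_pos <- c(pos[i], pos[match(secondary$snp_id, res$snp_id)])
    clumps[[length(clumps) + 1L]] <- list(
      index_snp = res$snp_id[i], index_p = res$wald_p[i],
      index_pos = pos[i], secondary = secondary,
      span_bp = c(min(member_pos), max(member_pos)))
  }
  structure(clumps, class = "clump_set")
}

#' @export
print.clump_set <- function(x, ...) {
  cat(sprintf("%d clump(s)\n", length(x)))
  for (cl in x) {
    cat(sprintf("  %s (p = %.3g): %d secondary, span %d-%d\n",
                cl$index_snp, cl$index_p, nrow(cl$secondary),
                cl$span_bp[1], cl$span_bp[2]))
  }
  invisible(x)
}

#' @export
as.data.frame.clump_set <- function(x, ...) {
  if (!length(x)) {
    return(data.frame(index_snp = character(), index_p = numeric(),
                      n_secondary = integer(), secondary = character(),
                      span_start = integer(), span_end = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(x, function(cl) {
    data.frame(index_snp = cl$index_snp, index_p = cl$index_p,
               n_secondary = nrow(cl$secondary),
               secondary = paste(sprintf("%s:%.4g:%.4g", cl$secondary$snp_id,
                                         cl$secondary$r2_with_index,
                                         cl$secondary$p_value),
                                 collapse = ";"),
               span_start = cl$span_bp[1], span_end = cl$span_bp[2],
               stringsAsFactors = FALSE)
  }))
}

#' Clumping-parameter sensitivity sweep
#'
#' Re-runs [clump()] along a grid of `r2_min` values (other parameters at
#' their defaults) and a grid of `p1` values, recording the number of index
#' SNPs identified at each grid point.
#'
#' @param results,gm,barred_index As in [clump()].
#' @param r2_grid Grid of `r2_min` values; defaults to 0.05..0.95 by 0.05
#'   united with 0.01..0.15 by 0.01.
#' @param p1_grid Grid of index thresholds; defaults to `10^-(4..12)`.
#' @param p2,max_kb Fixed secondary threshold and window.
#' @param r2_default,p1_default Values held fixed while the other parameter
#'   is swept.
#' @return Long-form data frame `parameter`, `value`, `n_index_snps`.
#' @export
sensitivity_sweep <- function(results, gm,
                              r2_grid = sort(unique(c(seq(0.05, 0.95, 0.05),
                                                      seq(0.01, 0.15, 0.01)))),
                              p1_grid = 10^-(4:12),
                              p2 = 0.01, max_kb = 250,
                              r2_default = 0.1, p1_default = 5e-7,
                              barred_index = NULL) {
  stopifnot(length(r2_grid) >= 1, length(p1_grid) >= 1)
  n_index <- function(p1, r2) {
    length(clump(results, gm,
                 clump_params(p1 = p1, p2 = max(p1, p2), max_kb = max_kb,
                              r2_min = r2),
                 barred_index = barred_index))
  }
  rbind(
    data.frame(parameter = "r2_min", value = r2_grid,
               n_index_snps = vapply(r2_grid, function(r) {
                 n_index(p1_default, r)
               }, 0L)),
    data.frame(parameter = "p1", value = p1_grid,
               n_index_snps = vapply(p1_grid, function(p) {
                 n_index(p, r2_default)
               }, 0L)))
}
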