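# SNP and sample quality control: call-rate, minor-allele-frequency and
# exact Hardy-Weinberg filters, applied in a fixed order (samples first).

#' QC parameters
#'
#' Defaults follow standard GWAS practice for this kind of panel: samples and
#' SNPs below 98% completeness, SNPs with MAF below 0.03 or an exact
#' Hardy-Weinberg p-value below 1e-5 are excluded.
#'
#' @param min_call_rate Minimum per-sample and per-variant completeness.
#' @param min_maf Minimum minor allele frequency (computed on non-missing
#'   calls, after call-rate exclusions).
#' @param hwe_p_floor Exact Hardy-Weinberg test p-value below which a
#'   variant is excluded.
#' @param hwe_population Population the HWE test is computed in:
#'   `"controls"` (default; disease association can distort HWE in cases)
#'   or `"all"`.
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(min_call_rate = 0.98, min_maf = 0.03,
                      hwe_p_floor = 1e-5,
                      hwe_population = c("controls", "all")) {
  hwe_population <- match.arg(hwe_population)
  for (v in c(min_call_rate, min_maf, hwe_p_floor)) {
    if (!is.numeric(v) || v <= 0 || v >= 1) {
      stop("QC thresholds must lie in (0, 1)")
    }
  }
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 hwe_p_floor = hwe_p_floor, hwe_population = hwe_population),
            class = "qc_params")
}

#' Per-sample and per-variant call rates
#'
#' @param gm A [genotype_matrix()].
#' @return List with named numeric vectors `sample` and `variant`, each the
#'   fraction of non-missing calls.
#' @export
call_rates <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"), length(gm$calls) > 0)
  ok <- !is.na(gm$calls)
  list(sample = rowMeans(ok), variant = colMeans(ok))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test given the allele counts: the p-value is the sum of
#' the probabilities of all heterozygote counts that are no more probable
#' than the observed one. Monomorphic variants return p = 1.
#'
#' @param n_hom1,n_het,n_hom2 Genotype counts (the two homozygote classes
#'   and the heterozygote class); non-negative, total > 0.
#' @return The exact p-value.
#' @export
hwe_exact_p <- function(n_hom1, n_het, n_hom2) {
  stopifnot(n_hom1 >= 0, n_het >= 0, n_hom2 >= 0)
  n <- n_hom1 + n_het + n_hom2
  if (n == 0) stop("total genotype count must be > 0")
  n_rare <- 2 * min(n_hom1, n_hom2) + n_het
  if (n_rare == 0) return(1)
  # unnormalized probabilities over all het counts with the parity of n_rare
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  lp <- vapply(hets, function(h) {
    rare_hom <- (n_rare - h) / 2
    com_hom <- n - h - rare_hom
    h * log(2) + lgamma(n + 1) -
      (lgamma(h + 1) + lgamma(rare_hom + 1) + lgamma(com_hom + 1))
  }, 0)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- which(hets == n_het)
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-10)]))
}

#' Per-variant exact HWE p-values
#'
#' @param gm A [genotype_matrix()].
#' @param sample_ids Optional subset of samples to compute the test in.
#' @return Named numeric vector of p-values (NA for fully missing variants).
#' @export
hwe_pvalues <- function(gm, sample_ids = NULL) {
  calls <- gm$calls
  if (!is.null(sample_ids)) {
    calls <- calls[gm$sample_ids %in% sample_ids, , drop = FALSE]
  }
  apply(calls, 2, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    hwe_exact_p(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  })
}

#' Apply the QC filters
#'
#' Filter order is fixed: (1) samples below the call-rate threshold are
#' dropped; (2) variant call rate, (3) MAF and (4) the exact HWE test are
#' then computed on the retained samples. The HWE test uses the population
#' named in `params$hwe_population`. Every exclusion is recorded with its
#' reason and the offending value.
#'
#' @param gm A [genotype_matrix()].
#' @param samples Data frame with `sample_id` and `status`.
#' @param params A [qc_params()].
#' @return List: `genotypes` (filtered [genotype_matrix()]), `samples`
#'   (filtered data frame), `report` (data frame `id`, `type`, `reason`,
#'   `value`).
#' @export
apply_qc <- function(gm, samples, params = qc_params()) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(params, "qc_params"))
  if (!identical(as.character(samples$sample_id), gm$sample_ids)) {
    stop("samples do not match genotype matrix rows")
  }
  rep_rows <- list()
  note <- function(id, type, reason, value) {
    rep_rows[[length(rep_rows) + 1L]] <<- data.frame(
      id = id, type = type, reason = reason, value = value,
      stringsAsFactors = FALSE)
  }

  cr <- call_rates(gm)
  bad_s <- cr$sample < params$min_call_rate
  for (i in which(bad_s)) {
    note(gm$sample_ids[i], "sample", "call_rate", cr$sample[i])
  }
  if (any(bad_s)) {
    gm <- subset_genotypes(gm, samples = !bad_s)
    samples <- samples[!bad_s, , drop = FALSE]
  }

  cr <- call_rates(gm)
  drop_v <- cr$variant < params$min_call_rate
  for (j in which(drop_v)) {
    note(gm$variants$snp_id[j], "variant", "call_rate", cr$variant[j])
  }

  maf <- minor_allele_freq(gm)
  low_maf <- !drop_v & (is.na(maf) | maf < params$min_maf)
  for (j in which(low_maf)) {
    note(gm$variants$snp_id[j], "variant", "maf", maf[j])
  }
  drop_v <- drop_v | low_maf

  hwe_ids <- if (params$hwe_population == "controls") {
    samples$sample_id[samples$status == "control"]
  } else samples$sample_id
  hwe <- hwe_pvalues(gm, hwe_ids)
  bad_hwe <- !drop_v & !is.na(hwe) & hwe < params$hwe_p_floor
  for (j in which(bad_hwe)) {
    note(gm$variants$snp_id[j], "variant", "hwe", hwe[j])
  }
  drop_v <- drop_v | bad_hwe

  if (all(drop_v)) stop("all variants excluded by QC: empty analysis set")
  if (any(drop_v)) gm <- subset_genotypes(gm, variants = !drop_v)

  report <- if (length(rep_rows)) {
    do.call(rbind, rep_rows)
  } else {
    data.frame(id = character(), type = character(), reason = character(),
               value = numeric(), stringsAsFactors = FALSE)
  }
  list(genotypes = gm, samples = samples, report = report)
}
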