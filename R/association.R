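# Logistic association models: a maximum-likelihood core (iteratively
# reweighted least squares with step-halving), the per-SNP simple and
# stratum-adjusted scans, and joint multi-SNP fits. Per-allele effects use
# additive 0/1/2 coding of the minor allele; missing genotypes are handled
# complete-case per model.

#' Maximum-likelihood logistic regression by IRLS
#'
#' Newton/IRLS with step-halving so the deviance is non-increasing across
#' iterations. Convergence is declared when the maximum absolute score
#' (gradient of the log-likelihood) falls below `tol`. The covariance matrix
#' is the inverse observed information at the optimum. Complete or
#' quasi-complete separation (coefficients drifting without the score
#' vanishing) is flagged rather than silently reported.
#'
#' @param design Numeric model matrix (include the intercept column
#'   yourself); must be of full column rank.
#' @param y Binary outcome (0/1, logical, or 2-level factor).
#' @param max_iter Maximum IRLS iterations.
#' @param tol Score tolerance for convergence.
#' @return List: `coefficients`, `covariance`, `diagnostics` (list with
#'   `converged`, `n_iter`, `max_abs_score`, `separation_flag`, `deviance`
#'   trace).
#' @export
fit_logistic <- function(design, y, max_iter = 50L, tol = 1e-8) {
  X <- as.matrix(design)
  y <- .as_binary(y)
  if (nrow(X) != length(y)) stop("design and outcome lengths differ")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop("rank-deficient design; collinear columns: ",
         paste(colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]], collapse = ", "))
  }

  beta <- rep(0, ncol(X))
  dev <- function(b) {
    eta <- drop(X %*% b)
    -2 * sum(y * eta - log1p(exp(eta)))
  }
  dev_trace <- dev(beta)
  converged <- FALSE
  max_score <- Inf
  it <- 0L
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(X, y - mu))
    max_score <- max(abs(score))
    if (max_score < tol) {
      converged <- TRUE
      break
    }
    w <- pmax(mu * (1 - mu), 1e-10)
    info <- crossprod(X * w, X)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    # step-halve until the deviance does not increase
    lambda <- 1
    d_old <- dev_trace[length(dev_trace)]
    repeat {
      cand <- beta + lambda * step
      d_new <- dev(cand)
      if (d_new <= d_old + 1e-12 || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    beta <- cand
    dev_trace <- c(dev_trace, d_new)
  }

  mu <- stats::plogis(drop(X %*% beta))
  # |beta| beyond any plausible per-allele effect, with either a
  # non-vanishing score or fitted probabilities pinned at 0/1
  separation <- max(abs(beta)) > 10 &&
    (!converged || min(pmin(mu, 1 - mu)) < 1e-9)
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- crossprod(X * w, X)
  covariance <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  if (separation) covariance[] <- NA_real_
  dimnames(covariance) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  list(coefficients = beta, covariance = covariance,
       diagnostics = list(converged = converged, n_iter = it,
                          max_abs_score = max_score,
                          separation_flag = separation,
                          deviance = dev_trace))
}

# Wald summary for one coefficient of a fitted model.
.wald_row <- function(fit, term, snp_id, n_used, model_tag) {
  beta <- fit$coefficients[[term]]
  se <- sqrt(fit$covariance[term, term])
  z2 <- (beta / se)^2
  data.frame(snp_id = snp_id,
             beta = beta, se = se,
             odds_ratio = exp(beta),
             ci95_low = exp(beta - 1.96 * se),
             ci95_high = exp(beta + 1.96 * se),
             wald_p = stats::pchisq(z2, 1, lower.tail = FALSE),
             n_used = n_used, model_tag = model_tag,
             reason = NA_character_, stringsAsFactors = FALSE)
}

.na_row <- function(snp_id, n_used, model_tag, reason) {
  data.frame(snp_id = snp_id, beta = NA_real_, se = NA_real_,
             odds_ratio = NA_real_, ci95_low = NA_real_, ci95_high = NA_real_,
             wald_p = NA_real_, n_used = n_used, model_tag = model_tag,
             reason = reason, stringsAsFactors = FALSE)
}

# Stratum indicator columns with the most frequent stratum as reference.
.stratum_design <- function(strata) {
  f <- factor(strata)
  ref <- names(which.max(table(f)))
  f <- stats::relevel(f, ref = ref)
  if (nlevels(f) < 2) return(NULL)
  m <- stats::model.matrix(~f)[, -1, drop = FALSE]
  colnames(m) <- paste0("stratum_", levels(f)[-1])
  m
}

#' Per-SNP association scan
#'
#' Fits one logistic model per SNP with additive minor-allele coding,
#' optionally adjusted for the risk-stratum covariate (entered as indicator
#' variables with the most frequent stratum as reference) and for a fixed
#' covariate SNP. Missing genotypes are handled complete-case per SNP. The
#' covariate SNP is never tested against itself (its row is omitted). SNPs
#' monomorphic in the analysis subset yield NA estimates with a reason code.
#'
#' @param gm QC-passed [genotype_matrix()].
#' @param samples Data frame with `sample_id`, `status` aligned to `gm`.
#' @param strata Optional vector of stratum ids/labels (one per sample);
#'   required for the adjusted model.
#' @param covariate_snp Optional snp id always included as an additive
#'   covariate.
#' @param model_tag Label stored with each result row; defaults to
#'   `"simple"` or `"adjusted"` depending on `strata`.
#' @return Data frame of per-SNP results (one row per tested SNP):
#'   `snp_id`, `chrom`, `pos_bp`, `beta`, `se`, `odds_ratio`, `ci95_low`,
#'   `ci95_high`, `wald_p`, `n_used`, `model_tag`, `reason`.
#' @export
assoc_scan <- function(gm, samples, strata = NULL, covariate_snp = NULL,
                       model_tag = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!identical(as.character(samples$sample_id), gm$sample_ids)) {
    stop("samples do not match genotype matrix rows")
  }
  y <- as.integer(samples$status == "case")
  if (is.null(model_tag)) {
    model_tag <- if (is.null(strata)) "simple" else "adjusted"
  }
  base <- matrix(1, length(y), 1, dimnames = list(NULL, "intercept"))
  if (!is.null(strata)) {
    if (length(strata) != length(y)) stop("strata length mismatch")
    sd <- .stratum_design(strata)
    if (!is.null(sd)) base <- cbind(base, sd)
  }
  g_cov <- NULL
  if (!is.null(covariate_snp)) {
    jc <- match(covariate_snp, gm$variants$snp_id)
    if (is.na(jc)) stop("covariate snp not found: ", covariate_snp)
    g_cov <- gm$calls[, jc]
  }

  snp_ids <- gm$variants$snp_id
  test_idx <- seq_along(snp_ids)
  if (!is.null(covariate_snp)) {
    test_idx <- test_idx[snp_ids[test_idx] != covariate_snp]
  }
  rows <- vector("list", length(test_idx))
  for (k in seq_along(test_idx)) {
    j <- test_idx[k]
    g <- gm$calls[, j]
    cc <- !is.na(g)
    if (!is.null(g_cov)) cc <- cc & !is.na(g_cov)
    n_used <- sum(cc)
    gj <- g[cc]
    if (n_used == 0 || length(unique(gj)) < 2) {
      rows[[k]] <- .na_row(snp_ids[j], n_used, model_tag, "monomorphic")
      next
    }
    X <- cbind(base[cc, , drop = FALSE], snp = gj)
    if (!is.null(g_cov)) X <- cbind(X, covariate_snp = g_cov[cc])
    # drop adjustment columns that became constant in the complete-case set
    keep <- apply(X, 2, function(col) length(unique(col)) > 1)
    keep["intercept"] <- TRUE
    X <- X[, keep, drop = FALSE]
    fit <- tryCatch(fit_logistic(X, y[cc]), error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[k]] <- .na_row(snp_ids[j], n_used, model_tag, conditionMessage(fit))
    } else if (fit$diagnostics$separation_flag) {
      rows[[k]] <- .na_row(snp_ids[j], n_used, model_tag, "separation")
    } else {
      rows[[k]] <- .wald_row(fit, "snp", snp_ids[j], n_used, model_tag)
    }
  }
  res <- do.call(rbind, rows)
  vi <- match(res$snp_id, gm$variants$snp_id)
  cbind(res[, "snp_id", drop = FALSE],
        chrom = gm$variants$chrom[vi], pos_bp = gm$variants$pos_bp[vi],
        res[, setdiff(names(res), "snp_id")])
}

#' Joint multi-SNP logistic model
#'
#' Fits all listed SNPs simultaneously (complete cases across the list) and
#' reports a per-SNP Wald test from the single joint fit, with or without
#' the risk-stratum covariate.
#'
#' @param gm A [genotype_matrix()].
#' @param samples Data frame with `sample_id`, `status`.
#' @param snp_list Character vector of snp ids to model jointly.
#' @param strata Optional stratum vector (required when
#'   `include_strata = TRUE`).
#' @param include_strata Add the stratum indicators to the model.
#' @return Data frame of per-SNP results as in [assoc_scan()], tagged
#'   `"joint"` or `"joint_strata"`.
#' @export
joint_fit <- function(gm, samples, snp_list, strata = NULL,
                      include_strata = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"), length(snp_list) >= 1)
  ji <- match(snp_list, gm$variants$snp_id)
  if (anyNA(ji)) stop("snp not found: ",
                      paste(snp_list[is.na(ji)], collapse = ", "))
  if (include_strata && is.null(strata)) stop("strata required")
  y <- as.integer(samples$status == "case")
  G <- gm$calls[, ji, drop = FALSE]
  cc <- stats::complete.cases(G)
  X <- cbind(intercept = 1, G[cc, , drop = FALSE])
  colnames(X) <- c("intercept", snp_list)
  if (include_strata) {
    sd <- .stratum_design(strata[cc])
    if (!is.null(sd)) X <- cbind(X, sd)
  }
  tag <- if (include_strata) "joint_strata" else "joint"
  fit <- fit_logistic(X, y[cc])
  rows <- lapply(snp_list, function(s) .wald_row(fit, s, s, sum(cc), tag))
  res <- do.call(rbind, rows)
  vi <- match(res$snp_id, gm$variants$snp_id)
  cbind(res[, "snp_id", drop = FALSE],
        chrom = gm$variants$chrom[vi], pos_bp = gm$variants$pos_bp[vi],
        res[, setdiff(names(res), "snp_id")])
}
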