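#' Genotype matrix container
#'
#' Samples-by-variants matrix of additive-coded unphased genotypes: each cell
#' counts copies of the variant's minor allele (0, 1, 2) or is `NA` when the
#' genotype is missing. Variants are kept strictly ordered by (chromosome,
#' position).
#'
#' @param calls Integer matrix, samples in rows, variants in columns; values
#'   in `{0, 1, 2, NA}`.
#' @param variants Data frame with columns `snp_id`, `chrom`, `pos_bp`,
#'   `allele_minor`, `allele_major`. Alleles may be `NA` when they cannot be
#'   determined (monomorphic or fully missing variants).
#' @param sample_ids Character vector of unique sample identifiers, one per
#'   row of `calls`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `variants`, `sample_ids`.
#' @export
genotype_matrix <- function(calls, variants, sample_ids) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  req <- c("snp_id", "chrom", "pos_bp", "allele_minor", "allele_major")
  if (!all(req %in% names(variants))) {
    stop("variants must have columns: ", paste(req, collapse = ", "))
  }
  variants <- as.data.frame(variants)[, req]
  variants$snp_id <- as.character(variants$snp_id)
  variants$chrom <- as.character(variants$chrom)
  variants$pos_bp <- as.integer(variants$pos_bp)
  sample_ids <- as.character(sample_ids)

  if (nrow(calls) != length(sample_ids)) {
    stop("nrow(calls) != length(sample_ids)")
  }
  if (ncol(calls) != nrow(variants)) {
    stop("ncol(calls) != nrow(variants)")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(variants$snp_id)) {
    stop("duplicate snp id: ",
         paste(unique(variants$snp_id[duplicated(variants$snp_id)]),
               collapse = ", "))
  }
  bad <- !(calls %in% c(0L, 1L, 2L)) & !is.na(calls)
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  if (any(variants$pos_bp <= 0L, na.rm = TRUE)) stop("pos_bp must be > 0")
  same <- !is.na(variants$allele_minor) &
    variants$allele_minor == variants$allele_major
  if (any(same)) stop("minor and major allele identical for: ",
                      paste(variants$snp_id[same], collapse = ", "))

  ord <- order(variants$chrom, variants$pos_bp)
  variants <- variants[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  key <- paste(variants$chrom, variants$pos_bp)
  if (anyDuplicated(key)) {
    stop("variant positions not strictly increasing (duplicate chrom:pos): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  rownames(calls) <- sample_ids
  colnames(calls) <- variants$snp_id
  rownames(variants) <- NULL

  structure(list(calls = calls, variants = variants, sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              length(x$sample_ids), nrow(x$variants)))
  if (nrow(x$variants) > 0) {
    cat(sprintf("  region: %s:%d-%d\n", x$variants$chrom[1],
                min(x$variants$pos_bp), max(x$variants$pos_bp)))
  }
  cat(sprintf("  missing calls: %.3f%%\n", 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Minor allele frequency per variant
#'
#' Computed over non-missing calls only. A fully missing variant gets `NA`.
#'
#' @param gm A [genotype_matrix()].
#' @return Named numeric vector of frequencies in `[0, 1]`.
#' @export
minor_allele_freq <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  colMeans(gm$calls, na.rm = TRUE) / 2
}

#' Subset a genotype matrix
#'
#' @param gm A [genotype_matrix()].
#' @param samples Character vector of sample ids or logical/integer row index.
#' @param variants Character vector of snp ids or logical/integer column index.
#' @return A [genotype_matrix()] restricted to the selection.
#' @export
subset_genotypes <- function(gm, samples = NULL, variants = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ri <- seq_along(gm$sample_ids)
  ci <- seq_len(nrow(gm$variants))
  if (!is.null(samples)) {
    ri <- if (is.character(samples)) match(samples, gm$sample_ids) else ri[samples]
    if (anyNA(ri)) stop("unknown sample id in selection")
  }
  if (!is.null(variants)) {
    ci <- if (is.character(variants)) match(variants, gm$variants$snp_id) else ci[variants]
    if (anyNA(ci)) stop("unknown snp id in selection")
  }
  genotype_matrix(gm$calls[ri, ci, drop = FALSE],
                  gm$variants[ci, , drop = FALSE],
                  gm$sample_ids[ri])
}
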