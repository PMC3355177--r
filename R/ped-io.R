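# PLINK-text (PED/MAP) and HLA table input/output.
# Conventions: 1-based inclusive coordinates; missing allele "0"; phenotype
# 1 = control, 2 = case; calls count minor alleles, minor determined from the
# pooled observed allele frequency (ties broken toward the lexicographically
# smaller allele).

.VALID_ALLELES <- c("A", "C", "G", "T", "0")
.HLA_CLASSES <- c("DQ2.5", "DQ2.2", "DQ7", "DQ8", "X")

#' Read PED/MAP genotype files
#'
#' Parses the whitespace-delimited PLINK text dialect. The MAP file carries
#' 4 columns (chrom, snp id, genetic distance, bp position); the PED file has
#' 6 leading columns (family, sample id, father, mother, sex, phenotype)
#' followed by two allele columns per variant. A genotype containing the
#' missing allele "0" becomes a missing call. Genotypes are additive-coded
#' as the count of minor alleles, with the minor allele determined from the
#' observed allele frequency over all samples (cases and controls pooled);
#' at a 50/50 tie the lexicographically smaller allele is taken as minor.
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @return List with elements `genotypes` (a [genotype_matrix()]) and
#'   `samples` (data frame `sample_id`, `status` with values
#'   `"case"`/`"control"`).
#' @export
read_ped_map <- function(ped_path, map_path) {
  map_lines <- .tokenize_lines(map_path)
  n_var <- length(map_lines)
  for (i in seq_len(n_var)) {
    if (length(map_lines[[i]]) != 4) {
      stop(sprintf("format error: MAP line %d has %d columns, expected 4",
                   i, length(map_lines[[i]])))
    }
  }
  chrom <- vapply(map_lines, `[`, "", 1)
  snp_id <- vapply(map_lines, `[`, "", 2)
  pos_bp <- suppressWarnings(as.integer(vapply(map_lines, `[`, "", 4)))
  if (anyNA(pos_bp)) {
    stop(sprintf("format error: MAP line %d has non-integer position",
                 which(is.na(pos_bp))[1]))
  }
  if (anyDuplicated(snp_id)) {
    stop("validation error: duplicate snp id: ",
         paste(unique(snp_id[duplicated(snp_id)]), collapse = ", "))
  }

  ped_lines <- .tokenize_lines(ped_path)
  n_samp <- length(ped_lines)
  want <- 6 + 2 * n_var
  for (i in seq_len(n_samp)) {
    if (length(ped_lines[[i]]) != want) {
      stop(sprintf(
        "format error: PED line %d has %d columns, expected %d",
        i, length(ped_lines[[i]]), want))
    }
  }
  sample_id <- vapply(ped_lines, `[`, "", 2)
  if (anyDuplicated(sample_id)) {
    stop("validation error: duplicate sample id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  pheno <- vapply(ped_lines, `[`, "", 6)
  bad_ph <- !(pheno %in% c("1", "2"))
  if (any(bad_ph)) {
    stop(sprintf(
      "validation error: PED line %d has phenotype '%s'; must be 1 (control) or 2 (case)",
      which(bad_ph)[1], pheno[which(bad_ph)[1]]))
  }

  # allele tokens as an n_samp x (2 n_var) matrix
  al <- matrix("", n_samp, 2 * n_var)
  for (i in seq_len(n_samp)) {
    toks <- ped_lines[[i]][-(1:6)]
    j <- which(!(toks %in% .VALID_ALLELES))
    if (length(j)) {
      stop(sprintf("format error: PED line %d has allele '%s'; must be one of A,C,G,T,0",
                   i, toks[j[1]]))
    }
    al[i, ] <- toks
  }
  a1 <- al[, seq(1, 2 * n_var, by = 2), drop = FALSE]
  a2 <- al[, seq(2, 2 * n_var, by = 2), drop = FALSE]

  calls <- matrix(NA_integer_, n_samp, n_var)
  allele_minor <- allele_major <- rep(NA_character_, n_var)
  for (j in seq_len(n_var)) {
    obs <- c(a1[, j], a2[, j])
    obs <- obs[obs != "0"]
    u <- sort(unique(obs))
    if (length(u) > 2) {
      stop(sprintf("validation error: snp %s has >2 alleles: %s",
                   snp_id[j], paste(u, collapse = ",")))
    }
    if (length(u) == 0) next               # fully missing column
    if (length(u) == 1) {
      allele_major[j] <- u
    } else {
      f1 <- mean(obs == u[1])
      # ties (f1 == 0.5) fall to the lexicographically smaller u[1]
      if (f1 <= 0.5) {
        allele_minor[j] <- u[1]; allele_major[j] <- u[2]
      } else {
        allele_minor[j] <- u[2]; allele_major[j] <- u[1]
      }
    }
    miss <- a1[, j] == "0" | a2[, j] == "0"
    cnt <- (a1[, j] == allele_minor[j]) + (a2[, j] == allele_minor[j])
    if (is.na(allele_minor[j])) cnt <- rep(0L, n_samp)  # monomorphic
    cnt[miss] <- NA_integer_
    calls[, j] <- cnt
  }

  variants <- data.frame(snp_id = snp_id, chrom = chrom, pos_bp = pos_bp,
                         allele_minor = allele_minor,
                         allele_major = allele_major,
                         stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sample_id,
                        status = ifelse(pheno == "2", "case", "control"),
                        stringsAsFactors = FALSE)
  list(genotypes = genotype_matrix(calls, variants, sample_id),
       samples = samples)
}

#' Write PED/MAP genotype files
#'
#' Emits the dialect read by [read_ped_map()]: single-space-delimited, family
#' id equal to the sample id, unknown parents/sex, phenotype 1/2, missing
#' genotypes as `0 0`, heterozygotes with alleles in alphabetical order.
#'
#' @param gm A [genotype_matrix()].
#' @param samples Data frame with `sample_id` and `status` columns matching
#'   the matrix rows.
#' @param ped_path,map_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_ped_map <- function(gm, samples, ped_path, map_path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!identical(as.character(samples$sample_id), gm$sample_ids)) {
    stop("samples do not match genotype matrix rows")
  }
  v <- gm$variants
  map <- sprintf("%s %s 0 %d", v$chrom, v$snp_id, v$pos_bp)

  n_var <- nrow(v)
  mi <- v$allele_minor
  ma <- v$allele_major
  ped <- character(length(gm$sample_ids))
  for (i in seq_along(gm$sample_ids)) {
    g <- gm$calls[i, ]
    toks <- character(2 * n_var)
    for (j in seq_len(n_var)) {
      p <- if (is.na(g[j])) {
        c("0", "0")
      } else if (g[j] == 0L) {
        c(ma[j], ma[j])
      } else if (g[j] == 2L) {
        c(mi[j], mi[j])
      } else {
        sort(c(mi[j], ma[j]))
      }
      if (anyNA(p)) {
        stop(sprintf("cannot write snp %s: allele unknown for non-missing call",
                     v$snp_id[j]))
      }
      toks[c(2 * j - 1, 2 * j)] <- p
    }
    ph <- if (samples$status[i] == "case") "2" else "1"
    ped[i] <- paste(c(gm$sample_ids[i], gm$sample_ids[i], "0", "0", "0", ph,
                      toks), collapse = " ")
  }
  writeLines(map, map_path)
  writeLines(ped, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read a per-sample HLA-DQ haplotype-class table
#'
#' Tab-separated file with header columns `sample_id`, `hap1`, `hap2`;
#' haplotype labels must be one of DQ2.5, DQ2.2, DQ7, DQ8, X. The pair is
#' unordered; it is returned in canonical (sorted) order.
#'
#' @param path Path to the TSV file.
#' @param sample_ids Optional character vector of genotyped sample ids; every
#'   sample in the table must occur in it, otherwise a reconciliation error
#'   listing the offending ids is raised.
#' @return Data frame `sample_id`, `hap1`, `hap2`.
#' @export
read_hla_table <- function(path, sample_ids = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = "character")
  req <- c("sample_id", "hap1", "hap2")
  if (!all(req %in% names(tab))) {
    stop("HLA table must have columns: ", paste(req, collapse = ", "))
  }
  for (col in c("hap1", "hap2")) {
    bad <- which(!(tab[[col]] %in% .HLA_CLASSES))
    if (length(bad)) {
      stop(sprintf("unknown haplotype label '%s' at line %d (must be one of %s)",
                   tab[[col]][bad[1]], bad[1] + 1L,
                   paste(.HLA_CLASSES, collapse = ", ")))
    }
  }
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicate sample id in HLA table: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]), collapse = ", "))
  }
  if (!is.null(sample_ids)) {
    extra <- setdiff(tab$sample_id, sample_ids)
    if (length(extra)) {
      stop("reconciliation error: HLA table samples absent from genotype data: ",
           paste(extra, collapse = ", "))
    }
  }
  swap <- tab$hap1 > tab$hap2
  h1 <- ifelse(swap, tab$hap2, tab$hap1)
  h2 <- ifelse(swap, tab$hap1, tab$hap2)
  data.frame(sample_id = tab$sample_id, hap1 = h1, hap2 = h2,
             stringsAsFactors = FALSE)
}

#' Write the per-sample HLA table dialect read by [read_hla_table()]
#' @param hla Data frame `sample_id`, `hap1`, `hap2`.
#' @param path Output path.
#' @export
write_hla_table <- function(hla, path) {
  utils::write.table(hla[, c("sample_id", "hap1", "hap2")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# split file into whitespace token lists, dropping blank lines at EOF
.tokenize_lines <- function(path) {
  lines <- readLines(path)
  while (length(lines) && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  lapply(lines, function(l) strsplit(trimws(l), "[ \t]+")[[1]])
}
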