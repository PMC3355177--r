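# End-to-end orchestration: QC -> simple scan -> risk-stratum partition ->
# adjusted scan -> LD clumping -> parameter sensitivity sweep -> joint
# models, with a machine-readable run report. The pipeline is a pure
# function of (inputs, config): no stage uses random numbers.

#' Pipeline configuration
#'
#' Inputs may be given as file paths (`ped`/`map`/`hla` in the formats of
#' [read_ped_map()] and [read_hla_table()]) or as in-memory objects
#' (`genotypes`, `samples`, `hla`).
#'
#' @param ped,map,hla Input file paths (alternative to in-memory objects).
#' @param genotypes,samples In-memory [genotype_matrix()] and sample table.
#' @param hla_table In-memory HLA pair table.
#' @param out_dir Output directory (created if absent).
#' @param qc A [qc_params()].
#' @param tree A [tree_params()].
#' @param clumping A [clump_params()].
#' @param covariate_snp Optional snp id forced into the adjusted model and
#'   barred from clump index status.
#' @param r2_grid,p1_grid Sensitivity-sweep grids (defaults as in
#'   [sensitivity_sweep()]).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(ped = NULL, map = NULL, hla = NULL,
                            genotypes = NULL, samples = NULL,
                            hla_table = NULL,
                            out_dir,
                            qc = qc_params(), tree = tree_params(),
                            clumping = clump_params(),
                            covariate_snp = NULL,
                            r2_grid = NULL, p1_grid = NULL) {
  has_files <- !is.null(ped) && !is.null(map) && !is.null(hla)
  has_objects <- !is.null(genotypes) && !is.null(samples) && !is.null(hla_table)
  if (!has_files && !has_objects) {
    stop("provide either ped/map/hla paths or genotypes/samples/hla_table objects")
  }
  if (has_files) {
    for (f in c(ped, map, hla)) {
      if (!file.exists(f)) stop("input file not found: ", f)
    }
  }
  stopifnot(inherits(qc, "qc_params"), inherits(tree, "tree_params"),
            inherits(clumping, "clump_params"))
  structure(list(ped = ped, map = map, hla = hla,
                 genotypes = genotypes, samples = samples,
                 hla_table = hla_table, out_dir = out_dir,
                 qc = qc, tree = tree, clumping = clumping,
                 covariate_snp = covariate_snp,
                 r2_grid = r2_grid, p1_grid = p1_grid),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys: `ped`, `map`, `hla`, `out_dir`, `covariate_snp`, and
#' nested `qc`, `tree`, `clumping` blocks whose fields are passed to
#' [qc_params()], [tree_params()] and [clump_params()].
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(
    ped = raw$ped, map = raw$map, hla = raw$hla,
    out_dir = raw$out_dir %||% dirname(path),
    qc = do.call(qc_params, raw$qc %||% list()),
    tree = do.call(tree_params, raw$tree %||% list()),
    clumping = do.call(clump_params, raw$clumping %||% list()),
    covariate_snp = raw$covariate_snp,
    r2_grid = raw$r2_grid, p1_grid = raw$p1_grid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stage order: QC, simple per-SNP scan, HLA risk-stratum partition,
#' stratum-adjusted scan, LD clumping, sensitivity sweep, joint multi-SNP
#' models (clump indices with and without strata). The eight contract
#' outputs are `simple_results.tsv`, `strata.tsv`, `tree.txt`,
#' `adjusted_results.tsv`, `clumps.tsv`, `sensitivity.tsv`,
#' `joint_results.tsv` and `report.json` (a `qc_report.tsv` is written in
#' addition). A stage failure aborts with the stage name and leaves a
#' `FAILED` marker in the output directory.
#'
#' @param config A [pipeline_config()].
#' @return The run report (list of 7 stage records plus output digests),
#'   invisibly also written to `report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  stages <- list()
  files <- character()
  current_stage <- "load"
  fail <- function(e) {
    writeLines(sprintf("stage=%s code=STAGE_ERROR message=%s",
                       current_stage, conditionMessage(e)), out("FAILED"))
    stop(sprintf("pipeline stage '%s' failed: %s", current_stage,
                 conditionMessage(e)), call. = FALSE)
  }
  record <- function(name, params, n_in, n_out, outputs) {
    stages[[length(stages) + 1L]] <<- list(
      stage = name, params = params, n_in = n_in, n_out = n_out,
      outputs = as.character(outputs))
    files <<- c(files, outputs)
  }

  tryCatch({
    if (!is.null(config$genotypes)) {
      gm <- config$genotypes
      samples <- config$samples
      hla <- config$hla_table
    } else {
      inp <- read_ped_map(config$ped, config$map)
      gm <- inp$genotypes
      samples <- inp$samples
      hla <- read_hla_table(config$hla, sample_ids = samples$sample_id)
    }

    current_stage <- "qc"
    n_in <- c(samples = nrow(samples), variants = nrow(gm$variants))
    qcd <- apply_qc(gm, samples, config$qc)
    gm <- qcd$genotypes
    samples <- qcd$samples
    .write_tsv(qcd$report, out("qc_report.tsv"))
    record("qc", unclass(config$qc), n_in,
           c(samples = nrow(samples), variants = nrow(gm$variants)),
           out("qc_report.tsv"))

    current_stage <- "simple_scan"
    simple <- assoc_scan(gm, samples, covariate_snp = config$covariate_snp)
    .write_tsv(simple, out("simple_results.tsv"))
    record("simple_scan", list(covariate_snp = config$covariate_snp),
           nrow(gm$variants), nrow(simple), out("simple_results.tsv"))

    current_stage <- "partition"
    hla <- hla[match(samples$sample_id, hla$sample_id), , drop = FALSE]
    if (anyNA(hla$sample_id)) stop("HLA pair missing for retained samples")
    prof <- dq_profile(hla$hap1, hla$hap2)
    tree <- fit_ctree(prof[, c("n_dq25", "n_dq8")],
                      samples$status == "case", config$tree)
    strata <- assign_strata(tree, prof)
    strata_df <- data.frame(sample_id = samples$sample_id,
                            stratum_id = as.integer(strata),
                            stratum_label = tree$labels[strata],
                            stringsAsFactors = FALSE)
    .write_tsv(strata_df, out("strata.tsv"))
    writeLines(utils::capture.output(print(tree)), out("tree.txt"))
    record("partition", unclass(config$tree), nrow(samples),
           tree$n_terminal, c(out("strata.tsv"), out("tree.txt")))

    current_stage <- "adjusted_scan"
    adjusted <- assoc_scan(gm, samples, strata = strata,
                           covariate_snp = config$covariate_snp)
    .write_tsv(adjusted, out("adjusted_results.tsv"))
    record("adjusted_scan", list(covariate_snp = config$covariate_snp),
           nrow(gm$variants), nrow(adjusted), out("adjusted_results.tsv"))

    current_stage <- "clump"
    clumps <- clump(adjusted, gm, config$clumping,
                    barred_index = config$covariate_snp)
    .write_tsv(as.data.frame(clumps), out("clumps.tsv"))
    record("clump", unclass(config$clumping), nrow(adjusted),
           length(clumps), out("clumps.tsv"))

    current_stage <- "sweep"
    sweep_args <- list(results = adjusted, gm = gm,
                       p2 = config$clumping$p2,
                       max_kb = config$clumping$max_kb,
                       r2_default = config$clumping$r2_min,
                       p1_default = config$clumping$p1,
                       barred_index = config$covariate_snp)
    if (!is.null(config$r2_grid)) sweep_args$r2_grid <- config$r2_grid
    if (!is.null(config$p1_grid)) sweep_args$p1_grid <- config$p1_grid
    sens <- do.call(sensitivity_sweep, sweep_args)
    .write_tsv(sens, out("sensitivity.tsv"))
    record("sweep", list(p2 = config$clumping$p2,
                         max_kb = config$clumping$max_kb),
           nrow(adjusted), nrow(sens), out("sensitivity.tsv"))

    current_stage <- "joint"
    idx <- vapply(unclass(clumps), `[[`, "", "index_snp")
    joint <- if (length(idx)) {
      rbind(joint_fit(gm, samples, idx),
            joint_fit(gm, samples, idx, strata = strata,
                      include_strata = TRUE))
    } else {
      joint_fit(gm, samples, gm$variants$snp_id[1])[0, ]
    }
    .write_tsv(joint, out("joint_results.tsv"))
    record("joint", list(n_index = length(idx)), length(idx), nrow(joint),
           out("joint_results.tsv"))
  }, error = fail)

  contract <- c("simple_results.tsv", "strata.tsv", "tree.txt",
                "adjusted_results.tsv", "clumps.tsv", "sensitivity.tsv",
                "joint_results.tsv", "report.json")
  report <- list(
    stages = stages,
    outputs = lapply(file.path(config$out_dir, setdiff(contract, "report.json")),
                     function(f) list(file = basename(f),
                                      md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (file.exists(out("FAILED"))) file.remove(out("FAILED"))
  invisible(report)
}

#' Render a human-readable run summary
#'
#' Markdown summary of a completed [run_pipeline()] output directory: QC
#' exclusion counts, the tree report, the top association rows per model,
#' the clump table and the sensitivity table. Missing artifacts are listed
#' as absent rather than raising an error.
#'
#' @param out_dir The pipeline output directory.
#' @param top_n Association rows shown per model.
#' @return Character vector of markdown lines (invisibly written to
#'   `report.md` in `out_dir`).
#' @export
make_report <- function(out_dir, top_n = 20L) {
  f <- function(name) file.path(out_dir, name)
  lines <- c("# xMHC conditional association run", "")
  read_or_null <- function(name) {
    if (!file.exists(f(name))) return(NULL)
    utils::read.table(f(name), header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }
  fmt_table <- function(df) {
    c(paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1, function(r) paste(r, collapse = " | ")))
  }

  qc <- read_or_null("qc_report.tsv")
  lines <- c(lines, "## Quality control", "")
  lines <- c(lines, if (is.null(qc)) {
    "qc_report.tsv absent"
  } else if (nrow(qc) == 0) {
    "0 exclusions"
  } else {
    cnts <- stats::aggregate(id ~ type + reason, qc, length)
    sprintf("- %s excluded for %s: %d", cnts$type, cnts$reason, cnts$id)
  }, "")

  lines <- c(lines, "## Risk-stratum tree", "")
  lines <- c(lines, if (file.exists(f("tree.txt"))) {
    c("```", readLines(f("tree.txt")), "```")
  } else "tree.txt absent", "")

  for (m in c("simple_results.tsv", "adjusted_results.tsv",
              "joint_results.tsv")) {
    res <- read_or_null(m)
    lines <- c(lines, sprintf("## Top associations: %s", m), "")
    lines <- c(lines, if (is.null(res)) {
      sprintf("%s absent", m)
    } else {
      res <- res[order(res$wald_p), , drop = FALSE]
      fmt_table(utils::head(res[, c("snp_id", "pos_bp", "odds_ratio",
                                    "wald_p", "model_tag")], top_n))
    }, "")
  }

  cl <- read_or_null("clumps.tsv")
  lines <- c(lines, "## Independent loci", "")
  lines <- c(lines, if (is.null(cl)) {
    "clumps.tsv absent"
  } else if (nrow(cl) == 0) {
    "0 independent loci"
  } else {
    c(sprintf("%d independent loci", nrow(cl)), "",
      fmt_table(cl[, c("index_snp", "index_p", "n_secondary",
                       "span_start", "span_end")]))
  }, "")

  sens <- read_or_null("sensitivity.tsv")
  lines <- c(lines, "## Sensitivity sweep", "")
  lines <- c(lines, if (is.null(sens)) "sensitivity.tsv absent" else
    fmt_table(sens), "")

  writeLines(lines, f("report.md"))
  invisible(lines)
}
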