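#!/usr/bin/env Rscript
# Stage 2: quality control.
#
# Standard SNP-panel filters: samples and SNPs below 98% call rate, SNPs
# with MAF < 0.03, and SNPs failing the exact Hardy-Weinberg test in
# controls at p < 1e-5. The clean genotype files feed every later stage.

suppressPackageStartupMessages(library(xmhcscan))

inp <- read_ped_map("results/sim.ped", "results/sim.map")
out <- apply_qc(inp$genotypes, inp$samples, qc_params())

write_ped_map(out$genotypes, out$samples,
              "results/clean.ped", "results/clean.map")
write.table(out$report, "results/qc_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message(nrow(out$report), " exclusions (",
        sum(out$report$type == "sample"), " samples, ",
        sum(out$report$type == "variant"), " variants); retained ",
        length(out$genotypes$sample_ids), " samples x ",
        nrow(out$genotypes$variants), " SNPs")
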