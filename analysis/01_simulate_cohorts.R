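#!/usr/bin/env Rscript
# Simulate the synthetic CD4+ T-cell study: target-gene sets, the scenario
# preset cohort (resting/activated, Th1/Th2, Treg subsets, supernatant-
# treated cells, healthy and patient compartments), and a per-sample QC
# metrics table with three planted failures.

suppressPackageStartupMessages(library(stpscore))
SEED <- 20260930L
dir.create("results", showWarnings = FALSE)

gene_sets <- demo_gene_sets()
write_gmt(gene_sets, "results/gene_sets.gmt")

sim <- simulate_cohort(scenario_presets(), gene_sets, seed = SEED)
write_expression_tsv(sim$cohort, "results/cohort_expression.tsv")
write_tsv(sim$cohort$annotations, "results/cohort_annotations.tsv",
          "per-sample scenario annotations", seed = SEED)
write_tsv(sim$truth, "results/cohort_truth.tsv",
          "planted per-pathway activation levels", seed = SEED)

qc <- simulate_qc_table(ncol(sim$cohort$values), n_planted_failures = 3,
                        seed = SEED + 1L)
qc$metrics$sample_id <- colnames(sim$cohort$values)
write_tsv(qc$metrics, "results/qc_metrics.tsv",
          "per-sample QC metrics (3 planted failures)", seed = SEED + 1L)

cat(sprintf("simulated %d samples x %d genes across %d scenarios\n",
            ncol(sim$cohort$values), nrow(sim$cohort$values),
            length(unique(sim$cohort$annotations$scenario))))
cat("planted QC failures:",
    paste(colnames(sim$cohort$values)[
      match(qc$failed_sample_ids, sprintf("S%03d",
                                          seq_len(ncol(sim$cohort$values))))],
      collapse = ", "), "\n")
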