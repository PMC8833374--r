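#!/usr/bin/env Rscript
# Apply the 11-rule per-sample QC panel to the simulated cohort and drop
# failing samples before any scoring, writing the QC report and the
# filtered expression matrix.

suppressPackageStartupMessages(library(stpscore))

cohort <- read_expression_tsv("results/cohort_expression.tsv")
metrics <- read_tsv("results/qc_metrics.tsv")

reports <- evaluate_qc_table(metrics)
write_tsv(qc_report_table(reports), "results/qc_report.tsv",
          "per-sample QC verdicts")
filtered <- filter_cohort(cohort, reports)
write_expression_tsv(filtered, "results/cohort_filtered.tsv")

n_fail <- sum(!vapply(reports, `[[`, logical(1), "pass"))
cat(sprintf("QC: %d of %d samples failed and were removed; %d remain\n",
            n_fail, length(reports), ncol(filtered$values)))
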