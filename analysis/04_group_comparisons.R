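#!/usr/bin/env Rscript
# Nonparametric group comparisons.  First the worked clinical example: the
# published TIL CD4+ T-cell scores compared between triple-negative and
# other breast-cancer subtypes (exact one-sided Mann-Whitney).  Then the
# synthetic preset contrasts: activated vs resting per pathway, and the
# pathway-pathway Pearson correlations across the simulated patient TIL
# samples.

suppressPackageStartupMessages(library(stpscore))

til <- read_tsv(system.file("extdata", "til_pathway_scores.tsv",
                            package = "stpscore"))
tn <- til$subtype == "triple_negative"
clin <- list()
for (pw in stp_pathways())
  clin[[paste0("TIL_", pw, "_tripleNeg_vs_other")]] <-
    mann_whitney(til[[pw]][tn], til[[pw]][!tn], alternative = "less")
write_tsv(comparisons_table(clin), "results/comparisons_clinical.tsv",
          "TIL subtype comparisons, exact one-sided Mann-Whitney")
cat("clinical TIL comparisons (triple-negative lower?):\n")
tab <- comparisons_table(clin)
print(data.frame(comparison = tab$comparison, U = tab$statistic,
                 p = round(tab$p_value, 3)), row.names = FALSE)

scores <- read_tsv("results/activity_scores.tsv")
ann <- read_tsv("results/cohort_annotations.tsv")
scen <- ann$scenario[match(scores$sample_id, ann$sample_id)]
syn <- list()
for (pw in stp_pathways())
  syn[[paste0(pw, "_activated_vs_resting")]] <-
    mann_whitney(scores[[pw]][scen == "activated"],
                 scores[[pw]][scen == "resting"])
write_tsv(comparisons_table(syn), "results/comparisons_synthetic.tsv",
          "synthetic activated-vs-resting contrasts, two-sided Mann-Whitney")

# pathway co-activation in simulated TIL samples (within-pathway scores
# across samples; raw scores are never pooled across pathways)
is_til <- scen == "patient_TIL"
cors <- list()
for (pair in utils::combn(c("NFkB", "JAK_STAT3", "TGFB", "Notch"), 2,
                          simplify = FALSE))
  cors[[paste(pair, collapse = "_vs_")]] <-
    pearson_cor(scores[[pair[1]]][is_til], scores[[pair[2]]][is_til])
write_tsv(comparisons_table(cors), "results/correlations_til.tsv",
          "pathway correlations across simulated TIL samples, Pearson")
cat(sprintf("wrote %d synthetic contrasts and %d TIL pathway correlations\n",
            length(syn), length(cors)))
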