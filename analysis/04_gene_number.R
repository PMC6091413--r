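#!/usr/bin/env Rscript
# Step 4: how many reference genes are enough?
#
# Per condition set: geNorm pairwise variations V_n/n+1, the 0.15-cutoff
# rule (falling back to the lowest V when nothing passes), and the
# Pearson correlation between NF over the top-3 genes and NF over the
# chosen count — high r means three genes already track the optimal set.

suppressPackageStartupMessages(library(refstab))
seed <- as.integer(Sys.getenv("ANALYSIS_SEED", "1"))

path <- "results/data/ct_survey_long.tsv"
ct <- if (file.exists(path)) {
  read_ct_table(path)
} else {
  simulate_all_presets(seed = seed)$ct
}
ct <- collapse_technical_reps(ct)

rows <- list()
for (set in unique(ct$samples$condition_set)) {
  q <- ct_to_quantity(subset_ct(ct, condition_set = set))
  gc <- gene_count_analysis(q)
  cat("\n==", set, "==\n")
  print(gc)
  rows[[set]] <- data.frame(
    condition_set = set, chosen_n = gc$chosen_n, rule = gc$rule_used,
    min_v = min(gc$v), r_log2 = gc$nf_correlation_r,
    r_linear = gc$nf_correlation_r_linear,
    recommended = paste(gc$recommended_genes, collapse = "+"))
}
dir.create("results", showWarnings = FALSE)
write.table(do.call(rbind, rows), "results/gene_number.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
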