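#!/usr/bin/env Rscript
# Step 6: 2^-ddCT validation of the chosen reference genes.
#
# Adds a cGMP-dependent protein kinase-like target gene with a planted
# tissue-specific expression profile to the larval-tissue design, then
# normalizes it by (a) the most stable gene, (b) the top-2 combination
# and (c) the least stable gene from step 3's consensus. Stable
# normalizers should agree with each other; the unstable one should
# distort the apparent expression. Group differences are tested with
# one-way ANOVA + Tukey compact letters.

suppressPackageStartupMessages(library(refstab))
seed <- as.integer(Sys.getenv("ANALYSIS_SEED", "1"))
dir.create("results", showWarnings = FALSE)

cfg <- paper_design_preset("larval_tissues", seed = seed + 60)
cfg$genes <- rbind(cfg$genes,
                   data.frame(symbol = "PKG", baseline_ct = 24,
                              drift_sd = 2.0, noise_sd = 0.3,
                              efficiency_percent = 99.1))
sim <- simulate_ct_dataset(cfg)
t <- collapse_technical_reps(sim$ct)

refs_only <- subset_ct(t, genes = setdiff(rownames(t$ct), "PKG"))
cons <- reffinder_consensus(list(
  genorm(ct_to_quantity(refs_only)),
  normfinder(ct_to_quantity(refs_only), normfinder_groups(refs_only)),
  bestkeeper(refs_only), delta_ct(refs_only)))
best <- cons$ordering[1]; second <- cons$ordering[2]
worst <- rev(cons$ordering)[1]
cat("Normalizers: best =", best, "| top-2 =", best, "+", second,
    "| least stable =", worst, "\n\n")

cmp <- compare_normalizers(
  t, "PKG",
  normalizers = stats::setNames(
    list(best, c(best, second), worst),
    c(best, paste(best, second, sep = "+"), worst)),
  calibrator = "brain")
write.table(cmp$ratios, "results/validation_normalizer_ratios.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("Fold ratios between normalizers (1 = indistinguishable):\n")
print(transform(cmp$ratios, ratio = round(ratio, 3)))

# among-tissue differences within each normalizer, Tukey letters
rows <- list()
for (nm in names(cmp$expressions)) {
  ex <- cmp$expressions[[nm]]
  tl <- tukey_letters(ex$expression, ex$samples$level)
  cat("\nPKG normalized by ", nm, ": F = ", round(tl$F, 2),
      ", p = ", signif(tl$p, 3), "\n", sep = "")
  print(data.frame(tissue = names(tl$letters),
                   mean_expr = round(unname(tl$group_means[names(tl$letters)]), 3),
                   letters = unname(tl$letters)))
  rows[[nm]] <- data.frame(normalizer = nm, tissue = names(tl$letters),
                           mean_expr = unname(tl$group_means[names(tl$letters)]),
                           letters = unname(tl$letters))
}
write.table(do.call(rbind, rows), "results/validation_expression.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
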