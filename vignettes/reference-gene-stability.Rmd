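---
title: "Evaluating reference-gene stability from RT-qPCR CT data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating reference-gene stability from RT-qPCR CT data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Relative quantification by RT-qPCR reports a target gene's expression as a
ratio against one or more reference ("housekeeping") genes measured in the
same sample. The whole construction stands or falls with the assumption
that the reference genes are themselves stably expressed across the
conditions being compared: a reference that drifts with tissue,
developmental stage or treatment silently rescales every target it
normalizes. Because no gene is universally stable, candidate references
must be screened per species and per experimental design.

`refstab` implements the standard screening workflow on cycle-threshold
(CT) tables: the four widely used stability statistics (geNorm,
NormFinder, BestKeeper, comparative ΔCT), a RefFinder-style geometric-mean
consensus over their rankings, the geNorm pairwise-variation rule for how
many reference genes to use, amplification-efficiency estimation from
dilution standard curves, and 2^−ΔΔCT target-gene validation with one-way
ANOVA and Tukey compact-letter displays. A seeded synthetic CT generator
with known ground truth makes the full pipeline testable end to end.

## Data model

The raw input is a gene × reaction CT matrix with per-reaction metadata
(condition set, level, biological replicate, optional technical
replicate) and per-gene assay metadata (symbol, optional amplification
efficiency). Technical replicates are averaged arithmetically into one
column per biological sample; a gene left with an empty cell after that
collapse is dropped with a warning rather than imputed, because all four
stability methods assume complete matrices. Biological replicates are kept
as separate samples by default — the alternative reading, averaging them
per level before analysis, is exposed as an option and recorded in the run
manifest, since published workflows are often ambiguous on this point.

Quantities for geNorm and NormFinder come from the efficiency transform
\(Q_{is} = E_i^{\,CT^{min}_i - CT_{is}}\), so each gene's
highest-expressing sample is the unit. \(E\) defaults to 2 (perfect
doubling) for every gene because the classical tools do; per-assay
efficiencies from standard curves can be switched on. Per-gene rescaling
of \(Q\) provably cancels out of every downstream statistic (the test
suite asserts this), so the choice of unit is cosmetic.

## The four stability statistics

**geNorm.** For genes \(j,k\), the pairwise variation \(V_{jk}\) is the SD
across samples of \(\log_2(Q_j/Q_k)\); a gene's \(M\) is its mean \(V\)
against the rest of the panel. The least stable gene (highest \(M\)) is
excluded and \(M\) recomputed until two genes remain. The reported
per-gene stability is its \(M\) at the step it was excluded, and the final
pair share the two-gene \(M\) and rank 1 — this convention, rather than
full-panel \(M\), is what produces the tied top pairs with identical
values seen in published geNorm tables, and it is the one the package
reports (full-panel \(M\) stays available in the detail block). Ties for
the current worst \(M\) are broken by excluding the lexicographically last
symbol, a deterministic rule recorded in the manifest.

**NormFinder.** Works on log-scale expression, sample-centred across
genes. In single-group mode the per-gene variance is bias-corrected for
the centring (subtract \(\bar{s}^2/(k-1)\), scale by \(k/(k-2)\), truncate
at zero), and the stability value is the corrected SD. With groups, the
model separates intergroup deviations \(d_{ig}\) (summing to zero over
genes within each group) from intragroup variances, estimates the
intergroup variance \(\gamma^2\) with the \((k-1)(G-1)\) divisor, shrinks
each \(d_{ig}\) toward zero by \(\gamma^2/(\gamma^2 + \sigma^2_{ig}/n_g)\),
and reports
\(\rho_i = \frac1G\sum_g\big[|\tilde d_{ig}| +
\sqrt{(\sigma^2_{ig}/n_g)\,\gamma^2/(\gamma^2+\sigma^2_{ig}/n_g)}\big]\).
Groups default to condition levels when every level has at least two
samples, else single-group mode; published studies rarely state their
grouping, so both modes are explicit arguments.

**BestKeeper.** Descriptive statistics on raw CT. The "SD" is the mean
absolute deviation from the arithmetic mean CT — the original tool's
definition — with classical \(n-1\) SD behind a switch; ranking is by
ascending SD. The per-sample BestKeeper index (geometric mean CT over
genes) and each gene's Pearson \(r\) against it are reported in the
detail table.

**Comparative ΔCT.** For every gene pair, the SD across samples of the
CT difference; a gene's stability is its mean pairwise SD. It operates on
raw CT, the scale on which the method is defined. With \(E=2\) for all
genes, log2 quantity ratios *are* CT differences, so the full-panel geNorm
\(M\) and the ΔCT statistic coincide — the test suite exploits this as an
exact cross-method oracle (agreement to 1e−9 on random tables).

Ranks always use the min-tie competition convention ("1, 1, 3"), matching
how published stability tables print tied pairs.

## Consensus and gene count

The RefFinder-style consensus takes the four per-method rank vectors and
scores each gene by the geometric mean of its ranks; lower is more stable.
Ties break by arithmetic mean rank, then symbol. The package integrates
its own four rankings (the web tool recomputes sub-rankings internally);
this keeps the consensus exactly auditable from the printed tables it
consumes, and the shipped worked example reproduces a published ten-gene,
nine-condition-set integration from the printed ranks alone.

How many reference genes are enough is decided by geNorm pairwise
variation: with genes in stability order, \(V_n\) is the SD across samples
of \(\log_2(NF_n/NF_{n+1})\), where \(NF_n\) is the per-sample geometric
mean quantity of the top \(n\) genes. The smallest \(n\) with
\(V_n < 0.15\) is chosen; when nothing passes the cutoff the \(n\) with
the lowest \(V\) is recommended (ties to the smallest \(n\)). As a
pragmatic check, the Pearson correlation between \(NF_3\) and
\(NF_{chosen}\) is reported — computed on \(\log_2 NF\), since NF is a
geometric-mean quantity; the linear-scale \(r\) is reported alongside
because published figures rarely say which scale they used.

## Target-gene validation

2^−ΔΔCT expression uses the arithmetic mean of reference CTs (equivalently
the geometric mean of reference quantities at \(E=2\)); the calibrator
level's expression has geometric mean 1 by construction, and the
calibrator defaults to the first level in metadata order because published
workflows rarely name theirs. An efficiency-corrected ratio mode is
available behind a flag and coincides with 2^−ΔΔCT at \(E=2\). Group
differences use classical one-way ANOVA with Tukey HSD, and the compact
letter display is built by the insert-and-absorb algorithm; every emitted
display is checked in the tests by a brute-force verifier (groups sharing
a letter must not differ at \(\alpha\); differing groups must share none)
and against an independent multiple-comparison implementation.

## The synthetic generator

`simulate_ct_dataset()` draws
\(CT_{i,(l,r,t)} = \mu_i + b_{il} + e_{ilr} + u_{ilrt}\) with per-level
drift \(b_{il}\sim N(0,\tau_i^2)\), biological noise
\(e\sim N(0,\sigma_{bio,i}^2)\) and technical noise
\(u\sim N(0,\sigma_{tech}^2)\). Additive Gaussian error on CT is the
natural assumption because CT is log-scale fluorescence. The "true
stability order" planted in the ground truth is ascending
\(\sqrt{\tau_i^2+\sigma_{bio,i}^2}\) — the total per-sample dispersion
that pairwise-SD methods measure. `paper_design_preset()` reproduces six
experimental layouts of a multi-condition insect survey (8 developmental
stages, 4 larval tissues, 6 adult tissues, 4 rearing densities,
2 photoperiods, 2 temperatures; 3 biological × 3 technical replicates per
level) over a ten-gene panel whose baseline CTs follow the published mean
CTs of that survey (28S at 10.7 up to TBP at 25.9; 18S, whose mean is not
printed, is set to 12 beside 28S at the high-expression end). Where the
survey reports no magnitudes, defaults were fixed once at realistic
RT-qPCR values and not tuned: \(\sigma_{bio}=0.3\) CT,
\(\sigma_{tech}=0.15\) CT, \(\tau=0.2\) CT for stable genes and
\(\tau=1.0\) CT for the three genes the survey found condition-sensitive
(18S, 28S, β-actin).

What the generator does *not* emulate: amplification-curve artefacts,
inhibitors, pipetting batch effects, non-Gaussian outliers, or
between-gene correlation of biological noise. Passing recovery tests
therefore show the statistics behave correctly under their own model
assumptions, not that any particular field dataset satisfies those
assumptions.

## Calibration of the recovery claims

Two planted-truth suites anchor the statistical behaviour, both run at
sizes chosen to finish in seconds on one core. NormFinder single-group
variance recovery uses 10 genes × 1000 samples over 20 seeds (observed
mean relative error ≈ 3%, asserted < 5%); the grouped mode must flag a
gene with a 2-CT between-group shift as least stable in ≥ 95% of 200
seeds. End to end, a gene with \(\tau = 1.5\) CT drift against nine
stable companions (6 levels × 3 replicates, \(\sigma_{bio}=0.3\)) must be
ranked last by the consensus in ≥ 95% of 200 seeded runs; with all
\(\tau = 0\) the final consensus ranks must be near-uniform (pooled
chi-square over the 10 × 10 gene-by-rank table, \(p > 0.01\)). The
thresholds were fixed with the study conditions before freezing the seeds,
and the seeds are not tuned.

## Numerical choices and degenerate inputs

All sample SDs use the \(n-1\) divisor except the BestKeeper MAD. CT
values must lie in (0, 45); amplification bases must exceed 1. geNorm
needs ≥ 3 genes (after the final exclusion a pair remains), NormFinder
≥ 3 genes (the \(k/(k-2)\) corrector), BestKeeper ≥ 3 samples, ANOVA
≥ 2 values per group. Zero-variance NF vectors make the NF correlation
undefined and it is reported as absent rather than guessed. Standard
curves with non-negative slope are flagged invalid with no efficiency.
Negative variance estimates in NormFinder truncate at zero. Parsing is
order-invariant and duplicate CT cells are hard errors naming the cell.

## A worked run

```{r example}
sim <- simulate_ct_dataset(paper_design_preset("developmental_stages",
                                               seed = 1))
t <- collapse_technical_reps(sim$ct)
q <- ct_to_quantity(t)

cons <- reffinder_consensus(list(
  genorm(q), normfinder(q, normfinder_groups(t)),
  bestkeeper(t), delta_ct(t)))
cons$ordering
rev(sim$truth$true_order)[1:3]   # planted least-stable genes
gene_count_analysis(q)
```

The planted unstable genes surface at the bottom of the consensus, and the
pairwise-variation rule reports how many of the top genes a normalization
factor needs.

## Limitations

The per-method stability values of any real published survey can only be
reproduced from its raw CT tables; where those are unpublished, the
consensus stage can still be replayed exactly from printed ranks (as the
shipped worked example does), but upstream statistics can be validated
only against planted synthetic truth and cross-method identities. The
BestKeeper stage reports correlations against the index but, like the
original tool, does not iterate index refinement. Confidence intervals on
stability values are out of scope.
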