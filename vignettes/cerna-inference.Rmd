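---
title: "Inferring hair-cycle ceRNA networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring hair-cycle ceRNA networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernet)
```

## The biological model

Murine hair follicles cycle through growth (anagen), regression (catagen)
and rest (telogen); the first two postnatal cycles are synchronized, which
makes dorsal-skin transcriptomes at P14/P17/P23 a clean three-group design.
Under the competing endogenous RNA (ceRNA) hypothesis, cytoplasmic lncRNAs
sequester ("sponge") miRNAs and thereby de-repress the miRNAs' mRNA
targets. A regulatory triplet lncRNA–miRNA–mRNA is therefore plausible when
four observations line up:

1. the miRNA's expression **rises** from anagen to telogen,
2. the mRNA is a target of the miRNA and **falls** over the same transition,
3. the lncRNA interacts with the same miRNA, is **not exclusively
   nuclear**, and also falls, and
4. the lncRNA is sponged by enough distinct miRNAs to be a credible ceRNA
   hub.

`cernet` implements this cascade as composable, file-to-file stages with a
single configuration object, and ships a synthetic-data generator whose
ground-truth manifest makes the whole chain testable end to end.

## The screening statistics

**miRNA screen.** For each miRNA we compute linear-scale phase means and
the two log2 fold changes FC(telogen/anagen) and FC(catagen/anagen). A
miRNA is selected when its p-value is below `mirna_p` (default 0.001, the
convention for pre-computed microarray p-values) *and both* fold changes
strictly exceed `mirna_log2fc` (default 1, i.e. two-fold at each step of
the cycle). The dual criterion encodes the monotone rise A < C < T rather
than a single endpoint contrast. When no external p-values are supplied the
package computes a one-way fixed-effects ANOVA across the three phases on
log2 values; this is a documented substitute for the upstream microarray
statistics, not a reproduction of them.

**Differential expression.** Telogen-vs-anagen (or any two-group) calls
use a two-sided Welch t-test on log2 intensities, with fold change taken
as the ratio of linear-scale group means. A gene is `up` when
p < `mrna_p` (default 0.05) and FC > `mrna_fc` (default 2), `down` when
p < `mrna_p` and FC < 1/`mrna_fc`. Deliberately, no multiple-testing gate
enters the call — the selection rule is the classical p + fold-change
filter — but BH q-values are reported alongside for information. We chose
a plain Welch test over moderated (empirical-Bayes) statistics so the
procedure has no fitted hyperparameters; consequences: slightly less power
at very small n, and no claim of reproducing counts obtained with
moderated pipelines. A paired mode (samples matched by column order) is
available for paired designs such as bald/haired biopsies from the same
scalp.

**Target integration.** miRNA→mRNA predictions from several databases are
intersected: a pair survives only if present in *every* required source
and carrying an experimental-evidence flag; prediction-only pairs are
dropped. miRNA→lncRNA interactions are filtered on subcellular
localization: exclusively nuclear lncRNAs are excluded (they cannot sponge
cytoplasmic miRNAs), while `cytoplasm`, `both` and `unknown` are retained
— only a positive nuclear annotation contradicts the ceRNA mechanism, and
well-known sponges carry nuclear annotations in some databases. Candidate
sponges must then be targeted by at least `min_sponge_degree` (default 3)
*distinct* miRNAs.

**Assembly.** Triplets are the exhaustive join of surviving
lncRNA–miRNA and miRNA–mRNA pairs on the shared miRNA, gated by the
direction constraints (miRNA up; mRNA and lncRNA down). Anticorrelation is
thus a direction-consistency check on phase-wise changes, not a Pearson
threshold — with three phase means per feature a correlation coefficient
would be mostly noise, while the direction pattern is exactly what the
screens established. The network object carries the triplet list, the two
deduplicated bipartite edge lists and per-class node sets, and exports to
SIF with deterministic lexicographic ordering.

**Enrichment.** Over-representation of a gene list in a GMT collection is
the hypergeometric upper tail P(X ≥ k) (equivalently a one-sided Fisher
exact test), BH-adjusted across all tested sets. The default universe is
the union of collection members — the measured-background convention —
because web-service backgrounds are not reproducible. Depletion is out of
scope.

**qPCR quantification.** Relative expression uses 2^−ΔΔCt: technical
replicates are averaged per (sample, gene); ΔCt subtracts the
reference-gene Ct (Gapdh or U6, chosen explicitly per run) within each
sample; ΔΔCt subtracts the *group-mean* calibrator ΔCt (per-sample
calibration is the other convention; the group mean is the package
default because validation designs summarise per group). Group contrasts
use Welch's t (two groups) or one-way ANOVA (three or more), with the
usual significance-star bins.

## Identifier and numerical conventions

* Gene/lncRNA symbols are matched case-insensitively and stored in murine
  canonical case (`Gspt1`); miRNA ids are matched after stripping species
  prefixes (`mmu-`, `hsa-`) and normalizing the `miR-` capitalization.
  Interaction tables from human-centric databases then join cleanly with
  murine expression data.
* Linear intensities are floored at `expression_floor` (default 1
  microarray unit, a background floor) before any ratio or log, which
  bounds fold changes and avoids infinities; `log2_fold_change()` itself
  refuses non-positive means.
* Both screening inequalities are strict (`>`), so a fold change exactly
  at the threshold does not pass.
* Output orderings are deterministic everywhere (screen records by
  descending log2 FC(T/A) with id tie-break; triplets and edges
  lexicographic), so reruns are byte-identical.
* Missing expression cells are rejected at load time; features may be
  dropped on request, but imputation is never performed.

## The synthetic-data generator

`simulate_expression()` draws baseline log2 abundances from N(8, 2) — a
standard microarray abundance model — and plants monotone effects:
up-features gain `0.6 × effect_log2fc` log2 units in catagen and
`effect_log2fc` in telogen (down-features mirror this), with i.i.d.
N(0, `noise_sd_log2`) log2 noise. The default bundle
(`simulate_cerna_bundle()`) uses 200 miRNAs, 2000 mRNAs and 50 lncRNAs
with 3 samples per phase, 10 planted triplets over 2 sponge lncRNAs
(each sponged by 5 distinct miRNAs, comfortably above the degree screen),
`effect_log2fc = 2.5` and `noise_sd_log2 = 0.2`. The effect size was
fixed so the *catagen* leg of a planted miRNA (0.6 × 2.5 = 1.5 log2
units) sits clearly above the screening threshold of 1, matching the
magnitude of the catagen fold changes actually observed in the published
hair-cycle screen (roughly 1.1–2.6); the noise level is a realistically
quiet microarray. Decoy interactions are constructed to fail at least one
filter — a strict subset of sources, prediction-only evidence, or nuclear
localization — so any decoy surviving integration indicates a defect, not
bad luck.

What the generator does **not** emulate: probe-level artifacts and
normalization residue, correlated noise between features, mechanistic
titration between sponge and target (coupling is encoded only through
planted effect directions), isoform families, or sequence-level target
sites. Passing the end-to-end recovery test therefore demonstrates that
the cascade's logic is correct under its own statistical assumptions, not
that real GEO series would yield the published gene lists.

## Problem sizes and runtime choices

The test suite and the acceptance script run the published 11-row screen
(deterministic, instantaneous), the default synthetic bundle over 10 seeds
(a few hundred milliseconds per run), a 2000-gene null for type-I
calibration, 200 random hypergeometric tables against the Fisher oracle,
and brute-force assembly cross-checks on instances up to 50 nodes per
class. These sizes were chosen to keep every stochastic check
well-powered while the whole suite completes in well under a minute.

## Known limitations

* The DE stage is a generic two-group Welch/paired t; multi-timepoint
  designs must be collapsed to two groups by the caller.
* Evidence flags are consumed as curated input, not mined; the package
  cannot detect stale or wrong evidence annotations.
* Enrichment results depend on the supplied GMT and universe; term-level
  agreement with web services is out of scope by design.
* No amplification-efficiency correction (Pfaffl) in the qPCR module;
  2^−ΔΔCt assumes near-perfect doubling per cycle.

## A minimal worked run

```{r example, eval = FALSE}
library(cernet)

# synthetic bundle + full cascade
dir <- tempfile()
manifest <- run_cerna_pipeline(run_config(seed = 42L), outdir = dir,
                               simulate = TRUE)
str(manifest$counts)

# published worked example: the dual screen on the 11 reported miRNAs
tab <- hair_cycle_mirnas()
m <- as.matrix(tab[, c("anagen", "catagen", "telogen")])
rownames(m) <- tab$mirna; colnames(m) <- c("A", "C", "T")
expr <- phase_expression_matrix(m, c(A = "anagen", C = "catagen",
                                     T = "telogen"))
screen_mirnas(expr, p_values = setNames(tab$p_value, tab$mirna))
```
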