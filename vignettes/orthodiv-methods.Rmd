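---
title: "Measuring cross-species divergence of obesity-induced expression changes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cross-species divergence of obesity-induced expression changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthodiv)
```

## The question and the statistic

Obesity changes gene expression in skeletal muscle, but not identically in
every species. Given bulk RNA-seq of obese and lean individuals in pig,
mouse and human, `orthodiv` asks, per 1:1:1 ortholog triple: how variable is
the obesity response across the three species?

Per species $s$ and gene $g$, the response is the log2 fold change

$$\lambda_{gs} = \log_2 \frac{\bar\mu_{gs}^{\text{obese}} + c}{\bar\mu_{gs}^{\text{lean}} + c},$$

computed on median-of-ratios-normalized counts with pseudocount $c = 0.5$.
The divergence statistic is the sample standard deviation (denominator
$n-1 = 2$) of the triple $(\lambda_{g,\text{pig}}, \lambda_{g,\text{mouse}},
\lambda_{g,\text{human}})$ after two noise controls:

1. **Empirical-Bayes shrinkage.** Low-count genes produce wildly noisy fold
   changes. Each $\lambda$ is replaced by the normal–normal posterior mean
   $\tilde\lambda = \lambda \,\tau^2 / (\tau^2 + \mathrm{se}^2)$, where
   $\tau^2 = \max(0, \widehat{\mathrm{Var}}_g(\lambda) -
   \overline{\mathrm{se}^2})$ is a per-species moment estimate of the prior
   variance. Precise genes ($\mathrm{se} \to 0$) keep their estimate; noisy
   genes are pulled toward zero.
2. **Low-expression zeroing.** A gene whose TPM exceeds 0.25 in fewer than
   half of the replicates of both conditions is considered unexpressed in
   that species, and its fold change is set to 0 before taking the SD.

Candidate triples are those differentially expressed in at least one
species (p < 0.05, |log2FC| > 1, expressed — all strict). Candidates are
then split by nearest-rank quartiles of the SD into high (top 25%), medium
(middle 50%) and low (bottom 25%) divergence; with all-distinct SDs this is
exactly 25/50/25. Sign patterns over $\{+,0,-\}^3$ at the |log2FC| > 0.3
threshold separate conserved responses from species-specific and
opposite-sign ones.

## The error model

The standard error of a log2 fold change comes from the delta method under
a negative-binomial model (variance $\mu + \phi\mu^2$):

$$\mathrm{se}^2 = \frac{1}{\ln^2 2}\left[\frac{1/\hat\mu_o + \hat\phi}{n_o}
 + \frac{1/\hat\mu_l + \hat\phi}{n_l}\right].$$

$\hat\phi$ is a tagwise method-of-moments estimate squeezed toward the mean
dispersion with prior weight $d_0 = 10$ (in residual-df units). The DE test
is the two-sided Wald test $z = \lambda/\mathrm{se}$ against the standard
normal, with $p = 1$ for degenerate all-identical genes. On 2000 simulated
null genes (10 vs 10 replicates, $\phi = 0.05$) the empirical type-I error
at nominal 0.05 sits near 0.04, inside the package's acceptance band
[0.03, 0.07].

One subtlety matters for the normalization-robustness comparison below: the
se of a log *ratio* is invariant to multiplying a gene's expression by any
constant, so the error model is always estimated on the count scale.
TPM rescales each gene by $10^6/(\text{length}_g \cdot \text{depth})$;
plugging TPM means into $1/\mu$ would understate the Poisson noise of short,
highly-scaled genes and under-shrink exactly the low-count genes the
shrinkage exists for. `expression_changes()` therefore lets the
normalization route choose the expression values while the dispersion and
se come from median-of-ratios-normalized counts.

## Robustness of the divergence SD to normalization

`normalization_robustness()` runs the full expression + divergence stages
twice — once on median-of-ratios normalized counts, once on TPM — and
correlates the two per-gene SD vectors over shared candidates. On the
default synthetic study the Pearson r is ≥ 0.995 across seeds; the
package's acceptance check asserts r ≥ 0.99, and `scripts/acceptance.R`
recomputes it end to end.

## What the generator plants, and why these defaults

`sim_config()` defines the study conditions: 3 species × 2000 ortholog
triples × 10 obese + 10 lean replicates, NB counts with dispersion
$\phi = 0.05$ (typical for inbred/controlled designs), per-gene baseline
log2 mean counts uniform on [0, 11] (so genuinely low-expressed genes
exist and exercise the shrinkage and zeroing paths), and per-sample depth
factors U(0.7, 1.4) so normalization is non-trivial.

Each gene gets one of four effect classes: **conserved** (same planted
log2FC, magnitude 2, in all species; 24%), **species_specific** (effect in
one random species; 4.5%), **inverse** (pig's sign opposite to mouse and
human; 1.5%), and **null** (70%). The mix encodes the biological prior
that most obesity responses are shared across mammals while a minority are
species-specific or sign-flipped; it also implies that the divergent
classes make up about a fifth of the DEG-filtered candidates, so a
successful analysis should place essentially all of them in the top-25%
(high) class — which is what the parameter-recovery check asserts (≥ 80%
of species-specific/inverse genes in high; ≥ 80% of conserved genes in
low ∪ medium).

Downstream truth is planted analogously: a TATA-box consensus inside the
[+200, −50] TSS window (at the canonical −30 position, transcribed-strand
oriented) and a Gardiner–Garden & Frommer-compliant CpG island (length
≥ 200, GC ≥ 0.5, obs/exp CpG ≥ 0.6) spanning the TSS, with per-class
planting rates; conservation tracks with per-class mean levels; ATAC peaks
inside the [+2200, −500] promoter window with per-reference usage labels
(species-specific / usage-specific / usage-conserved) realized by
including or omitting synteny blocks and homologous reference peaks, minus
orientation included; eQTLs inside a configurable fraction of the OCR
windows; and 11-species gene-family tables whose expanded/contracted rows
satisfy the median-of-other-species rule by construction. CpG-island
generation is part of the synthetic study design (real analyses consume a
CGI annotation track); the shipped TATA matrix (`tata_pwm()`) is likewise
synthetic, derived from the TATAAAAG consensus rather than from a motif
database.

All randomness flows from a single master seed through per-output
sub-streams, so a fixed seed gives byte-identical outputs and partial
re-runs stay reproducible.

## Supporting stages

- **GSEA** (`enrichment_score`, `normalize_es`): the weighted
  Kolmogorov–Smirnov running sum with weight exponent p = 1 (the common
  software default), leading edge = set members at or before the peak (at
  or after, for negative ES). NES and p come from gene-label permutations
  preserving set size (the phenotype-permutation alternative needs raw
  per-sample ranks that a ranked-list interface does not carry);
  $p = (1 + \#\{|ES^\ast| \ge |ES|, \text{same sign}\}) / (1 + n_{\text{same sign}})$.
  Ranking ties break by gene id, permutation ES values use the identical
  tie rule as the full running sum (first position at the maximal
  |deviation|, 1e-9 tolerance).
- **ORA**: upper-tail hypergeometric with BH adjustment, as a stand-in for
  web enrichment services.
- **Gene families**: the expansion/contraction flag is p < 0.05 (an
  external birth–death p-value, consumed as input) AND focal copies
  strictly above/below the median of the other species. Direction
  enrichment uses a one-sided (greater) Fisher test on copies × direction,
  fold = observed/expected direction proportion; the universe is all
  copies with measured fold change.
- **Motifs**: log-odds scanning with exact p-values from a dynamic
  programme over the discretized score distribution (bin 0.01 bits —
  enumeration-exact on that grid, verified against full $4^w$ enumeration);
  default match threshold p ≤ 1e-4. Backgrounds are per-sequence
  mononucleotide shuffles (composition-preserving). TATA scans are
  strand-aware (transcribed strand only: the element is directional); OCR
  motif enrichment scans both strands. AME-style enrichment is Fisher on
  sequence-level presence with BH q < 0.05.
- **Promoter architecture**: windows are "a upstream / b downstream" in
  transcription orientation, 0-based half-open internally (BED-native);
  overlap is ≥ 1 bp, so abutting intervals do not overlap. Conservation
  profiles anchor on the TSS (position 1 = TSS−1, strand-aware), median
  over covered bases only (missing bases excluded, not imputed), Wilcoxon
  rank-sum between classes (p = 1 for all-tied degenerate input); TATA and
  CGI fractions compare classes by Student's t across per-species values,
  matching the test named for each comparison.
- **OCR synteny**: peaks are anchored on the summit when present
  (narrowPeak column 10) else the midpoint, extended to 501 bp, shifted
  inward at chromosome edges. Lifting uses explicit synteny-block maps
  with min_cover = 0.95 (mirroring liftOver's default minMatch) and
  orientation-aware affine transforms; classification is one-way (focal →
  reference). The eQTL test draws, per permutation, one uniform 501-bp
  window inside each OCR's own promoter, and uses the add-one permutation
  p-value.
- **dN/dS**: Nei–Gojobori (1986) pairwise estimates with equal-weight
  pathway averaging (stop-traversing paths excluded unless all paths hit a
  stop) and Jukes–Cantor correction; omega is missing when dS = 0 or a
  proportion reaches 3/4. This is a deliberate, documented estimator
  choice for a self-contained package — branch-site likelihood models are
  a different (and heavier) machinery, and outputs are labelled
  accordingly. Class comparisons use the equal-variance t-test (Welch
  behind a flag).

## Numerical and degenerate-case decisions

- Size factors rescale to geometric mean 1; they are undefined (explicit
  error) when no gene has all-positive counts.
- All-zero samples get TPM 0 with a warning; all-identical log2FCs give
  $\tau^2 = 0$ and all-zero shrunken values.
- All-identical SDs classify everything medium with a warning.
- Batch adjustment is per-gene one-factor mean centering on
  log2(normalized + 1) — the single-factor no-covariate case of standard
  linear-model batch removal; it is idempotent and warns when batch is
  perfectly confounded with condition.
- "Exactly half the replicates above the TPM threshold" counts as
  expressed ("at least half"); the low flag requires failing in both
  condition groups, the permissive reading that keeps on/off genes.
- Ties at quantile boundaries share the class of their value; the high
  class uses strict ">".

## Problem sizes and runtime

The default study (3 × 2000 × 20 samples) runs the expression + divergence
stages in seconds; the full pipeline including annotation, ATAC and dN/dS
stages (`run_pipeline(sim_config())`) completes in about two minutes on one
CPU. Property suites enumerate small instances exhaustively: all subsets of
8-gene ranked lists, all sense-codon pairs (61 × 61), all $4^w$ windows for
motif widths ≤ 6, and Wilcoxon/Fisher tables small enough for full
enumeration.

## What passing tests do and do not show

The generator draws independent NB counts per gene with exchangeable
replicates: no gene–gene correlation, no outlier samples, no GC or
length biases within a species, no mappability artifacts, and a single
optional batch factor. Passing recovery tests therefore demonstrates that
the statistics identify the structures they define — not that real
cross-species data meet these assumptions. In particular, real ortholog
sets carry annotation-quality differences between genomes that the
identity ortholog map cannot emulate, and cohort-scale biological
quantities (DEG counts, candidate-list sizes, per-class OCR densities)
depend on the particular animals and datasets studied and are not
reproduced by simulation.
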