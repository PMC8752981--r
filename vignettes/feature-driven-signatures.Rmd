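---
title: "Feature-driven mutational signature analysis with featsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-driven mutational signature analysis with featsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(featsig)
```

## The problem

Somatic mutations in a cancer genome are the cumulative footprint of
mutagenic exposures and failing repair pathways. The standard summary is the
96-channel trinucleotide spectrum: every single-base substitution is
collapsed onto the pyrimidine strand and classified by substitution type
(C>A, C>G, C>T, T>A, T>C, T>G) and its 5'/3' flanking bases. A *mutational
signature* is a probability distribution over those 96 channels attributed
to one process — APOBEC cytidine deaminases, mismatch-repair deficiency
(MMRd), POLE proofreading loss, homologous-recombination (HR) deficiency,
and so on.

Most signature work is either *de novo* extraction (NMF over a cohort) or
*refitting* (estimating nonnegative exposures of known signatures in each
genome). `featsig` implements a third, supervised route: when a genomic or
phenotypic **feature** with a suspected mutagenic consequence is measured
per sample — APOBEC3A expression, MLH1 expression and promoter methylation,
POLE mutation status, copy-number-derived HR-deficiency scores (NtAI, LST,
HRD-LOH), mRNA-based hypoxia scores — a signature can be derived *directly
from the feature* as the differential trinucleotide frequencies between
feature-high and feature-low genomes, and the level of that derived
signature can then be read back out of any genome's spectrum by metagene
projection, serving as a mutation-based proxy for the original feature.

## Pipeline and model

**Spectra.** `build_spectra()` classifies SNVs via `classify_substitution()`
(purine-reference records are reverse-complemented, so spectra are invariant
under strand flips), tallies per-sample channel counts, and tracks TMB as
the number of all accepted somatic calls (SNVs plus indels and other
substitutions); only SNVs fill channels, so TMB >= SNV count always.
Coordinates are 1-based with context taken at `pos - 1` and `pos + 1` (MAF
convention). Duplicate records (same sample/chrom/pos/alt) are removed;
reference mismatches, unknown chromosomes and ambiguous contexts are
skipped with warnings, not errors. Samples with fewer than 50 SNVs are
flagged ineligible for signature analysis — below that, a 96-bin frequency
vector is mostly sampling noise — but kept for burden-level analyses.

**Refitting.** `refit_exposures()` solves the convex problem
`min || f - t(P) w ||` over `w >= 0`, where `f` is the genome's normalized
spectrum and `P` the K x 96 row-stochastic catalog, using nonnegative least
squares; signatures with relative weight below 6% are then zeroed and the
reduced problem re-solved, mirroring the conventional exposure cutoff.
Compared with iterative forward-selection refitters this is deterministic
and has a single optimum; on subcatalogs of two or three signatures it
agrees with an exhaustive simplex grid search to well under one weight
percentage point (tested). Weights are not forced to sum to 1 — the
residual absorbs unexplained mass — but are rescaled if the unconstrained
optimum overshoots 1, and `renormalize = TRUE` gives proportions. Exposures
are reported both as proportions and as mutation counts
(`weights * n_snv`), since either scale is a legitimate "signature level"
for correlation work.

**Feature-driven signatures.** `stratify_samples()` supports three designs:
extreme percentiles of a continuous feature (default 95th/5th), a median
split, and binary status. The quantile is R's default (type 7) with
inclusive comparison, a deterministic rule whose behaviour on `1..100` is
`{96..100}` vs `{1..5}`. `differential_signature()` takes the mean of
per-sample normalized frequencies in each group and subtracts low from
high; `invert = TRUE` swaps the groups, the natural call for
deficiency-driven features (for MLH1 the *low*-expression genomes are the
mutagenic ones). The positive part of the differential, renormalized, is
the feature-representing signature; the sign-flipped negative part
represents the opposite pole; the two always have disjoint support. We use
means of per-sample frequencies rather than pooled counts so a single
hypermutant cannot dominate its group; `pooled = TRUE` implements the
alternative. Groups below 10 samples warn (below 3, error): the variance of
a 96-bin mean from a tiny group makes differentials unusable.

**Projection.** `project_levels()` stacks a pair into the 96 x 2 basis
`M = [pos, neg]` and applies `MASS::ginv(M)` to each genome's normalized
frequency vector. For any spectrum in the span of the pair this recovers
the mixing coefficients to machine precision. Spectra are normalized per
genome only; no across-genome column standardization is applied — we read
"normalized mutation frequencies" as per-genome frequencies, and document
that a column-standardized variant is a possible alternative reading.
Unconstrained projection can return small negative levels on genomes
outside the cone of the pair; they are reported as-is with a warning count
because silently truncating would bias downstream correlations, and
`nonneg = TRUE` provides the constrained fit (identical whenever the
unconstrained solution is already nonnegative). `score_concordance()`
correlates the projected levels with the originating score; a pair derived
from a score should give `r_pos > 0` and `r_neg < 0`.

**Comparison with known signatures.** `similarity_matrix()`, `hcluster()`
(distance `1 - cosine`, average linkage by default; leaves pre-sorted by
name so ties break deterministically) and `nearest_known()` implement the
usual catalog comparison; `first_merge_partners()` answers "which
signatures does the derived one co-segregate with first". Cosine with
average linkage is the field's default choice; Euclidean/complete variants
are exposed through the `linkage` argument should a user prefer them.

**Correlation layer.** `correlate_features()` produces ranked Pearson
tables (`log2(x + 1)` transforms where requested, BH q-values appended —
raw p-values remain the primary output, matching common practice).
`four_class_stratify()` median-splits two features ("hi" strictly above the
median, so the rule is deterministic under ties) and `compare_levels()`
runs Welch's t-test between any two classes; Welch is the safer default
when class sizes are unequal, as they always are after median splits of
coupled features.

## The synthetic cohort generator

Real inputs at PanCancer scale are controlled-access, so the package ships
a fully seeded generator whose defaults *are* the study conditions used in
the test-suite and acceptance runs:

* **Catalog.** `preset_catalog()` builds six stylized synthetic shapes —
  Clock.like (C>T at NpCpG), APOBEC.CtoT / APOBEC.CtoG (C>T / C>G in TpC),
  MMRd.like, POLE.like, and a broad HRD.like spread over the channels the
  focal five leave empty. They are identifiable (all pairwise cosines
  < 0.8) and deliberately not the published COSMIC profiles;
  `read_cosmic_catalog()` ingests the real ones. `make_catalog()` draws
  random sparse-Dirichlet catalogs with a rejection step enforcing the same
  identifiability bound.
* **Activities and exposures.** Each causal process has a log-normal latent
  activity `A = exp(0.6 z)`, `z ~ N(0,1)`. The causal signature's exposure
  share is *linear* in the standardized activity
  (`share = 0.30 + 0.15 * stdA`, floored at 0, causal total capped at
  0.85), and the remaining mass is split across non-causal signatures by a
  symmetric Dirichlet. The linear link is the key design choice: a
  multiplicative tilt saturates at the activity extremes and quietly
  destroys the correlation between feature and projected signature level,
  whereas the linear map transmits the configured coupling through the
  whole pipeline. The cap binds only in the far tail (~2% of genomes).
* **Spectra.** Counts are multinomial draws from the per-genome mixture
  profile. Burdens are either fixed (2,000 in the standard runs) or
  log-normal with median 600, log-sd 1.1, clamped to 50–10,000 — the span
  of typical exome cohorts.
* **Features.** A continuous feature is `rho * stdA + sqrt(1 - rho^2) * e`,
  so its realized correlation with the activity is the requested coupling
  (tested to within ±0.1 at n >= 300). Binary status features threshold
  the activity at a configured prevalence (default 15%) and flip labels
  with probability `(1 - |rho|)/2`. Anti-coupled readouts (e.g. promoter
  methylation vs expression) are modeled as a second feature with opposite
  sign on the same latent.
* **Presets.** `simulate_scenario()` ships five designs: `apobec`
  (APOBEC3A expression, +0.8, with an anti-coupled NHEJ1 modifier), `mlh1`
  (expression −0.8 plus methylation +0.7, derivation inverted), `pole`
  (binary, 0.8), `hrd` (three scores on one latent) and `hypoxia` (one
  score driving both APOBEC signatures, plus an APOBEC3A expression
  readout). Single-gene presets use coupling 0.8; the score-based presets
  (hrd, hypoxia) default to 0.85 because aggregate copy-number/mRNA scores
  are direct readouts of the latent process, tighter than any single gene's
  expression. Note the information-theoretic consequence: the correlation
  between a projected signature level and the score can never exceed the
  score's own coupling to the activity, so these defaults put the expected
  concordance around 0.84.
* **Round trips.** `write_maf()` materializes any count matrix as a MAF on
  a synthetic context-scaffold FASTA (every mutation gets its own
  position, so duplicate-removal cannot eat records); re-ingestion through
  `build_spectra()` reproduces the counts exactly and the files are
  byte-stable, which pins down the whole reader/classifier path.

What the generator does *not* emulate: genomic position structure
(replication timing, chromatin), signature profiles evolving across
cohorts, purity/ploidy artifacts, and inter-sample contamination. Passing
tests therefore certify the estimators' statistical behaviour under the
assumed generative model, not robustness to real-data artifacts.

## Worked example

```{r example}
cohort <- simulate_scenario("hrd", n_samples = 300, seed = 7)
pair <- derive_scenario_signature(cohort)
pair

nearest_known(pair$pos, preset_catalog())

levels <- suppressWarnings(project_levels(cohort$spectra, pair))
scores <- setNames(cohort$features$NtAI, cohort$features$sample_id)
round(score_concordance(levels, scores), 3)
```

The derived positive signature is essentially the HRD-like catalog profile,
and its projected level correlates strongly (positively) with the NtAI-like
score it came from, while the normoxia/low-score signature level correlates
negatively — the sign pattern that makes a feature-driven pair usable as a
mutation-based score proxy.

## Numerical choices and limitations

* Problem sizes in the standard validation runs (300 genomes, 2,000
  mutations each, 20–100 replicates per property) were chosen so the whole
  suite exercises every stage at realistic scale while remaining quick on a
  laptop.
* NNLS is solved by an active-set method (`pracma::lsqnonneg`); the
  threshold-and-refit step is a hard cutoff, not a penalty, so exposures
  below 6% are exactly zero.
* All-zero spectra, constant features, collinear or zero signature pairs,
  and sub-minimum groups raise informative errors rather than propagating
  NaNs.
* Derived differential signatures are relative objects: they depend on the
  cohort's composition (what the low group looks like matters as much as
  the high group). They should be interpreted within the cohort that
  produced them, or validated by refitting in an independent one.
* The correlation layer reports association, not causation; the package
  deliberately stops short of any mechanistic claim.
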