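---
title: "Targeted epigenetic clocks for mice: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted epigenetic clocks for mice: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readclock)
library(dplyr)
```

DNA methylation (DNAm) at a small number of age-associated CpG sites is
a practical biomarker of aging in mice: a linear model over the DNAm
levels of a handful of CpGs predicts chronological age to within a few
weeks, and deviations of that prediction track biological aging (they
are accelerated in shorter-lived strains). `readclock` implements the
three targeted measurement routes such clocks are built on --
pyrosequencing-style DNAm tables, droplet digital PCR (ddPCR), and deep
bisulfite amplicon sequencing -- together with a single-read age
estimator that exploits the binary methylation pattern of individual
DNA strands, and a synthetic cohort generator so that the entire
pipeline can be exercised and validated without any external data.

This vignette documents the models, the tunable parameters, and the
design decisions; the README shows the quick-start workflow.

## Per-read methylation calling

Bisulfite conversion turns unmethylated cytosine into uracil (read as
T) and leaves 5-methyl-cytosine intact. An amplicon sequencing read is
therefore called positionally against the *unconverted* reference: at
each CpG cytosine, C means methylated, T unmethylated, anything else a
missing call. Because amplicon reads are fixed-layout PCR products, no
indel alignment is performed; gross misalignments are instead caught by
two per-read QC statistics:

* **conversion rate** -- the fraction of non-CpG reference cytosines
  read as T. Incomplete conversion inflates apparent methylation, so
  reads below `min_conversion` (default 0.90) are discarded.
* **mismatch fraction** -- disagreement with the reference over
  positions where the reference is not a C (C positions differ
  legitimately after conversion). Reads above `max_mismatch_frac`
  (default 0.10) are discarded.

Both defaults are conventional bisulfite-QC practice; they are fields
of the `amplicon()` spec so a panel can carry its own thresholds.
Bottom-strand reads live in G→A space and are recognized by trying the
reverse-complement interpretation and keeping whichever orientation has
the lower mismatch fraction (`orient = "auto"`). Reads shorter than the
amplicon produce trailing missing calls rather than errors; only read 1
of a pair is used (overlapping-pair reconciliation is out of scope).

CpG coordinates are 1-based offsets of the C of each CG dinucleotide on
the top strand, matching R's string indexing.

The three-amplicon default panel (*Prima1*, *Hsf4*, *Kcns1*, with 4, 12
and 21 neighboring CpGs) ships with **synthetic reference sequences**:
deterministic constructions with the right CpG counts, realistic
spacing and non-CpG cytosines for conversion QC, but not the genomic
sequences. Real panels are supplied as `amplicon()` specs or a YAML
file (see `inst/FORMATS.md`).

## ddPCR Poisson quantification

A ddPCR well partitions the reaction into $N$ droplets; a droplet is
positive in the methylated (or unmethylated) probe channel if it
received at least one copy of that species. With copies
Poisson-distributed across droplets, the mean copies per droplet is

$$\lambda_c = -\ln\!\left(1 - \frac{k_c}{N}\right),$$

where $k_c$ is the positive count in channel $c$, and the percent
methylation is $100\,\lambda_\text{meth} / (\lambda_\text{meth} +
\lambda_\text{unmeth})$. Double-positive droplets are counted in both
channels -- the convention the per-channel formula assumes. The 95%
interval propagates the binomial variance of $k_c/N$ through the log
and the ratio (delta method); a closed form was preferred over a
bootstrap because it is exactly testable. A fully positive channel is
saturated: $\lambda$ is capped at $-\ln(1/2N)$ and the estimate is
flagged rather than dropped. `ddpcr_simulate_well()` draws positives
as $\text{Binomial}(N, 1-e^{-\mu})$ -- the exact distribution under the
Poisson model -- and serves as the estimator's independent oracle.

## Clock models

All clocks are linear in the beta fractions:
$\hat a = b_0 + \sum_j c_j \beta_j$ (weeks). Two trainers:

* `train_multivariable()` -- ordinary least squares on pre-selected
  CpGs, classically the single most age-correlated CpG of each of the
  three amplicons (`select_top_cpgs()`, ties broken deterministically
  to the lower CpG index). Rank-deficient designs error, naming the
  collinear columns.
* `train_lasso()` -- glmnet with $\alpha = 1$, predictors standardized
  internally, coefficients reported on the beta scale. The penalty is
  chosen by 10-fold cross-validation over a 100-value log-spaced grid
  down to $10^{-4}\,\lambda_\max$; fold assignment is a deterministic
  shuffle under a required seed, recorded in the model metadata so a
  training run is exactly reproducible.

Rows with a missing selected beta are dropped, not imputed: cohorts are
small and imputation would be silent invention. Predictions are not
clamped -- a negative predicted age is reported as such.

`evaluate_clock()` reports the squared Pearson correlation of predicted
versus chronological age as the headline $R^2$ (robust to calibration
shifts) alongside the identity-line variant $1 - SS_\text{res} /
SS_\text{tot}$, plus median and mean absolute error in weeks. The two
$R^2$ definitions coincide only for a perfectly calibrated clock, so
both are always emitted. `fit_acceleration()` summarizes strain effects
as a least-squares trend of predicted on chronological age, linear or
logarithmic ($a \ln(\text{age}) + b$).

## Single-read age estimation

Deep amplicon sequencing reads carry a binary sequel of methylated and
unmethylated CpGs. Within a sample, neighboring CpGs are modified near
independently -- methylation accrues stochastically rather than through
coherent writer activity -- which licenses a simple per-read model:
from training-set trajectories, CpG $i$ is methylated at age $a$ with
probability

$$p_i(a) = \mathrm{clip}(\beta_{0i} + s_i a,\; \varepsilon,\;
1 - \varepsilon),$$

and a read with pattern $x$ is assigned the age

$$\hat a(x) = \arg\max_{a \in \{0, 1, \ldots, 200\}} \sum_i
\left[x_i \ln p_i(a) + (1 - x_i)\ln(1 - p_i(a))\right],$$

the maximizer of the independent-Bernoulli log-likelihood over an
integer week grid. We fix this likelihood interpretation explicitly
(the independence assumption is the one the data supports); the
likelihood tables are precomputed per model, so prediction is a single
matrix product, and an exhaustive-evaluation oracle in the test suite
confirms exact agreement including tie-breaks.

Numerical choices: grid step 1 week with fixed bounds 0 and 200;
$\varepsilon = 0.01$ by default (must lie strictly in $(0, 0.5)$ -- a
zero clip would put unmethylated calls at $-\infty$ likelihood at the
grid edge); ties resolve to the lowest age, which is deterministic and
conservative; missing calls drop out of the sum, and reads with more
than half their calls missing are excluded because near-empty patterns
otherwise pile up at boundary ages. A model needs at least two usable
CpGs -- a single site carries essentially no per-read age signal.

A sample's age is the read-count-weighted mean of its read ages
(`predict_sample_age()`), and the full predicted-age frequency
distribution over the grid is returned for heatmap rendering; the
stored distribution is linear, with the customary log10 display applied
only at plot time. Per-amplicon sample means are combined by an
(equal-weight by default) mean over amplicons.

## The cohort simulator

`sim_panel()` + `simulate_cohort()` generate the study conditions every
recovery test runs under:

* **Bell-shaped age association.** CpG $i$ of an amplicon ages with
  slope $s_i = s_\text{peak} \exp(-(i - c)^2 / 2w^2)$: age association
  peaks mid-amplicon and decays toward the edges, the positional
  profile characteristic of age-associated regions.
* **Defaults** (chosen once, as the conditions to emulate): peak slope
  0.0045 beta-fraction/week from a baseline of 0.10, spanning roughly
  half the beta range over a 0--130-week lifespan, comparable to
  strongly age-associated clock CpGs; per-sample per-CpG Gaussian
  trajectory noise of sd 0.03 on the probability scale (clipped to
  [0, 1]); ages uniform on 5--120 weeks; 2,000 reads per amplicon per
  sample, typical deep-amplicon coverage; cohort sizes 24 (training)
  and 21 (validation) in the recovery checks, matching the scale of
  real mouse clock studies. Centers sit mid-amplicon and widths (1.5,
  3, 4 for the 4-, 12- and 21-CpG amplicons) scale with CpG count.
* **Within-read dependence knob.** Reads draw each CpG independently as
  Bernoulli($q_i$) by default (`inter_cpg_rho = 0`); a positive rho
  couples CpGs through a per-read shared standard-normal latent with
  thresholds $\Phi^{-1}(q_i)$, preserving the marginals. Pooled across
  samples, age variation alone already induces the moderate
  neighbor-correlation seen in real data, so independence is the
  honest within-sample default; the knob exists to stress the
  single-read model's independence assumption.
* **Strain acceleration.** Effective age $a' = T(a)$ with $T$ identity
  (reference strain), linear $sa$, or logarithmic
  $A\ln(1 + a/\tau)$ -- smooth at 0, defaults $A = 55$, $\tau = 15$ so
  the accelerated strain predicts older than controls across the whole
  5--120-week range while flattening toward old age, the shape observed
  for shorter-lived strains.
* **FASTQ rendering.** `cohort_fastq()` writes each simulated read as a
  converted sequence (non-CpG C→T, CpG C kept iff methylated) with
  constant quality; with zero conversion-failure rate the round trip
  through calling recovers the generating pattern tables *exactly*,
  which the test suite asserts. A `conversion_failure` parameter leaves
  that fraction of non-CpG Cs unconverted to exercise the QC.

Everything is bit-reproducible under `(configuration, seed)`, and the
simulator restores the caller's RNG state.

**What the simulator does not emulate** -- and hence what passing
recovery tests do and do not show: sequencing errors beyond conversion
failure, indels, quality-score structure, PCR amplification bias
between methylated and unmethylated strands, cell-composition shifts,
and nonlinear DNAm trajectories. Recovery results on synthetic cohorts
demonstrate the pipeline's correctness and calibration under its own
model, not the field performance of any particular assay.

## Problem sizes and checks

The acceptance script and test suite run the full pipeline at the
study scale above (24 + 21 mice, three amplicons, 2,000 reads each,
FASTQ round trip) and verify: validation $R^2 \ge 0.85$ and a median
error within twice the generating inverse model's noise floor for the
3-CpG clock; $R^2 \ge 0.8$ for mean single-read predictions on the 12-
and 21-CpG amplicons; exact agreement of `predict_read_age()` with
exhaustive grid evaluation; ddPCR closed-form values and simulation
bias below one percentage point; lasso solutions no worse than an
independent proximal-gradient solver's objective plus $10^{-6}$; and
the structural mirrors (bell profile peaking at the configured center,
near-zero neighbor correlation under independence rising with rho,
systematically older and better-log-fit predictions for accelerated
strains). Smaller unit fixtures use hand-computed or brute-force
oracle values.

## Known limitations

* The default panel's reference sequences are synthetic stand-ins; use
  real amplicon sequences for real data.
* Paired-end merging and indel-tolerant alignment are out of scope;
  reads must be anchored amplicon products.
* The single-read model assumes independent CpGs and linear
  trajectories clipped to the grid; strongly coherent regions (high
  rho) will compress its dynamic range.
* ddPCR estimates assume per-channel counting of double positives; if
  an instrument exports exclusive classes, convert before import.
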