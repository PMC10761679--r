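---
title: "Methods and design of the slipir pipeline"
author: "slipir authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the slipir pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slipir)
```

## The problem

Cell-free RNA (cfRNA) circulates in plasma as short, heavily fragmented
molecules with heterogeneous 5' termini. A phosphate-independent library
design captures these fragments by appending, on read 1, a poly-A tail, an
8-nt sample barcode, and the sequencing adapter 3' of the cfRNA insert,
while read 2 starts with the same barcode followed by poly-T. `slipir`
implements the complete downstream analysis for such libraries at desk
scale: demultiplexing and trimming, construction of derived small-RNA
references, exact-match quantification, per-sample quality control,
negative-binomial differential expression, stability feature selection,
and repeated-partition classification — together with a fully seeded
synthetic-data generator that stands in for controlled-access patient
data.

## The synthetic-data generator

Every simulation is a pure function of a `sim_config()`, whose defaults
are the study conditions of the package:

* **Fragment lengths** follow Gamma(shape $\alpha$ = 10.22, rate $\beta$ =
  0.24), the maximum-likelihood fit to plasma mRNA fragment sizes under
  this library design (mean $\alpha/\beta \approx 42.6$ nt). Inserts are
  clipped to at least 15 nt (the clean-read floor) and to the read
  capacity, so that the poly-A tail, the 8-nt barcode, and at least the
  10-nt adapter seed always fit in a 150-nt read.
* **Read structure.** R1 is `insert + poly-A (10–30 nt) + barcode +
  adapter`, padded with random bases or truncated to the read length; R2
  is `barcode + poly-T`. Base qualities are constant Phred 40 by default;
  an optional fraction of reads receives Phred 2 throughout to exercise
  the quality filter. Fragments are sense-strand only, as exonic cfRNA
  reads are in this library design.
* **Count matrices** are negative binomial:
  $K_{fs} \sim \mathrm{NB}(\mu = b_f\, s_s\, 2^{\Delta_{fs}},\
  \mathrm{Var} = \mu + \phi\mu^2)$ with log-normal baselines $b_f$,
  size factors $s_s$ drawn from a uniform library-size range, dispersion
  $\phi = 0.2$, and a planted effect $\Delta_{fs} = 1.5$ log2 units in 5%
  of features for samples of the case class. Multi-class runs plant
  disjoint per-class sets plus an optional "common cancer" set shared by
  all case classes.
* **Composition.** Per-type abundance weights scale the baselines so
  expected read shares track the measured plasma composition (tsRNA
  14.4%, miRNA 10.3%, ysRNA 9.6%, lncRNA 8.4%, mRNA 7.9%, rsRNA 6.0%);
  the remaining small types (snRNA, snoRNA, piRNA) were given small
  shares of 4%, 3%, and 5% once, as plausible values for types whose
  printed shares are not available. Without this scaling, a uniform
  composition would push mRNA+lncRNA above the 30% QC limit for every
  simulated sample, which real plasma does not do.

What the generator does **not** emulate: sequencing errors beyond the
optional uniform low-quality mode, UMIs, isomiR end-heterogeneity,
batch effects, and real human reference sequences (parents are random).
Passing tests therefore demonstrate the correctness and calibration of
the analysis machinery under the stated generative model, not
performance on real plasma.

## Read processing

Assignment uses the first 8 nt of R2 with exact matching — no mismatch
tolerance, since the design gives no error budget for barcodes and
exactness maximizes specificity; `N` counts as a mismatch. Trimming
locates the adapter on R1 by an exact match of its first 10 nt, falling
back to a partial adapter prefix of at least 6 nt at the read end. The
8-nt index immediately 5' of the adapter is removed only when an adapter
was actually found, which makes trimming idempotent on already-clean
inserts. The maximal trailing A-run is then removed when at least 4 nt
long (`polyA_min`), a compromise that spares genuine short 3'-A insert
ends; an insert that truly ends in A is inseparable from the appended
tail, which is why round-trip tests quantify insert recovery on the
unambiguous (non-A-ending) subset. Reads shorter than 15 nt or with mean
Phred below 20 are rejected with a reason, not an error.

## Derived references and counting

For rsRNA/ysRNA, every distinct clean read that occurs as an exact sense
substring of a parent becomes one reference entry with a deterministic ID
`{type}-{parent}-{start}-{length}` (0-based start), ordered by (parent,
start, length); a fragment present in several parents is assigned to the
lexicographically first (parent, start), a convention the upstream design
leaves open. Counting for tsRNA/rsRNA/ysRNA requires full-length identity
(a single extra base yields no count). miRNA/piRNA and transcript-level
features use containment counting with length gates of 19 nt (miRNA) and
23 nt (mRNA/lncRNA/snRNA/snoRNA); reads contained in more than one
feature are discarded as ambiguous, mirroring the default discard of
multi-overlap assignments in genome-based counting. This containment rule
replaces genome alignment at desk scale and is slightly stricter than a
soft-clipping aligner would be; it is a documented fidelity deviation. A
read may count in several RNA-type workflows (each reference is queried
independently); no cross-type deduplication is performed.

## Quality control

Per sample the pipeline reports total, clean, and assigned ("mappable" at
desk scale) reads, per-type read shares, and species detected (RPM > 0).
Exclusion uses four strict predicates: clean-read ratio < 20%, clean
reads < 2 million, rsRNA share > 30%, mRNA+lncRNA share > 30%; a sample
exactly on every threshold is retained. The clean-read floor is a
configurable threshold because synthetic desk-scale libraries are far
shallower than 2 million reads. Fragment-length distributions are
summarized by a Gamma maximum-likelihood fit — Newton iteration on
$\log\alpha - \psi(\alpha) = \log\bar x - \overline{\log x}$, tolerance
1e-8, at most 100 iterations, $\beta = \alpha/\bar x$ — and by
non-excess kurtosis $m_4/m_2^2$, whose printed reference values (around
11–30 on heavy-tailed data) are on the non-excess scale.

## Differential expression

Size factors are median-of-ratios: the median over all-nonzero features
of the ratio of a sample's count to the feature's geometric mean (with a
positive-count fallback when no feature is everywhere nonzero). Each
feature is fit with a negative-binomial GLM (log link) on the group
indicator with log size-factor offsets. Dispersion is estimated per
feature by method-of-moments on normalized counts, pooled within groups
and floored at 1e-8, then treated as known; the Wald statistic is the
log2 fold change over its standard error (model dispersion fixed at 1,
not a re-estimated quasi-dispersion) with a two-sided normal p-value and
Benjamini–Hochberg q-values; q < 0.1 flags differential expression.
Candidates additionally require upregulation with log2 fold change
strictly above 0.8 and mean **raw** counts strictly above 10 (the raw
scale was chosen where the rule leaves the scale open; it is an
argument). Empirical-Bayes dispersion shrinkage and independent filtering
of full DESeq2 are deliberately not reproduced; correctness is
established by simulation calibration instead.

Two calibration facts, both visible in the acceptance suite, deserve
notice. First, the plug-in dispersion makes the Wald test mildly
anticonservative: the null rejection rate at $\alpha$ = 0.05 sits near
0.055 at $n$ = 50+50. Second, with one-directional planted effects
(cases up, as observed in cancer plasma where most differential cfRNAs
gain expression), the planted features inflate the case samples' size
factors, every null feature acquires a small negative shift, and the
empirical FDR of the q < 0.1 rule rises to roughly 0.2–0.35 under the
default conditions. This is a property of median-of-ratios normalization
under asymmetric differential expression — the reference NB
implementation reproduces the same numbers on identical matrices — and
is reported honestly rather than hidden by rebalancing the simulation.

## Feature selection

All three strategies run over repeated stratified 80/20 partitions (100
by default) with a selection-frequency floor of 10 of 100:

* **Top-N** walks a significance ranking (p, then q, then |log2FC|, then
  ID) starting at the top two features, evaluating each candidate set by
  the mean held-out AUC across ridge LR, random forest, and linear SVM on
  one fixed bank of partitions (so comparisons across N are paired), and
  removes any feature whose addition lowers that AUC; ties keep the
  smaller set (parsimony).
* **Boruta-style** augments the training features with per-feature
  shuffled shadow copies; a feature scores a hit when its random-forest
  permutation importance exceeds the best shadow's, and is confirmed or
  rejected by a two-sided binomial test at $\alpha$ = 0.01 over rounds
  (capped at 500). Rejected features stay in the forest rather than
  being dropped — a simplification of the canonical algorithm that only
  makes confirmation harder. Importance forests use 100 trees per round
  as a runtime choice.
* **LASSO** fits an L1-penalized logistic regression on z-scored
  features per repeat, with lambda.1se from 10-fold cross-validated
  deviance, recording non-zero coefficients.

Selector behavior depends on the feature universe: run over the full
transcriptome (as the pipeline does), the per-repeat false selections
spread over ~1000 null features and none recurs past the frequency
floor; run over an artificially truncated 50-null panel, the same mass
concentrates and precision degrades. The recovery analyses therefore use
the realistic full-matrix design.

## Classification

The repeated-partition harness fits on 80% and scores the held-out 20%,
100 times; risk scores are strictly out-of-fold (a sample is scored only
in iterations where it was held out) because in-fold scores would leak
training labels; its median is the sample's risk score, with 0.5 as the
high-risk threshold (scores at the threshold count as high). Ridge LR
(penalty by internal cross-validation, folds shrunk to at least 3 for
very small training sets), 500-tree random forests, and linear SVM with
cost 1 (decision values, not probabilities) are the three backends; risk
scores are interpreted probabilistically for LR/RF only. AUC is the
Mann–Whitney concordance with half-ties. Sensitivity is cases called
high over all cases; specificity follows the precision-style screening
definition — cases called high over all called high. Combination panels
enumerate all 31 non-empty subsets of the five candidate RNA types and
refit jointly on the concatenated panel (stacking per-type models is the
unexplored alternative). One-vs-rest classification runs each class —
plus a pooled "cancers" class — against all other samples, and the
two-step rule calls a sample positive only when the common cancer score
and at least one type-specific score are both high, which can only
remove positives relative to the common score alone.

## Numerical and reproducibility choices

All randomness flows from one master seed through fixed per-stage
derivations, so `run_pipeline()` reruns are bit-identical, which the
tests assert on raw bytes. Degenerate situations are handled explicitly:
all-zero features get NA statistics and leave the FDR adjustment;
single-class training splits are skipped with a warning (LASSO) or
redrawn with the next seed (harness); constant fragment lengths are a
degenerate-fit error; an NA median risk score (possible when repeats are
few) can never support a high-risk call. Desk-scale problem sizes — 1100
features, 50 samples per class, 2500 null features for calibration, 1e5
draws for the Gamma refit — were chosen once as the package's simulation
conditions and are stated in the tests.

## Known limitations

Exact containment counting cannot model soft-clipped or mismatched
alignments; the FDR inflation under asymmetric differential expression
discussed above applies to any median-of-ratios pipeline; linear SVM
scores are not calibrated probabilities; and none of the synthetic
results speak to performance on real plasma cohorts, which requires the
original controlled-access data.
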