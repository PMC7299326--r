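---
title: "Quantifying dyadic brain-transcriptomic and behavioral synchrony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dyadic brain-transcriptomic and behavioral synchrony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pibs)
```

## The question and the design

When two male fighting fish (*Betta splendens*) fight, their behavior
gradually synchronizes, and so — remarkably — do their whole-brain
transcriptomes. `pibs` implements the statistical machinery for detecting
and dissecting that synchronization in a three-group design: a set of
non-fighting baseline fish (`B`) and two sets of fighting pairs sampled
after a 20-min (`D20`) or 60-min (`D60`) bout, two opponents per pair.
With 5 baseline fish and 5 pairs per group this is 25 brain RNA-seq
samples.

The central objects are *dyads*: unordered pairs of samples within a
fighting group. Ten fish give 45 dyads, of which exactly 5 are *paired*
(the two opponents of one fighting pair) and 40 are *unpaired*. Every
synchrony statistic in the package reduces to comparing paired against
unpaired dyads.

## Normalization

Counts are filtered (CPM ≥ 1 in ≥ 1 sample, inclusive boundary) and scaled
by trimmed-mean-of-M-values (TMM) normalization. A "TMM value" here means
CPM computed on the TMM-effective library size — library size times the
TMM factor — which is the standard operational meaning of TMM-normalized
expression. Factors use the published algorithm's defaults: two-sided
trimming of 30% on log-ratios (M) and 5% on average log-abundance (A),
inverse approximate-binomial-variance weights, reference chosen as the
sample whose upper-quartile CPM is closest to the mean, and rescaling to
geometric mean 1. The implementation is validated in the test suite
against an independent reference implementation to 10^-6.

Two numerical notes. M and A are computed in the same single-expression
form for every gene so that genes with identical count ratios stay exactly
tied in floating point — the trim boundary is rank-based, and ulp-level
asymmetries would otherwise make it irreproducible. And the
inverse-variance weights depend on sequencing depth, so TMM factors are
*exactly* invariant to rescaling a library only when the kept genes share
a common M; on real data the invariance is approximate (relative
differences around 10^-3), which is a property of weighted TMM itself.

## Differential expression

Fight-responsive genes are called per group against baseline. The log2
fold change is the difference of group means of log2 TMM values
(pseudocount 1). The default p-value is a Welch two-sample t-test on log2
TMM values; a negative-binomial likelihood-ratio option with a pooled
method-of-moments dispersion is provided for count-scale inference.
Replicating a specific DE framework's empirical-Bayes dispersion machinery
is deliberately out of scope: the synchronization analysis downstream is
method-agnostic (any gene list can be injected into `sync_pipeline()`),
and the package's own calls are used for the simulated studies only.

Two threshold profiles mirror the two uses of the DE results: the
stringent characterization list (FDR ≤ 0.05 and |logFC| > 2) and the
permissive up-regulated list feeding the synchronization step (FDR ≤ 0.05
and logFC > 0). Where sources alternate between "<" and "≤" for the FDR
boundary we adopt ≤ throughout; the per-gene synchrony call below uses
strict p < α, and pair assignment uses strict D < B, exactly as printed.
Set overlaps are tested with the upper-tail hypergeometric probability
P(X ≥ overlap), evaluated via `phyper(log.p = TRUE)` so that extreme
significance (p below 10^-300) remains representable; with the study-scale
set sizes (518 and 859 of 23,306, overlap 295) this reproduces a log10 p
of about −297.1.

## The synchronization analysis

For each gene *i* and dyad *j* with linear-scale TMM values $x_1, x_2$,
the expression distance is

$$D_{ij} = \left| \log_{10}\frac{x_1 + \varepsilon}{x_2 + \varepsilon} \right|$$

with an offset $\varepsilon$ guarding zero TMM values (default: half the
smallest positive value in the matrix; the formula's source is silent on
zeros, so the offset is explicit and configurable). The distance is
symmetric in the two samples and zero iff they agree.

A gene is *synchronized* when its 5 paired distances are significantly
smaller than its 40 unpaired distances under a permutation test
(one-sided, p < 0.05). Three test modes are provided:

* `exact_rank` (default): the exact Wilcoxon rank-sum p-value via the
  Streitberg–Röhmel shift algorithm on doubled midranks, matching the
  default behavior of classical exact rank-test software. At 5-vs-40 the
  full rank-sum distribution is computed in milliseconds.
* `exact_enum`: full enumeration of all C(45,5) = 1,221,759 label
  assignments with the difference of group means as statistic; used as the
  oracle in tests.
* `monte_carlo`: random assignments with the add-one correction
  p = (1 + #extreme)/(1 + n); the fallback for designs too large to
  enumerate.

The smallest attainable p at the study design is 1/1,221,759 ≈ 8.2×10^-7.

Each synchronized gene is then assigned to the specific pairs in which it
synchronizes: the *baseline* $B_i$ is the 25th percentile of the gene's 40
unpaired distances (linear-interpolation percentile convention
$h = (n-1)p + 1$, giving 10.75 on the values 1..40), and gene *i* is
synchronized in pair *j* iff $D_{ij} < B_i$, strictly. `sync_pipeline()`
chains the whole procedure and reports the tally of synchronized genes by
the number of pairs (1..5) plus the synchronized fraction of the input
gene list.

Group-level synchrony is tested on dyad correlations: Pearson r of log2
TMM values over genes for each of the 45 dyads, paired vs unpaired, by the
same permutation machinery (one-sided: paired r larger). Sample-level
structure is summarized by hierarchical clustering (1 − r distance,
average linkage) of one group's samples on the most variable genes
(ranked by sd of log2 TMM; top `floor(fraction × n)`, lexicographic gene
id tie-break), scored by the fraction of pairs whose two members are
sister leaves.

### A calibration caveat the user should know

The 45 distances of a gene are not independent: every fish contributes to
9 dyads. The permutation test treats the 45 values as exchangeable, and
the real "paired" label set is the unique *sample-disjoint* matching of
the 10 fish. Under the package's generative null (no pair-shared effect)
this makes the per-gene test conservative: the empirical rejection rate at
α = 0.05 is about 0.034 rather than 0.05. The effect is structural — with
an arbitrary (sample-sharing) label subset the same machinery rejects at
the nominal rate — and it is inherited faithfully from the published
procedure, which we reproduce rather than repair. Detected synchronized
genes are therefore, if anything, under-called; specificity is not
compromised. The dyad-correlation test shares the caveat.

## The count simulator

`simulate_counts()` draws negative-binomial counts
(variance $\mu + \phi\mu^2$; per-gene $\phi$ log-uniform on a configurable
range) around the model

$$\log_2 q_{gs} = \log_2 \lambda_g + \text{fight}_s \cdot \text{LFC}_g
  + w \, u_{g,\text{pair}(s)} + (1-w) \, e_{gs}$$

for responsive genes, where $u$ is the pair-shared effect, $e$ the
fish-specific effect, and $w$ the group's synchrony weight for
synchronized genes (0 for non-synchronized responsive genes). Expected
counts scale relative abundances to a lognormal library size. The weight
is the single knob that moves the design from the weak-synchrony D20
regime to the strong-synchrony D60 regime.

Default parameters (chosen once, as the package's definition of the study
conditions): 2,000 genes at desk scale (scalable to the study's 23,306);
baseline log2 abundance N(5, 2); dispersion on [0.05, 0.2] (biological CV
0.22–0.45, typical of controlled animal experiments); library size 5×10^5
with CV 0.2; 10% responsive genes with log2 fold change N(2.5, 1); 65% of
responsive genes synchronized; $\sigma_{pair} = 2.5$, $\sigma_{fish} =
0.5$ (log2); $w = 0.3$ (D20) and $0.9$ (D60). The pair-effect scale is
deliberately comparable to the fight response itself: that is what the
observed D60 regime implies, where all five pairs cluster as sisters and
well over half of the up-regulated genes synchronize, nearly half of them
in all five pairs. Under these defaults the pipeline recovers
synchronized genes with sensitivity ≈ 0.84 and specificity ≈ 0.99 within
the DEG set, and the pair co-clustering score is 1.0 in essentially every
run.

What the simulator does *not* emulate: winner/loser asymmetries,
escalation dynamics, gene–gene correlation beyond the shared pair effects,
length/GC biases, and the two-batch sequencing structure of the real
experiment. Passing tests therefore demonstrate the statistical machinery
under the stated model, not robustness to those real-data features.

## The behavior simulator and its summaries

A 60-min fight log contains three behaviors. Mouth-locking is dyadic and
follows an alternating renewal process: first onset lognormal (mean 10.60
min), episode durations lognormal (mean 1.29 min, truncated at the
observation end), inter-episode gaps exponential. The gap mean is
calibrated so the *expected episode count* matches its target (12.12 per
hour) using the second-order renewal expansion
$E\,N(t) = t/\mu + \sigma^2/(2\mu^2) - 1/2$; a Monte-Carlo check shows the
calibration is unbiased to within ±0.01 episodes, with an episode-count sd
of ≈ 2.4 per hour.

Bite/strike and surface-breathing are point events of each fish, Poisson
within 2-min blocks whose log-rate is a pair-shared draw (sd 0.8) plus
fish noise (sd 0.2) around base rates of 6/min and 3/min. The pair-level
first occurrence of each behavior is an explicit lognormal onset event
(means 0.94, 3.49, 10.60 min — the recorded fight structure), and all
bite/breath events inside a mouth-lock episode or before the onset are
deleted, reproducing the observed exclusivity. Event rates and
intensity sds are simulator conventions: the source observations report
onsets and mouth-lock structure, not rates. Distributional forms
(lognormal onsets/durations, exponential gaps) are likewise conventions
chosen for positivity and simplicity, not claims about the fish.

Summaries use half-open interval conventions throughout: a bite exactly at
a mouth-lock's end is not inside it, and an event belongs to every window
$[k\,\text{step}, k\,\text{step} + \text{width})$ containing its start.
With a 60-min observation, 2-min windows and 1-min steps there are 59
windows. Opponent synchrony is the Pearson correlation of the two fish's
windowed frequency series; overlapping windows inflate serial correlation,
which is reproduced as stated and should be kept in mind when interpreting
r values. Point events carry duration 0, so frequency (not duration) is
their primary statistic.

## Enrichment

`ora()` is a generic hypergeometric over-representation test of a gene set
against an annotation (two-column TSV or GMT), reporting terms with at
least 2 overlapping genes and flagging p < 0.05. The default universe is
the set of post-filter tested genes; an annotated-only universe is a
configurable alternative (shrinking the universe makes a fixed overlap
less surprising, so p grows). Terms with identical memberships are merged;
no ontology-graph propagation or semantic deduplication is attempted.

## Reproducibility and problem sizes

Every random stage flows from named seeds; `run_all()` derives all stage
seeds from one master seed and stamps reports with a configuration hash,
so two runs with the same configuration are identical. The bundled
analyses and tests run at desk scale — 1,000–2,000 genes, 25 samples,
300–1,000 simulated fights, exact 5-vs-40 rank tests per gene and one full
C(45,5) enumeration — which keeps the complete pipeline in the minutes
range while preserving the study's geometry; all statistics scale
unchanged to 23,306 genes.

## Known limitations

* The per-gene and group-level permutation tests inherit the
  exchangeability approximation discussed above; their p-values are
  conservative under the generative model.
* The D20/D60 comparison shares the baseline group between contrasts, and
  the two DEG lists are compared by set overlap without accounting for
  that sharing.
* Distances are not invariant to per-sample rescaling — TMM normalization
  is precisely what makes them comparable; the ε offset bounds, but does
  not remove, sensitivity to near-zero expression.
* The Welch-on-log2 DE default is a documented deviation from count-model
  DE frameworks; with strong pair-shared effects it loses power in the
  D60 contrast (pair effects act as extra within-group variance), which is
  visible in the simulated studies.
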