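---
title: "Methods: differential expression, co-expression networks, and qPCR quantification in lncnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential expression, co-expression networks, and qPCR quantification in lncnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncnet)
```

# Scope and data model

lncnet analyses two-group (tumor vs normal) transcriptome profiles that
carry both long non-coding RNAs (lncRNAs) and mRNAs, the typical product of
a normalized expression microarray. The central container,
`expression_matrix()`, holds strictly positive linear-scale intensities for
transcripts x samples together with a sample-group map (`TUMOR`/`NORMAL`)
and a transcript-class map (`LNCRNA`/`MRNA`). Intensities from log2-scale
sources are unlogged on input (`scale = "log2"`), so every later log
transformation is explicit and documented at the call site.

The pipeline has four analysis stages, each usable on its own:

1. **Volcano screen** (`volcano_screen()`): joint fold-change / t-test
   thresholding of every transcript.
2. **Co-expression network** (`coexpression_network()`): thresholded
   Pearson correlation over candidate lncRNA x mRNA pairs, with topology
   summaries.
3. **Over-representation analysis** (`enrich()`): hypergeometric tests of
   gene lists against GMT collections.
4. **qRT-PCR quantification** (`ddct()`, `concordance()`): Livak
   `2^-ddCt` ratios and direction agreement with the array calls.

A latent-factor simulator (`simulate_expression()`, `simulate_ct_table()`)
generates data with machine-readable ground truth so that each stage can be
verified without any external download.

# Differential expression

## Fold change

Fold change is the ratio of arithmetic group means of the **linear**
intensities, reported unsigned (`max(m_t/m_n, m_n/m_t) >= 1`) alongside the
signed `log2(m_t/m_n)`. Arithmetic means on the linear scale match how
"fold change" is conventionally computed on normalized microarray
intensities; a geometric-mean variant was considered and rejected as the
default because the input intensities are already normalized summaries, not
raw replicate measurements.

## The t-test

`t_test_pvalue()` is a two-sided two-sample Student's t-test with pooled
variance, computed on log2 intensities. Defaults and why:

* **log2 scale** (`log_scale = TRUE`): variance of microarray intensities
  grows with their magnitude; volcano-plot P values are conventionally
  computed after log transformation, which stabilizes the variance the
  t-test assumes.
* **pooled variance** (`var_equal = TRUE`): with 5 samples per group there
  is little information to estimate separate variances; the pooled test is
  also what legacy array-analysis software reports by default. Welch's
  test is available behind the flag.

Both choices are configurable because upstream tools do not document their
internals; a user reproducing a specific legacy analysis can try the four
combinations.

Degenerate inputs are resolved deterministically: two constant groups with
equal means give P = 1; constant groups with different means give the
smallest representable positive P with a warning, because the t statistic
diverges and a "significant" zero would otherwise poison `-log10(P)`
displays.

## The screen

A transcript is `UP` when fold change `>= fc_min` (**inclusive**, so a
transcript at exactly 2.0 passes the conventional 2-fold cut), P `< alpha`
(**strict**), and the tumor mean exceeds the normal mean; `DOWN`
symmetrically; otherwise `UNCHANGED`. The screen uses **raw** P values —
that is what joint fold-change + P volcano filtering historically means —
and reports Benjamini–Hochberg adjusted values in an extra column for
readers who want error-rate control. With 10,000 truly null transcripts
the fraction with P < 0.05 is, by construction of the test, binomially
distributed around 0.05; the acceptance suite verifies this within three
binomial standard errors.

## Clustering

`cluster_expression()` clusters samples and transcripts with distance
`1 - Pearson r` (computed on log2 intensities over the chosen transcript
subset) and **average linkage** — the de facto default behind two-way
expression heatmaps. The result is deterministic for a fixed input
ordering; a singleton axis degenerates to a length-1 leaf order with no
merge history.

# The co-expression network

## Model

Two transcripts are called co-expressed when their intensities are linearly
correlated across **all samples pooled** (both groups together; 10 in a
5 + 5 design). The statistic is the sample Pearson correlation of the
linear normalized intensities; `log_scale = TRUE` correlates log2
intensities instead. Pooling the groups is deliberate: differential
expression itself induces correlation between co-regulated transcripts
across the pooled samples, which is exactly the signal this class of
lncRNA–mRNA screens exploits.

## P values

`pearson_pvalue()` uses the exact t-transform under bivariate normality:

$$ t = r\sqrt{\frac{n-2}{1-r^2}}, \qquad t \sim t_{n-2} \text{ under } \rho = 0, $$

two-sided. This is the standard exact test for Pearson's r, and it makes
the conventional paired thresholds internally consistent at n = 10:
r = 0.9 maps to P ≈ 3.9e-4, just below the 5e-4 cutoff, so both
thresholds bind together (`pearson_pvalue(0.9, 10)` =
`r signif(pearson_pvalue(0.9, 10), 3)`). A one-sided or normal-approximation
variant would break that correspondence. `|r| = 1` returns the smallest
representable positive P with a warning rather than 0.

The permutation distribution of r for a *given* dataset (shuffling one
vector's labels) is a conditional null: at n = 10 its tail probabilities
differ from the unconditional t-distribution values by a few percent
relative, no matter how many permutations are drawn. The test suite
therefore compares analytic and permutation P values within Monte-Carlo
error *plus* a 5% relative finite-sample allowance; the same applies to
the exhaustive 252-relabeling check of the two-sample t-test.

## Thresholds and edge semantics

Defaults `pcc_min = 0.9` and `p_max = 5e-4`, both **strict** inequalities
(`|r| > 0.9`, `P < 5e-4`), matching the stringent convention for these
screens. Relaxing either threshold can only add edges (tested as a
monotonicity property). Zero-variance transcripts have no defined
correlation; their pairs are skipped with a warning and counted in
`n_pairs_skipped` instead of aborting a whole run, because a single
saturated probe should not destroy a network build. Candidate lists follow
the validated-shortlist design: a small set of confirmed lncRNAs crossed
with all differentially expressed mRNAs (`auto_lncrna = TRUE` switches to
all DE lncRNAs).

## Topology

`degree_summary()` reports per-node degrees and *all* tied argmax nodes per
class; `negative_edges()` extracts anti-correlated pairs;
`network_components()` returns connected components of the bipartite graph
ordered by size (ties by smallest member id), which makes disconnected
"satellite" sub-networks — a biologically interesting pattern —
directly inspectable. Exports (`write_network()`) produce SIF,
edge-attribute TSV and GraphML with node `type` and edge `pcc`/`p_value`
attributes, loadable in Cytoscape.

# Over-representation analysis

`hypergeom_tail(k, n, K, N)` is the upper tail
`P(X >= k)` of the hypergeometric distribution — the standard ORA test,
identical to a one-sided Fisher exact test. It is computed through R's
numerically stable distribution function and verified in the tests against
exhaustive enumeration of every draw for all universes up to N = 12.
`enrich()` ranks sets by ascending **raw** P value (ties: larger overlap,
then name) and cuts at `top_k = 20`, mirroring "top 20 enriched terms"
presentations; BH-adjusted values ride along in a column. The universe
defaults to the union of the collection's members because the annotation
snapshot that produced a given GMT is usually unknown; supplying the
measured-gene universe via `gene_sets(..., universe = )` is recommended
when available. Query genes outside the universe are dropped with a
warning and counted — silently keeping them would inflate `n_selected`.

# qRT-PCR quantification

`ddct()` implements the Livak estimator: per-sample
`dCt = Ct(gene) - Ct(reference)`, group-averaged
`ddCt = mean dCt(tumor) - mean dCt(normal)`, ratio `2^-ddCt`. Averaging
per-sample dCt within groups is the standard aggregation when group sizes
are unequal (validation cohorts often are — e.g. many tumors vs few
controls). Amplification efficiency is fixed at 2 (perfect doubling), as
the plain `2^-ddCt` method assumes; efficiency calibration is out of
scope. Reference-gene cancellation is exact: adding a constant to every Ct
of one sample leaves all ratios unchanged (tested). Technical replicates
must be pre-averaged upstream; the loader rejects duplicate
(sample, gene) rows rather than guessing an aggregation.
`concordance()` scores direction agreement (UP/DOWN/UNCHANGED) between
qPCR ratios and array regulation calls.

# The synthetic-data generator

`simulate_expression()` draws log2 intensities as

$$ x_{ts} = b_t + \delta_t\,[s \in \text{TUMOR}] + \lambda_t f_{B(t),s} + \varepsilon_{ts}, $$

with baselines `b_t ~ N(8, 1)`, planted DE shifts
`delta_t = +/- log2(U)`, `U ~ Uniform(fc_range)`, one latent factor
`f_{B,s} ~ N(0, factor_sd)` per co-expression block, signed loadings
`lambda_t`, and noise `epsilon ~ N(0, noise_sd)`; the matrix is returned on
the linear scale (`2^x`). Defaults mirror a small FFPE microarray study:
5 + 5 samples, ~100 transcripts (10 lncRNAs + 90 mRNAs), 20% planted DE
with fold changes 2–10, `noise_sd = 0.1` on log2 (tight technical
replication of strong array signals), `factor_sd = 2` so that unit-loading
block members correlate at `4/4.01 ≈ 0.998`, comfortably above the 0.9
screen. These were chosen once as realistic study conditions and are not
tuned to any test outcome.

The single-shared-factor block is the simplest mechanism producing the
linear co-expression the Pearson screen assumes. One subtlety is scale:
a member with loading -1 is *exactly* linearly anti-correlated on the log2
scale but follows a reciprocal curve on the linear scale, where |r|
attenuates (to ~0.6 at these settings). The linear-intensity screen —
the default, matching how normalized intensities are usually screened —
therefore detects planted negative edges less readily than positive ones,
consistent with the empirical rarity of negative correlations in such
networks; the log-scale screen recovers them exactly. Tests exercise both.

What the generator does **not** emulate: probe-level effects, batch and
hybridization artifacts, FFPE RNA degradation, heavy-tailed noise,
correlated noise between blocks, and realistic annotation structure in the
GMT sets. Passing tests on synthetic data show the estimators recover the
generative model they assume — not that real FFPE arrays satisfy that
model.

`simulate_ct_table()` plants Ct values so `2^-ddCt` recovers each planted
fold change exactly at zero Ct noise (reference gene: zero group shift,
base Ct 18; targets: base Ct Uniform(22, 30), tumor shift
`-log2(FC)` cycles for UP genes).

# Reproducibility and problem sizes

All randomness flows from explicit integer seeds (`set.seed` inside the
simulators; the Ct simulator offsets the seed to decouple its stream from
the matrix). `make_demo(seed, dir)` writes a complete synthetic study —
matrix, annotations, GMT, Ct table, shortlist, ground truth, config — as a
pure function of the seed, and `run_pipeline()` is deterministic given its
inputs, which the tests verify byte-for-byte.

The verification suite runs at deliberately modest sizes chosen to
exercise the asymptotics that matter while staying interactive: 10,000
null transcripts for the type-I check, 20 seeded replicates of the
800-pair recovery experiment (mean precision and recall ≥ 0.9 at the
default thresholds), 50 null replicates for the false-edge expectation
(800 x 5e-4 = 0.4 edges per replicate), 1e5 permutations for the
correlation-null comparison, and exhaustive enumeration for hypergeometric
tails (N ≤ 12) and 5v5 t-test relabelings (252).

# Known limitations

* The screen tests one transcript at a time; no moderated-variance
  (empirical Bayes) shrinkage, which would help at n = 5 per group.
* Pearson correlation on 10 samples has wide sampling error even at
  |r| = 0.9; the network should be read as a hypothesis-generating screen,
  not an estimate of regulatory structure. No partial correlations or
  directionality.
* ORA ignores gene-set topology (GO parent/child propagation) and
  annotation bias; results depend on the supplied GMT snapshot.
* `2^-ddCt` assumes perfect amplification efficiency and a stable
  reference gene.
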