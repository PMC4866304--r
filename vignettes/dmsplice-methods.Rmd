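---
title: "Methods: scoring, classifying and mapping splicing effects from doped-library DMS"
author: "dmsplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, classifying and mapping splicing effects from doped-library DMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The experiment this package models

A doped-oligonucleotide library tiles an alternatively spliced exon — here
human FAS/CD95 exon 6, 63 nt, carried on a 135-nt amplicon between invariant
intronic flanks of 22 and 50 nt — with random substitutions at a small
per-position rate (1.2% per alternative base). The pool, dominated by
wild-type, single- and double-mutant molecules (analytically ~10/23/27% at
the design values), is cloned into a minigene, transfected, and the
exon-inclusion isoform is amplified and sequenced alongside the input
plasmid library. A variant that improves exon inclusion is over-represented
in the spliced output relative to its input frequency; one that promotes
skipping is depleted.

`dmsplice` implements the complete downstream analysis: read counting,
enrichment scoring, effect classification, calibration of scores to percent
spliced in (PSI), mutational-robustness comparison across genetic
backgrounds, and pairwise epistasis mapping — plus a generative simulator
whose ground truth makes every stage testable.

# The enrichment score

For variant $v$, replicate $r$ and channel $c \in \{\text{input},
\text{output}\}$, the frequency $f_c(v, r)$ is the variant's read count over
the channel total of *all* accepted reads, including a lumped bin for
molecules with more than two substitutions: those molecules are never scored
individually, but they dilute everything else and therefore belong in the
denominator.

The score takes medians across replicates first, then the ratio:

$$\mathrm{ES}(v) \;=\; \log_2\frac{\operatorname{med}_r f_o(v,r)}
{\operatorname{med}_r f_i(v,r)} \;-\;
\log_2\frac{\operatorname{med}_r f_o(\mathrm{wt},r)}
{\operatorname{med}_r f_i(\mathrm{wt},r)},$$

so $\mathrm{ES}(\mathrm{wt}) = 0$ exactly. The median-of-frequencies order
of operations is deliberate and is *not* equivalent to the median of
per-replicate ratios; per-replicate non-normalised enrichments
$\log_2 f_o/f_i$ are retained separately because the statistics below
operate on them. Under the package's selection model (output probability
proportional to input frequency times PSI), the noiseless score is exactly
$\log_2 \mathrm{PSI}(v)/\mathrm{PSI}(\mathrm{wt})$, which serves as the
closed-form oracle in the test suite.

**Zero counts.** A variant with any zero frequency entering the formula, or
with median input coverage below `min_input_reads` (default 10 reads), is
reported `quantified = FALSE` rather than scored. No pseudocount is added by
default: a silent pseudocount would bias exactly the low-coverage double
mutants the epistasis analysis depends on. A `pseudocount` argument exists
for sensitivity analysis only.

# Classification of single-mutant effects

Each quantified single mutant is compared to wild type with Welch's
unequal-variances t-test on the per-replicate *non-normalised* enrichments
(this uses every replicate on both sides and does not assume equal
variance). P-values are Benjamini–Hochberg adjusted over the family of
tested singles — 189 at full coverage. Labels:

* `I` — FDR < 0.05 and ES > 0 (inclusion up);
* `S` — FDR < 0.05 and ES < 0 (skipping up);
* `N` — not significant and replicate variance ≤ 0.15 (near-neutral);
* `X` — not significant but replicate variance > 0.15 (not classified).

The variance entering the 0.15 rule is the sample variance of the
per-replicate wild-type-normalised scores. The rule needs *some*
per-variant spread statistic and the replicate-level normalised score is the
one the output tables carry; the threshold and the statistic are both
configurable (`var_threshold`).

With three replicates, degenerate inputs are possible: when both sides of
the Welch test have zero variance the statistic is undefined, and the
package returns p = 1 for equal means and p = 0 otherwise, flagged
`degenerate`, instead of dividing by zero.

# Calibrating scores to PSI

A small panel of variants with independently measured inclusion levels
anchors the map from scores to PSI. The package fits
$\mathrm{PSI} = A e^{B \cdot \mathrm{ES}}$ by nonlinear least squares on
the PSI scale, initialised from the exact log-linear regression; fitting the
log-linearised model instead would over-weight low-inclusion points (the
`log_scale` flag exposes that alternative). The fit is deterministic given
the points. Predictions above 100% are *flagged*, not clipped — a score
extrapolating beyond full inclusion is an informative anomaly. Under the
selection model the exact calibration is $A = \mathrm{PSI}(\mathrm{wt})$,
$B = \ln 2$, which the test suite recovers to 1e-6 on noiseless data.

# Mutational robustness across backgrounds

The effect of mutation $A$ in the background of single mutant $B$ is
$\mathrm{ES}(A{\to}B) = \mathrm{ES}(AB) - \mathrm{ES}(B)$, defined when the
double was quantified; effects in the wild-type background are
$\mathrm{ES}(A)$ itself. Backgrounds are the near-neutral (`N`) singles —
`X` variants are excluded precisely because their high replicate variance
makes their score, and hence every effect computed against it, unreliable.

Comparing spreads naively would be confounded by coverage: wild-type-background
effects come from deeply covered singles, background effects from shallow
doubles, and shallow sampling alone widens a score distribution. The package
therefore resamples the wild-type effect set from the output-channel reads,
multinomially with probabilities equal to each variant's median selection
frequency, at a total depth whose per-variant average matches the double
mutants' (mean-matching by default; median-matching is a flag). This is done
once per background (73 times in the original design), and the set of
wild-type resample IQRs is compared to the set of background IQRs with a
two-sided Mann–Whitney U test. Backgrounds with fewer than `min_effects`
(default 20) quantified effects are dropped — the IQR of a tiny sample is
too unstable to compare.

# Pairwise epistasis

The no-interaction expectation is a per-replicate ordinary least-squares
regression of the observed double-mutant score on the sum of its two
single-mutant scores, fitted separately within each replicate so that
replicate-specific scale differences stay inside that replicate. The
replicate-level epistasis signal is the residual; the empirical epistasis
score $E$ is the median residual across replicates. Significance is a
paired t-test between the replicate-wise observed and predicted scores —
the predictions come from each replicate's own fit, which is the reading
consistent with fitting separately per replicate. BH adjustment is applied
separately within network families defined by the constituent single-mutant
classes (`NxN`: both near-neutral; `NxX`: one near-neutral; `XxX`: neither),
since the scientific questions — rewiring among neutral variants versus
modulation of functional sites — are asked family by family. Pairs with
FDR < 0.05 are `positive` or `negative` by the sign of $E$.

The variance explained by the no-interaction model (pooled $R^2$ across
replicates) summarises how additive the landscape is; on purely additive
noiseless data it is exactly 1 and every $E$ is 0, which the acceptance
suite checks to 1e-9.

Network summaries report per-mutation interaction degrees (overall and per
family), hubs as mutations whose degree exceeds a configurable quantile of
the degree distribution (default 0.95 — the degree distributions are
long-tailed, so a fixed count would be arbitrary), and a Mann–Whitney
comparison of the nucleotide distance separating epistatic versus
non-epistatic pairs.

# The simulator: what it emulates and what it does not

`simulation_config()` defaults are the study conditions: 1.2% doping over
the 63-nt FAS exon, three biological replicates, an input channel of
1.3×10⁷ reads (giving a median single-mutant coverage near 16,000 reads and
~200 reads per double), an output channel of 4.2×10⁶ reads, wild-type
inclusion of 50%, a 73/189 fraction of exactly-neutral single effects, and
remaining effects drawn from Normal(−0.5, 0.75) in log2 units so the
landscape is skewed towards skipping, as regulatory exons typically are.
Ground-truth inclusion is
$\mathrm{PSI}(v) = \mathrm{clip}(\mathrm{PSI}_\mathrm{wt} \cdot
2^{\sum_i e_i + \varepsilon}, \mathrm{PSI}_{\min}, 100)$
with a 0.1% floor keeping output probabilities positive. Reads are
multinomial: the input channel over the variant universe with the analytic
doped-library class probabilities spread uniformly within each mutation
class (plus a lumped >2-mutation bin, assigned wild-type PSI), the output
channel with probabilities proportional to input frequency × PSI.

Choices worth knowing about:

* **Interactions are planted only where PSI stays strictly inside the
  dynamic range.** A clipped PSI cannot express an interaction, so planting
  $\varepsilon$ on a saturated pair would make recovery tests measure the
  clip rather than the method.
* **Uniform frequency within a mutation class.** The real doping process
  has positional bias and inter-variant dispersion that are not published;
  uniform-within-class is the simplest null and a per-position bias vector
  is the natural extension point.
* **Not simulated:** sequencing errors, PCR jackpotting, barcode structure,
  paired-end overlap artefacts. Passing tests therefore demonstrate
  correctness of the analysis under the stated sampling model, not
  robustness to library-preparation artefacts.
* **Clipping is the one built-in non-additivity.** Additivity-control tests
  restrict their exactness assertions to the unclipped portion of the
  landscape for this reason.

# Numerical and scale choices in the validation suite

The test and acceptance suites run the full FAS geometry (189 singles,
17,577 doubles) at the depths above for the oracle, null-error-control,
recovery and additivity checks; unit tests of individual operations use
small exons (4–10 nt) at depths of 10³–10⁵ reads, where brute-force
enumeration and closed-form moments are available as independent oracles.
Error control uses 20 null seeds; interaction recovery plants 250 pairs per
$\varepsilon$ level in $\{\pm 0.5, \pm 1, \pm 2\}$ — about 8% of all pairs,
a prevalence comparable to the pervasive epistasis such assays detect; with
a sparse handful of planted pairs, no 3-replicate test could survive BH
across a ~13,000-pair family, so sparse planting would test the
multiple-testing burden rather than the estimator. Median recovery bias is
required within ±0.1 ES units and detection power must rise with
$|\varepsilon|$; absolute power at FDR < 0.05 is intrinsically modest at
double-mutant coverage with three replicates, and the package reports the
bias-free $E$ estimates alongside the conservative classifications rather
than pretending otherwise.

# Known limitations

* Substitutions only: the design is substitution-based, and indel-bearing
  reads are rejected at trimming (`length_mismatch`).
* The analysis starts from merged, demultiplexed reads; barcode splitting
  and read-pair merging are upstream of the package's contract.
* No higher-order (>2 mutation) epistasis: such molecules contribute to
  denominators only.
* The exponential calibration is monotone and unsaturating; a saturating
  alternative would need a different functional form and is out of scope.
* Coverage matching corrects sampling-depth differences but not
  PCR-amplification noise shared between channels.
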