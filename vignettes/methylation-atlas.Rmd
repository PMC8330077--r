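---
title: "Models and methods behind the methylation atlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the methylation atlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methatlas)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generators do and do not emulate, and the numerical
choices that were genuinely open.

## 1. CpG observed/expected profiling

### The statistic

In animals, 5-methyl-cytosine occurs almost exclusively at CpG
dinucleotides, and methylated cytosines deaminate to thymine at an
elevated rate. Over evolutionary time a methylated gene body therefore
loses CpGs: the observed CpG count falls below what the sequence's C and
G content predicts. Per sequence we compute

$$\mathrm{o/e} \;=\; \frac{n_{CpG}}{n_C\,n_G}\cdot\frac{L^2}{L-1},$$

where $L$ is the N-excluded length, $n_C$, $n_G$ count N-excluded
residues, and $n_{CpG}$ counts CG dinucleotides over consecutive non-N
pairs (a pair interrupted by an N is not counted — the formula assumes
clean counts, so ambiguity codes are excluded from both numerator and
denominator). The $L^2/(L-1)$ factor is the small-sample correction for
there being only $L-1$ dinucleotide positions. The ratio is reported as
undefined (NA) rather than an error when $n_C=0$, $n_G=0$ or $L<2$.
Sequences shorter than 200 bp (the `min_len` default) are excluded
before profiling, because the ratio's variance explodes for short
sequences.

### Density estimation and modes

The distribution of per-sequence o/e values across a transcriptome is
the classifier's input: one depleted mode indicates global gene-body
methylation; one high mode indicates none; two modes indicate a mosaic
genome. We estimate it with a Gaussian kernel density, Silverman's
rule-of-thumb bandwidth, and a 512-point grid on $[0, \max(2,
\max\mathrm{o/e})]$. Because o/e is non-negative and mass often sits
near small values, the estimate is boundary-corrected by reflection at
zero (the density below zero is folded back), then renormalized so it
integrates to one (tolerance $10^{-3}$, tested). The KDE internals are
this package's documented choice; other mode-modelling tools in this
area fit Gaussian mixtures instead, which we deliberately do not
(model-count selection adds fragility that a prominence rule avoids).

Modes are local maxima of the gridded density filtered by *topographic
prominence*: a peak is retained when its height above the higher of its
two key saddles is at least a fraction (default 0.1) of the global
maximum. Ties in height break toward the lower o/e. The default was
chosen so that bootstrap-scale ripples on a unimodal density never
register as modes while genuinely bimodal (mosaic) mixtures always do;
it is exposed as `prominence`.

### Uncertainty and classification

A percentile bootstrap (default `n_boot = 1000` resamples, seeded)
gives a 95% CI for the *mean* o/e; the CI is attached to the mean rather
than the mode because the mean is the quantity whose sampling
distribution the bootstrap approximates well at these sample sizes —
mode locations are grid-quantized and their bootstrap distribution is
lumpy.

`classify_methylation_type()` maps mode structure to the four-type
scheme used for gene-body methylation surveys: two or more retained
modes give type 4 (mosaic); a single mode $m$ gives type 1 if $m \ge
0.90$ (no historical depletion), type 2 if $0.70 \le m < 0.90$, and
type 3 if $m < 0.70$ (substantial gene-body methylation). The 0.90 and
0.70 cut points approximate the cluster boundaries of published
multi-species surveys, which do not print exact thresholds; both are
arguments, and the returned `rule_trace` records which branch fired with
the thresholds used.

## 2. The transcriptome generator

`simulate_transcriptome()` draws sequences from a first-order Markov
chain constructed so that (i) the stationary mononucleotide composition
equals the requested GC fraction and (ii) the C$\to$G transition
probability equals $t \cdot p_G$, making the expected o/e of a long
sequence equal the target $t$. The C row's remaining mass is spread
proportionally over A, C, T, and the shared A/G/T row is solved from
the stationarity constraints, so the composition is *exactly* stationary
— this gives a closed-form calibration (tested: mean o/e within
$\pm 0.03$ of targets 0.3, 0.55 and 1.0 over 5,000 transcripts) rather
than emulating the mutational process (iterated CpG$\to$TpG decay)
that produces depletion in nature. A target $t$ with $t \cdot p_G > 1$
is a parameter error.

Defaults — 5,000 transcripts, lengths uniform on 500–3,000 bp, GC 0.40
— are the package's fixed study conditions: typical invertebrate
transcriptome scale and composition. Real transcriptomes additionally
have isoform redundancy, composition heterogeneity across genes, and
length-expression correlations that the generator does not emulate; a
passing recovery test shows the *pipeline* is calibrated, not that any
particular species' distribution is unimodal.

## 3. Restriction digestion and LUMA

### Forward model

The digestion model is deterministic. MspI cuts every CCGG at C^CGG
(cut index = site start + 1); HpaII cuts only sites whose internal CpG
is unmethylated; EcoRI cuts every GAATTC at G^AATTC; combined reactions
take the union of cut sets; the molecule is linear, so $k$ cuts give
$k+1$ fragments whose lengths always sum to the genome length (tested
invariant, together with HpaII cuts $\subseteq$ MspI cuts). Sites are
binary — hemimethylation and the outer-cytosine sensitivity of MspI
(methylation of the *outer* C can block MspI in vitro) are out of the
model, because the assay logic treats MspI as the fully insensitive
isoschizomer.

Pyrosequencing fill-in follows the overhang chemistry: a CCGG cut
leaves two 5'-CG overhangs, so filling each end incorporates one C and
one G (4 incorporations per cut in total); an EcoRI cut leaves two
5'-AATT overhangs, two A and two T per end (8 per cut). At one light
unit per incorporation under the dispensation order dATP; dGTP+dCTP;
dTTP; H2O; dGTP+dCTP; dATP; dTTP, the label totals are split evenly
across the two dispensations of each label — an arbitrary choice that
is observationally irrelevant because the estimator sums them. The H2O
dispensation is a zero-peak control.

### Estimator and noise

With $r = (\mathrm{dGTP+dCTP}) / \mathrm{mean}(\mathrm{dATP};
\mathrm{dTTP})$ per reaction,
$$\%\,\mathrm{methylated\;CCGG} = 100\left[1 -
\frac{r_{HpaII}}{r_{MspI}}\right].$$
Under the forward model $r = \mathrm{CCGG\;cuts} / \mathrm{EcoRI\;cuts}$
exactly, so the EcoRI count cancels in the ratio of ratios (tested over
10–1,000 sites) and the noise-free chain returns $100f$ exactly for an
exact-count methylome with fraction $f$. Technical noise multiplies
each peak by an independent positive factor with mean 1 and CV `cv`
(Gaussian truncated at 0): pyrosequencing light intensities scale with
template quantity, so the noise is proportional rather than additive.
Raw percentages pushed outside $[0,100]$ by noise are clamped, with the
raw value kept for QC. Replicates are combined by computing percent
per replicate and averaging — the alternative (averaging peaks before
the ratio) is not what the returned object does, and the choice matters
only at second order in the noise.

The genome generator places exactly the declared numbers of
non-overlapping CCGG and GAATTC sites at seeded positions and destroys
accidental occurrences of either motif by point substitution, iterating
until an independent scan finds exactly the declared sites. Genomes are
linear, single-contig and N-free, and CCGG is palindromic, so a site is
one unit on both strands. The methylome assigns methylation to exactly
$\mathrm{round}(f \cdot n)$ sites without replacement, so recovery
targets are exact rather than Bernoulli-fuzzy.

## 4. Bisulfite quantification

Bisulfite converts unmethylated cytosines to uracil (read T) while 5mC
stays C. The simulator methylates each CpG cytosine per read with its
site probability, converts unmethylated Cs (CpG and non-CpG alike) with
probability $c$ (`conversion_rate`, default 0.98 — a typical kit
efficiency), then applies independent substitution errors (default
0.001). Reads are pre-aligned by construction; alignment and PCR bias
are out of scope.

The estimator is $100 \cdot n_C / (n_C + n_T)$ per CpG; its expectation
is $100\,[m + (1-m)(1-c)]$ at error rate 0 — the incomplete-conversion
bias term $(1-m)(1-c)$ is verified by simulation in the tests. Raw
(uncorrected) percentages are the default output, since that is what
pyrosequencing software reports; an optional corrected estimator
$\hat m = (p - (1-c))/c$, clamped to $[0,1]$, uses the conversion rate
estimated from non-CpG cytosines (`conversion_qc`, flagged below 0.95).
Replicate profiles over identical CpG sets aggregate to per-CpG mean and
sample SD; SD for a single replicate is reported as missing, not zero.

## 5. Dollo parsimony on species trees

Gene families of the DNA-methylation machinery and the NuRD complex
originate once and are subsequently lost in scattered lineages, which is
exactly the Dollo assumption: one gain, any number of losses. For a
family with possessing leaves $S$, the origin is placed at
$\mathrm{MRCA}(S)$; a node is present iff it lies on a path from the
origin to a possessing leaf; losses are the edges from a present parent
into an all-absent subtree. This reconstruction is the unique
minimal-loss single-gain assignment — the test suite proves it against
exhaustive enumeration of *all* single-gain state assignments on random
trees with up to 8 leaves. Fitch parsimony (which would allow multiple
gains) is deliberately not offered.

Polytomies are treated as hard (simultaneous divergence): a present
polytomy node loses the family separately into each absent child. A
tree is interpreted as rooted at its unique top node — note that ape's
`is.rooted()` calls a basal trifurcation "unrooted", whereas here such a
tree is a legitimate hard root polytomy encoding uncertainty about the
deepest splits; alternative rootings are analysed simply by supplying
alternative trees. Counts collapse to presence/absence for
reconstruction; ancestral copy numbers are not reconstructed (the
summaries report per-species totals and single-copy counts instead).

The packaged fixture (`repertoire_demo.tsv`, `metazoa_demo.nwk`) encodes
the published *P. dumerilii* repertoire — 17 families, 16 single-copy,
four Chd3/4/5 members — inside a deliberately schematic six-species
matrix and tree; the non-annelid rows and the topology are synthetic
scaffolding for exercising gains/losses, and user matrices of any size
load through `read_repertoire_matrix()`.

The validation generator evolves counts down the tree edge by edge
(whole-family loss with probability `loss_rate`, single-copy gain with
`dup_rate`, never re-gained after loss), so its histories are
Dollo-compatible by construction and loss-only runs give exact recovery
targets.

## 6. Expression dynamics

Transitions between stages are categorized from FPKM values at a strict
two-fold threshold: fold change $> 2$ up or down, everything else
(including exactly 2) stable. Both values are shifted by a pseudocount
(default 0.01) before the ratio so zero FPKM is well defined — the
choice of pseudocount only affects genes whose expression is near zero
at both stages, which the low-expression flag (both stages $< 5$ FPKM,
the conventional in-situ detectability threshold) captures anyway.
Because it is ambiguous whether low-expression genes belong in
category denominators, `transition_summary()` reports proportions both
over all genes and over the expressed subset, and lists the flagged
genes.

Correlation analysis uses Spearman's rank correlation with average
ranks for ties and asymptotic p-values (with ties the exact permutation
null is unavailable), Holm-adjusted across all unordered variable pairs
of the matrix as one family. Constant columns have undefined
correlations; they are reported NA and excluded from the Holm family
rather than absorbing adjustment room.

## 7. Orchestration and reproducibility

`run_atlas()` executes the requested stages in dependency order from a
single nested configuration (R list or JSON file; unknown keys are
rejected), derives each stage's seed deterministically from the global
seed, and writes per-stage TSV/JSON outputs plus a manifest recording
parameters, seeds, package version and every file written. Identical
configurations produce byte-identical outputs (tested). Missing
upstream stages raise dependency errors naming the stage.

## 8. Problem sizes and limitations

The packaged analyses are desk-scale by design: recovery simulations use
5,000 transcripts, 200 kb genomes with a few hundred sites, thousands of
reads, and trees of up to eight leaves for the exhaustive parsimony
cross-check — sizes at which closed-form expectations and brute-force
oracles are available. Known limitations: no mixture-model mode
selection; no hemimethylation or partial digestion; no bisulfite
alignment or PCR bias; no ancestral copy-number inference; no
sequence-based orthology (count matrices are inputs); expression tables
are consumed as given, with no normalization.
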