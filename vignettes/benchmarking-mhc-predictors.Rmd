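---
title: "Benchmarking peptide-MHC predictors on novel alleles: methods"
author: "mhcbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking peptide-MHC predictors on novel alleles: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhcbench)
```

This vignette is the package's account of its statistical machinery: the
models and conventions behind each stage, the parameters that matter, what
the synthetic world does and does not emulate, and the numerical choices
made where more than one reading was defensible.

## The problem

Peptide–MHC presentation predictors are trained on eluted-ligand (EL) data
whose HLA allele composition is heavily skewed toward European-ancestry
donors. Two questions follow. First, *how many people* carry alleles such a
predictor has never seen? Second, *does it matter* — does prediction quality
degrade on those alleles? Answering the second requires benchmark
statistics that are comparable across alleles whose binding motifs differ
wildly in selectivity, which is what most of this package computes.

## Population coverage

Given a population × allele frequency table for one locus and a set of
training alleles, the covered mass of a population is
$p = \sum_{a \in \text{training}} f_a$. We model a genotype as two
independent allele draws (Hardy–Weinberg equilibrium), so the fraction of
individuals carrying **at least one** uncovered allele is $1 - p^2$. HWE is
the standard conversion from allele frequencies to carrier fractions; the
real HLA region violates it mildly through linkage disequilibrium, which we
deliberately ignore (and which also limits the across-locus union
`combinedUncoveredFraction()`, computed as $1 - \prod_\ell p_\ell^2$ under
cross-locus independence).

Frequency mass absent from the table ("residual mass") defaults to
**uncovered** — the conservative choice, since unlisted alleles are rare
alleles nobody has trained on — with `residual = "covered"` exposed for the
optimistic reading. Cross-locus Pearson correlations of the per-population
fractions (`locusCorrelations()`) report `NA`, never 0, when a locus has
zero variance.

## Spike-in benchmarking

### Fractional ranks

An evaluation set mixes $n$ verified binders with $\mathrm{round}(n(1-f)/f)$
background decoys at spike fraction $f = 0.01$. Every peptide gets an EL
score in $[0,1]$ and a fractional rank

$$\mathrm{rank}_i = \frac{\#\{j : EL_j > EL_i\}}{N}, \qquad N = n/f,$$

so the best peptide has rank 0 and ties contribute nothing (strict
counting; a midrank option exists but is off by default). Two calibration
facts make ranks interpretable and are verified by the test suite and the
acceptance script: a *random* scorer places ~90% of verified peptides at
$\log_{10}$ rank in $(-1, 0]$, and a *perfect* separator places all of them
at $\log_{10}$ rank $\le -2$ at the 1% spike.

The top rank of 0 has no logarithm. We floor raw ranks at $1/(2N)$ — half
the smallest nonzero rank — before the log transform, preserving order with
minimal distortion, and flag floored peptides in the output. Dropping those
peptides instead would bias the best predictions out of the statistics.

### Core weighting

Class-II-like peptides repeat one 9-mer binding core with varying flanks.
Counting each repeat as an independent success inflates every statistic, so
verified peptides sharing a reported core split weight $1/m$ ($m$ = core
multiplicity); each distinct core carries total weight 1. Decoys keep
weight 1: their cores have no experimental meaning. The weights enter
medians, the correction regression, PR counts and PPV as frequency weights.

### Motif information correction

Selective motifs are easy: a predictor looks better on an allele whose
motif is far from background regardless of its real quality. We measure
selectivity as the Kullback–Leibler information of the motif,

$$I = \sum_{i=1}^{L}\sum_a p_{a,i} \log_2 \frac{p_{a,i}}{q_a} \;\text{bits},$$

with $p$ the position frequency matrix (PFM) of the verified binding cores
(pseudocount 1 per amino acid per column) and $q$ a bundled
human-proteome-like background, overridable. We then fit ordinary least
squares of the pooled per-peptide weighted $\log_{10}$ ranks of verified
peptides against their allele's $I$, and subtract the per-allele correction

$$C_{\text{allele}} = \alpha + \beta I_{\text{allele}} - \mu,$$

where $\mu$ is the weighted grand mean of the pooled log ranks. Two exact
identities follow and are tested to $10^{-9}$: the corrected pool keeps its
grand mean (the $\mu$ term), and a refit of corrected log ranks against $I$
has slope 0. Fitting on pooled peptides rather than per-allele medians was
an open choice — pooling uses all data and weights alleles by evidence; the
median variant is available via `perAlleleMedians = TRUE`. Only verified
peptides enter the fit: decoy ranks carry no information about motif
difficulty. For cutoff metrics the corrected log rank is exponentiated back
to the rank scale and clamped to $[0,1]$.

### AUPRC, PPV, bootstrap

AUPRC sweeps every distinct (corrected) rank value as a cutoff, groups
ties at one threshold, applies core weights to verified counts, and sums
precision × recall increments step-wise with no interpolation — the
convention that matches an exhaustive threshold enumeration exactly, which
is how the tests verify it. PPV is the weighted fraction of verified
peptides with corrected rank < 0.01 (the spike fraction). Confidence
intervals for between-group median differences use the percentile
bootstrap: resample each group with replacement to its own size, take the
0.025/0.975 quantiles of the replicate median differences. The package
default is $10^4$ replicates (an argument; precision studies in the test
suite use 2,000 replicates over 500 simulated experiments, where the
interval attains ~95% empirical coverage).

## Sequence space

Aligned full-length HLA proteins first have gaps filled with the most
common residue of the alignment column (ties alphabetical). Filling *all*
gap columns is the default; `terminalOnly = TRUE` restricts filling to
leading/trailing gap runs and errors on interior gaps, for alignments where
gaps are known to occur only at the ends.

Similarity between two equal-length sequences is the summed PAM100 log-odds
over positions, $S(a,b) = \sum_i M[a_i, b_i]$ (the canonical 20×20 PAM100
table ships with the package as plain text). Distance is maximum similarity
minus similarity. "Maximum" is ambiguous; we default to the per-pair
self-maximum $\max(S(a,a), S(b,b))$, which yields a pseudo-metric with an
exactly zero diagonal, and also implement a single global maximum
(`convention = "global"`). Either way the matrix is divided by its largest
entry, so distances live in $[0,1]$ with maximum exactly 1, and the divisor
is recorded in the object.

Motif distance between two PFMs is the per-position Jensen–Shannon
divergence in bits, summed over core positions (bounded by 1 bit/position);
symmetric KL is available as `method = "symmetric_kl"` since both
conventions appear in practice. Embedding uses classical (Torgerson) MDS
via `stats::cmdscale` with default parameters; when fewer than $k$ positive
eigenvalues exist, coordinates are zero-padded with a warning. Axis signs
are not identified — only inter-point distances are meaningful.

## Occlusion scanning

For each MHC residue in the scanned range, the 19 possible substitutions
are scored against a verified peptide set. Per peptide we average the $k=5$
*lowest* mutated scores — the most disruptive substitutions — and report
the mean of (unmutated − that average) over peptides. Positive impact means
the predictor relies on the residue. Selecting the 5 lowest per peptide is
the literal reading of "the 5 substitutions with the lowest scores"; a
per-residue aggregate mode (5 lowest mean-score substitutions) is provided
and agrees exactly in the constant-shift case. Residue numbering is 1-based
over the supplied sequence and the scan range is caller-controlled, so
class-I-like (1–205) or class-II-like (29–125) windows are just arguments.

## The synthetic world

Real benchmarks need a closed-source network plus several external
datasets. The synthetic world replaces them with a deterministic predictor
whose ground truth is known, which is what turns qualitative claims
("important residues are pocket residues") into exact tests:

* **Catalog**: one ancestral sequence per cluster, i.i.d. per-site
  substitutions at rate 0.05 by default — alleles form sequence clusters as
  HLA alleles do.
* **Frequencies**: symmetric Dirichlet per population, concentration 0.5 by
  default so a few alleles dominate each population, as in real HLA tables;
  large concentrations give the uniform limit.
* **Predictor**: nine "pocket" MHC positions each key one column of a 9×20
  PWM through a fixed random lookup table; peptide score = best sliding
  9-mer window sum, squashed by a logistic with midpoint 12 and scale 3.
  These squash parameters place motif-sampled binders on the upper shoulder
  and background decoys near 0, giving the binder/decoy separation the
  benchmark presumes. Because the PWM depends *only* on pocket residues,
  substitutions elsewhere change scores by exactly 0 — the occlusion
  module's null is exact, not approximate.
* **Binders/decoys**: binders sample cores position-wise from the softmax
  of the PWM columns with background flanks; decoys are i.i.d. background
  strings or proteome substrings, with an exact length-histogram mode for
  the class-II matching rule.

What the world does **not** emulate: real motif anchor structure (two
dominant anchors rather than nine equally informative positions), binding
affinity in nM, inter-locus linkage disequilibrium, peptide-length effects
on binding, or anything about real network architectures. Green tests
therefore certify the *statistical machinery* — ranks, corrections, PR
areas, CIs, distances, scans — on data with known truth; they do not
certify any claim about a real predictor's accuracy.

## Problem sizes and determinism

The shipped tests and the acceptance script run at deliberately modest
sizes chosen as the smallest that make the statistics stable: evaluation
sets of 50–500 binders (5,000–50,000 peptides at 1% spike), worlds of 4–12
alleles with 40–60-residue sequences, bootstrap precision studies at 2,000
replicates × 500 simulations, occlusion scans over 40 residues × 19
substitutions × 15 peptides. Every stochastic step takes an explicit seed
and restores the caller's RNG state, so identical seeds give byte-identical
outputs; `runPipeline()` derives per-stage child seeds as
`seed * 100 + stage` and records them, with input checksums, in its
manifest.

## Known limitations

* HWE and cross-locus independence understate coverage gaps where linkage
  disequilibrium is strong.
* The information correction is linear in $I$; a strongly nonlinear
  difficulty–information relationship would leave residual trend.
* The bundled background is a proteome-wide average; organelle- or
  tissue-specific proteomes shift $q_a$ slightly.
* MDS coordinates are only as Euclidean as the distance matrix; large
  negative eigenvalues (reported in the `MDSEmbedding`) signal distortion.
* The synthetic predictor's deterministic pocket→PWM map has no epistasis
  between pocket positions, which real binding grooves do exhibit.
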