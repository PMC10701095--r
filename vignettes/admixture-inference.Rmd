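---
title: "Admixture inference with f-statistics: models, benchmarks and design notes"
author: "admixscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Admixture inference with f-statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

African taurine cattle carry a genetic signature that plain
descent-with-drift from Near-Eastern domestic taurine does not explain. One
candidate explanation is introgression from a basal ("deep") taurine
lineage — plausibly the extinct African aurochs — into the ancestors of
breeds such as Muturu. A second, separate question concerns the indicine
(zebu) ancestry of admixed African breeds: it is closest to North-Indian
indicine, yet a small residue of Southeast-Asian indicine affinity remains,
concentrated in short genomic segments.

`admixscan` implements the allele-frequency machinery with which such
questions are asked and, crucially, stress-tested: f-statistics with block
jackknife errors, qpAdm-style mixture models, admixture-graph fitting with
bootstrap model comparison, an explicit coalescent benchmark for
false-positive/false-negative calibration of the introgression signal, and a
windowed f2 scan that localizes minor-ancestry segments.

## The model layer

### f-statistics

For sample allele frequencies $a,b,c,d$ with $n$ called chromosomes per
population, the per-SNP terms are

* $f_2(A,B) = (a-b)^2 - \frac{a(1-a)}{n_A-1} - \frac{b(1-b)}{n_B-1}$
* $f_3(C;A,B) = (c-a)(c-b) - \frac{c(1-c)}{n_C-1}$
* $f_4(A,B;C,D) = (a-b)(c-d)$

averaged over usable SNPs. A pseudo-haploid individual contributes one
chromosome; at $n=1$ the correction's numerator $a(1-a)$ is identically
zero, and we define the correction as 0 there (`min_n = 1`). The resulting
per-population inflation equals that population's expected heterozygosity,
which the graph layer absorbs into terminal drift edges and which cancels
exactly in every $f_4$; standalone `f2Stat`/`f3Stat` default to `min_n = 2`,
where no such inflation exists.

Standard errors come from the weighted delete-one-block jackknife
(Busing–Meijer–van der Leeden pseudovalue form) over contiguous genetic-map
blocks of at most 5 cM (`makeBlocks`), with block SNP counts as weights.
When the input has no genetic map, a constant 1 cM/Mb is assumed — the
analyses here need consistent blocks, not a calibrated map.

### qpAdm

For target $T$, sources $s_1..s_m$ and references $r_0..r_{n-1}$ the matrix
$X_{ij} = f_4(s_i, T; r_j, r_0)$ has rank at most $m-1$ when $T$ is an
$m$-way mixture of the sources' ancestries. Weights minimize the
generalized quadratic form of $w^\top X$ under the joint block-jackknife
covariance (iteratively reweighted closed-form solve with $\sum w = 1$);
the minimized form is $\chi^2$ with $n-m$ degrees of freedom, giving the
model-fit P-value, and weight standard errors come from leave-one-block-out
re-estimation. Weights are deliberately not constrained to $[0,1]$:
excursions outside it are a useful misfit diagnostic and are flagged with a
warning.

The *ghost-lineage* variant (`ghostProportion`) estimates the contribution
of an unsampled deep branch: restrict the references to populations cladal
with the anchor source relative to the deep split, and any population
branching below all references (an outgroup, or an indicine breed) becomes
a valid stand-in for the ghost; its weight estimates the ghost proportion.
The validity condition — cladality of the references — is the caller's
responsibility and is exactly what the restricted reference sets in the
benchmark encode.

### Admixture graphs

A graph is a rooted DAG with drift lengths $c_e \ge 0$ on ordinary edges
and two-parent admixture nodes with mixing weight $\alpha$. Under the
linearized drift model,
$E[f_2(A,B)] = \sum_e (w_A(e) - w_B(e))^2 c_e$ with $w_X(e)$ the
root-to-$X$ path mass through $e$. Fitting minimizes the generalized
least-squares objective over the $f_2$ of all leaf pairs with jackknife
covariance (diagonal-regularized by $10^{-4}\times$ its mean diagonal).
Because the objective is linear in $c_e$ given the alphas, the fit profiles
an exact non-negative least-squares inner solve (ridge-stabilized: graph
designs are structurally rank-deficient, e.g. the two root edges are
collinear in every f2 contrast) inside a multi-start Nelder-Mead/Brent
search over logit-alphas. Fit quality is summarized by the objective
("likelihood score" = its negative, higher better) and by the worst
residual |Z| over all leaf $f_4$ quadruples, whose model values follow from
fitted $f_2$ by the combination identity (so per-leaf pseudo-haploid
inflation cancels).

Model comparison uses the block bootstrap: per replicate, resample the
5-cM blocks with replacement, refit both graphs on the in-bag blocks
(warm-started at the full-data fits), and evaluate each graph's objective
on the out-of-bag blocks, with observed f2 and covariance recomputed from
those blocks (a flag switches to the in-bag covariance). The empirical P is
the fraction of replicates in which the simpler graph scores at least as
well; ties count for the simpler model. Self-comparison of a graph against
itself centres at P ≈ 0.5 because replicate fits receive a small
independent warm-start jitter; without it, exact ties would degenerate the
convention.

## The coalescent benchmark

`buildDemography` encodes the three competing 7-population topologies as
explicit demographies: constant Ne 10,000, 6-year generations, splits at
300 kya/3 Mya (African buffalo), 180 kya (indicine–taurine), 60 kya (deep
taurine), 36/24/15 kya (British/Armenian/Moroccan aurochs), 9 kya
(Sahiwal's taurine donor), 6 kya (Muturu–IranBronzeAge), with pulses of 20%
taurine into Sahiwal (6 kya), 40% deep taurine into the Moroccan aurochs
(12 kya), and — in the gene-flow topologies — 40% Moroccan-related (B-2) or
20% deep-taurine (B-3) ancestry into Muturu at 3 kya. Samples follow the
study design (2+2 diploid buffalo/Sahiwal, 9 diploid Muturu, 1+1+1+2
pseudo-haploid aurochs/IranBronzeAge). `simulateDataset` runs 800 unlinked
50-kb regions through msprime (the bundled Python worker; all demography
encoding, validation and I/O stay in R), yielding ~200,000 biallelic
segregating sites at the 300 kya split; each region is one jackknife
block. All samples are drawn at time 0 — the study states no archaeological
sampling ages for the simulated ancient populations — which slightly
inflates drift on ancient terminal branches; drift lengths are free
parameters in every fit, so this is absorbed.

`fpfnExperiment` wires the whole loop: simulate, build the f2 basis, fit
B-1/B-2/B-3, run the bootstrap comparison, tabulate false positives (a
gene-flow graph significantly better than the true B-1, empirical P <
0.05) and false negatives (B-1 surviving against the true gene-flow
topology, P ≥ 0.05).

### Problem sizes and replicate budgets

The full-scale experiment is 100 datasets × 1000 replicates per condition.
The package's own benchmarks scale down the *datasets* (6 per condition at
300 kya, 3 at 3 Mya in the acceptance script; 2 in the test suite) while
keeping replicate counts high exactly where they matter: the per-dataset
empirical P under gene-flow truths sits at 0.00–0.04 — always below the
0.05 threshold, but close enough that a few-hundred-replicate Monte Carlo
estimate can cross it by discreteness alone. Gene-flow conditions therefore
use 1200 warm-started replicates (optimizer budget 15 iterations per
replicate; win rates verified insensitive between 15 and 100) and the
no-flow condition, whose empirical P sits near 0.5, uses 300.

### The ghost benchmark

The restricted-reference estimator needs at least three cladal references,
but the printed 7-population demography contains only two clean ones
(British and Armenian aurochs — the Moroccan aurochs is itself admixed with
the deep lineage). `buildDemography(..., extra_taurine_refs = TRUE)`
therefore adds two reference demes, "BalkanLike" (split 12 kya, 4
pseudo-haploid samples) and "ShimaoLike" (7 kya, 2 samples), named for the
roles such populations play in real reference panels. Their positions are
a design choice of this package: anywhere inside the taurine clade below
the 60 kya deep split and above the 6 kya Muturu split preserves the
cladality the estimator requires. On B-3 simulations, the buffalo-proxy
estimate recovers ≈ 0.20; indicine proxies run slightly higher, mirroring
the fact that indicine breeds themselves carry taurine ancestry.

## Synthetic generators

`driftSim` draws root frequencies from Uniform(0.05, 0.95) and adds
independent Gaussian increments with variance $c_e$ per edge (clamped to
[0, 1]); admixture nodes average their parents. With constant-variance
increments the generator's expected f2 equals `expectedF2Matrix` *exactly*,
so the two are mutual oracles; boundary clamping is the only bias and is
negligible for the drift scales the tests use (path sums ≲ 0.01 with the
default root law). This is a deliberate trade: real Wright–Fisher drift
scales increment variance by $p(1-p)$, under which expected f2 would be
$\bar{h}\sum c_e$ rather than $\sum c_e$; realism at that level is the
coalescent harness's job.

`mosaicSim` builds diploid target genomes as positional mosaics: minor
donor tracts with exponential lengths (mean 5 kb) from an alternating
renewal process covering an expected fraction φ, the remainder switching
between the two major sources in ~100-kb blocks. Panel frequencies use
$p(1-p)$-scaled drift here (no oracle role); the default donor drift of 1.0
diffusion units emulates the deeply diverged minor contributor the scan
targets, and closely related major sources (0.01) keep the composite-model
residual small. What the generator does *not* emulate: linkage
disequilibrium within panels, mutation/ascertainment structure, and
recombination-mediated tract-length decay — so passing scan tests show the
statistic reacts to short diverged tracts as designed, not that real-data
power equals the synthetic power.

## The localization scan

`binF2Scan` scores fixed half-open bins (anchored at coordinate 0 per
chromosome; 1/10/50 kb defaults) by the mean bias-corrected f2 between the
target's observed frequency and a fixed composite model frequency
$\alpha p_A + (1-\alpha) p_B$ (weights straight from the 2-way qpAdm fit;
no renormalization — mis-summing weights is an error). The correction uses
only the target's sample size: the composite is treated as fixed, its
panels' sampling noise entering instead through the f4 step's jackknife.
The top 1% of scored bins (genome-wide ranking; ties to the lower
coordinate) feed `enrichmentF4`, which contrasts
$f_4(\mathrm{outgroup}, X; \mathrm{composite}, \mathrm{target})$ on
top-bin SNPs against all SNPs, jackknifed over the same blocks restricted
to each SNP set, reported with the ±3 SE display convention. Short minor
tracts produce positive enrichment at 1-kb and 10-kb bins that attenuates
at 50-kb bins (tract dilution); with φ = 0 deltas sit within noise.

## Worked example

```{r example}
library(admixscan)

# simulate one dataset under the B-2 (Moroccan-related gene flow) truth
dem <- buildDemography("B-2", "300kya")
gt <- simulateDataset(dem, seed = 11)
ft <- alleleFrequencies(gt)
blocks <- makeBlocks(gt)

# f2 basis, graph fits, bootstrap comparison
basis <- f2Basis(ft, blocks)
obs <- f2Observed(basis)
fitB1 <- fitGraph(muturuGraph("B-1", with_truth = TRUE), obs, basis = basis)
fitB2 <- fitGraph(muturuGraph("B-2", with_truth = TRUE), obs, basis = basis)
cmp <- bootstrapCompare(muturuGraph("B-1", with_truth = TRUE),
                        muturuGraph("B-2", with_truth = TRUE),
                        basis, n_replicates = 200, seed = 1,
                        fitA = fitB1, fitB = fitB2)
fitB2@alphas       # MUTADM ~ 0.6: donor weight 1 - alpha ~ 0.4
cmp@empiricalP     # << 0.05: the no-flow graph is rejected
```

## Numerical choices, degenerate inputs, limitations

* Covariances are regularized by `1e-4 * mean(diag)` before inversion; the
  qpAdm solve flags near-singular weight systems (duplicated sources) as
  degenerate rather than returning arbitrary weights.
* Graph optimization is deterministic given `seed`; replicate fits are
  warm-started and jittered (σ = 0.05 on the logit scale).
* Empty out-of-bag draws are redrawn and logged; blocks never cross
  chromosomes; SNP subsets spanning fewer than two blocks are an error for
  any jackknifed quantity.
* The 52-bp spacing filter is one reading of an ambiguous rule: scanning
  left to right over the survivors of the other filters, a SNP is dropped
  when the *next* SNP to its right is closer than 52 bp. The rule is
  idempotent under this reading.
* The f2 leaf-pair basis carries the full f-statistic information (all f3
  and f4 are linear combinations), but root-adjacent edges are not
  individually identifiable — only well-determined functionals (alphas,
  internal contrasts, fit scores) should be interpreted.
* Real-data headline numbers (deep-taurine ~13%, 38.2 ± 2.5%, ghost 18–19%
  / 24–27%, empirical P = 0.001, the model-battery counts) require the
  published accession genomes and are shipped as reference values only
  (`referenceEstimates()`); nothing in this package recomputes them.
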