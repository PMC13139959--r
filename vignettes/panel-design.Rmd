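---
title: "Designing and validating species-diagnostic SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating species-diagnostic SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snppanel)
```

## The problem

Recently diverged species complexes often cannot be told apart by the
handful of polymorphisms in standard plant DNA barcodes, while thousands
of genome-wide SNPs from reduced-representation sequencing separate them
easily. A practical identification assay sits between the two: a panel of
a few dozen SNPs, ascertained on a small set of species-representative
reference individuals ("controls"), genotyped cheaply in replicate on a
microfluidic platform, and interpreted by comparing each unknown sample's
alleles with the controls. `snppanel` implements both phases — panel
design from a genome-wide matrix and panel-based identification — along
with a simulator that generates data with exactly the structure the
analysis assumes, so every stage is testable end to end.

## The data model

Genotypes travel as wide tibbles (`sample_id` plus one integer column per
biallelic locus; 0/1/2 alternate-allele counts, `NA` missing). A light
`snp_geno` container adds per-call read depth, genotype quality and
allele depths — only the filter stages need them — plus per-locus
contig/position/allele annotation. Replicated assay runs add a
`replicate` column. A population map ties samples to a group and a role:
`control` samples define the species, `unknown` samples are to be
assigned, `outgroup` and `ntc` rows are excluded from analysis matrices
(no-template-control fluorescence screening happens upstream in the
instrument software; the package honours it as a role flag).

## The simulator and what it does (not) emulate

Population allele frequencies follow the Balding–Nichols model: an
ancestral frequency drawn uniformly from `maf_range` (default 0.1–0.5)
and, per population, a Beta(p(1−F)/F, (1−p)(1−F)/F) draw whose parameter
F is the expected per-locus F_ST. The model was chosen because its single
parameter targets exactly the quantity panel selection windows on.
Defaults mirror the study conditions the package targets: K = 3
populations, per-locus F spread uniformly over 0.2–0.7 so that every
selection window is populated, 2000 loci at desk scale (a down-sampled
stand-in for tens of thousands of discovery SNPs), samples of 20/20/10, a
2% missing-call rate (the ~98% call-rate regime of a well-behaved assay),
and quadruplicate replicates with a 5% per-allele error rate, inside the
2%–10% range typical of allele-specific PCR. Replicate noise flips each
allele copy independently, which biases errors toward heterozygote/
homozygote confusions the way real allele-specific PCR does; dropout is
uniform at random. Admixed individuals draw each allele copy from
population k with probability q_k.

The simulator does *not* emulate linkage, coalescent ancestry,
sequencing-read noise, RAD-locus assembly artefacts, or ascertainment
bias in the control panel. Passing tests therefore demonstrate that the
estimators and decision rules behave correctly on data satisfying their
own assumptions — not that any particular field data set meets those
assumptions.

All randomness flows from one integer seed; multi-stage drivers derive
per-stage substreams from it, so each component run is independently
reproducible.

## Filtering

The discovery cascade masks calls below depth 10 or genotype quality 30,
masks heterozygous calls whose reference-read fraction falls outside
0.25–0.75, then drops loci with minor allele count below 2 (counted on
post-masking calls — masking first is the documented order, since the
order is otherwise underdetermined) or missingness above 0.5. All
boundaries are inclusive: depth exactly 10, balance exactly 0.25, or a
locus at exactly half missing survive. An optional per-sample missingness
cutoff exists but is off by default. The cascade is idempotent and only
ever moves codes to missing or drops loci.

## Diversity and differentiation statistics

Per locus the package reports N, minor allele frequency, observed
heterozygosity, Nei's unbiased gene diversity `2N/(2N−1)(1−p²−q²)`, and
the Botstein biallelic PIC `1−p²−q²−2p²q²`. These two formulas were
adopted because they reproduce the published 23-assay reference table
(bundled as `greyia_panel_stats()`) to three decimals from its printed
N/MAF columns; `reconstruct_genotypes()` rebuilds a genotype composition
from a printed (N, MAF, H_O) triple to make that check executable.
Statistics use pairwise-complete calls, so N varies by locus.

Differentiation is Weir–Cockerham (1984) theta from the a/b/c variance
components; the multilocus estimate is the ratio of summed components,
and 95% CIs come from a percentile bootstrap resampling loci (default
1000 replicates), with significance declared when the CI excludes zero.
The estimator may legitimately be negative near panmixia. Nei's D_A
distance and genetic identity I are computed from group allele
frequencies for group-level summaries.

## Panel selection

Candidate subsets are taken from closed windows on per-locus theta
(defaults 0.3–0.5, 0.5–0.7, 0.8–1; windows are free parameters). Inside
an over-full window the default rule is a seeded uniform draw — the
choice is genuinely arbitrary, so it is randomised reproducibly — with a
"central" (closest-to-midpoint) alternative. Subsets are scored by PCA on
mean-imputed, centered, unscaled genotype codes (no scaling, so
divergence-driven loci dominate) and by the mean silhouette of the known
groups in the PC1–PC2 plane; "three distinct clusters" is
operationalised as silhouette > 0.5, a deliberately conservative
threshold standing in for the visual judgement a human makes on the
plots. Loci diagnostic for a species (all its controls homozygous for one
allele, all other controls homozygous for the other, no missing control
calls) are detected by exhaustive per-locus test. Assay design needs
clean primer-binding sequence, so any candidate within 30 bp of another
SNP on the same contig is excluded. The final panel takes the best
subset's loci — diagnostic loci first, then decreasing theta — up to the
target size, appends any user-supplied barcode loci, de-duplicates, and
re-scores.

## Consensus genotyping and error

Replicates with a call rate at or below 85% are excluded; loci that
amplified in fewer than 80% of all reactions are removed (boundary
inclusive). Consensus is majority logic per sample and locus: two or more
missing replicates give a missing ("insufficient") call; otherwise the
plurality genotype wins, which covers the canonical patterns (three
consistent homozygotes beat one heterozygote; two heterozygotes beat one
each of the contrasting homozygotes). A 2–2 tie that plurality cannot
break — two homozygous-reference against two homozygous-alternate, or
two heterozygotes against two identical homozygotes — becomes missing
and is logged as a `tie`; the source procedure is silent here and
guessing a genotype seemed worse than abstaining. Replicate concordance
is the Match Score: the percentage of allele copies agreeing between two
vectors over loci called in both (a het/hom mismatch costs half), with
the per-sample value averaged over all replicate pairs, and error rate
defined as exactly 100 minus it. The allele-sharing distance used for
assignment is the same quantity on the complementary scale, and the
package asserts that identity in its tests.

## Assignment and clustering

"Shared genotypic information" with a species is the mean allele-sharing
similarity with that species' controls, in percent. The mean (rather
than, say, the maximum over controls) was chosen because it is stable
under uneven control quality; the aggregation is configurable in spirit —
the distance matrix is exposed, so alternatives are one line of dplyr. A
sample is assigned to the top species at or above 80% sharing; below
that it is reported unassigned with its two top fractions, which is how
admixed or intermediate individuals present. UPGMA uses hand-rolled
average-linkage agglomeration so the tie-break is documented
(lexicographically smallest original indices) and bootstrap support
resamples loci, not samples; heights are ultrametric (half the joining
distance). PCoA is classical MDS of the allele-sharing matrix; negative
eigenvalues (expected for non-Euclidean genetic distances) are dropped
with a note and variance percentages refer to the positive part.

The admixture model is the standard binomial mixture
(`g ~ Binomial(2, Σ_k q_ik f_kl)`) fitted by EM block updates, with
cluster frequencies clamped to [1e-6, 1−1e-6], missing genotypes omitted
from the likelihood, and convergence declared when the log-likelihood
gain drops below `tol` (default 1e-6; the trace is returned and is
monotone). K is selected by masking 20% of the non-missing entries,
refitting, predicting masked dosages as 2·Σ q f, and minimising the mean
squared error over (default) five masking replicates for K = 1..6 —
a masked-entry analogue of the cross-validation used by model-based
clustering tools. Individuals with max q below 0.8 are flagged admixed.
Frequency-based assignment tests score each sample's genotype under
Hardy–Weinberg with each group's frequencies, leave-one-out for
controls, with zero frequencies floored at 1/(2N+1).

## Pipelines and problem sizes

`run_discovery()` and `run_identification()` chain the stages under one
seed and return all intermediate artifacts as tibbles. Samples whose
consensus genotyping rate falls below 0.4 are excluded as outgroup-like
(off-target genera fail to amplify) and reported separately.

The test suite runs the whole pipeline at desk scale: hundreds to two
thousand loci, tens of samples, bootstraps of a few hundred replicates.
These sizes were chosen so that every property — estimator recovery
within stated tolerances, ≥95% assignment accuracy over twenty seeded
studies, K = 3 recovery by cross-validation — is demonstrated in well
under a minute per test file; the estimators themselves are vectorised
and handle much larger matrices.

## Known limitations

Biallelic SNPs only; no phasing, imputation, linkage-aware subset
selection, or coancestry MCMC. The genotype-table dialect models a
generic long-format microfluidic export (sample, assay, allele-pair
call); instrument-specific exports may need a column rename. Bootstrap
supports use Newick round-trips through `ape` and are only defined for
bipartitions present in the point-estimate tree. The admixture EM, like
all such likelihoods, has label-switching and local-optimum behaviour;
seeds make runs reproducible, and multiple initialisations can be
emulated by varying the seed.
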