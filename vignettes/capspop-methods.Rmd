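---
title: "Methods: CAPS genotyping and population-genetic analysis in capspop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CAPS genotyping and population-genetic analysis in capspop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capspop)
```

## Scope and data model

`capspop` implements the analysis workflow used to characterize small
germplasm collections typed with CAPS (cleaved amplified polymorphic
sequence, i.e. PCR–RFLP) markers: in-silico assay evaluation, per-locus
diversity statistics, Nei-distance/UPGMA clustering, principal coordinates
analysis, codominant AMOVA with permutation testing, admixture-model
clustering with Evanno's ΔK, and minimum-marker-set selection.

The central container is the `genotype_matrix`: accessions × markers of
unordered diploid allele pairs (`"A/G"`), with `"-/-"` as the on-disk
missing sentinel and `NA` internally. Alleles are stored as nucleotide
symbols rather than abstract 1/2 codes so that the restriction-digestion
machinery and transition/transversion bookkeeping share one vocabulary.
Button-mushroom accessions are heterokaryons; the two nuclear types are
treated as a diploid-equivalent genotype throughout, which is exactly what
a codominant gel readout measures.

The package ships two plain-text transcriptions of the published
70-marker *Agaricus bisporus* panel — the marker definitions
(`table2_markers.tsv`: SNP alleles, enzyme, incubation temperature,
primers) and the per-locus diversity table (`table3_stats.tsv`) — plus a
curated restriction-enzyme table (`enzymes.tsv`). The enzyme motifs follow
standard REBASE prototype definitions; the source study names its 38
enzymes but not their recognition sequences, so this table is an editable
stand-in, not an authoritative database.

## In-silico CAPS assays

A CAPS assay is differential when the SNP creates or destroys a
recognition site, so the two alleles yield different fragment-length
multisets. `find_recognition_sites()` scans both strands of the amplicon
with IUPAC expansion and reports forward-strand coordinates (0-based,
half-open); `digest_amplicon()` cuts at `site + cut_offset` (mirrored as
`site + |motif| − offset` for bottom-strand sites) and skips, with a
warning, cut positions that fall outside the sequence (outside cutters
near an end). The gel is abstracted as a multiset of fragment lengths; no
intensity, dosage, partial digestion or star activity is modeled. A single
cut position per site is used rather than separate top/bottom cut
coordinates — fragment lengths on a gel cannot resolve sticky-end
overhangs.

Genotype calling compares the observed band *set* against the expected
ref-homozygote, alt-homozygote and heterozygote (union) band sets, with
comigrating bands collapsed, because a gel cannot distinguish equal-length
fragments. A pattern matching zero or multiple candidates yields a missing
call with a diagnostic rather than a guess.

## Diversity statistics

Per locus, with allele frequencies \(p_u\) counted over two copies per
non-missing call:

* MAF — the major allele frequency (ties at 0.5 report 0.5);
* NA/NG — observed allele and unordered-genotype class counts;
* gene diversity \(GD = 1 - \sum_u p_u^2\);
* He — the **observed** heterozygote proportion.

He is deliberately observed, not expected, heterozygosity: in the
published table He exceeds \(2pq\) at several loci (e.g. 0.826 at MAF
0.587), which only an observed-proportion definition can produce, and
cultivated heterokaryotic stocks are far from Hardy–Weinberg equilibrium.
No small-sample \(n/(n-1)\) corrections are applied.

Because a k-allele marker system tops out at \(GD_{max} = (k-1)/k\),
`scaled_gene_diversity()` divides by that maximum to compare marker types
(biallelic CAPS/SNP vs multiallelic SSR) on a common scale; the published
comparison uses \(k = 3\), treating a SNP locus as having at most three
observable alleles.

Report output is conventionally rounded to 3 decimals; all internal
computation keeps full precision. A consequence worth knowing: summary
means recomputed from a 3-decimal published table can differ from the
published means by ~0.001 (e.g. polymorphic-mean MAF 0.69902 recomputed
vs 0.698 printed). The acceptance tests therefore compare such quantities
at the printed-precision tolerance (|Δ| ≤ 0.002 for means over ~64 values,
|Δ| ≤ 0.001 for single rounded values), tolerances fixed by rounding
arithmetic before the tests were run.

## Distances, clustering, ordination

Nei's standard distance is defined on frequency profiles; to apply it
between single diploid accessions each individual is given a per-locus
profile (homozygote → 1; heterozygote → 0.5/0.5), and
\(D = -\ln(J_{XY}/\sqrt{J_X J_Y})\) is computed over loci scored in both
individuals (pairwise deletion). Pairs sharing no allele anywhere have
infinite distance; `distance_matrix()` raises an error rather than impute,
since UPGMA is undefined on infinite entries.

UPGMA uses the classic size-weighted cluster-mean update with node height
= merge distance / 2. Ties are broken on the lexicographically smallest
(row, column) pair in the current label order — the literature does not
specify a rule, and determinism matters more than any particular choice.
Newick output orders children by smallest leaf label, serializes branch
lengths at 6 significant digits, and quotes labels containing structural
characters.

PCoA Gower-centers \(-d^2/2\) and eigendecomposes. Percent variance is
computed over positive eigenvalues only; negative eigenvalues are
reported and dropped by default, with an optional Cailliez correction for
users who want a fully Euclidean embedding. Axis signs are fixed by making
each axis's largest-magnitude coordinate positive so output is
reproducible across eigensolvers.

## Codominant AMOVA

Three levels: among populations, among individuals within populations,
within individuals, with df \((P-1, N-P, N)\). The distance between allele
copies is the 0/1 mismatch indicator per locus summed over loci (the
infinite-allele codominant default). Sums of squares come from the
counts identity \(\sum_{i<j} d_{ij} = (m^2 - \sum_u c_u^2)/2\) per group
per locus, divided by group size; variance components are solved from the
expected mean squares with the unequal-size coefficient
\(n_0 = (2N - \sum_p (2N_p)^2/2N)/(P-1)\), truncating negative components
to zero before percentages (GenAlEx convention). Missing calls are
removed locus-wise. Significance permutes whole individuals among
populations (sizes preserved), testing \(F_{ST}\) specifically, with
\(p = (\#\{F_{perm} \ge F_{obs}\} + 1)/(n_{perm}+1)\). Note that
permutations which happen to reconstruct the original partition tie the
observed statistic, so on tiny completely-fixed toys the exact p-value is
the share of partition-reconstructing assignments (1/3 for two
populations of two), not \(1/(n_{perm}+1)\).

## Admixture model and model choice

`run_admixture_gibbs()` is the vanilla no-linkage admixture model:
cluster allele frequencies get a uniform Dirichlet(1) prior, each
individual's admixture vector \(q_i\) a symmetric Dirichlet(α) prior, and
the Gibbs cycle samples copy origins, frequencies, \(q\), and finally α by
a symmetric-proposal Metropolis step (uniform prior on (0, 10], initial
1.0, proposal sd 0.05). The location-informed (LOCPRIOR) variant and the
correlated-frequencies prior are deliberately not implemented: the
workflow's conclusions are group counts and memberships, which the
vanilla model recovers on data of this size, and both extensions add
hyperparameters that obscure what a green test establishes. The sampler
core is compiled (Rcpp) because the acceptance-scale experiments run a
hundred chains; it consumes R's RNG stream, so `seed` gives bit-identical
results.

Model log-evidence is estimated as \(\bar\ell - \mathrm{Var}(\ell)/2\)
(population variance) over recorded iterations, and Evanno's
\(\Delta K = |\bar L(K+1) - 2\bar L(K) + \bar L(K-1)| / s(K)\) uses the
sample (n−1) standard deviation across replicate chains. Membership
classification assigns an accession to its max-q cluster when that q
meets a threshold (default 0.7 — the source workflow names an "Admix"
class but no cutoff) and to "Admix" otherwise. Chain defaults (10,000
burn-in, 100,000 iterations, thinning 10, 10 replicates) mirror common
practice; tests use reduced chains, which is sufficient for the
well-separated synthetic panels they run on.

## Marker selection

"Ability to subdivide the highest number of accessions" is
operationalized as maximizing the count of distinct multilocus genotypes
(MLGs), the only reading consistent with a stop-when-all-distinct rule.
The greedy selector starts from the locus with the highest GD (ties: NG,
then NA, then id; `first_marker` lets users pin the start, since the
published pipeline's first pick does not follow its own stated criterion
— it selects a GD-0.499 locus over the GD-0.500 one). Verification here
is exact profile uniqueness, stronger and more deterministic than the
tree-inspection the source workflow used; a tree on the selected subset
is still emitted for reports. Missing calls match only missing calls, so
missing data can never fake discrimination. An exhaustive breadth-first
oracle (≤ 15 loci) provides ground truth for the greedy heuristic in
tests; greedy is not guaranteed minimal, only feasible-when-possible.

## Synthetic data: what it emulates, and what a green test means

The published genotype matrix itself is not available, so validation runs
on a generator with known truth. `sim_config()` defaults state the
emulated world once: 41 accessions (two core populations of 17 + 7
admixed), 70 biallelic loci with 6 monomorphic, Balding–Nichols
divergence at \(F_{ST} = 0.15\) (the published model-based estimate),
ancestral frequencies uniform on (0.1, 0.9), and homozygote excess
`f_excess = 0.15`, chosen a priori so mean observed He lands near the
published 0.26 panel mean. Population frequencies are
\(\mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)\) draws (mean p, variance
\(p(1-p)F\)); genotypes use heterozygote probability \(2pq(1-f)\);
admixed individuals draw each allele copy through an
individual-specific two-population mixture. Loci are independent — no
linkage, no coalescent history, no genotyping error model — so green
tests establish correctness of the estimators under the stated model,
not robustness to real-data pathologies.

Two stochastic-validation choices deserve emphasis. First, a 70-locus
panel's *realized* differentiation fluctuates around the Balding–Nichols
parameter with replicate sd ≈ \(F\sqrt{2/((P-1)L)}\); at \(F = 0.30\)
that is ~0.03, so requiring the estimate within ±0.04 of the *parameter*
in ≥90% of replicates is unattainable for any estimator, and the
corresponding acceptance clause fails honestly (the estimator is
unbiased: replicate means 0.050/0.151/0.301). A companion test shows the
estimate tracks each replicate's realized differentiation tightly.
Second, generator calibration is asserted on the mean of several seeded
large simulations rather than a single draw, because a single draw
confounds bias with the same locus-sampling noise.

## Numerical conventions

0-based half-open coordinates in all sequence code; allele pairs sorted
lexicographically; missing sentinel `"-/-"`; UPGMA/selection tie-breaks as
above; eigenvalues below `max|λ|·1e-9` treated as zero; `n₀` computed in
allele-copy units; permutation p-values use the +1 correction. Every
stochastic routine takes an explicit seed, and the pipeline derives fixed
per-stage offsets from one global seed, so disabling a stage never
shifts another stage's stream.

## Known limitations

dCAPS mismatch-primer design, primer thermodynamics, methylation
sensitivity, VCF/PLINK ingestion, LOCPRIOR/correlated-frequency structure
models, bootstrap support values, and reproduction of the unpublished
per-accession results (tree memberships, AMOVA sums of squares, the
specific 10-marker set) are all out of scope. The three-group topology of
the source study cannot be checked without its genotype matrix; what the
package validates instead is that each method recovers known structure
from the generator above.
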