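---
title: "Two-tier forensic timber identification: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-tier forensic timber identification: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timberid)
```

## The problem

Verifying where a piece of tropical timber came from is a two-resolution
problem. At the *population* tier, maternally inherited chloroplast DNA is
strongly geographically structured: a haplotype observed only in one region
of a country places any sample carrying it in that region. At the
*individual* tier, a panel of nuclear STR (microsatellite) loci gives each
tree an essentially unique multilocus profile, so a seized log can be
matched to a stump with a quantified random match probability (RMP).

`timberid` implements both tiers for a sampling design of 27 natural
populations split between Western (Peninsular) and Eastern (Bornean)
Malaysia — 1032 trees genotyped at 15 STR loci and a 214-tree subset
sequenced at seven chloroplast intergenic spacers — together with the
statistical machinery that makes the individual tier defensible in a
forensic setting: coancestry/inbreeding-corrected genotype frequencies,
database conservativeness testing, and Bayesian assignment.

## Population tier: the haplotype database

Haplotypes are defined over the variable sites of the concatenated spacer
alignments: nucleotide substitutions plus insertion/deletion events under
**simple indel coding** — a maximal run of adjacent gap-containing columns
is one binary presence/absence character regardless of length
(`extract_variable_sites()`). Columns inside a gap run are scored only for
the indel event; whether a substitution adjacent to an indel should be a
separate character is genuinely ambiguous in the field, and this coding is
our declared convention. Ambiguous bases (`N`) yield an unknown state for
that sample rather than dropping the site.

`collapse_haplotypes()` groups identical state vectors, numbers haplotypes
by descending count (ties broken by first occurrence — the numbering is
presentation-only and permutation-invariant exactly when counts are
distinct), and records each haplotype's per-population occurrence and its
region status: confined to one region or shared. Classification of a query
vector (`classify_haplotype()`) is an exact lookup by default
(`max_unknown = 0`): forensic caution argues against imputing unknown
sites, though unique-completion matching is available behind the argument.
The origin report (`summarize_region_origin()`) attributes a sample to a
region only when its haplotype is region-confined; shared haplotypes are
*ambiguous*, unmatched vectors are *NOVEL*, and both count as
unattributed. Population-level output is always the candidate set of
populations where the haplotype was observed, never a point assignment —
chloroplast resolution supports regional inference only.

## Individual tier: database characterization

`allele_frequencies()` builds per-locus frequency vectors for a pool
(national, regional, or per-population) with a minimum-frequency floor of
$5/(2N)$, so every allele used in an RMP computation is effectively
observed at least five times ($N$ = 1032 gives 0.0024). Flooring does
**not** renormalize the remaining frequencies: leaving the vector summing
to slightly more than one only inflates estimated genotype frequencies,
which is the conservative direction for match probabilities. A
renormalizing variant sits behind `renormalize = TRUE`.

`locus_summary()` reports the standard forensic panel per locus: allele
count $A$, observed heterozygosity $H_o$, Nei's unbiased expected
heterozygosity $H_e = \frac{2n}{2n-1}(1 - \sum_i p_i^2)$ (the estimator
used by the classic population-genetics packages this database style
follows), polymorphic information content
$\mathrm{PIC} = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$, matching
probability $\mathrm{MP} = \sum_g \hat{P}(g)^2$ over observed genotype
proportions, and power of discrimination $\mathrm{PD} = 1 - \mathrm{MP}$.
Monomorphic loci return the degenerate values rather than erroring.

Equilibrium testing uses Monte-Carlo exact tests with a fixed seed and a
`+1`-corrected p-value. For Hardy–Weinberg (`hwe_exact_test()`) the $2n$
observed alleles are re-paired at random and the conditional probability of
the genotype array (the Guo–Thompson statistic) compared with the observed
one; for linkage equilibrium (`le_exact_test()`) one locus's genotype
column is permuted and the contingency-table log-likelihood-ratio (G)
statistic recomputed. Full-enumeration chains are deliberately out of
scope: at these sample sizes the Monte-Carlo versions are exact up to
quantifiable simulation error, and their type-I error is validated against
binomial bounds in the test suite. `multiple_testing()` provides plain
Bonferroni ($p < \alpha/m$; $0.05/15 = 0.0033$ for the panel) and the
sequential (Holm) rule.

## Coancestry and inbreeding

`variance_components()` implements the Weir–Cockerham (1984)
method-of-moments components $a$ (among populations), $b$ (among
individuals within populations) and $c$ (within individuals), per locus
and allele, with the $\bar n$/$n_c$ unequal-sample-size weights and
complete-case handling per locus. Estimates are ratio-of-sums across
alleles and loci:
$$\hat\theta = \frac{\sum a}{\sum(a+b+c)}, \qquad
  \hat f = 1 - \frac{\sum c}{\sum(b+c)},$$
and `bootstrap_ci()` attaches percentile 95% intervals from resampling
loci with replacement (1000 replicates by default) — the percentile
flavour, not BCa, matching the convention of the classic GDA-style
analyses. With a single population the among-population component is
undefined; `f_only = TRUE` permits the within-population estimator (an
all-heterozygote biallelic sample correctly returns $\hat f = -1$). Under
complete fixation between populations $\hat\theta = 1$ and $\hat f$ is
undefined (no within-population allele pairs); it is returned as `NA`.

## Match probabilities: the subpopulation-cum-inbreeding model

Single-locus genotype frequencies (`genotype_frequency()`) follow the
conditional (match-probability) construction: Balding–Nichols sampling
with coancestry $\theta$, extended so within-population inbreeding $f$
enters as an identity-by-descent mixture at the second allele draw:
$$P_{AA} = \frac{2\theta + (1-\theta)p}{1+\theta}
  \left(f + (1-f)\frac{3\theta + (1-\theta)p}{1+2\theta}\right),$$
$$P_{AB} = 2(1-f)\,\frac{\theta + (1-\theta)p_A}{1+\theta}\cdot
  \frac{\theta + (1-\theta)p_B}{1+2\theta}.$$
The literature that names this model cites rather than prints its
equations, so the binding definition here is the set of limit
identities the implementation must satisfy (all enforced in the test
suite): at $f = 0$ it is exactly Balding–Nichols; at $\theta = f = 0$ it
is Hardy–Weinberg; the homozygote probability weakly dominates its
unconditional counterpart and is strictly increasing in $\theta$; and the
`mode = "unconditional"` variant ($p^2 + fp(1-p)$; $2p_ip_j(1-f)$) sums
to one over all genotypes constructible from a locus's allele set. One
documented consequence of the conditional form: heterozygote match
probabilities can fall *below* $2p_ip_j$ for common alleles — a property
of the model, not a defect. Multilocus profile frequencies
(`profile_frequency()`, `profile_frequencies()`) multiply per-locus
match-mode terms over complete profiles only, using floored frequencies
throughout; alleles absent from a database contribute at the floor.

## Conservativeness of the pooled database

A national database understates profile frequencies for individuals from
a differentiated subregion (the Wahlund effect working against the
defendant). `conservativeness_test()` scores every eligible individual
(complete profile, population of at least 16 individuals) twice:
$P_\mathrm{origin}$ against its region's database with region-specific
$(\theta, f)$, and $P_\mathrm{combined}$ against the national database
with the combined parameters, reporting
$d = \log_{10}(P_\mathrm{origin}/P_\mathrm{combined})$ per individual.
The database is conservative for a profile when $d < 0$. Individuals (not
unique profiles) are the test units. The published analyses this follows
are silent on whether $P_\mathrm{origin}$ uses regional or national $f$;
we use the regional estimates and record the choice in the result's
`params` so the alternative convention is one argument away.

`theta_sweep()` raises the combined-database $\theta$ along a grid
(default step 0.01, conventionally starting at the estimated national
$\theta$) recomputing only $P_\mathrm{combined}$ — $P_\mathrm{origin}$
stays fixed — and reports the first grid value per region at which every
test is conservative, plus the full trace (mean $d$, proportion negative,
mean combined profile frequency) for plotting. For all-homozygote
profiles the homozygote monotonicity above makes the negative proportion
provably non-decreasing along the sweep; with heterozygotes the trend is
empirical, which is why the sweep reports a trace instead of assuming
monotonicity. Failure to achieve conservativeness by `theta_max` is a
reported outcome, not an error.

## Bayesian assignment

`rm_genotype_likelihood()` is the Dirichlet posterior-predictive genotype
probability underlying the classic Bayesian assignment method: with a
symmetric Dirichlet$(1/k, \ldots, 1/k)$ prior over the $k$ alleles
observed at a locus across the **whole** reference (the convention of the
standard implementation of the method), a candidate population with
allele counts $n_i$ (total $n$) assigns an unordered genotype
$$P(A_iA_j) = \frac{2(n_i + 1/k)(n_j + 1/k)}{(n+1)(n+2)}, \qquad
  P(A_iA_i) = \frac{(n_i + 1/k)(n_i + 1 + 1/k)}{(n+1)(n+2)}.$$
The prior mass keeps every likelihood positive, including for alleles the
candidate never showed. `self_assign()` runs leave-one-out
self-classification — each individual's two alleles per locus are removed
from its own population's counts before scoring, since resubstitution
self-assignment is trivially optimistic; the flag is exposed because the
convention is not universal. Populations below 16 individuals are
excluded. Region-level rates count an individual as correct when its
best population lies in its true region (the alternative — pooled
regional references — is noted but not used). `assign_query()` scores
unknowns without leave-one-out and withholds any call whose normalized
score (likelihoods scaled to sum to 100) is below the threshold, 80 by
default. Ties are broken by candidate order with a warning.

## The synthetic-data generator

Because the raw genotype matrix behind this kind of reference database is
typically not deposited, validation runs on synthetic data whose
generating process matches the model the corrections assume — which makes
parameter recovery a fair test of the estimators, not a claim about
nature.

`simulate_str_dataset()` draws, per locus, national ancestral frequencies
from a symmetric Dirichlet over the configured allele set, then regional
ancestral vectors by a Balding–Nichols Dirichlet layer
(`theta_between`), then population vectors by the region's $\theta$;
genotypes take both alleles identical-by-descent with probability the
region's $f$. Defaults encode the study conditions: the 27-population
sample-size vector (933 Western, 99 Eastern individuals), the 15-locus
panel with its published allele counts (12–31), regional
$\theta = 0.0333/0.1064$ and $f = 0.0358/0.1248$. Three defaults were
chosen once, on domain grounds:

* `ancestral_alpha = 0.2` — STR allele-frequency spectra are skewed; a
  flat Dirichlet would put every locus near maximal heterozygosity. The
  value 0.2 reproduces the observed characterization scales (locus
  $H_e$ mostly 0.6–0.9, complete-profile frequencies around
  $10^{-12}$–$10^{-18}$ at forensic $\theta$ values).
* `theta_between = 0.03` — an extra between-region layer so the national
  coancestry exceeds both within-region values, as hierarchical
  structure requires.
* `missing_rate = 0.002` per genotype — matches the ~97% complete-profile
  eligibility rate typical of such databases.

`simulate_cpdna_dataset()` constructs 29 distinct haplotype state vectors
over 39 sites (31 substitutions, 8 two-column indel events) embedded in
seven spacer alignments at their published lengths (314, 277, 531, 449,
362, 559, 400 bp), and allocates them to the 214 chloroplast samples so
that the dominant haplotype is Western-confined at 57.5% and present in
every Western population, two haplotypes are shared between regions, 16
occur in single individuals, and the remainder are region-confined.
Backbone columns are invariant, so extraction recovers exactly the
designed sites. `frim_fixture()` emits the worked-example query set: 40
haplotype calls (27/4/2/1 across four known haplotypes plus 6 novel) and,
optionally, STR queries drawn from four northwestern source populations.

What the generator does *not* emulate: STR mutation processes (allele
labels are arbitrary integer sizes), linkage or null alleles, isolation
by distance within regions, and chloroplast mutation dynamics (haplotype
vectors are constructed, not evolved). Passing tests therefore validate
the estimators and the pipeline under the stated model, and say nothing
about, e.g., how the assignment method degrades under unmodelled clines.

## Numerical choices and problem sizes

Monte-Carlo p-values carry the `+1` correction in numerator and
denominator and compare statistics with a `1e-9` tie tolerance; seeds are
explicit arguments everywhere randomness enters, and the simulators
refuse to run without one. Profile frequencies are accumulated in
log10-space. The validation suite uses problem sizes chosen to exercise
the full design at interactive cost: 400 null loci (HWE) and 210 null
locus pairs (LE) at 1999 permutations for the type-I calibration, 50
seeds of the full 1032-individual design for parameter-recovery coverage
(bootstrap 1000 replicates), and the complete national table for the
assignment and conservativeness patterns: Eastern-like populations assign
better than Western-like ones, regions assign better than populations,
and the Eastern-like region needs a larger conservativeness adjustment —
the orderings the real database exhibits.

## Limitations

Chloroplast inference is regional only, and exclusion ("this sample is
from neither region") is not supported: a novel haplotype means *not in
the database*, nothing more. The conservativeness adjustment guarantees
$d < 0$ only for the profiles tested, on the database as built. The
assignment method assumes the candidate set contains the true source;
scores near 100 against the wrong candidate are expected when the true
population is unsampled. Bootstrap intervals across 15 loci undercover
slightly, as percentile intervals at that resampling depth do; this is
visible in the coverage harness and documented rather than corrected.
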