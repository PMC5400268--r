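# timberid

Two-tier forensic identification databases for tropical timber, in R.

Illegal logging is prosecuted on evidence, and DNA is the only label a log
carries that cannot be forged. `timberid` implements the two databases such
evidence rests on, for a sampling design of 27 natural populations split
between Western (Peninsular) and Eastern (Bornean) Malaysia:

* **Population tier** — a chloroplast-DNA haplotype database built from
  aligned intergenic spacers. Haplotypes are defined over substitution
  sites and indel events (simple indel coding: one event, one character);
  a sample carrying a haplotype confined to one region is attributed to
  that region, shared haplotypes are ambiguous, unknown haplotypes are
  novel.
* **Individual tier** — an STR profiling database: allele frequencies with
  a 5/(2N) minimum-frequency floor, locus diversity and forensic
  parameters (Ho, He, PIC, MP, PD), Monte-Carlo exact tests of
  Hardy–Weinberg and linkage equilibrium with Bonferroni/Holm handling,
  Weir–Cockerham coancestry (θ) and inbreeding (f) with locus bootstrap,
  and random match probabilities under the subpopulation-cum-inbreeding
  model:

  P(AA) = [2θ+(1−θ)p]/(1+θ) · ( f + (1−f)·[3θ+(1−θ)p]/(1+2θ) )
  P(AB) = 2(1−f) · [θ+(1−θ)p_A]/(1+θ) · [θ+(1−θ)p_B]/(1+2θ)

  plus the database *conservativeness* test d = log10(P_origin/P_combined)
  with an incremental θ-adjustment sweep, and Bayesian population
  assignment with Dirichlet posterior-predictive genotype likelihoods
  (leave-one-out self-assignment and thresholded query assignment).

A hierarchical-Dirichlet simulator generates STR and chloroplast datasets
with the statistical structure the analysis assumes (region-level θ/f,
the 27-population sample-size design, a dominant region-confined
haplotype), so the
whole pipeline runs and is validated without any external data.

## Worked example

```r
library(timberid)

sim <- simulate_str_dataset(str_sim_config(seed = 1))
sim$table
#> STR genotype table: 1032 individuals x 15 loci
#>   populations: 27  regions: Eastern=99, Western=933
#>   missing genotypes: 0.20%

fit <- bootstrap_ci(sim$table, "Malaysia", reps = 1000, seed = 2)
fit
#> Weir-Cockerham F-statistics - level: Malaysia
#>   theta = 0.0455  95% CI [ 0.0400 , 0.0510 ]
#>   f     = 0.0439  95% CI [ 0.0321 , 0.0540 ]
#>   ( 1000 bootstrap replicates across loci )

afd <- allele_frequencies(sim$table, "Malaysia")
afd
#> allele frequency database [Malaysia]: 15 loci, N = 1032, floor 5/(2N) = 0.0024 (applied)

id <- sim$table$ids[complete_profiles(sim$table)][1]
profile_frequency(sim$table, id, afd, theta = fit$theta, f = fit$f)
#> profile frequency for P01_001 against Malaysia (theta = 0.0455, f = 0.0439)
#>   P(profile) = 6.0498e-16   RMP: 1 in 1.6529e+15

theta_sweep(sim$table, theta_start = fit$theta, f_combined = fit$f)
#> coancestry adjustment sweep (start 0.04553 , step 0.01 )
#>   Western: fully conservative at theta = 0.0455
#>   Eastern: fully conservative at theta = 0.2355

self_assign(sim$table)
#> Bayesian self-assignment (leave-one-out), 24 candidate populations
#>   Eastern: 96.97% by population, 96.97% by region (n = 99)
#>   Western: 55.85% by population, 99.89% by region (n = 906)
```

Reading the output: each simulated tree's 15-locus profile is rarer than
one in 10^15 against the national database, so a profile match is
individual-level evidence. The national database is already conservative
for the weakly differentiated Western region at the estimated national θ,
but the strongly differentiated Eastern region (θ ≈ 0.11) needs the
combined-database θ raised to ≈ 0.24 before every Eastern profile's
national frequency is an overstatement — the safe direction for casework.
The more differentiated Eastern populations also self-assign far better
(97% vs 56%), while region-level assignment is near-perfect everywhere.

The population tier, on simulated chloroplast data:

```r
cp <- simulate_cpdna_dataset(cp_sim_config(seed = 1))
db <- collapse_haplotypes(extract_variable_sites(cp$alignments), cp$sample_pops)
db
#> haplotype database: 29 haplotypes over 39 variable sites; 214 samples
#>   region status: confined:Eastern=8, confined:Western=19, shared=2
#>   unique (single-population) haplotypes: 21

fx <- frim_fixture(with_queries = FALSE)   # 40-sample planted-stand query set
summarize_region_origin(fx$calls)
#>      Western      Eastern unattributed
#>           75            0           25
```

Of the 40 queried trees, 30 carry haplotypes confined to Western Malaysia
(75.0%); the rest carry a region-shared haplotype or none known, and stay
unattributed.

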