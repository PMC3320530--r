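---
title: "Models and methods behind citrusnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind citrusnp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(citrusnp)
```

## The problem

Cultivated *Citrus* is an extreme case for SNP-array population genetics:
a few strongly differentiated ancestral gene pools (mandarins,
*C. reticulata*; pummelos, *C. maxima*; citrons, *C. medica*; wild
papedas), held apart by geography and breeding system, plus commercially
dominant "secondary species" (sweet and sour orange, grapefruit, lemon,
limes) that are interspecific hybrids frozen by apomixis and grafting —
clones carrying *fixed heterozygosity* rather than segregating
populations. Array markers for such a genus are typically mined from a
single heterozygous genotype, which injects two coupled artifacts that
this package is built to expose and to work around:

* **Ascertainment bias.** Markers required to be heterozygous in the
  discovery genotype over-sample the discovery taxon's internal diversity
  and under-sample between-taxon differentiation.
* **Null alleles.** Probe-site polymorphism in distant taxa silences one
  or both alleles; a heterozygous carrier of a null is indistinguishable
  from the expected homozygote, so naive allele frequencies are biased
  taxon-dependently.

Every stage therefore runs in two marker regimes: loci *without* null
alleles (WONA, categories C2+C5 below), analyzed with standard
allele-frequency machinery, and loci *with* null alleles (WNA, C3+C4+C6),
analyzed with genotype-state statistics that never pretend allele
frequencies are observable.

## Genotype model

A call is an unordered diploid pair over `{A, B, 0}` where `0` is the
null allele; `00` (a reproducible no-signal genotype) is distinct from
missing (assay failure). Stored calls may contain nulls (the synthetic
generator knows the truth); what an array reports is the *observable*
collapse `A0 -> AA`, `B0 -> BB`, applied by `observed_calls()` at the
entry of every analysis, never in storage.

## Marker classification from F1 segregation

Category assignment (`classify_locus()`) mirrors array QC practice on a
wide cross (here "Chandler"-like female x discovery genotype):

* **C1** technical failure. The original criterion is fluorescence
  clustering failure; without intensities we operationalize it as call
  rate < 80% (a documented proxy; the threshold is a tunable with little
  sensitivity because failed loci are far below it).
* **C2/C3** discovery genotype heterozygous. Progeny counts are tested by
  chi-square goodness of fit against *every* parental-genotype hypothesis
  compatible with the observed parent calls — each observed homozygote
  may hide a null heterozygote — with expected observable-state ratios
  derived by gamete enumeration (e.g. `AB x A0` gives A-like : AB :
  B-like = 2:1:1; the unexpected B-like homozygote is what betrays the
  null). A null-bearing best model, or null homozygotes seen in the
  germplasm, yields C3; otherwise C2.
* **C4** the best segregation model makes the discovery genotype itself a
  null heterozygote (the `00 x 0A` pattern: half the progeny null
  homozygous).
* **C5/C6/C8** no segregation from the discovery genotype: ordinary SNP
  polymorphism without null states in the germplasm (C5), null
  presence/absence polymorphism (C6), monomorphic (C8). We assign C6
  whenever null homozygotes are observed, even alongside SNP
  polymorphism: WONA must stay genuinely free of null alleles, which is
  what its downstream allele-frequency statistics assume.
* **C7** heterozygous-like in every sample including a haploid control —
  the signature of a duplicated locus (two paralogs fixed for different
  alleles); a homozygous haploid control contradicts the diagnosis and
  the locus is reported `unassigned` rather than guessed.

Numerical choices: segregation alpha is 0.01 with **no multiple-testing
correction** — this is per-locus QC screening, not inference, and a
correction would only hide genuinely distorted loci. Ties between models
with equal p-value resolve to the hypothesis with fewer null alleles
(parsimony). A consequence of any alpha is that about 1% of true C2 loci
are rejected by sampling noise and surface as `unassigned`; we consider
an honest `unassigned` preferable to a silent guess, and overall category
recovery on the default scenario is ~99.7%.

Valid-set selection keeps loci with **strictly less than 5% missing
data** (`select_valid()`, `max_missing = 0.05`).

## Diversity and F-statistics

* He is plain Nei gene diversity `1 - sum(p^2)` (biased form). The
  small-sample correction `2n/(2n-1)` is available via the `n` argument
  of `nei_he()` but is off by default; with the group sizes in play the
  difference is below the reported precision.
* Ho is the per-locus heterozygote fraction among non-missing calls;
  in null-aware (WNA) summaries `00` is excluded from the denominator
  and the null-homozygote frequency is reported as its own column.
* GD, genotypic diversity `1 - sum(g_i^2)` over observed genotype-state
  frequencies, replaces He where null alleles make allele frequencies
  unobservable.
* The `+/-` reported with per-group means is the standard error over
  loci; for F-statistics it is a jackknife-over-loci SE.
* F-statistics use the Weir-Cockerham (1984) per-locus variance
  components (a, b, c) combined as ratios of sums across loci:
  `Fst = sum(a)/sum(a+b+c)`, `Fit = sum(a+b)/sum(a+b+c)`,
  `Fis = sum(b)/sum(b+c)`; the Wright identity
  `(1-Fit) = (1-Fis)(1-Fst)` then holds exactly by construction. The
  fixation index printed in per-group tables is `F = 1 - Ho/He` (Wright's
  form on the pooled means); both definitions are available because
  published tables do not always say which they use.

## Distances, trees, ordination

The simple-matching dissimilarity between accessions i and j is
`d = 1 - mean(m_l/2)` over loci typed in both, `m_l` being the multiset
intersection of the two allele pairs. On WONA loci `00` is treated as
missing; a `null_as_state` flag matches the null allele like any allele
for WNA runs.

Neighbor joining is the standard Saitou-Nei agglomeration. Because
published "weighted NJ" options in legacy software are unspecified, we
fix the canonical branch-length update and make the two numerically
loose spots explicit: ties on the Q criterion break deterministically to
the lowest-index pair, and negative branch lengths are clamped to zero
with the length transferred to the sister edge (path length of the
joined pair preserved). `ape::nj` serves as an independent oracle in the
test suite. Bootstrap support resamples *loci* with replacement
(`bootstrap_nj()`), rebuilding distance and tree per replicate; support
is the percentage of replicates containing each internal bipartition.
Figures conventionally show only values above 60% but all are kept.

PCA runs on the individual-by-allele frequency matrix (0/0.5/1 per
allele column), columns centered on the **active** individuals only and
not variance-scaled (all columns share the frequency scale — the
covariance, not correlation, convention). Supplementary individuals are
projected onto the active axes and cannot influence them, which is what
makes hybrid placement against parental-pool axes honest. Missing and
`00` cells are imputed with the active column mean; zero-variance
columns are dropped with a message. A variable's cos² on an axis is its
squared correlation with the axis scores; the two columns of a biallelic
locus are collinear and share one value (`locus_cos2()`), which on a
two-taxon active PCA tracks per-locus Fst almost perfectly (r² > 0.8 on
the default scenario).

## Linkage disequilibrium

With unphased diploids we use composite LD: r² is the squared Pearson
correlation of 0/1/2 allele dosages over pairwise-complete accessions
(`00` and missing are dropped; pairs with fewer than 5 complete
observations are skipped). Significance is a seeded Monte-Carlo exact
test — permute one dosage vector B times, `p = (hits+1)/(B+1)` — because
the legacy "exact test" procedure is not published. The scientific
contrast of interest needs no p-values at all: in a stratified germplasm
even unlinked loci are correlated, so mean r² in the germplasm panel
must exceed mean r² in the F1 progeny (where only true linkage could
generate it, and none is simulated).

## Parentage by incompatibility counting

For a trio, a locus is *genotype-incompatible* when no allele of parent
A combined with an allele of parent B recomposes the hybrid genotype,
and *orphan-allele* when no reading of the hybrid is contained in the
union of parental alleles (a strictly stronger exclusion, so
orphan-count <= incompatible-count always). Null-aware mode lets every
observed homozygote — parental or hybrid — also read as X/null, which
can only remove exclusions, never add them. Both counters are reported
because published "% agreement" figures do not state which was used.
Candidate pair ranking sorts by incompatibilities, then orphans, then
lexically — fully deterministic.

## The synthetic gene pool

There is no deposited genotype matrix, so the generator *is* the study
condition and everything downstream is tested against its ground truth:

* **Divergence**: ancestral frequency `p ~ U(0.05, 0.95)` per locus;
  taxon frequencies Beta-distributed with mean p and variance
  `F p(1-p)` (Balding-Nichols) — the minimal model that produces the
  strong stratification observed in the genus. Default F = 0.6 for all
  taxa, inside the published 0.4-0.8 between-taxa band; realized
  multi-locus Fst is verified within ±0.05 at large n.
* **Sample sizes**: 12 mandarin-like, 10 pummelo-like, 5 citron-like,
  5 papeda-like accessions, mirroring a real germplasm panel; hybrid
  groups (sweet orange, sour orange, clementine = mandarin x sweet
  orange, grapefruit, lemon, Mexican lime) each a single F1 genotype
  emitted as clonal copies — fixed heterozygosity by construction.
* **Null alleles** live on a null-prone subset of loci (default fraction
  0.19 ~ 116/622) with taxon-specific allele frequencies 0.33 / 0.78 /
  0.80 / 0.69, chosen so the expected null-homozygote frequencies
  (nu² under HWE) land near the published 0.11 / 0.61 / 0.64 / 0.47 —
  low in the discovery taxon, high outside it.
* **Duplicated loci** (4%) are heterozygous-like in everyone including
  the haploid control; **failed loci** (5%) carry 50% missingness.
* **The cross**: 52 F1 progeny of pummelo-like female x the discovery
  hybrid, each drawing one allele per parent per locus, *unlinked* —
  deliberate: germplasm LD here must come from structure alone, which is
  exactly the contrast the LD stage measures. Nulls are inherited as
  alleles.
* **Observation**: null collapse, then symmetric allele-swap genotyping
  error, then missingness. Defaults are noise-free so category truth is
  exactly attributable; tests switch error on explicitly when they need
  it.

What the generator does **not** emulate: linkage maps and LD decay with
distance, coalescent within-taxon history, allele-specific intensity
behaviour, taxon-specific inbreeding (HWE within taxa is assumed, as the
near-zero published within-taxon Fis supports), and secondary admixture
beyond single F1 events. Passing tests therefore validate the
*estimators and their bias directions*, not any claim about real citrus
data.

## Problem sizes and determinism

The default scenario is 600 loci x ~95 samples (seed 42), which keeps
the full test suite under two minutes while leaving every Monte-Carlo
margin wide; the calibration checks that need asymptotics (Fst recovery,
HWE Ho=He) raise n to 240 accessions / 3000 loci locally in their own
tests. All randomness flows from explicit integer seeds: the generator
from `sim_config(seed=)`, bootstrap and permutation tests from `seed`
arguments, and the pipeline derives per-stage substreams from one root
seed, so a rerun with the same configuration reproduces every output
digest in its manifest.

## Known limitations

* Category C1 is a missingness proxy, not an intensity-cluster decision.
* The chi-square goodness of fit is asymptotic; with 52 progeny and
  expected classes of 13 it is adequate for screening but an exact
  multinomial test would be preferable at much smaller progeny sizes.
* Composite r² differs from haplotype-EM r² under strong departure from
  HWE; in a panel of clones this is a real (documented) difference, and
  the germplasm-vs-progeny contrast is robust to it.
* `percent_agreement` counts loci, so its scale depends on the locus set
  used; compare hypotheses only within one locus set.
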