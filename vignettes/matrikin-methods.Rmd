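---
title: "Models and design choices in matrikin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in matrikin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matrikin)
```

`matrikin` reconstructs kinship and social structure of a small endogamous
community from pseudo-haploid genotypes, and ships a synthetic community
generator whose exact truth tables make every inference stage testable. This
vignette is the package's account of the underlying models, the parameters
that matter, the numerical choices, and the places where the design was
genuinely open.

## The data model

All genotypes are *pseudo-haploid*: one sampled allele per site per
individual, coded 0/1/`NA`. This is the standard representation for
low-coverage ancient genomes, where a single high-quality read is sampled per
site; there are no heterozygotes by construction. Coordinates are half-open
`[start, end)` intervals in centimorgans, 0-based, with one constant
cM-per-bp rate per chromosome (`genetic_map()`); physical positions appear
only at file boundaries (1 Mb windows, EIGENSTRAT `.snp` files, which store
Morgans as is conventional). The default map is a 22-autosome, ~35 Morgan
approximation of the human autosomal map at SNP-capture scale; tests use a
3-chromosome toy map (330 cM) because every algorithm is length-agnostic.

## Pairwise mismatch and degree classification

For individuals $a, b$ the statistic is the proportion $P_0$ of jointly
called sites at which their sampled alleles differ, computed in 1 Mb
non-overlapping windows and averaged (unweighted) over windows with at least
`min_overlap = 20` jointly called sites — the floor bounds the variance a
single window can contribute; windows below it are dropped, and a pair with
no retained window is flagged and excluded rather than guessed at.

If a relationship spends genome fractions $(k_0, k_1, k_2)$ in states with
0/1/2 haplotypes shared identical-by-descent, then under pseudo-haploid
sampling

$$E[P_0] = b\,(1 - k_1/4 - k_2/2),$$

where $b$ is the unrelated-pair expectation. Normalised by $b$ this gives 1
(unrelated), 7/8 (second degree), 3/4 (first degree), 1/2 (identical); the
classifier's cutoffs 0.90625, 0.8125, 0.625 are exactly the midpoints of
adjacent tiers. Cutoffs are applied with strict less-than, so a pair sitting
exactly on a boundary takes the more distant class. The baseline defaults to
the *median of mean $P_0$ across all pairs*, on the assumption that the
typical pair is unrelated. That assumption degrades in heavily related
cohorts: the median then absorbs the background relatedness, all normalised
values inflate, and pairs near the second-degree boundary leak into
"unrelated". We keep the median default because it requires no external
data, expose `baseline =` for cohorts with a better external estimate, and
quantify the consequence below under "Known limitations".

`kin_classify()` is a deliberate simplification of HMM-based IBD-state
classifiers: window $P_0$ values are modelled as a mixture over the three
IBD states with weights $(k_0, k_1, k_2)$ and means $(b, 0.75b, 0.5b)$, the
observation model being a normal approximation to the binomial window count
whose variance is inflated by `error_spread = 1.5` (post-mortem damage,
mapping error and window-to-window rate variation overdisperse real data
relative to binomial). It ignores the genomic autocorrelation of IBD states
— window likelihoods multiply as if independent — which costs power but not
consistency for the model-selection use made of it; the log-likelihood-ratio
acceptance threshold of 1.0 follows the convention for such classifiers.
Parent–child and sibling relationships share $E[P_0]$ (both first degree)
and are separated only by window-level dispersion ($k_2 > 0$ adds a
lower-mean mode), so this classifier wants larger windows than the cutoff
classifier: 10 Mb by default (`window_grid(sites, 1e7)`), matching the scale
at which IBD segments of close relatives span whole windows.

## Uniparental lineages

A haplogroup tree is a labelled rooted tree whose branches carry defining
SNPs with ancestral/derived states; haplogroup $h$'s theoretical genotype is
derived exactly on its root path. The similarity score of a sample against
$h$ is the fraction of its called markers matching $h$'s theoretical allele
— normalising by markers called (not raw matches) keeps samples of different
coverage comparable. Alleles matching neither state count as mismatches
against every haplogroup (conservative), ties are reported as ties rather
than broken by coin flip, and samples with fewer than `min_snps = 1000`
called markers fail QC (the conventional floor for low-coverage Y calls;
configurable, since toy trees have far fewer markers).

Matrilines are recovered from mtDNA as connected components of the
zero-difference graph of consensus sequences — the operational criterion
being that members of one maternal lineage have *identical* mtDNA — with the
minimum between-component difference reported as the separation of the
inferred matrilines.

Simpson diversity is exposed in both the plain ($1 - \sum p_i^2$) and
unbiased ($1 - \sum n_i(n_i-1)/(N(N-1))$) forms because published values in
this field mix the two: a set of $K$ singletons has unbiased diversity
exactly 1 but plain diversity $1 - 1/K$, so Y-lineage statements like "three
males, three lineages, diversity 1" require the unbiased form, while
frequency statements such as a 44:2 split rounding to 0.08 match the plain
form. Both are returned by `simpson_index()`; choosing per marker system is
left to the caller, as done in `run_pipeline()` (plain for mtDNA
frequencies, unbiased for Y counts).

## ROH tracts and effective population size

We model the homozygosity structure of one diploid genome as the partition
of each chromosome into tracts delimited by recombination events whose
interiors coalesce to a single ancestor at TMRCA $t$ (generations). With
diploid effective size $N_e$ and $\lambda = 1/(2N_e)$:

* the TMRCA at a fixed genomic position is exponential, $t \sim
  \mathrm{Exp}(\lambda)$ (mean $2N_e$) — the continuous-time limit of the
  discrete geometric coalescent, with $O(1/N_e)$ error;
* conditional on $t$, recombination events accrue at rate $2t$ per Morgan,
  so tract lengths are $\mathrm{Exp}(2t)$;
* mixing over the TMRCA marginal gives the density of interior tracts of
  length $l$ (Morgans) per Morgan of map:
  $$n(l) = \int_0^\infty 4t^2 e^{-2tl}\,\lambda e^{-\lambda t}\,dt
         = \frac{8\lambda}{(2l+\lambda)^3}.$$

**The redraw law at breakpoints matters.** A tract simulator must decide
what TMRCA the *next* tract takes after a recombination event. Redrawing
from the marginal $\mathrm{Exp}(\lambda)$ is tempting but wrong: tracts with
small $t$ are long, so the per-tract and per-position TMRCA laws differ, and
the marginal-redraw walk drifts away from stationarity (its per-tract length
density is $2\lambda/(2l+\lambda)^2$, not the mixture above). Balance of the
jump process $t \mapsto$ new $t$ at rate $2t$ shows the unique redraw that
keeps the position marginal $\mathrm{Exp}(\lambda)$ invariant is the
recombination-rate-biased law with density $\propto t\,\lambda e^{-\lambda
t}$, i.e. $\mathrm{Gamma}(2, \lambda)$. `simulate_roh_tracts()` therefore
draws the chromosome-start TMRCA from $\mathrm{Exp}(\lambda)$ and redraws
$\mathrm{Gamma}(2, \lambda)$ at each breakpoint; the closed form $n(l)$ is
then *exact* for interior tracts, which is what the test suite verifies by
simulation. Tract-to-tract TMRCA correlations (SMC vs SMC′-style) are
deliberately not modelled: the binned counts the estimator consumes depend
only on the marginal tract-length mixture, which the independent redraw
preserves.

Finite chromosomes truncate terminal tracts; they are returned (tract
lengths partition each chromosome exactly) but flagged `interior = FALSE`
and excluded from binned counts, and the expectation uses the matching
$(L - l)^+$ weighting:
$E[\text{count in } [l_1, l_2)] = \sum_c \int_{l_1}^{\min(l_2, L_c)} n(l)\,
(L_c - l)\,dl$, evaluated in closed form.

$N_e$ is estimated by treating total observed ROH counts in the 4–8, 8–12
and 12–20 cM bins as independent Poisson draws with mean $n \cdot
E[\text{count}](N_e)$, maximised on a log-spaced grid (50–20,000) with
golden-section refinement; the 95% CI is the profile set $\{N_e : \log L \ge
\log L_{max} - 1.92\}$. The 4–20 cM range is where counts respond to
population size; segments above 20 cM respond to recent consanguinity
instead, which is why individuals with more than 40 cM of such segments are
excluded before fitting (`exclude_threshold_cM`, configurable to 50, a
variant threshold also in circulation), and more than 100 cM flags probable
close consanguinity. All-zero counts leave the upper CI bound unbounded and
are reported as such.

## The synthetic community generator

The generator emulates the statistical structure this pipeline is designed
to detect: a small sedentary community of `n_clans = 2` matrilineal clans
persisting `generations = 10` (a multi-century occupation), burying its dead
by maternal clan, with `endogamy_prob = 0.9` of finding a mate inside the
community — the remainder are external men contributing fresh haplotypes and
Y lineages, the male-in-migration pattern expected around a matrilineal
core. Each clan's founding females share one matriline label and one
founding mtDNA lineage (clan = matriline by construction; founding lineages
are seeded `mt_clan_mutations = 5` private mutations apart, and transmission
adds a private singleton with probability `mt_mut_prob = 0.01`). Mothers are
capped at `founders_per_clan = 20` per clan per generation with
Poisson(`offspring_mean = 2.5`) children per couple, holding the census near
one hundred per generation — small enough for drift to generate the high
short/medium ROH burden and pervasive distant relatedness characteristic of
such communities. Parent–offspring and full-sib unions are avoided by
default (`avoid_close_kin`), reflecting that consanguinity is typically
incidental, not preferred. Genotypes default to 100k SNPs with 30%
missingness and a 0.5% per-call error, aDNA-like degradation at capture-panel
scale. Founder allele frequencies follow a Beta(0.5, 0.5) spectrum truncated
to [0.05, 0.95]: a folded-SNP-panel-like shape whose truncation keeps
mismatch statistics informative at every site.

Truth tables are exact, not estimated: pedigree degrees map the kinship
coefficient $\varphi$ through the band rule (degree $d$ iff $\varphi \in
(1.5 \cdot 2^{-(d+2)}, 1.5 \cdot 2^{-(d+1)}]$, self = 0, beyond 6 =
unrelated), and true IBD/ROH segments are interval algebra on the
founder-haplotype mosaics from gene dropping (Poisson crossovers, no
interference — consistent with the coalescent model above, and what makes
dense grid-scan oracles exact).

What the generator does *not* emulate: sequencing reads and post-mortem
damage patterns (missingness and symmetric allele error stand in for them),
reference bias, the X chromosome, crossover interference, population
substructure beyond the external-mate mechanism, and deep ancestry — all
founders are unrelated, so coalescence older than the simulated pedigree
does not exist. Passing tests on this generator therefore demonstrate the
*inference machinery* (window arithmetic, cutoff calibration, likelihoods,
interval algebra, permutation calibration), not robustness to damage or
reference artefacts.

## Known limitations and open choices

**Degree recovery degrades with pedigree depth under endogamy.** In a
ten-generation endogamous community, the median pair is itself distantly
related; the median-based baseline then absorbs that background, and truth
degrees defined on the *total* kinship coefficient disagree with
classification defined on kinship *excess over the cohort median* for pairs
near the second-degree band edge. The recovery test therefore validates the
classifier on a five-generation community (founders 25 per clan, 50 sampled,
100k sites, 30% missingness), where pedigree degrees are identifiable; at
full depth, second-degree recovery against band-rule truth drops well below
the shallow-pedigree rate even though first-degree recovery is unaffected.
An externally calibrated baseline is the remedy `read_classify(baseline =)`
exposes.

**Pedigree-based $N_e$ reads high.** Truth ROH from a $G$-generation
pedigree lack all coalescences older than $G$, which depletes the 4–8 cM bin
most; estimates from shallow pedigrees are upward-biased (the census-scale
cross-check in the test suite uses a 25-generation closed population, deep
enough for the 4–20 cM bins to equilibrate at census ~50). The coalescent
tract simulator has no such truncation and is the right source for
calibration curves.

**Absolute-cutoff rounding.** At baseline 0.214 the normalised identical
cutoff 0.625 gives 0.134, while 0.136 also circulates for that quantity; the
normalised cutoffs are primary in this package and the absolute values are
derived from them, so the discrepancy is surfaced here rather than resolved.

**Which Simpson estimator** a published value used is often unstated; both
are exported and the pipeline's choice (plain for mtDNA frequencies,
unbiased for Y counts) is recorded in its report.

**Statistical honesty of the intra/inter test.** Cumulative-IBD values of
pairs sharing an individual are dependent, so the Welch t-test on pairs is
anti-conservative; it is reported for comparability, but the headline
p-value is the label permutation (individual cemetery labels shuffled, mean
difference recomputed), which respects the dependence.

**Permutation conventions.** All permutation p-values use add-one smoothing
$(1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n_{perm})$ with
`n_perm = 9999` by default (stable three-decimal resolution); seeds are
required arguments and are logged in pipeline reports. Mantel tests use the
standard joint row/column permutation (via `vegan::mantel`) with genetic
distance $1 - \text{cumulative IBD}/\text{map length}$, falling back to
degree rank when IBD summaries are absent.

**Problem sizes in the test suite** (chosen as desk-scale validation sizes):
the simulator-vs-closed-form check uses 1,000 diploid genomes at $N_e \in
\{100, 500, 2000\}$ with three-standard-error bands; CI coverage uses 50
replicates of 1,000 genomes at $N_e = 300$; the k-vector identity uses 30
pairs of 50k sites per relationship; degree recovery uses one 50-individual
cohort at 100k sites; burial-rule discrimination uses 20 communities per
rule at the generator defaults. Mendelian segment-fraction checks use 500 to
1,000 replicate pairs on the toy map.

## Reproducibility

Every stochastic function takes an explicit seed and restores the caller's
RNG state; identical `(config, seed)` reproduce outputs byte-for-byte
(`run_pipeline()` reports embed the seed, a configuration hash and the
package version). Writers emit deterministic column order; readers reject
malformed input — dimension mismatches, non-monotone map positions, illegal
genotype codes — rather than coercing it. Pseudo-haploid `.geno` files use
the `{0, 2, 9}` alphabet (never 1) to signal haploid calls inside a diploid
container; consumers assuming diploid dosage would misread them, which is
why the writer never emits heterozygote codes.
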