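---
title: "Methods: from IUPAC-coded dikaryon alignments to diversity, concordance and recombination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from IUPAC-coded dikaryon alignments to diversity, concordance and recombination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycopop)
```

`mycopop` analyses multilocus sequence data from dikaryotic fungi — the
situation where each field specimen is a two-nucleus mycelium, so direct
sequencing returns one composite sequence per locus with heterozygous
positions coded as two-base IUPAC symbols.  This vignette explains the
statistical machinery stage by stage, the assumptions each stage makes,
the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical and design
choices a maintainer would want written down.

## 1. Alignments and site classification

Input alignments are pre-aligned FASTA, one file per locus.  The package
deliberately supports one gap dialect (`-`) and only the six two-base
ambiguity codes (`R Y M K W S`); `.` gaps and three/four-fold codes
(`B D H V N`) raise errors rather than being guessed.  The rationale: a
biallelic dikaryon cannot carry more than two alleles at a site, so a
three-fold code indicates an upstream base-calling problem the analyst
should see, not something to absorb silently.

`classify_sites()` expands heterozygous codes into both bases before
judging variability, so a column that is `A` everywhere except one `R`
strain is a substitution site.  Any column containing a gap is an indel
site — gap takes precedence over substitution variation, which is
instead flagged in the per-site detail table (`substitution_within_indel`).
Consecutive indel columns form maximal disjoint *tracks*, each read as
one insertion/deletion event region.  With this convention the identity
`n_variable = n_substitution + n_indel_sites` holds by construction and
is asserted property-style in the tests.

## 2. Genotypes and genotypic diversity

The genotyping unit is the strain's full aligned composite string —
gaps and ambiguity codes included, so an indel difference or `Y` vs `T`
separates sequence types.  This treats each dikaryon's unphased
composite as the observable, which is exactly what direct sequencing
delivers.

Diversity per population is the unbiased probability that two isolates
drawn at random have different genotypes:

$$D = \Bigl(1 - \sum_i p_i^2\Bigr)\frac{n}{n-1}, \qquad p_i = c_i/n .$$

The $n/(n-1)$ factor makes this the exact without-replacement pair
probability, $1 - \sum_i c_i(c_i-1)/(n(n-1))$; the test suite checks the
formula against literal pair enumeration for every count vector up to
$n = 12$.  Values are kept at full precision and rounded to three
decimals only in reports.  Populations of one isolate get `NA`
(undefined), never 0.  One published table row this package was checked
against is internally inconsistent: the Ailaoshan genotype counts give
$D = 0.943$ under the stated formula while the table prints 0.945; the
package reports the recomputed value and surfaces the discrepancy
rather than "correcting" either number.

## 3. Divergence between lineages

For a pair of lineages, every aligned site is classified from the two
per-group state sets (heterozygotes expanded; `-` a full state): *fixed*
(both monomorphic, disjoint), *private* to group 1 or 2 (polymorphic in
one, monomorphic in the other — whether or not the states overlap, which
is the standard partition), *shared* (both polymorphic, ≥ 2 common
states), or *other* (both polymorphic, < 2 common states; rare, kept as
its own category so that categories partition the segregating sites
exactly).  Expanding heterozygotes means a single `R` strain makes its
group polymorphic — consistent with treating each dikaryon as two
alleles.  Gaps being full states means planted indel tracks count toward
fixed differences, matching how indels are counted among polymorphisms
in this kind of study.

## 4. Maximum parsimony, concordance, constraint

Parsimony scoring is Fitch's post-order state-set pass (intersection if
non-empty, else union and one step), vectorized over characters with
four-bit state masks.  Gaps are treated as **missing data** in scoring —
the indel signal already enters the genotype and divergence stages, and
double-counting it as a fifth state would let single events dominate the
tree; this is also a common default of the classic parsimony programs.
Two-base codes enter as partial uncertainty (their two-bit mask).

Per character, $m_i$ (distinct observed states − 1) and
$g_i$ (scored strains − count of the commonest state) bound the steps
$s_i$, giving CI $= \sum m_i / \sum s_i$ and
RI $= (\sum g_i - \sum s_i)/(\sum g_i - \sum m_i)$.  Because conventions
differ on whether parsimony-uninformative characters belong in these
sums, both variants are reported (`ci`/`ri` over variable characters,
`ci_informative`/`ri_informative` over informative ones).

The search is random-addition stepwise insertion followed by NNI
branch swapping to a local optimum, repeated `n_random_addition` times
(default 10); all distinct minimal topologies found are returned, with
ties ordered by a lexicographic bipartition encoding so the "first best
tree" is reproducible.  NNI rather than TBR is a deliberate scale
choice: the package's correctness surface is exact oracle equivalence on
small instances (the tests compare against exhaustive enumeration of all
topologies and all ancestral assignments for ≤ 6 taxa across a 200-case
fuzz suite), not search exhaustiveness on hundreds of taxa.  On rugged,
signal-free random alignments a handful of addition replicates can stick
in an NNI local optimum; ten replicates was sufficient everywhere in the
fuzz suite.

Bootstrap resamples alignment columns with replacement (resampling is
indexed by column, so supports do not depend on strain input order) and
reports, for each internal edge of the best tree, the percentage of
replicate best trees containing that bipartition.

Two concordance tools support species-delimitation arguments.  The
partition-homogeneity (ILD) test compares the summed per-locus best
lengths against random repartitions of the pooled variable characters
into blocks of the original sizes; `p` is the fraction of repartitions
with a sum ≤ the observed one (observed included), so congruent loci
give `p` near 1 and conflicting loci give small `p`.  The
monophyly-constrained search enforces each constraint group during
stepwise addition and NNI (moves that would break a group are rejected)
and reports `delta = constrained − unconstrained length`, which is 0
exactly when the data are compatible with the grouping.  The published
procedure behind the "topology-dependent permutation test" is not fully
specified anywhere we could follow, so the implemented interpretation —
a character-wise permutation null for `delta` — is labelled as such and
kept optional (`n_permutations = 0` skips it).

## 5. EM haplotype phasing

`snpify()` reduces a locus to its biallelic substitution sites (indel
columns are excluded; a triallelic site is an error naming the site).
`em_phase()` then treats each strain as an unordered pair of haplotypes
over those sites: with $k$ heterozygous sites there are $2^{k-1}$
compatible resolutions, enumerated explicitly (the data this is meant
for have $k \le 4$; enumeration is capped at $k = 14$).  The E-step
weights each resolution $(h_1, h_2)$ by $2f_{h_1}f_{h_2}$ (or $f_h^2$),
the M-step re-estimates frequencies from expected counts — the classic
haplotype-frequency maximum-likelihood EM.  The observed-data
log-likelihood is non-decreasing by construction and asserted in tests;
iteration stops when the largest frequency change is below `tol`
(default 1e-8, `max_iter` 10000).

Initialization is **exactly uniform** over the compatible haplotypes.
This is a deliberate choice about ties: a random nudge at initialization
would let EM fall into one of two symmetric likelihood modes and report
a confident phase for a strain that is genuinely ambiguous (the extreme
case is a lone double-heterozygote, where the likelihood is maximized
equally by either resolution).  From a symmetric start EM preserves the
symmetry, the tie survives to convergence, and the strain is reported
with posterior 0.5 and a `tied` flag — ambiguity is surfaced, never
silently broken.  The `seed` argument remains in the signature for
interface stability but no randomness is consumed.  Haplotypes whose
estimated frequency decays below 1e-6 are numerically dead EM mass and
are dropped from the catalogue, with the remainder renormalized.

EM is used here as a deterministic, dependency-free stand-in for
Bayesian phasing samplers; at the heterozygosity these data show (a few
heterozygous sites per strain, strong homozygote anchoring) the
difference is immaterial, and the output metadata records the method.
For ITS-like multi-copy loci the phasing output carries a caveat note:
heterozygous sites there may reflect paralog variation rather than the
two nuclear haplotypes, so haplotype-level conclusions from ITS deserve
extra caution.

## 6. Index of association and phylogenetic compatibility

Multilocus genotypes are tidy tibbles (`strain_id`, `locus`,
`allele_a`, `allele_b`), with alleles typically the haplotype labels
from phasing.  The per-locus distance between two strains is 0 / 0.5 / 1
for identical pair / one shared allele / none — the convention of the
classic multilocus-association software, printed in every report since
the choice is not universal.  With $V_O$ the variance over strain pairs
of the summed distance and $V_E = \sum_l V_l$ the sum of per-locus
variances (denominator = number of pairs, also stated in the output),

$$I_A = V_O/V_E - 1, \qquad
\bar r_d = \frac{V_O - V_E}{2\sum_{l<m}\sqrt{V_l V_m}} .$$

The null permutes single-locus genotypes among strains independently at
each locus, preserving single-locus frequencies while destroying
cross-locus association.  The tail probability counts the observed
arrangement in numerator and denominator,
$p = (1 + \#\{I_A^{perm} \ge I_A^{obs}\})/(1 + B)$ — conservative and
never exactly 0.  For small samples an exhaustive mode enumerates all
relative per-locus permutations (fixing the first locus loses nothing
because $I_A$ is invariant under simultaneous relabelling), which the
tests compare against literal brute-force enumeration at $n = 5$.
Monomorphic loci are excluded with a warning; with one informative locus
$I_A$ is identically 0.  Strains with identical multilocus genotypes are
*not* clone-corrected by default (the test is usually reported over all
isolates); `clone_correct = TRUE` collapses them first.

The compatibility test asks, for every pair of alleles at each of two
loci, whether all four combinations are evidenced.  Because cross-locus
phase is unobserved, a combination counts as evidenced only when a
witness strain is homozygous at one of the two loci (phase then
unambiguous) or when a doubly heterozygous strain shows the combination
under *both* possible pairings.  Fully crossed quartets — impossible
under strict clonality without recurrent mutation — are reported with
their witness strains.

## 7. The synthetic-data generator

The generator emulates the structure the analysis assumes, at the scale
of the motivating study: three divergent lineages of 11 dikaryons each;
an ITS-like 683-site locus whose planted pairwise divergence totals
21/47/37 fixed differences, made of lineage-private substitution sites
(15/2/13), one three-state site, a 3 bp poly-T indel absent from
lineages 1 and 3, and an 18 bp deletion private to lineage 3; an
RPB2-like 422-site locus with within-lineage polymorphism confined to
lineage 1; and two conserved rRNA-like loci that never vary within
lineages.  Pairwise fixed-difference targets are planted by a star
decomposition $d_{ij} = x_i + x_j + x_0$ (with $x_0$ three-state sites
absorbing parity); targets with no non-negative solution are a
configuration error, as is any site budget overflow.  Within-lineage
polymorphism lives in a per-lineage haplotype pool (default size 6);
sexual strains unite two pool haplotypes drawn independently per locus
(free recombination between unlinked loci), clonal strains copy a small
founder set with per-site substitution mutation.  Indels are planted,
never mutated, and are always shared within a lineage — so no strain is
heterozygous for an indel, matching the observation that motivates
composite-sequence genotyping.

Allele-level counterparts (`simulate_mlg()`, `simulate_dikaryon_panel()`)
drive the clonality and phasing property tests directly, since those
properties are stated in terms of loci with a handful of alleles rather
than sequences.  The clonal mode builds its founders by clonal descent
under an infinite-alleles mutation model (every mutation is a brand-new
allele); this is what makes "strictly clonal panels show no fully
crossed quartet" a theorem rather than a tendency, and it is the
honest null for the four-combination test.

What the generator does *not* emulate: intra-locus recombination,
coalescent genealogies within lineages, selection, migration,
rate heterogeneity along sequences, and sequencing error.  Passing
tests therefore demonstrate that the statistics recover planted truth
under the model's own assumptions — they do not validate the biological
assumptions on real data.

Determinism is a contract: every public simulation and every stochastic
stage takes a seed, all internal seeds derive from it, and identical
configurations reproduce byte-identical outputs (asserted in tests).
One infrastructure note: child seeds are derived by scrambling through
the generator itself (seed, stream-keyed burn-in, emit one draw), not by
an affine map — sequential user seeds fed straight to `set.seed()`
produce measurably correlated simulated panels, which showed up as a
mean-shift in permutation p-values across seed sweeps before the
scrambling was introduced.

## 8. Problem sizes and runtime

The shipped test-suite scales are chosen to make exhaustive oracles
feasible while exercising every code path: parsimony fuzzing at ≤ 6 taxa
and ≤ 8 characters (200 cases against full topology/assignment
enumeration), diversity oracles to $n = 12$, index-of-association
uniformity at 200 seeded sexual panels of 30 strains × 2 loci × 5
alleles with 199 permutations each, clonal power at 100 panels, phasing
recovery at 10 panels of 30 dikaryons from 5-haplotype pools, and
end-to-end runs at 4–6 strains per lineage.  The full suite runs in
about a minute on one CPU.

## 9. Known limitations

* NNI-only swapping with few addition replicates can miss the optimum on
  large or signal-free alignments; increase `n_random_addition` when the
  answer matters and the data are hard.
* EM phasing reports a point estimate of frequencies; posterior
  uncertainty beyond the per-strain resolution posterior is not
  quantified, and ITS paralogy can masquerade as heterozygosity.
* The ILD statistic uses heuristic per-partition searches; on data where
  the heuristic is unreliable the null and observed sums are affected
  alike, but exactness is not guaranteed.
* Divergence categories are computed per site; linked-site structure
  (e.g. one indel track = one event) is reported via tracks but not
  modelled statistically.
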