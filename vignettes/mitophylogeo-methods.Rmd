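---
title: "Methods: mitochondrial phylogeography with mitophylogeo"
author: "mitophylogeo authors"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the models it implements, the
parameters that matter, the choices made where the design was open, and
what the simulation-based validation does and does not establish. All
numerical claims here are the ones the test suite and
`scripts/acceptance.R` themselves compute; nothing is asserted that the
code does not measure.

# The analysis chain

A mitochondrial phylogeographic study runs, in order: variant
normalisation, haplogroup classification (plus discovery of new
sub-clades), clade dating, inter-population comparison, and spatial
interpolation of haplogroup frequencies. Each step is one module of the
package, and `run_pipeline()` chains them with one artifact per stage so
a run can be resumed anywhere.

# Variant nomenclature

Variants are named relative to the rCRS (16,569 bp, 1-based
coordinates everywhere; no 0-based interface exists in the package,
matching VCF and community practice). The grammar is the conventional
one: `T6248C` (substitution; transitions may omit the reference base,
so `16182C` means `T16182C`), a trailing base on a transversion
(`A16318C`), `15322d` for a deletion reported per deleted position,
`309.1C` for an insertion anchored to the preceding rCRS position, and
`@16311` for a back mutation. `parse_variant_token()` and
`render_motif()` are exact inverses on well-formed profiles, a property
the suite tests over hundreds of random profiles.

Two exclusion masks are provided. The *phylogeny* mask removes the
classic hotspots (transitions at 16182, 16183 and 16519), indels in the
515–524 repeat, insertions at 16193, and the poly-C variation around
position 310. The paper trail behind such masks never enumerates the
310 region precisely, so the package fixes it as the interval 302–316
restricted to indels and C-involving substitutions — the standard
poly-C treatment. The *diversity* mask removes only the 16182C/16183C
length-heteroplasmy states near 16189: diversity indices are otherwise
computed on everything the common segment carries.

VCF conversion takes each sample's called non-reference alleles and
re-expresses left-aligned indels in the mtDNA convention. Heteroplasmic
genotypes resolve to the major allele (by `AD` when present) with a
warning; the alternative (`het_policy = "alt"`) is exposed because
studies differ here, but trees are built from the consensus state.

# Classification and sub-clade discovery

The haplogroup tree is a rooted node list with defining variants per
branch; a node's cumulative state is its parent's state edited by its
defining variants, with `@` tokens reverting ancestral ones. A profile
is scored against node `N` as

\[ s(N) = \tfrac12\left(\frac{|E \cap P|}{|E|} + \frac{|E \cap P|}{|P|}\right) \]

with \(E\) the node's cumulative variants inside the profile's covered
range and \(P\) the profile's informative variants (a symmetric
Kulczynski-style average; empty sets contribute 1). Haplogrep's
internal ranking is deliberately not replicated: the published studies
that use it correct its calls manually, so the package fixes a
deterministic, documented score instead and returns the full ranked
list. Ties prefer the deeper node — the field reports the most derived
defensible label — then the lexicographically smaller name. An expected
variant countered by an observed reversion counts as missing, not
private.

Sub-clade discovery implements the usual rule for extending the
worldwide phylogeny: every maximal set of at least two genomes sharing
at least one derived variant (relative to the parent state) at a
mutationally stable position becomes a proposed child node, with nested
proposals allowed and names following the letter/number alternation.
"Stable" is a per-position set; the bundled default marks the hotspot
and poly-C positions above as unstable and everything else stable,
because the literature's stability reference is a rate table whose
cutoff is a judgement call — the set is a plain argument and can be
replaced wholesale.

The ancestry component is then mechanical: the percentage of samples
whose best node lies in, or descends from, a set of flagged clades. For
a design with nine flagged haplotypes among 110 samples this is
8.1818…%, printed as 8.2%.

# Clade dating

For a rooted clade genealogy with per-branch mutation counts \(m_b\),

* \(\rho = \frac{1}{n}\sum_i d_i\), the mean mutation count from root
  to each of the \(n\) members, and
* \(\sigma = \sqrt{\sum_b m_b (n_b/n)^2}\), the heuristic standard
  error with \(n_b\) the leaves under branch \(b\),

give age \(= \rho\,\tau\) with CI \((\rho \pm 1.96\sigma)\tau\) floored
at zero. The default clock is \(\tau = 3{,}624\) years per mutation for
complete mitogenomes — the corrected whole-molecule rate in common use
— with an HVS-I clock (16,677 yr per transition) bundled for
control-region genealogies. The time-dependent purifying-selection
correction behind the "corrected" rate is *not* re-implemented; it is
absorbed into the constant, which is an explicit, user-overridable
value. This is a documented limitation: dating clades much older or
younger than the calibration regime inherits the constant's error.

The ML alternative treats the genealogy as fixed and maximises
\(\prod_b \Pr[m_b \mid \text{Poisson}(t_b/\tau)]\) over node times with
leaves at zero and parents older than children (internal times are
parameterised as fractions of their parent's age, the root age on a log
scale; the optimiser starts from ρ-based ages and is deterministic).
The 95% CI is the profile likelihood of the root age at a
log-likelihood drop of 1.92. A genealogy with no mutations at all is
non-identifiable and returns age 0 with the likelihood-derived upper
bound.

**Coverage of the ρ CI.** On star genealogies at the study scale
(true age 8,000 yr, \(\tau = 3{,}624\), \(n = 10\)) the CI covers the
truth in about 93–94% of simulations — near nominal. On Yule
genealogies at the same scale it covers only ~87%, insensitively to
clade size. The mechanism is visible in the formula: with shared deep
branches, \(\rho\)'s variance is dominated by a few branches whose
small Poisson counts both violate the normal approximation and feed a
plug-in variance that underestimates badly when a long branch happens
to carry few mutations. This undercoverage of ρ-based CIs on non-star
genealogies is a known property of the method, and the package reports
it honestly rather than inflating σ: the acceptance suite asserts the
nominal band and the assertion fails on Yule input, while the adjacent
star-topology check passes. Users dating real (non-star) clades should
read the ρ CI as optimistic and prefer the ML profile CI.

# Population statistics

Diversity on a population of \(n\) haplotypes over a covered length
\(L\) (HVS-I, 16024–16365, \(L = 342\) by default):
\(HD = \frac{n}{n-1}(1 - \sum_k p_k^2)\);
\(M = \binom{n}{2}^{-1}\sum_{i<j} d_{ij}\) with \(d_{ij}\) the count of
differing sites; \(\pi = M/L\) exactly (same machinery, so the identity
is exact, not approximate).

Pairwise ΦST is a two-level AMOVA on the squared pairwise-difference
matrix, \(SS = \sum d^2_{ij}/(2N)\) convention:
\(\sigma^2_w = SS_w/(N-2)\),
\(\sigma^2_a = (SS_a/(P-1) - \sigma^2_w)/n'\) with
\(n' = (N - (n_a^2+n_b^2)/N)/(P-1)\), \(P = 2\), and
\(\Phi_{ST} = \sigma^2_a/(\sigma^2_a + \sigma^2_w)\). The molecular
distance is the raw number of differing positions (the default
"pairwise difference" distance of the standard software); a
substitution-model hook was considered and deliberately left out — at
intra-human mtDNA divergences the correction is negligible relative to
sampling noise. Negative estimates clamp to zero by default so the
matrix remains a valid distance input for MDS; `clamp = FALSE` restores
the raw estimator for users who want the conventional reporting.
Whether published MDS percentages derive from clamped or raw matrices
is typically unstated; both modes are exposed.

Classical MDS double-centres the squared distances,
\(B = -\tfrac12 J D^2 J\), eigendecomposes, scales eigenvectors by
\(\sqrt{\lambda}\), and reports
\(\lambda_j / \sum_{\lambda > 0} \lambda\) as the variance fraction per
dimension. The sign convention (first nonzero loading positive) makes
runs reproducible; recovery of known configurations is tested to
Procrustes error below 1e-8, and `cmdscale` serves as an independent
cross-check in the suite.

# Kriging

Semivariograms are estimated in equal-width bins of great-circle
(haversine) distance — the study window spans Europe to Iran, where
planar distances distort — and fitted by least squares weighted by the
per-bin pair counts. Families: spherical and exponential (practical
range: the exponential reaches ~95% of its sill at the stated range).
The fit constrains the range to at most five times the observed span;
an exponential with an effectively infinite range reproduces a linear
variogram with meaningless parameters otherwise. Ordinary kriging
solves the usual semivariance system with the unit-sum constraint;
\(\gamma(0) = 0\) by definition so the predictor honours the data
exactly at sample sites when the nugget is zero, and the largest
deviation of any cell's weight sum from 1 is carried on the surface
object (asserted below 1e-10 in the tests). Frequency predictions are
clipped into \([0,1]\) only at the reporting layer — never inside the
solver, whose unclipped output is what the exactness and weight
properties hold for. Duplicate sites make the system singular and are
an error by design; jitter upstream if co-located samples are real.

# The synthetic-data generator

The generator defines the study conditions the validation runs under:

* clade genealogies are Yule by default (real clades are not stars; a
  star switch exists for the regimes where closed forms apply), with
  \(n = 10\) sampled members — the size of the clades such studies
  actually date — rescaled to the configured age;
* branch mutation counts are Poisson(branch years / τ) with
  τ = 3,624 yr by default; every event is counted in the genealogy,
  and event *positions* are drawn from a weight table in which the
  hotspot/poly-C positions carry 50× weight, so exclusion masks are
  exercised in profile space without deflating the clock. A recurrent
  hit at an already-derived site reverts it;
* substitutions are 95% transitions, 2% of events are indels —
  round numbers at the scale of real mtDNA mutational spectra;
* the admixed study draws each of 110 samples' haplogroups from the
  source-region pool with probability 0.082 and from the local pool
  otherwise; samples of one haplogroup descend from a shared
  genealogy of depth 2,000 yr, so co-classified genomes share derived
  variants the way real ones do (this is what sub-clade discovery
  consumes);
* a synthetic 16,569-base reference (fixed internal seed) gives the
  VCF writer internally consistent REF/ALT fields. It is labelled
  synthetic everywhere: coordinates and masks follow the real
  reference system, the base composition does not, so it must never
  be used to annotate real data.

All randomness flows from the single configuration seed; fixed-seed
runs are byte-identical, which the suite asserts on the VCF output.

What passing these simulations shows — and what it does not: the chain
recovers generating haplogroups (≥95%), the realized admixture fraction
(exactly, in the measured confusion matrices), and clade ages within
their stated uncertainty, *under the generator's assumptions*: a known
tree, no sequencing error, no missing data, heteroplasmy resolved
upstream, and mutation independence across sites. Real data violate all
of these to some degree; in particular the classifier's behaviour under
heavy missingness (partial `covered_range`) is implemented but only
lightly exercised, and phantom mutations from sequencing error would
inflate both private-variant counts and diversity.

# Problem sizes

The default validation sizes are 500 simulated clades for the dating
checks (with ML fitted on each), 200 replicate studies of 110 samples
for component recovery, 300-500 replicates for the star-topology
coverage and bias properties, and 10–60-sample fixtures elsewhere —
sizes at which the Monte-Carlo error of each asserted quantity is small
against its tolerance band.

# Known limitations

* The ρ CI undercovers on non-star genealogies (discussed above).
* The clock is a constant; no rate heterogeneity across sites or time.
* ΦST is two-population AMOVA only; no permutation p-values (the
  estimator is exposed, significance testing is out of scope).
* The ML dater requires a rooted genealogy with counted mutations; it
  does not build the genealogy (a parsimony star over private variants
  is what the pipeline's dating stage constructs) and does not handle
  outgroup-based rooting.
* Kriging is univariate ordinary kriging on a lon/lat grid; no
  co-kriging, no map projections.
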