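# mitophylogeo

Phylogeographic analysis of human mitochondrial genomes in R: from
per-sample variant calls to haplogroup assignments, founder-age
estimates, inter-population distance structure, and interpolated
haplogroup-frequency surfaces.

## What problem this addresses

Population studies of mtDNA ask where a population's maternal lineages
came from and when. The workflow this package implements is the standard
one for such studies: express each mitogenome as its differences from
the rCRS reference in the community nomenclature; classify each sequence
into the worldwide haplogroup phylogeny; look for new sub-clades shared
by two or more genomes; date clades of interest with a molecular clock;
compare populations with diversity indices, ΦST distances and
multidimensional scaling; and map haplogroup frequencies across
geographic space. The motivating design is the study of a European
population pool (such as Tuscans) carrying a minority component of
Near-Eastern maternal lineages, where the quantity of interest is the
percentage of the pool that sits in clades of source-region origin.

The package is aimed at population geneticists who want the full chain
to be scriptable and testable, with a seeded synthetic-mitogenome
generator standing in for restricted-access raw data.

## Core methods

* **Variant nomenclature** — tokens like `T6248C`, `A16318C` (suffix
  letter on a transversion), `15322d` (deletion), `309.1C` (insertion),
  `@16311` (back mutation); VCF records are re-expressed in this
  convention; hotspot-exclusion masks (16182/16183/16519, 515–524
  indels, 16193 insertions, the poly-C stretch around 310) for
  phylogenetic work, and the 16189-adjacent length-variation mask for
  diversity work.
* **Haplogroup classification** — each tree node is scored by the
  symmetric average of expected-variant recall and profile precision on
  the covered range; ties prefer the deeper node. New sub-clades are
  proposed for every maximal set of ≥ 2 genomes sharing ≥ 1 derived
  variant at a mutationally stable position.
* **Clade dating** — the ρ statistic, ρ = (1/n) Σᵢ dᵢ (mean mutational
  distance of the n members from the clade root), with the Saillard
  heuristic standard error σ = √(Σ_b m_b (n_b/n)²) over branches, and
  age = ρ · τ with a clock of τ = 3 624 years per mutation for complete
  mitogenomes; alternatively a maximum-likelihood TMRCA under a strict
  Poisson clock (m_b ~ Poisson(t_b/τ)) with a profile-likelihood CI.
* **Population statistics** — haplotype diversity HD, mean pairwise
  differences M, nucleotide diversity π = M/L on the common HVS-I
  segment (16024–16365); pairwise ΦST from two-level AMOVA variance
  components on the pairwise-difference matrix; classical MDS of the
  ΦST matrix with per-dimension variance fractions.
* **Geostatistics** — binned empirical semivariograms over great-circle
  distances, weighted-least-squares variogram fitting, and ordinary
  kriging (unit-sum weights via a Lagrange multiplier; exact at the
  data when the nugget is zero).
* **Synthetic data** — mitogenomes evolved down star or Yule genealogies
  by Poisson mutation at a known rate, structured populations with
  staggered divergence, and an admixed study population with a known
  source-region fraction; writers for VCF and motif-database fixtures.

## Worked example

The `analysis/` directory holds the study replica as numbered drivers.
Stage 1 simulates the admixed study pool and writes its VCF, tree,
metadata and motif database; stage 2 runs conversion, classification,
sub-clade discovery and the ancestry component:

```sh
Rscript analysis/01_simulate_study.R
Rscript analysis/02_classify_component.R
```

```
wrote results/simdata: 110 samples, 4 (3.6%) drawn from the source region
...
recovered Near-East component: 3.6% (truth 3.6%)
proposed new sub-clades: 7
motif search (steps=0): 1 match(es) [Iraq=1]
motif search (steps=1): 1 match(es) [Iraq=1]
```

The recovered component equals the realized truth of the draw: with
n = 110 and an 8.2 % admixture probability the per-study realization
varies binomially (here 4 samples), and classification adds no error.
Stages 3–5 date simulated clades with ρ/σ and ML, compute the
diversity/ΦST/MDS comparison, and krige a frequency surface:

```
yule: mean rho-age 7861 yr (bias -1.7%), CI coverage 86.6%, median |ML-rho| 8.6% of truth
star: mean rho-age 7984 yr (bias -0.2%), CI coverage 93.0%, median |ML-rho| 0.0% of truth

 population  n   L     HD     M       pi
     Europe 20 342 0.5158 0.784 0.002293
      Study 20 342 0.2789 0.479 0.001400
   Caucasus 20 342 0.4421 0.489 0.001431
   NearEast 20 342 0.5000 0.626 0.001831

MDS variance fractions: dim1 53%, dim2 35%

fitted exponential variogram: nugget 0.0000, sill 0.0574, range 18407 km
surface: 60 x 40 cells, values 0.021-0.393, max weight error 3.3e-14
mean frequency: eastern third 0.292 vs western third 0.059
```

In code, the same operations are plain function calls:

```r
library(mitophylogeo)
p <- parse_motif("A73G-T152C-A263G-C295T-T489C-C16069T-T16126C")
tree <- toy_haplogroup_tree()
classify(apply_exclusions(p, exclusion_policy("phylogeny")), tree)[1, ]

star <- clade_genealogy(data.frame(parent = "root",
                                   child = paste0("s", 1:4),
                                   mutations = 1))
age_from_rho(star)   # rho 1, sigma 0.5, age 3624 yr (CI 72-7176)
```

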