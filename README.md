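# mutselpip

Detecting site-specific shifts in amino acid preference between a
designated sub-clade of a phylogeny and the rest of the tree, using
codon-level mutation–selection substitution models with a finite mixture
of amino acid fitness profiles.

## The problem

Protein sites evolve under site-specific selective preferences for amino
acids, and those preferences can change — for example when a virus jumps
from one host to another, a position may switch from favouring one
biochemical class of residues to favouring another. `mutselpip` is for
molecular evolutionists who have a protein-coding DNA alignment, a fixed
rooted tree, and a known monophyletic sub-clade of interest (say,
human-host strains inside a mostly avian-host phylogeny), and want to
know *which codon sites* changed their amino acid preference along the
transition into that sub-clade.

## The model

Each codon site *n* is allocated, via a latent indicator *z<sub>n</sub>*,
to one component of a fixed mixture of *K* amino acid fitness profiles
ψ<sup>(1)</sup>, …, ψ<sup>(K)</sup> (each a probability vector over the
20 residues). Given its profile, the site evolves along the tree under a
mutation–selection codon substitution process on the 61 sense codons:
for codons *i*, *j* differing at exactly one nucleotide (*a* → *b*, and
*j* not a stop),

&nbsp;&nbsp;&nbsp;&nbsp;
*Q<sub>ij</sub>* = ρ<sub>ab</sub> φ<sub>b</sub> · *S<sub>ij</sub>* / (1 − e<sup>−*S<sub>ij</sub>*</sup>),
&nbsp;&nbsp;&nbsp;&nbsp;
*S<sub>ij</sub>* = ln ψ<sub>f(j)</sub> − ln ψ<sub>f(i)</sub>,

where ρ are symmetric nucleotide exchangeabilities, φ nucleotide
propensities, *f(i)* the amino acid encoded by codon *i*, and
*S*/(1 − e<sup>−S</sup>) the population-genetic fixation factor. The
stationary distribution is
π<sub>i</sub> ∝ φ<sub>i₁</sub>φ<sub>i₂</sub>φ<sub>i₃</sub>ψ<sub>f(i)</sub>
and the process is reversible. Peaked profiles mechanistically suppress
the non-synonymous rate; flat profiles allow it — so rate heterogeneity
across sites and clades emerges from the mixture rather than being
bolted on.

MCMC is run **independently** on the two taxa partitions (the sub-clade
and its complement, each with its induced subtree, stem branch dropped),
sampling the allocations *z* with either a count-based Gibbs sampler
(weights integrated out under a flat Dirichlet; probability ∝
(η<sub>k</sub>+1)·p(D<sub>n</sub> | θ, ψ<sup>(k)</sup>)) or the default
parallelisable weight-conditional sampler (probability ∝
w<sub>k</sub>·p(D<sub>n</sub> | θ, ψ<sup>(k)</sup>), with w refreshed
from Dirichlet(1+η)). From the posterior allocation frequencies
p<sub>A</sub><sup>(n)</sup>(k) and p<sub>B</sub><sup>(n)</sup>(k) of the
two partitions, each site gets the **probability of identical profiles**

&nbsp;&nbsp;&nbsp;&nbsp;
PIP<sub>n</sub> = Σ<sub>k</sub> p<sub>A</sub><sup>(n)</sup>(k) · p<sub>B</sub><sup>(n)</sup>(k),

which is 1 when both partitions allocate fully to the same component and
0 when the supports are disjoint. Sites with PIP ≤ 0.05 (inclusive, and
configurable) are called preference shifts; an optional entropy filter
excludes calls where both partitions are only weakly allocated.

The package also ships the grouped profile constructor used for
simulation studies: eight components, one per disjoint biochemical class
(small nonpolar AGST; aromatic FWY; nonpolar aliphatic ILVM; polar
positive HKR; polar negative DE; polar neutral NQ; proline; cysteine),
with a *peakedness* parameter giving the probability mass shared equally
by the dominant group. Empirical mixture tables (the C10–C60 layout) can
be loaded from whitespace-delimited files.

## Worked example

Simulate 200 codon sites on a random 16-taxon tree with a 6-taxon
sub-clade, embedding 20 sites whose profile shifts inside the sub-clade,
then detect the shifts:

```r
library(mutselpip)
set.seed(11)
rt       <- random_tree(16, mean_branch = 0.35, clade_size = 6)
profiles <- mutsel_bc(0.95)
alloc    <- draw_allocations(200, 8)
shifts   <- embed_shifts(alloc, 20, 8)
des <- simulation_design(rt$tree, rt$subclade, profiles,
                         alloc, shifts$allocation_sub)
sim <- simulate_alignment(des, seed = 12)
res <- detect_shifts(sim$alignment, rt$tree, rt$subclade, profiles,
                     chain_config(sweeps = 2000, seed = 99))
head(res$report[res$report$shift, ], 5)
#>    site          pip   entropy_a  entropy_b top_a top_prob_a top_b top_prob_b shift
#> 1     1 0.000000e+00 0.000000000 0.00000000     5   1.000000     8   1.000000  TRUE
#> 25   25 8.262109e-03 1.019449703 0.01047142     6   0.628125     1   0.998750  TRUE
#> 30   30 4.179688e-05 0.385176520 0.01570654     1   0.921250     3   0.998125  TRUE
#> 40   40 1.250000e-03 0.077026699 0.00000000     3   0.988750     6   1.000000  TRUE
#> 49   49 0.000000e+00 0.005235904 0.00000000     4   0.999375     2   1.000000  TRUE

m <- confusion_metrics(res$report, sim$truth)
sprintf("TPR = %.3f, FPR = %.3f, precision = %.3f", m$TPR, m$FPR, m$precision)
#> "TPR = 0.750, FPR = 0.000, precision = 1.000"
```

Site 1, for instance, allocates with posterior probability 1 to
component 5 (polar negative) outside the sub-clade and to component 8
(cysteine) inside it — PIP 0, a maximally confident shift call. Site 25
shows the entropy column at work: allocation in partition A is spread
(entropy ≈ 1 nat), so if you enable `entropy_max` such sites are
filtered from the calls.

A shell interface covering the same steps (profile construction,
simulation, chain running, PIP scoring, evaluation, and the end-to-end
pipeline) is installed at `inst/cli/mutselpip`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "mutselpip", package = "mutselpip"))')" \
  pipeline --peakedness 0.95 --seed 1 --out-prefix demo
```

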