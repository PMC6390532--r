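---
title: "Detecting amino acid preference shifts with mutation-selection mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting amino acid preference shifts with mutation-selection mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutselpip)
```

## The model

`mutselpip` models protein-coding DNA evolution at the codon level with a
mutation-selection substitution process. Each of the $N$ codon sites is
allocated, through a latent indicator $z_n \in \{1,\dots,K\}$, to one
component of a *fixed* finite mixture of amino acid fitness profiles
$\psi^{(k)}$ (probability vectors over the 20 residues). Given its
profile, a site evolves on the 61 sense codons of the universal code
with infinitesimal rates, for codons $i \to j$ differing at one
nucleotide $a \to b$ at position $c$ (and $j$ not a stop),

$$Q_{ij} = \rho_{ab}\,\varphi_b \cdot \frac{S_{ij}}{1 - e^{-S_{ij}}},
\qquad S_{ij} = \ln \psi_{f(j)} - \ln \psi_{f(i)},$$

where the six $\rho_{ab}$ (unordered pairs, summing to 1) are nucleotide
exchangeabilities, the four $\varphi_a$ (summing to 1) nucleotide
propensities, and $f(i)$ the amino acid encoded by codon $i$. The
fixation factor $S/(1 - e^{-S})$ is the classical scaled fixation
probability relative to neutral; it is 1 at $S = 0$, suppresses
deleterious changes and promotes advantageous ones, and gives the
process two structural properties we rely on throughout:

* the stationary distribution has the closed form
  $\pi_i \propto \varphi_{i_1}\varphi_{i_2}\varphi_{i_3}\,\psi_{f(i)}$, and
* the process is reversible with respect to $\pi$
  (since $h(S) = e^{S} h(-S)$).

Assumptions worth stating plainly: the tree topology is fixed and
correct; the profiles are fixed (they are *inputs*, not estimated); a
site evolves under exactly one profile within a taxa partition; codons
are independent given their allocations; and the root is at equilibrium,
which together with reversibility forces the component's stationary
distribution as the root prior in the pruning likelihood.

## Detecting shifts: two partitions and the PIP

To ask whether a site's preference changed in a designated monophyletic
sub-clade, the taxa are split into the sub-clade and its complement.
Each partition keeps its induced subtree; the stem branch connecting the
sub-clade to the rest is *dropped*, i.e. the two partitions are treated
as fully independent data sets (equivalently, the connecting branch is
taken to be of infinite length). This is deliberately crude — it
sacrifices the information in the stem — but it makes the comparison
clean: each partition yields its own posterior allocation probabilities
$p^{(n)}_A(k)$ and $p^{(n)}_B(k)$, estimated as the proportion of MCMC
draws with $z_n = k$, and each site is scored with the probability of
identical profiles

$$\mathrm{PIP}_n = \sum_{k=1}^K p^{(n)}_A(k)\, p^{(n)}_B(k),$$

the posterior probability that the same component governed the site in
both partitions. Sites with $\mathrm{PIP}_n \le 0.05$ are called shifts.
The threshold is inclusive and configurable; 0.05 is a reasonable
operating point because precision-recall sweeps on simulated data are
flat between roughly 0.025 and 0.075. A low PIP can also arise from
*weak* allocation on both sides (two near-uniform vectors over many
components have PIP near $1/K$): the optional `entropy_max` filter in
`classify_sites()` removes such calls by requiring both partitions'
allocation entropies to be small. It is off by default because it
changes the semantics of a call from "probably different components" to
"confidently different components", and users should opt into that.

## Samplers

Two allocation samplers are implemented, targeting the same marginal
posterior over $z$:

* **Count-based Gibbs** (`gibbs_allocation_sweep`): sites are updated
  sequentially; site $n$'s component count is decremented and a new
  component drawn with probability $\propto (\eta_k + 1)\,
  p(D_n \mid \theta, \psi^{(k)})$. The $(\eta_k + 1)$ factor is the
  Pólya-urn predictive of a flat Dirichlet prior on the mixture weights,
  i.e. the weights are integrated out.
* **Weight-conditional** (`weighted_allocation_sweep`, the default):
  given weights $w$, all sites are drawn independently with probability
  $\propto w_k\, p(D_n \mid \theta, \psi^{(k)})$ (one vectorised
  Gumbel-max draw), then $w$ is refreshed from its conjugate conditional
  $\mathrm{Dirichlet}(1 + \eta)$. Because no site's update depends on
  another's, the sweep is order-independent; it is also the faster
  sampler here, which is why it is the default.

The equivalence of the two routes is asserted in the tests against the
*exactly enumerated* posterior of a two-site, two-component fixture.

Nucleotide parameters and branch lengths can be resampled
(`update_mut`, `update_bl` in `chain_config()`): $\rho$ and $\varphi$
take Metropolis-Hastings steps with a Dirichlet proposal centred at the
current value under flat Dirichlet priors; branch lengths take
multiplicative proposals $\ell' = \ell\, e^{\lambda(U - 0.5)}$ (Jacobian
$\ell'/\ell$) under i.i.d. exponential priors with mean 0.1
substitutions/site. Proposal steps adapt towards ~25% acceptance during
burn-in only and are frozen afterwards, keeping the post-burn-in chain a
valid fixed-kernel sampler. Both blocks are *off* by default: the
package's central use cases (simulation studies, fixed-$\theta$
reanalyses) condition on known or externally estimated $\theta$, and
freeing the blocks multiplies the per-sweep cost by the number of
likelihood-table rebuilds. When the two partition chains are run with
free $\theta$, each partition re-estimates its own copy — consistent
with the partitions being modelled as independent.

Defaults elsewhere: burn-in is the first 20% of sweeps; thinning keeps
at most 2000 stored draws; every run is reproducible from a single
integer seed (`detect_shifts()` derives the two partition seeds
deterministically from it). The weighted sweep is a single vectorised
draw from R's seeded RNG stream, so results do not depend on site
processing order or thread count.

## Tunable parameters

| parameter | default | units / range | why |
|---|---|---|---|
| `peakedness` (`mutsel_bc`) | — | (0, 1] | probability mass shared equally by a component's dominant biochemical group; controls how distinct the 8 components are |
| `rho` | AG 0.30, CT 0.45, transversions 0.05–0.10 | simplex over 6 pairs | transition-rich mutation spectrum typical of RNA-virus coding genes |
| `phi` | A 0.35, C 0.18, G 0.23, T 0.24 | simplex over 4 | A-biased composition typical of the same data class |
| `threshold` | 0.05 | PIP units, [0, 1] | inclusive call cutoff; PR curves are flat around it |
| `entropy_max` | off | nats | optional guard against weak-allocation calls |
| `sweeps` | 2000 | sweeps | enough for allocation-only chains on desk-scale data; raise for free-$\theta$ runs |
| `bl_prior_mean` | 0.1 | expected subs/site | weakly informative branch-length prior |

Branch lengths are interpreted as expected substitutions per codon site:
each component generator is rescaled so that
$-\sum_i \pi_i Q_{ii} = 1$ at its own stationary distribution. This is
the dominant convention and makes branch lengths comparable across
components; the unscaled matrix is available via
`build_generator(..., normalize = FALSE)` for cross-checks against
software with other conventions, where a global scale difference should
be expected.

## Numerical choices

* **Profile flooring.** Any profile entry below $10^{-10}$ is raised to
  $10^{-10}$ and the profile renormalised, so $\ln \psi$ — and hence
  every selection coefficient — is finite even at peakedness 1 or for
  sparse empirical tables.
* **Fixation factor near 0.** For $|S| < 10^{-8}$ the second-order
  series $1 + S/2$ replaces $S/(1 - e^{-S})$ to avoid 0/0.
* **Matrix exponential.** Reversibility makes
  $D^{1/2} Q D^{-1/2}$ (with $D = \mathrm{diag}(\pi)$) symmetric, so
  $e^{Qt}$ is computed by symmetric eigendecomposition — numerically
  exact to tolerance; the tests verify agreement with a dense
  scaling-and-squaring exponential at $10^{-10}$. Entries are clamped at
  0 and rows renormalised to absorb rounding at the $10^{-15}$ level.
* **Pruning.** Partial likelihoods are rescaled by their per-site
  maximum at every internal node, with the log-scale accumulated, so
  alignments on trees with hundreds of taxa do not underflow.
* **Missing data.** Gaps, Ns, ambiguity codes and partially resolved
  codons are treated as fully missing at the codon level (all-ones
  partials). Per-nucleotide ambiguity expansion would retain slightly
  more information but complicates the state space for little gain at
  the alignment qualities this method targets.
* **Ties and boundaries.** The PIP call threshold is inclusive
  ($\le$); the Gumbel-max categorical draw breaks exact ties towards the
  lower component index (a probability-zero event for continuous
  likelihoods).

## The simulator, and what passing tests do and do not show

`simulate_alignment()` draws each site's root codon from the stationary
distribution of its allocated component and propagates states branch by
branch by sampling from $e^{Qt}$ — equivalent in distribution to
event-level (Gillespie) simulation, and easier to verify: the tests
check ergodic convergence of simulated leaves to the component's
stationary law on long-branch star trees.

Shifted sites switch to their alternative component on every branch from
the sub-clade's **stem** downward: the regime change is placed before
the sub-clade's most recent common ancestor, matching the biological
picture of a transfer event preceding the clade's radiation. Since the
inference drops the stem anyway, this choice only affects how much of
the shifted regime the sub-clade data reflect.

The generator emulates: uniform i.i.d. site allocations over the $K$
components; a uniformly chosen different component at each shifted site;
exponential branch lengths on a random sequential-join topology with a
designated monophyletic sub-clade. It does **not** emulate: indels or
alignment error; codon usage bias beyond what $\varphi$ induces;
among-site mutation-rate variation; recombination or topology error;
epistasis; or gradual (rather than discrete) preference change. Passing
the simulation-based tests therefore shows that the inference machinery
recovers the truth *under the model's own assumptions* at desk scale —
it does not certify performance on real data, where profile
misspecification (see below) is the dominant risk.

Study conditions used by the simulation tests: 16 taxa with a 6-taxon
sub-clade, 200 codon sites, 20 embedded shifts, mean branch length 0.35
(total tree length ≈ 10–11 expected substitutions/site), grouped
profiles at peakedness 0.5–0.95, 2000-sweep allocation chains with
$\theta$ fixed at the simulation truth. These sizes give clear
signal-to-noise separation for the monotonicity checks (power rising
with peakedness and with branch-length scale) while keeping the whole
suite runnable on a single CPU in minutes.

## Design choices that were genuinely open

* **Codon ordering**: lexicographic over A < C < G < T, fixed and
  documented so matrix indices are reproducible; any fixed convention
  works if used consistently.
* **Amino acid column order** in profile tables: alphabetical by
  single-letter code, recorded in a `#` header comment.
* **Root prior**: the component's stationary distribution — forced by
  reversibility plus the equilibrium assumption, not a free choice in
  practice.
* **Weights in loaded profile sets**: published empirical tables may
  carry component weights; both ignoring them (count-based sampler,
  which integrates weights out under a flat prior) and using them as the
  initial state of the weighted sampler are supported.
* **Dirichlet-centred simplex proposals** rather than multiplicative
  subset moves: the Hastings ratio is exact in closed form, the identity
  limit (step 0) is well-defined, and prior recovery is directly
  testable.

## Known limitations

* Near-identical components in an empirical profile set can split a
  site's allocation differently in the two partitions and produce a low
  PIP without any biophysically meaningful shift — a false positive mode
  that grouped, disjoint profiles avoid by construction. The tests
  assert this mechanism directionally on a two-near-identical-component
  fixture.
* The method conditions on a known, monophyletic sub-clade; it does not
  search for where shifts occurred.
* Dropping the stem branch discards information; with very short
  partition subtrees (low information content) allocation weakens and
  power drops, as the branch-scale study shows.
* No multiple-testing correction is applied to the PIP cutoff; the
  threshold is an operating point, not a significance level.
* $K$ is fixed; there is no reversible-jump over the number of
  components, and profiles are never re-estimated from the data.
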