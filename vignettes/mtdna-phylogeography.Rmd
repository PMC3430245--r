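---
title: "Methods: mtDNA phylogeography with mtphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mtDNA phylogeography with mtphylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtphylo)
```

mtphylo implements the standard analysis chain for small mitochondrial DNA
panels of domestic animals and their wild relatives: aligned D-loop and
cytochrome b blocks are screened for variable sites, collapsed into
haplotypes, summarised with diversity statistics, placed on
Neighbor-Joining trees under the Kimura 2-parameter model, and finally used
to date the split between major clades through net between-clade distances
and a molecular clock. This vignette explains the models, the parameters
that matter, the numerical conventions, and what the simulation-based tests
do and do not establish.

## Coordinates and alignment handling

All positions are 1-based and inclusive in *reference space*: column $c$ of
a block anchored at `ref_start` corresponds to reference position
`ref_start + c − 1`. The reference sequence (the complete pig mitochondrial
genome used for numbering) is assumed gap-free over the analysed span, so a
gap column in another taxon still occupies one reference position. This
matches how positions such as "15,571" are quoted in the literature. Note
that the conventional D-loop window 15,455–16,068 spans 614 reference
positions while the aligned fragment has 613 columns (one position is
absorbed by the single indel in non-reference taxa); because published
descriptions do not resolve which endpoint convention was used, both
truncation endpoints are plain arguments and nothing is hard-coded.

`N` is permitted and treated as *missing*, never as a fifth state: it
cannot create a variable site, it is skipped by pairwise deletion in
distances, and a sequence containing `N` joins the unique haplotype it
matches elsewhere (or founds its own, with a warning, when the match is
ambiguous). Exact string identity defines a haplotype; this is the only
collapsing rule that is reproducible without arbitrary thresholds.

## Variable sites and per-breed summaries

A column is variable when at least two distinct states among
`{A, C, G, T, -}` occur. Two-state columns are classified by the state
pair: purine↔purine or pyrimidine↔pyrimidine is a transition, a cross-class
base pair a transversion, base↔gap a deletion. Columns with more than two
states are tagged `multi-state` and carry the class of their majority state
pair (ties broken by count, bases before the gap, then alphabetically), so
per-class tallies stay single-valued per site, as in published tables.

Per-breed "polymorphic site" counts are ambiguous in the literature:
breeds represented by a single haplotype still show nonzero counts, which
is only possible if the comparator includes something beyond the breed
itself. mtphylo exposes both readings — `within` (variation among the
breed's own sequences) and `vs-reference` (differences among the breed's
sequences *or* from the designated reference row) — and defaults to
`vs-reference`, which reproduces the qualitative behaviour of such tables.
Neither mode is asserted as "the" published definition.

## Diversity statistics

For haplotype counts $n_i$ with $\sum n_i = n$:

$$H_d = \frac{n}{n-1}\Bigl(1 - \sum_i p_i^2\Bigr), \qquad p_i = n_i / n.$$

Nucleotide diversity $\pi$ is the mean, over all unordered pairs, of the
per-pair difference proportion with pairwise deletion. Watterson's
estimator is computed from the total number of mutations $\eta$ (a
three-state column contributes two mutations) rather than the number of
segregating columns $S$:

$$\theta_{seq} = \frac{\eta}{a_n}, \quad a_n = \sum_{i=1}^{n-1} \frac1i,
  \qquad \theta_{site} = \theta_{seq} / L.$$

Deletion columns are excluded from $\pi$, from $\eta$ and from $L$ by
default (`include_indels = TRUE` reverses this for $\eta$): indels are
reported as sites but kept out of the substitution-based estimators, which
is consistent with how the classic polymorphism programs treat them. At the
study scale the distinction between $L = 1753$ and $1752$ is invisible at
five decimals of $\theta_{site}$. Report rounding follows the conventional
precisions: $H_d$ 3 dp, $\pi$ and $\theta$ 5 dp.

## Distances

The Kimura 2-parameter distance uses transition and transversion
proportions $P$ and $Q$ over the sites valid in both sequences:

$$d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q),$$

with a *saturation error* (never a silent `NaN`) when either logarithm's
argument is non-positive. Pairwise deletion is used rather than complete
deletion because a documented indel column would otherwise silently drop a
site from every comparison.

Synonymous/non-synonymous distances follow Nei–Gojobori (1986): per-codon
synonymous site fractions, equal-weight averaging over substitution
pathways for multi-hit codons (pathways through stop codons excluded),
Jukes–Cantor correction $d = -\tfrac34\ln(1 - 4p/3)$. The genetic code is
the vertebrate mitochondrial code (NCBI table 2) — forced by the locus:
`AGA`/`AGG` are stops and `TGA` is tryptophan, so using the standard code
would misclassify sites. Substitutions that would create a stop codon are
counted as non-synonymous. The method is deliberately the simple
equal-weight variant: it is the standard contemporaneous default, and the
counting layer is separated (`syn_nonsyn_counts()`) so a modified-NG
weighting could be added without touching the distance code.

The net between-clade distance is Nei's decomposition
$K = d_{XY} - (d_X + d_Y)/2$, with within-group means defined as 0 for
singletons. Group means are unweighted by haplotype frequency (each
haplotype is one taxon), matching the taxon set of the trees. Because no
published analytic variance is identified with the quoted SDs, the SD of
$K$ is estimated by a seeded site bootstrap (default $B = 1000$): columns
are resampled with replacement, the full distance matrix and $K$ are
recomputed per replicate (vectorised through per-pair site-indicator
matrices), and replicates with saturated pairs are dropped, with a hard
error if more than 10% are lost.

## Trees

Neighbor-Joining follows Saitou–Nei: join the pair minimising
$Q(i,j) = (r-2)\,d(i,j) - R_i - R_j$; branch lengths from the standard
split formula; the last three nodes close the unrooted tree. Numerical
conventions, all documented and tested:

* exact $Q$ ties break towards the lowest (row, column) pair in current
  label order — deterministic and order-stable;
* negative branch lengths are clamped to 0 with the deficit moved to the
  sister edge (the common MEGA-compatible convention); raw lengths are kept
  in an attribute;
* the all-zero (star) matrix is handled and yields zero-length edges.

Bootstrap supports are percentages of column-resampled replicates whose
rebuilt tree contains each internal bipartition of the original tree.
Supports are attached to *splits*, not nodes, so outgroup rooting (which
places the root at the midpoint of the outgroup's pendant edge) cannot
corrupt them. Replicate column indices are drawn once per replicate from a
single documented seed. On concatenated data the resampling runs over all
1,753 columns unstratified; a per-region stratified scheme would also be
defensible, but unstratified is the common default and the choice is
config-visible rather than buried.

## Divergence dating

Times follow $T = K / 2r$: the net divergence $K$ accrues along two
lineages. Published per-region mammalian mtDNA rates are quoted as
percentages; the only unit reading under which all published times are
reproduced is $10^{-9}$ substitutions/site/year, i.e.
$T\,[\mathrm{yr}] = (K/100) / (2 r \times 10^{-9})$. This interpretation is
fixed and tested, not configurable. With the bundled tables
(`inst/extdata/substitution_rates.tsv`, `net_divergence_k.tsv`):

```{r dating}
rates <- read_rate_table(system.file("extdata", "substitution_rates.tsv",
                                     package = "mtphylo"))
ktab <- read.delim(system.file("extdata", "net_divergence_k.tsv",
                               package = "mtphylo"), comment.char = "#")
tab <- divergence_table(ktab$region, ktab$K_percent, rates$rate_1e9)
data.frame(region = tab$region, T_kyr = tab$T_thousands)
unlist(summarize_times(tab, exclude = "dloop_central"))[c(2, 4)]
```

Averages are taken over *unrounded* times and only then rounded to integer
thousands; averaging the rounded values would sit exactly on a half-unit
and round ambiguously. The central control-region domain is excluded from
the second average because its low rate makes the implied time
statistically unstable. ETAS/central domain boundaries are required
configuration with no default: the domain split for the pig control region
has no universally agreed coordinates, so silently assuming one would be
worse than asking.

## The simulator: what it emulates, and what it does not

`generate_dataset()` draws a uniform ancestral sequence (cytochrome b
in-frame, stop-free under the mitochondrial code), evolves two clade
ancestors $\kappa/2$ expected substitutions/site each under the exact K2P
process (so the estimator's model assumptions hold by construction, making
parameter-recovery tests well-posed), derives within-clade haplotypes by a
fixed number of transition-biased point mutations, samples individuals by
configured haplotype counts, adds an outgroup and optionally one D-loop
deletion column, and records a truth record (planted haplotypes, mutation
events with classes, realised ancestor divergence, back-mutation flag).

Defaults are the study conditions the package is built around: 45 + 1 + 15
ingroup animals with haplotype counts 13/13/12/7 (one haplotype shared
across two populations), a monomorphic wild boar population, a 15-animal
opposite-clade panel, $L = 613 + 1140$, `kappa = 15` (a 7.5:1
transition:transversion count ratio, as observed in such panels),
between-clade divergence 0.03 substitutions/site (the scale of
European–Asian swine mtDNA divergence), two private mutations per derived
haplotype (which makes the 45-animal population's $\eta = 6$, matching its
$\theta_{seq} = 1.372$), and exactly one planted deletion.

What the simulator does **not** emulate — and therefore what passing tests
do *not* establish about real data: recombination (absent from mtDNA, so
harmless), rate heterogeneity across sites (real control regions have
hypervariable positions; K2P distances on real data are therefore
downwardly biased in a way these tests cannot detect), selection on
cytochrome b (the generator mutates neutrally, so simulated $d_N/d_S$ is
near 1, unlike real data), sequencing error and alignment uncertainty
(inputs arrive aligned by assumption). Tests against the simulator
establish *algorithmic correctness under the stated model*, not robustness
to model violation.

## Test problem sizes

The test suite runs the statistics at the study's own scale (45/15-member
populations, 1,753 columns), NJ recovery on 100 random additive 4–8 taxon
matrices (topology exact, path lengths to $10^{-10}$), the K2P lower bound
$d \ge P + Q$ on 1,000 random $(P, Q)$ draws, and net-divergence recovery
on 100 seeded two-clade datasets (20 + 20 taxa, planted
$\kappa \in [0.02, 0.05]$, site-bootstrap SE at $B = 100$, coverage
$|\hat K - \kappa| \le 3\,\mathrm{SE}$ in at least 95 of 100), with the
clade-defining bipartition checked at $B = 200$ bootstrap replicates.
These sizes keep the full suite under a couple of minutes on one core
while leaving the stochastic checks enough replicates to be meaningful.

## Known limitations

* Independent oracles exist in-tree for K2P, NJ and raw distances
  (cross-checked against `ape`), but the published panel itself is not
  redistributable, so panel-level numbers (86 variable sites, 32
  haplotypes, $\pi = 0.00158$) are reproduced structurally (via the
  fixture's planted shape) rather than literally.
* `multi-state` columns contribute a single majority-pair class to
  per-class tallies; a fully pairwise accounting would double-count sites
  relative to published per-site tallies.
* The site-bootstrap SD of $K$ treats sites as exchangeable; under strong
  rate heterogeneity it underestimates uncertainty.
* No confidence intervals for $H_d$ or $\theta$, no neutrality tests, no
  ML/Bayesian trees — deliberately out of scope.
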