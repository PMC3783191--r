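---
title: "Deconvolving bulk aberration frequencies into clonal evolution trees"
author: "cloneDecon developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving bulk aberration frequencies into clonal evolution trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneDecon)
```

## The model and its assumptions

A bulk sample from a heterogeneous cell population (a tumor biopsy, a
germinal-center B-cell pool) is a mixture of *subclones*, each defined by
the set of genomic aberrations its cells share. A pooled measurement
observes only the aggregate frequency $y_i$ of each aberration. With $C$
the binary genotype matrix and $x$ the subclone fractions, the measurement
model is $y = Cx$, $x \ge 0$.

Three biological assumptions turn this underdetermined system into a tree
problem:

* **Evolutionarity** — subclones arise from one another by accumulating
  aberrations; an aberration, once acquired, is never lost (no
  back-mutation, no deletion of events — a stated non-goal of this
  package).
* **Parsimony** — each aberration arises exactly once, so aberration $i$
  *names* the clone in which it first occurred. With $N$ measured
  aberrations (plus an artificial dummy present in every cell, carrying
  the wildtype fraction) the genealogy is an $N$-clone rooted tree.
* **Sorting** — after sorting $y$ non-increasing, a clone's parent always
  has a smaller index (a subclone can only descend from a clone whose
  aberration is at least as frequent), so all candidate trees are the
  parent arrays with `parent[j] < j`; there are $(N-1)!$ of them.

Clone frequencies follow by back-substitution,
$x_i = y_i - \sum_{j \in \text{children}(i)} y_j$, and a parent array is
*feasible* when all $x_i \ge 0$ (up to the error model's slack). Among
feasible trees the package optimizes **sparsity** — the fewest populated
subclones $P$ ($x_j > 0$) — then **shallowness** — the smallest depth $D$
(edges from root; the wildtype-only tree has $D = 0$). All co-optimal
trees are returned: with one bulk sample the solution is often not unique,
and pretending otherwise would be misleading.

## The staged search

The solver never enumerates all $(N-1)!$ trees. The key observation: clone
$i_0$ is unpopulated exactly when $y_{i_0} = \sum_{j \in S} y_j$ for the
complete set $S$ of its direct descendants. Each such certified pair
$(i_0, S)$ is a *first-generation tree*; a compatible collection of them
(no shared parent, no clone claimed as child twice) is a *partial tree*;
and every solution with the minimum $P = N - h^\ast$ must contain one of
the partial trees of maximum size $h^\ast$. The pipeline is: detect all
first-generation trees (subset-sum scan with two-sided partial-sum
pruning, children sorted by descending frequency); find all maximum
compatible collections (a max-clique search organized by parent groups);
grow each into full trees by ordered insertion (first-generation children
are forced to their certified parent; all other clones try every unfrozen
placed clone, subject to feasibility and user constraints); fit
frequencies; rank.

Ordered insertion plus the frozen child sets make over-counting
impossible; in the exact model an attachment that drives a non-frozen
parent's frequency to zero is additionally rejected, because the resulting
tree belongs to a larger partial tree and is enumerated there.

## Error models and their parameters

Every "is this zero" decision runs through one of three models:

* `exact` — noise-free frequencies; equality at tolerance $10^{-9}$
  (see *Numerical choices*).
* `bound` — measurement $i$ lies within $y_i \pm \varepsilon_i$; a sum
  criterion gets the additive interval allowance
  $\varepsilon_{i_0} + \sum_S \varepsilon_j$. This is the natural model
  for the simulation harness's uniform noise.
* `normal` — independent Gaussian errors with sd $\varepsilon_i$; a
  residual is indistinguishable from zero when 0 lies in its two-sided
  $1-\alpha$ confidence interval, i.e. allowance
  $z_{1-\alpha/2}\sqrt{\varepsilon_{i_0}^2 + \sum_S \varepsilon_j^2}$.
  Default $\alpha = 0.05$. This is the model for read-count data, with
  $\varepsilon$ from the binomial normal approximation
  $\sqrt{y(1-y)/n}$.

The dummy's error is 0 when a signal is built by `build_signal()`, but an
explicitly supplied nonzero value participates in the interval arithmetic
— the dummy measurement is exact only by construction, and the allowance
formulas are defined for a general error vector.

Under noisy models the back-substitution can go slightly negative, so
frequencies are re-fitted by Lawson–Hanson nonnegative least squares with
*exact* zeros forced at the unpopulated clones of the generating partial
tree. This yields $x \ge 0$, distributes measurement error across the
populated clones, and records the fit residual. $P$ is counted as
$N - h$ from the partial tree by default; `count_populated_from_fit`
switches to counting post-fit nonzeros (the two differ only when NNLS
zeroes a nominally populated clone).

Caps: signals larger than `max_n = 25` are refused with the advice to
cluster similar frequencies first (large systems should be reduced to
their effective aberration groups — by gene panel, pathway, or the
built-in frequency clustering); enumeration stops at
`max_solutions = 10000` with a truncation flag. `sparsity_slack` keeps
partial trees of size $\ge h^\ast - s$, exposing less-sparse candidates.

## Preprocessing recipes

* Entries indistinguishable from 0 are dropped (absent); entries
  indistinguishable from 1 are removed from deconvolution and recorded as
  ubiquitous trunk annotations rather than placed in the tree — aggregate
  data cannot order trunk events anyway, so annotation loses nothing.
  Both are kept in the provenance map.
* Ties sort by ascending label, making all enumeration deterministic.
* Frequency clustering merges entries pairwise-indistinguishable under the
  active model (single-linkage transitive closure), replacing each cluster
  by its median with error $1.4826 \cdot \mathrm{MAD}$ — the consistency
  scaling that estimates a normal sd. No $\sqrt{n}$ shrinkage is applied:
  the cluster error describes the spread of the underlying measurement,
  not a standard error of the median. The even-size median is the midpoint
  of the central pair.
* Read counts give $y = m/n$ and the binomial-normal
  $\varepsilon = \sqrt{y(1-y)/n}$; variant filters keep records with
  coverage strictly above a threshold (e.g. `min_coverage = 200`), inside
  a region, or present in named samples. No VAF-to-cellular-prevalence
  doubling is applied: allele fractions are fed directly (germline
  heterozygous variants then sit near 0.5); a multiplier can be applied
  upstream if copy-number context justifies it.

## Polyallelic loci

When one nucleotide mutates repeatedly (common under somatic
hypermutation), the observed per-allele frequencies are compatible with
several *phasings*: alleles on sibling branches (parallel, mutually
exclusive events) or along one lineage (serial; a cell that went
A→G→C still carries the A→G event, so the upstream event's frequency is
the sum of its own and all downstream allele frequencies). The package
reduces each site to all arrangements of its derived alleles into chains
(3 hypotheses for two alleles, 13 for three), attaches the implied
ancestor/exclusivity constraints, combines sites by Cartesian product
(capped at 729), solves each binary reduction, and ranks hypotheses by
$(P, D, \text{residual})$.

An identifiability caveat discovered while validating this module: with a
single sample's aggregate frequencies alone, serial and parallel phasings
of a small site are generally *not* distinguishable — a parallel
reconstruction ties the serial one on sparsity and is shallower, so it
wins the ranking. Order information must come from outside (read pairs,
sequenced clones), which is what the `known_chains` field / the site
table's `chain` column carries; declared chains prune the hypothesis set
before solving. The winning hypothesis is always reported alongside the
solutions, so users can see which phasing an answer assumes.

## Multi-sample joint solving

Related samples (e.g. several metastases of one patient) should be
explainable as subsets of one global evolutionary tree. The package makes
that notion concrete pairwise: each per-sample solution induces, for every
pair of its aberrations, one of three relations — ancestor, descendant, or
separate branches. A tuple of per-sample solutions is compatible when no
shared pair's relations conflict and the merged relations (after
transitive closure and antisymmetry/exclusivity checks) assemble into a
single tree over the label union, each label attaching under the unique
deepest element of its ancestor set. Only solutions participating in at
least one compatible tuple survive; the assembled global trees are
returned, and when nothing is compatible the conflicting pairs are
reported. The tuple search is exhaustive (capped) — per-sample optimal
sets are small in practice.

## The synthetic-data generator

`simulate_clone_tree(n, p)` emulates the noisy-aggregate validation
protocol: a uniformly random ordered tree (`parent[i]` uniform on
$1..i-1$), a populated set of all leaves plus random extras up to $p$
(leaves must be populated — an unpopulated leaf would have frequency 0 and
not be measured at all), populated frequencies from a flat Dirichlet
(symmetric, parameter 1 — the simplest "randomly assigned" distribution on
the simplex), exact aggregates, and relabeling into sorted order.
`perturb_signal` adds uniform $\pm E$ noise to every entry except the
dummy, clipping to $[0,1]$ (the dummy is exact by construction; clipping
keeps perturbed values interpretable as frequencies). The paired error
vector (all $E$) feeds the bound model, mirroring how a user would declare
a known noise magnitude. Default noise grid: $E \in \{0, 0.01, 0.05\}$,
spanning noise-free to the upper end of typical sequencing-experiment
error on frequencies; trees whose leaf count exceeds $p$ are resampled
(rejection keeps the tree distribution uniform conditional on the leaf
bound).

What the generator does *not* emulate: correlated errors across variants,
copy-number distortion of allele fractions, sampling noise that scales
with coverage (use the read-count path for that), or mutation-rate
heterogeneity. A green benchmark therefore establishes correctness of the
*deconvolution machinery* under the stated noise model, not performance on
any particular sequencing platform.

`mix_genotypes` emulates the complementary protocol — mixing *known*
genotype profiles with Dirichlet (or user) weights and asking whether
deconvolution finds every input genotype in its correct proportion
(`recovery_check`), optionally comparing co-occurrence of mutation pairs
against reference single-cell profiles (`cooccurrence_fraction`; the
fraction of solution co-occurring pairs confirmed by at least one
reference genotype — our documented formalization of a criterion the
source protocols leave informal).

`evaluate_run` scores a run by three nested criteria: the planted truth is
sparsest; it is among the returned optimal solutions; it is the unique
one. A solution "equals the truth" when its parent array and frequencies
match, or when its populated clones carry exactly the truth's genotypes at
the truth's frequencies. The second clause matters under noise: an
unpopulated parent and its single child have *exactly* equal clean
aggregates, noise reorders such ties half the time, and after re-sorting
the planted parent array may violate descent ordering even though the
recovered populated genotypes are identical. The two notions coincide
whenever no frequencies tie.

## Numerical choices

* Machine tolerance $10^{-9}$ for exact-model equality, feasibility and
  populatedness; all criteria are *inclusive* ($\le$ allowance +
  tolerance). Boundary cases (residual exactly equal to the allowance) are
  therefore accepted — the defensible interval-arithmetic reading, and
  float noise makes a strict boundary meaningless anyway.
* Ties everywhere break deterministically: descending frequency then
  ascending label on input; ascending depth then lexicographic parent
  array on output.
* NNLS is the classical Lawson–Hanson active-set method (pure R; problems
  have at most 25 columns), with rank-deficient passive sets handled by
  dropping null directions.
* Degenerate inputs: an empty record set yields the wildtype-only signal;
  a signal of one entry returns the wildtype-only solution; duplicate
  frequencies are legal (the solver flags nothing, but the recommended
  pipeline clusters ties first).
* Exact-model sums $\Sigma x = 1$ hold by telescoping; under noisy NNLS
  fits the total is tied to 1 only through the dummy row, so
  $|1 - \Sigma x|$ is bounded by the fit residual — the invariant the
  conservation tests assert.

## Limitations

* Aberrations are binary presence/absence events; copy-number dosage is
  out of scope (polyallelic loci are handled by reduction, not by a
  multi-state model).
* With one sample, solutions are often non-unique by nature; the package
  returns all optima rather than guessing.
* The sparsity objective can be misled by heavy noise: wide allowances
  certify spurious first-generation trees and solutions sparser than the
  truth (visible in the benchmark grid as the decline of the
  truth-is-sparsest percentage with $E$).
* Serial-vs-parallel phasing of polyallelic sites is unidentifiable from
  single-sample frequencies (see above); declare known chains.
* The brute-force oracle is deliberately naive and capped at $N \le 9$;
  it exists to keep the staged solver honest, not to be fast.
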