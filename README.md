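# cloneDecon

Subclonal deconvolution of a **single aggregate aberration-frequency
vector** — for example bulk variant allele fractions from one tumor
biopsy — into subclone genotypes, subclone mixing fractions and the clonal
evolution tree relating them.

## The problem

A bulk sample is a mixture of subclones: groups of cells sharing an
identical aberration profile. Sequencing the pooled sample measures, for
each aberration *i*, only its **aggregate frequency** *y<sub>i</sub>* — the
fraction of cells carrying it. Writing **C** for the binary genotype matrix
(*C<sub>ij</sub>* = 1 iff aberration *i* is present in subclone
*C<sub>j</sub>*) and **x** for the subclone mixing fractions, the
measurement is the linear mixture

> **y** = **C x**,  x ≥ 0.

To carry the normal-cell (wildtype) fraction in the same linear model, an
artificial *dummy* aberration present in every cell is prepended
(*y*₁ = 1), and **y** is sorted non-increasing. Under the standard
evolutionarity and parsimony assumptions — every aberration arises exactly
once and is never lost, so each aberration *i* defines the subclone in
which it first occurred — every admissible genealogy is an *N*-clone tree
whose parent indices satisfy `parent[j] < j`, and the clone frequencies are
the back-substitution

> *x<sub>i</sub>* = *y<sub>i</sub>* − Σ<sub>children j of i</sub> *y<sub>j</sub>*.

This system is underdetermined: up to (N−1)! trees exist. The package
returns the solutions that optimize, in order, **sparsity** (fewest
populated subclones, *P*) then **shallowness** (smallest tree depth *D*),
using a staged search instead of brute force:

1. detect all **first-generation trees** — an unpopulated clone *i₀*
   together with the complete set *S* of its direct descendants, certified
   by *y<sub>i₀</sub>* = Σ<sub>S</sub> *y<sub>j</sub>* (exactly, or within
   the active measurement-error model);
2. combine them into maximal **partial trees** (compatible collections of
   size *h\**); every sparsest solution (*P = N − h\**) contains one;
3. grow each partial tree into all consistent full trees by ordered clone
   insertion;
4. fit frequencies — back-substitution in the exact model, or constrained
   nonnegative least squares (`x ≥ 0`, forced zeros at unpopulated clones)
   under the `bound` (interval) or `normal` (Gaussian, level α) error
   models;
5. rank by (*P*, *D*) and return all optima.

Extensions: frequency clustering (median / 1.4826·MAD representatives),
read-count preprocessing (VAF with binomial-normal errors), user ancestor /
branch-exclusivity constraints, polyallelic loci (several mutations hitting
one nucleotide, reduced to binary problems over serial/parallel phasing
hypotheses), multi-sample joint solving under one global evolutionary tree,
a brute-force oracle, and a simulation/benchmark harness.

## Worked example

Five aberrations measured at frequencies 0.72, 0.40, 0.28, 0.25, 0.15:

```r
library(cloneDecon)
sig <- build_signal(data.frame(label = c("a2","a3","a4","a5","a6"),
                               y = c(0.72, 0.40, 0.28, 0.25, 0.15)))
res <- deconvolve(sig)
print(res)
```

```
Deconvolution: N = 6, 2 first-generation trees, h* = 2, min P = 4
1 optimal solution(s) of 1 candidate(s)
Solution: P = 4 populated subclones, depth D = 3, residual = 0
 clone parent label    x
     1      - dummy 0.00
     2      1    a2 0.32
     3      2    a3 0.00
     4      1    a4 0.28
     5      3    a5 0.25
     6      3    a6 0.15
```

Reading the output: two first-generation trees were certified
(1.00 = 0.72 + 0.28 and 0.40 = 0.25 + 0.15), so the wildtype clone and
clone `a3` are unpopulated (`x = 0`) and the sparsest genealogy has
P = 6 − 2 = 4 populated subclones. The unique optimal tree says: `a2` arose
first (its clone is 32% of cells), `a4` arose independently of `a2` (28%),
`a3` arose inside the `a2` lineage but no pure-`a3` cells remain — its
lineage split into an `a5` subclone (25%, genotype {a2,a3,a5}) and an `a6`
subclone (15%, genotype {a2,a3,a6}). No normal cells are present.

The same run from the command line:

```sh
Rscript inst/scripts/clonedecon solve input.tsv --error-model exact --out result
# input.tsv: TSV with columns id, freq, optional err, optional sample
# writes result.json, result.dot, result.nwk
```

Exit codes: 0 success, 2 input error, 3 cap exceeded (e.g. N > 25 without
clustering). Subcommands: `solve`, `simulate`, `mix`, `joint`, `oracle`.

### Newick dialect

No standard exists for clone trees, so the `.nwk` export is fixed as:
every node (internal or leaf) is named by its aberration label, children
are ordered by clone index, and the clone frequency rides in a bracketed
comment. A chain wildtype → a → b is `((b[x=..])a[x=..])wildtype[x=..];`.

## Layout

* `R/` — signal/tree types, preprocessing, staged solver, NNLS, brute-force
  oracle, polyallelic reductions, joint multi-sample solving, simulation
  harness, IO and CLI
* `tests/testthat/` — unit, property and acceptance suites
* `vignettes/subclonal-deconvolution.Rmd` — methods vignette (model,
  assumptions, error models, synthetic-data design, limitations)
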