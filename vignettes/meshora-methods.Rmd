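---
title: "Methods and design of meshora"
author: "meshora authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of meshora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meshora)
```

# What the package computes

Over-representation analysis (ORA) asks whether an annotation term occurs
among a list of selected genes (differentially expressed genes, mutation
carriers, screen hits, ...) more often than drawing the same number of
genes at random from the universe would explain. `meshora` performs ORA
against Medical Subject Headings (MeSH), the controlled vocabulary used to
index the biomedical literature. MeSH covers far more than molecular
biology — its 16 lettered categories range from Anatomy (A) and Diseases
(C) through Chemicals and Drugs (D) to disciplines, technology and
geography — so its enriched terms can expose clinical, pharmacological or
methodological structure in a gene list that a purely molecular vocabulary
cannot. Because MeSH terms index documents, each enriched (gene, term)
pair also points at the concrete literature supporting it; the
`collectDocRecords()`/`organizeDocs()` layer turns an enrichment table
into a locally organised reading list.

The package is self-contained: annotation stores are built from plain TSV
tables, orthology-based annotation transfer runs on an exact local
aligner, and synthetic generators emulate every input so that the entire
pipeline is testable offline.

# The enrichment model

For one term, let $N$ be the number of universe genes carrying at least
one annotation in the tested category/source slice, $k$ the number of
selected genes among them, $M$ the number of universe genes annotated to
the term and $x$ the number of selected genes annotated to it. Under the
null hypothesis that the selection is unrelated to the term, $x$ follows
the hypergeometric distribution

$$P(X = x) = \frac{\binom{M}{x}\binom{N-M}{k-x}}{\binom{N}{k}}.$$

The quantity reported as the enrichment p-value is the **upper tail**
$P(X \ge x)$, not the point mass. The point mass alone (available as
`hypergeomPmf()`) can be small merely because many outcomes are possible;
the tail is the probability of an overlap at least as extreme as the one
observed and is the convention used by the classical ORA engines this
package follows. This is the single most consequential interpretation
decision in the package and is therefore spelled out here: `hypergeomPvalue()`
= upper tail, `hypergeomPmf()` = point mass. Both are computed in
log-factorial (`lchoose`) arithmetic; the tail agrees with exhaustive
enumeration of all $\binom{N}{k}$ draws to below $10^{-14}$ for every
feasible configuration with $N \le 12$ (the acceptance suite recomputes
this).

Two further counting decisions matter:

* **Universe restriction.** $N$ counts only universe genes with at least
  one annotation in the selected category and source(s). Genes with no
  annotation in the slice are uninformative for every term of that slice;
  including them would deflate the null overlap and inflate significance
  uniformly.
* **No hierarchy propagation.** $M$ and $x$ count direct links only;
  annotations are *not* propagated up the ancestor-offspring closure.
  Propagation would make parent terms redundantly significant whenever a
  child is; the hierarchy is exposed for interpretation
  (`meshAncestors()`, `meshOffspring()`) rather than folded into the
  counts. Tools differ on this point, so counts from other
  implementations need not match exactly.

The multiple-testing family of one run is the set of terms actually
tested: the terms of the selected category/source slice with $M \ge 1$.
Corrections are applied within that family only.

# Multiple-testing corrections

Thousands of terms are tested per run, so the package reports adjusted
values from one of three methods, all sharing the rejection rule
"adjusted value strictly below the threshold".

**Benjamini-Hochberg (BH).** On the sorted p-values,
$q_i = p_{(i)} \, m / i$, followed by the step-up monotonization (running
minimum from the largest rank) and a cap at 1. The monotonization is not
optional decoration: without it the per-rank quantities are non-monotone
and are not valid adjusted p-values, and with it the strict-threshold rule
is exactly the textbook step-up rejection rule. BH assumes the null
p-values are uniform and controls the false discovery rate at
$\pi_0 \alpha \le \alpha$.

**Q-value.** When many hypotheses are non-null, BH over-corrects by the
factor $1/\pi_0$. The q-value scales the BH quantities by an estimate of
the null proportion: $Q_i = \hat\pi_0 \, p_{(i)} \, m / i$. $\hat\pi_0$
comes from the familiar histogram-extrapolation estimator: for
$\lambda \in \{0.05, 0.10, \ldots, 0.90\}$,
$\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m(1-\lambda))$, a natural cubic
smoothing spline with 3 degrees of freedom is fitted to
$\hat\pi_0(\lambda)$ against $\lambda$, and the estimate is the spline
value at the largest $\lambda$, clamped to $(0, 1]$ (lower clamp $1/m$).
Below $m = 20$ hypotheses, or for a degenerate all-equal vector, the
estimator falls back to the conservative $\pi_0 = 1$, where the q-value
reduces exactly to BH.

Because $\hat\pi_0 \le 1$, q-values are elementwise no larger than the BH
values and the q-value rejection set is a superset of BH's. The flip side
is worth stating plainly: the q-value targets the nominal level $\alpha$
while BH undershoots at $\pi_0\alpha$, so in simulation the realized
false-discovery proportion of the q-value sits close to $\alpha$ and
*above* BH's — less conservative, not more accurate per rejection. The
package's simulations measure both.

**Local FDR.** Rather than a tail-average error rate, the local FDR is
the posterior probability that an individual hypothesis is null:
$\mathrm{lFDR}(p) = \pi_0 f_0(p) / f(p)$ with uniform null density
$f_0 \equiv 1$. The marginal density $f$ is estimated with the Grenander
estimator — the left-hand slopes of the least concave majorant of the
empirical CDF — which is the maximum-likelihood density estimate under
the one natural shape constraint available here, that a p-value density
is non-increasing. It requires no bandwidth choice and is deterministic.
Values are clamped to $[0, 1]$. The estimator needs a reasonable sample;
below 20 p-values the function refuses and advises BH. Under a pure-null
sample both $\hat\pi_0 \to 1$ and $f \to 1$, so the local FDR approaches
1 everywhere (the acceptance suite checks a median of at least 0.85 at
$m = 5000$).

**Choosing among them.** `pvalueDiagnostics()` reports decile counts and
a Kolmogorov-Smirnov distance from uniformity, advisory only: near-flat
histograms suggest plain BH; a pronounced spike near zero justifies the
q-value or local FDR.

**A numerical guard.** The arithmetic $p \cdot m / i$ can land one ulp
away from the intended value (e.g. the worked case
$p = 0.01, \ldots, 0.05$, whose adjusted values are all exactly $0.05$
mathematically). The strict `< alpha` comparison is therefore guarded by
an absolute tolerance of $10^{-12}$: a value within $10^{-12}$ of the
threshold counts as equal to it and is not rejected. Any decision this
guard could flip is far below the resolution of the methods themselves.

# The annotation store

A `MeshDb` holds the vocabulary (term, category, qualifiers, synonyms),
the hierarchy and the gene-to-term links with their provenance
(`gendoo`-style text-mining imports, `gene2pubmed`-style curated
literature links, or `RBBH` orthology transfer) and supporting document
ids. Design choices:

* **Poly-hierarchy.** MeSH terms occur at multiple tree positions, so the
  parent-child relation (PCR) is a multi-parent DAG, not a tree; a DAG
  subsumes the tree case. Cycles are rejected at construction, naming a
  term on the cycle.
* **Derived closure.** The ancestor-offspring relation (AOR) is never
  stored; it is computed at build time as the strict transitive closure
  of PCR (a term is not its own ancestor). Deriving it removes an entire
  class of stored-inconsistency bugs and makes the AOR/PCR invariant
  checkable — the test suite verifies the closure against an independent
  breadth-first-search oracle on random DAGs.
* **Relational SELECT.** `meshSelect(db, keys, cols, keytype)` returns
  the joined term/link relation in long format with duplicates preserved,
  like a SQL SELECT. Missing keys yield zero rows, never errors; only
  malformed schema names error. Row order is deterministic (C-locale
  radix sort on the keytype column, then the remaining requested
  columns), so query answers diff cleanly across machines and reloads.
* **Plain-text storage.** A store directory is TSV tables plus a
  `key=value` manifest. A reloaded store answers every query identically
  to the original, byte for byte.

# Building annotations

**Literature joins.** `joinGenePubmedMesh()` joins a (gene, article)
table with an (article, term) table. Articles tagged with more than 1000
distinct genes — genome papers, database announcements — carry
essentially no gene-specific information, so they are dropped *before*
the join; the threshold is strict (exactly 1000 genes is kept). The
filter counts distinct genes per article in the gene-article input alone
and is applied per input table. Matches are aggregated to one link per
(gene, term), collecting all contributing article ids.

**Orthology transfer.** Organisms with little literature inherit
annotations from well-studied ones through reciprocal best hits: genes in
two proteomes that are each other's unique best alignment hit. The
aligner is exact Smith-Waterman with BLOSUM62 and affine gaps (open 11,
extend 1) — at desk scale the heuristics of a search engine buy nothing,
and the best-hit/reciprocity logic, not the engine, is the method. Best
hits keep subjects scoring positively and at least `minScore`
(default 0, i.e. maximally permissive, the analog of running a search at
an extremely loose E-value cutoff and letting reciprocity do the
filtering); ties break to the lexicographically smallest subject id so
results are reproducible. The substitution matrix and gap costs are
stated package defaults, not facts inherited from any particular search
deployment. `transferByRbbh()` then copies every donor link to the
recipient gene, tagged `RBBH` with documents preserved, unioning over
multiple donors; it can never introduce a term absent from the donor
links.

# Synthetic data: what it emulates and what it does not

The generators produce every input dialect the package consumes, with
ground truth retained:

* `makeVocabulary()` — a random DAG over `nTerms` terms (~10%
  multi-parent), categories drawn from the 16 codes.
* `makeAnnotations()` — independent (gene, term) links at a fixed
  density, each with 1-3 synthetic document ids.
* `makeStudy()` — genes selected independently at a base rate, with the
  selection *odds* of genes annotated to one planted term multiplied by
  an effect size; effect 1 makes selection independent of annotation.
* `makePvalueMixture()` — nulls Uniform(0,1), alternatives
  Beta(shape, 1) with shape < 1, Bernoulli($\pi_0$) labels.
* `makeProteomes()` — ortholog pairs as two independent mutated copies of
  a random ancestor sequence, plus unrelated decoys.

Every generator runs under its own seed and restores the caller's RNG
state, so fixtures are pure functions of their parameters.

The benchmark condition used by the recovery tests is the generator
default: 2000 genes, 200 terms, density 0.05, base selection rate 0.05,
planted odds effect 8. Those sizes give a typical term ~100 annotated
genes and a selected list of ~120, i.e. a planted-term overlap around 30
against a null expectation around 6 — a strong but not caricatured
signal; 100 seeded replicates complete in about 90 seconds. The RBBH
benchmark (20 ortholog pairs of length 120 at 5% divergence, 20 decoys a
side) is evaluated at `minScore = 100`: random length-120 BLOSUM62 local
alignments score around 25-35 (the Karlin-Altschul expectation at these
lengths) while 5%-diverged orthologs score above 400, so 100 sits in the
wide gap between noise and signal rather than on a tuned boundary.

What the synthetic data deliberately does **not** emulate: correlated
literature co-occurrence (real gene-term links are strongly clustered by
research fashion), organism-specific amino-acid composition, hierarchy-
correlated annotation (real child terms share genes with their parents),
and realistic universe incompleteness. Passing the recovery tests
therefore demonstrates the machinery is correct and calibrated under the
stated model, not that real MeSH enrichments are as clean; on real data
the independence assumptions are optimistic and corrected significance
should be read with the usual caution.

# Numerical and degenerate-input choices

* Hypergeometric quantities via `lchoose`; tails summed over the feasible
  overlap range only.
* `M = 0` terms are never tested (the family is terms with $M \ge 1$).
* An empty intersection of selected genes with the annotated universe
  returns an explicit `nothingTestable()` result, not an error.
* Tag-cloud weights are $-\log_{10} p$ (so $p = 0.01 \mapsto 2$);
  $p \le 0$ is rejected.
* Reports serialise numerics as `%.17g`, which round-trips doubles
  exactly: serialise, parse, re-serialise is byte-identical.
* All tie-breaks (result ordering, best-hit subjects, planted-term
  choice) are lexicographic on identifiers, making every output
  deterministic given the inputs.

# Limitations

* Gene identifiers are Entrez-style positive integers only; identifier
  conversion is out of scope.
* Text-mining relevance scores behind `gendoo`-style inputs are accepted
  as precomputed tables, never recomputed.
* The local FDR's Grenander estimate is coarse near $p = 1$ for small
  samples; the $m \ge 20$ floor is a pragmatic, not a sharp, bound.
* Annotation transfer trusts reciprocity alone; paralog families can
  still swap partners at high divergence. The benchmark's 5% divergence
  is easy territory by design.
* No network retrieval anywhere: document fetching is an injected
  callable, and the bundled default writes placeholders.

# A worked run

```{r example}
spec <- fixtureSpec(nGenes = 500, nTerms = 50, seed = 7)
voc <- makeVocabulary(spec)
links <- makeAnnotations(spec, voc)
study <- makeStudy(spec, links)
db <- MeshDb(voc$terms, voc$edges, links,
             metadata = c(organism = "synthetic"))
db

categ <- meshTerms(db)$category[meshTerms(db)$mesh_id == study$plantedTerm]
res <- meshHyperGTest(db, study$universe, study$selected,
                      MeshOraParams(categ, correction = "QV",
                                    threshold = 0.05))
res
head(termWeights(res), 3)
```

The planted term (`study$plantedTerm` in the code above) surfaces at
rank one with a q-value far below the threshold, and its weight is its
$-\log_{10} p$.
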