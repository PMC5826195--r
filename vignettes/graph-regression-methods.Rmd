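---
title: "Scoring miRNA-disease associations by latent graph regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring miRNA-disease associations by latent graph regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grmda)
```

## The problem

Experimentally validating a single miRNA-disease association is slow and
expensive, so computational ranking of candidate pairs is used to decide
what to test next. The inputs are a binary association matrix $A$
($nm$ miRNAs $\times$ $nd$ diseases, $A_{ij} = 1$ for a curated
association), a precomputed miRNA functional similarity matrix $FS$, and
per-disease ontology DAGs (MeSH-style), from which the package produces a
real-valued confidence matrix $C$ of the same shape: higher $C_{ij}$ means
the pair is a more plausible association.

The driving assumption is the standard one in this literature: functionally
similar miRNAs tend to associate with semantically similar diseases. The
method therefore fuses three graphs — the bipartite association graph and
one similarity graph per axis — and regresses between their low-rank latent
representations.

## Similarity construction

**Disease semantic similarity.** Each disease $D$ is a node in an ontology
DAG; $T(D)$ is $D$ plus its ancestors. Model 1 gives $D$'s own node
contribution 1 and each ancestor $d$ the contribution
$\max_{d' \in \mathrm{children}(d)} \Delta \cdot c(d')$, a geometric decay
with hop distance ($\Delta \in (0,1)$, default 0.5 — the value used
throughout the MISIM lineage of functional similarity measures). Model 2
replaces the decay by corpus specificity: term $t$ contributes
$-\ln(\text{number of DAGs containing } t / \text{number of DAG-bearing
diseases})$, so terms shared by every disease contribute nothing and rare
terms contribute a lot. Under either model the similarity of two diseases
is the sum of both sides' contributions over the shared terms, divided by
the sum of the two semantic values; identical DAGs score 1, disjoint ones
score 0.

Two choices here were genuinely open. The logarithm base in model 2 is
unspecified in the literature this follows; any single base consistently
applied cancels between numerator and denominator only if used throughout,
so we fix the natural log. The model-2 denominator counts diseases that
*have* DAGs in the corpus, not all diseases on the association axis — only
DAG-bearing diseases can contain a term. A root-level disease can have
model-2 semantic value exactly 0 (all of its terms occur in every DAG);
pairs involving two such diseases are assigned similarity 0 rather than the
undefined $0/0$.

**Gaussian interaction-profile kernels.** Disease $j$'s interaction profile
is column $j$ of $A$; the kernel is
$KD_{ij} = \exp(-\gamma_d \lVert IP(d_i) - IP(d_j)\rVert^2)$ with
$\gamma_d = \gamma'_d / \overline{\lVert IP(d)\rVert^2}$, i.e. the
bandwidth scaler normalized by the mean number of known associations per
disease. $\gamma'_d = 1$ is the conventional setting; we extend the same
default to the miRNA side by the symmetry of the two formulas. If every
profile is all-zero the normalizer vanishes; we then set
$\gamma = \gamma'$ and warn, which keeps new-disease workflows total (the
kernel degenerates to all-ones, carrying no information, which is exactly
what an empty matrix supports).

**Integration.** Where a disease pair shares at least one ancestor (the
"has semantic similarity" mask, implemented as $SS1 > 0$ — an all-zero
semantic score carries no signal, and the kernel is the stated fallback),
the integrated disease similarity is the plain average $(SS1+SS2)/2$,
treating the two models as equally informative; elsewhere it is the kernel
value. Likewise miRNA similarity is $FS$ where $FS > 0$ off the diagonal
and the miRNA kernel elsewhere.

## The scoring model

Three truncated SVDs project the graphs into latent spaces:

$$A \approx A_r A_d^T, \quad S_m \approx F_r F_r^T, \quad S_d \approx F_d F_d^T,$$

with $A_r = U_r \Sigma_r^{1/2}$, $A_d = V_r \Sigma_r^{1/2}$ from the SVD of
$A$ (rank $r$), and $F_r$, $F_d$ the analogous rank-$p$ and rank-$q$
factors of the two similarity matrices. The symmetric $\Sigma^{1/2}$ split
is the unique one for which the factor product reproduces the truncated
SVD; the residual is exactly the sum of the discarded squared singular
values (Eckart-Young), which the test suite verifies against the raw
spectrum. Singular-vector signs are fixed so each left singular vector's
largest-magnitude entry is non-negative, making results reproducible across
LAPACK builds. Similarity matrices are factorized as-is without projecting
onto the positive semidefinite cone: the SVD route is total on any
symmetric matrix, and a PSD projection would silently alter the input.

Two multi-response PLS regressions link the spaces: $A_r$ on $F_r$ and
$A_d$ on $F_d$ (NIPALS, regression mode, fitted by the mixOmics engine).
Columns are centered but not variance-scaled — the latent factors carry
singular-value weighting that unit scaling would destroy. The number of
components kept is a count, $\max(1, \lfloor 0.9 \cdot \min(f, t, n-1)
\rfloor)$ by default; a variance-explained reading of "90% of components"
is available via `plsMode = "variance"`. Centering induces intercepts that
the bare bilinear formula lacks; they are propagated by default,

$$C = (F_r B_r + \mathbf{1} b_{r0}^T)(F_d B_d + \mathbf{1} b_{d0}^T)^T,$$

because dropping them (available via `intercept = FALSE`) discards the mean
structure of the latent association factors and measurably hurts held-out
ranking. If a latent feature matrix is entirely constant in every column (a
degeneracy reachable on two-disease toys), the regression limit is the
response mean, and the pipeline uses that directly rather than failing.

## Choosing the ranks

`r`, `p`, `q` accept explicit counts or fractions of the relevant
dimension. The fraction defaults — 0.45 of each axis for the similarity
spaces and 0.47 of the smaller axis for the association space — reproduce
the reference settings $p = 220 \approx 223$, $q = 170 \approx 172$,
$r = 180$ on a 495-miRNA $\times$ 383-disease corpus, the scale this method
was designed for. There is no principled generalization rule behind the
association-space setting ("moderately" chosen in the source literature);
the fraction is a back-fit and should be treated as a starting point. On
small, sparse matrices these fractions retain enough components to nearly
interpolate the observed matrix, which suppresses held-out generalization —
see Limitations.

## Cross-validation protocol

`loocv()` masks each known association in turn, rescales the whole
pipeline, and ranks the held-out cell's score against all never-known
pairs, pooled in the Mann-Whitney form with ties credited 0.5 — exactly the
pair-counting definition of AUC, which the tests verify against brute-force
enumeration and an independent ROC implementation. By default the Gaussian
kernels (and hence $S_m$, $S_d$) are rebuilt from the masked matrix inside
every fold: computing them once from the full matrix leaks each held-out
association into the similarity graphs. Whether the original protocol
recomputed them is not documented; both behaviors are exposed
(`recomputeKernels`), and the leak-free default is the defensible one.
`kfoldCv()` partitions the known associations into $k$ near-equal parts
(first $n \bmod k$ folds take the remainder), pools each repetition's folds
into one AUC, and reports mean $\pm$ sd over seeded repetitions. Candidate
scores are taken from each fold's own score matrix, so they drift
fold-to-fold rather than being frozen from a single full-data run. The per-disease ranking
(`rankForDisease()`) breaks score ties by miRNA label so output is
deterministic, and the new-disease mode (`zeroDiseaseColumn()`) empties a
disease's column before scoring.

## The synthetic generator

`makeBundle()` emulates the three curated inputs jointly. Latent factors
$X$ ($nm \times g$) and $Y$ ($nd \times g$) are gamma(2, 1) draws, so the
probability matrix $P \propto XY^T$ (rescaled to the target mean density,
capped at 1) is non-negative and right-skewed like real association data;
$A$ is sampled cellwise as Bernoulli($P$). $FS$ is the cosine similarity of
$X$ plus symmetric Gaussian noise, clipped to $[0,1]$, with a fraction of
off-diagonal entries zeroed to exercise the kernel fallback. The DAG corpus
is a random rooted tree (depth 3, branching 4 by default, padded with extra
leaves when diseases outnumber nodes); to make semantic similarity
informative, diseases whose nodes share a parent draw their factors around
a shared group component. The sharing is additive — group gamma(1, 1) plus
individual gamma(1, 1) — which preserves the gamma(2, 1) marginal exactly
while giving siblings correlation 0.5. A configurable fraction of diseases
(default 0.2) is left without a DAG to exercise the kernel branch of the
disease integration.

What the generator does *not* emulate: the heavy-tailed degree
distributions of curated databases, the nested topology of real MeSH trees,
the disease-set-overlap construction of real functional similarity, or
curation bias (well-studied diseases accumulate associations). Passing
tests on bundles therefore demonstrate protocol and implementation
correctness and recovery of a known planted signal — not performance on
curated data.

## Problem sizes and numerical tolerances

The shipped tests and the acceptance script run at desk scale: bundles of
100 miRNAs $\times$ 60 diseases (rank-3 truth, density 0.05), LOOCV over a
seeded 50-association subsample, and 100-repetition five-fold runs with
either the full pipeline or a cheap deterministic scorer where only the
protocol bookkeeping is under test. Symmetry is enforced to 1e-9 on input
matrices; exact reconstruction claims are tested at 1e-10 relative,
Eckart-Young residuals at 1e-6 relative, PLS exactness at 1e-8 relative,
and score round trips through TSV at 1e-9.

## Limitations

* **Desk-scale recovery is bounded well below 1.** Under the default
  generator conditions the Bayes-optimal ranking — scoring by the true $P$,
  which no method can systematically beat for Bernoulli-sampled cells — is
  itself far from perfect: `scripts/acceptance.R` recomputes this ceiling
  (`loocv_auc_oracle`) next to the pipeline's own `loocv_auc` each run. A
  300-association matrix with weak planted spread simply does not determine
  held-out cells well. Comparisons of `loocv_auc` against
  `loocv_auc_oracle` and `loocv_auc_null` (entry-rewired matrix) are the
  meaningful readout; absolute AUC values at this scale are not comparable
  to full-corpus results.
* **Default ranks at small scale.** The 45-47% retained-rank defaults are
  back-fits to the full-corpus setting; at desk scale they nearly
  interpolate the association matrix and smaller explicit ranks recover
  more held-out signal. Set `r`, `p`, `q` explicitly when the data are far
  from the reference scale.
* **No joint optimization.** The five terms of the underlying objective are
  minimized independently (SVD then PLS), as the method defines; no
  alternating refinement is attempted.
* **Identifier hygiene is the caller's job.** Matching across inputs is
  exact, case-sensitive text; harmonizing database versions and aliases
  must happen upstream.
* **Literature verification is out of scope.** The package ranks
  candidates; checking top-k lists against external databases is a manual,
  version-dependent step.
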