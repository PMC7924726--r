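---
title: "Supervised GRN inference by genomic kernel fusion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised GRN inference by genomic kernel fusion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnfuse)
```

## The inference problem

A gene regulatory network (GRN) is a directed graph whose edges connect
transcription factors (TFs) to the genes they regulate. grnfuse treats
genome-wide GRN inference as a collection of independent supervised
classification problems, one per TF: given a handful of known targets of a
TF (positive labels) and the rest of the genome (presumed negatives), rank
all genes by how strongly their measured profiles resemble those of the
known targets. This is the SIRENE-style supervised scheme, extended in two
directions:

* **Data fusion.** Several heterogeneous genomic data types — an expression
  compendium, a methylation matrix, a protein–protein interaction (PPI)
  graph — are each transformed into a gene × gene positive semi-definite
  (PSD) kernel and summed into one combined kernel,
  $K = \sum_i \mu_i k_i$ with $\mu_i \ge 0$. The classifier only ever sees
  the fused kernel, so adding a data type never changes the surrounding
  machinery.
* **Parallel decomposition.** The per-TF subproblems share the kernel and
  nothing else, so they are distributed over a static, near-equal partition
  of the TF list across worker processes and collected into a single
  genes × TFs decision-score matrix `DS`.

The method ranks candidate regulations; it does not attempt to determine
whether regulation is activating or repressive, and it can only be applied
to TFs that already have at least a couple of known targets.

## Kernels

**Expression / methylation (RBF).** Feature matrices are compared per gene
with the Gaussian radial basis function
$K_{ij} = \exp(-\gamma \lVert x_i - x_j \rVert^2)$. The bandwidth default is
the median heuristic $\gamma = 1/(2m^2)$, with $m$ the median pairwise
Euclidean distance computed over a deterministic, seeded subsample of at
most 1,000 genes. The heuristic is scale-free and reproducible; it fails
loudly (asking for an explicit $\gamma$) on degenerate inputs where the
median distance is zero.

**PPI (diffusion).** The interaction graph enters through the diffusion
kernel $K = e^{\beta H}$ with $H = A - D$, the negative graph Laplacian
built from the weighted adjacency matrix $A$ and diagonal degree matrix
$D$. The exponential is computed exactly by symmetric eigendecomposition —
not by series truncation — which simultaneously guarantees symmetry and
positive semi-definiteness. Because $H$ has zero row sums, every row of $K$
sums to one: each gene's unit of similarity mass is redistributed along
paths of the interaction network, with $\beta$ (default 1) controlling how
far it spreads. Genes absent from the interaction file are treated as
isolated nodes of the graph rather than dropped from the universe: absence
of interaction evidence is not evidence the gene does not exist, and an
isolated node simply contributes an identity row.

**Normalization and fusion.** Before fusion every kernel is cosine
(unit-diagonal) normalized, $K'_{ij} = K_{ij}/\sqrt{K_{ii}K_{jj}}$, so that
no data type dominates the sum purely through its scale; the raw unweighted
sum is available by disabling normalization. Default fusion weights are
uniform ($\mu_i = 1$). An optional alternating p-norm weight learner
(`learn_kernel_weights()`) trains the SVM at fixed weights and then applies
the closed-form update
$\mu_m \propto (\lVert w_m \rVert^2)^{1/(p+1)}$,
$\lVert w_m \rVert^2 = \mu_m^2 (\alpha \circ y)^\top k_m (\alpha \circ y)$,
renormalized to $\lVert \mu \rVert_p = 1$, until the dual objective
stabilizes. It is off by default: fixed uniform weights are the method's
canonical fusion rule, and the learner is provided as an extension for
weighing the contribution of individual data types.

## The per-TF classifier

Each TF's model is a 1-norm soft-margin SVM solved in the dual:

$$\max_\alpha \sum_i \alpha_i - \tfrac12 \sum_{i,j} \alpha_i \alpha_j y_i y_j K_{ij}
\quad \text{s.t.} \quad 0 \le \alpha_i \le C_i, \;\; \textstyle\sum_i \alpha_i y_i = 0.$$

The solver is a sequential minimal optimization (SMO) routine (in C++ via
Rcpp) with second-order working-set selection; it terminates when the
maximal Karush–Kuhn–Tucker violation falls below `epsilon` (default 1e-5).
The contract is the KKT system, not the algorithm: `kkt_residuals()`
exposes box, equality and stationarity residuals for any trained model, and
the test suite cross-checks solutions against an independent interior-point
QP solver.

Two numerical choices matter in practice:

* **Class rebalancing (default on).** Known targets are rare — tens of
  positives against a genome of negatives — so the soft-margin penalty is
  split per class, $C_+ = C \cdot n_-/n_+$, $C_- = C$. Without this the
  trivial all-negative solution dominates at genome scale. A flag restores
  the plain single-penalty formulation.
* **Bias.** Computed as the mean of $y_i - f^0_i$ over free support vectors
  ($0 < \alpha_i < C_i$); when none exist the midpoint of the KKT-feasible
  interval is used.

Labelling follows the accepted supervised-GRN convention: every gene not
listed as a target of the TF is a training negative, knowingly accepting
some false negatives among them. The decision scores tolerate this because
only the *ranking* of candidate genes is consumed downstream.

## Out-of-fold scoring and parallel execution

A single seeded cross-validation plan (default 10 folds, sizes differing by
at most one) is shared by all TFs of a run. For each TF and each fold, a
model trained on the genes outside the fold scores the genes inside it, so
every gene receives exactly one score from a model that never saw its
label, and the full `DS` matrix remains comparable across columns. Known
positives are scored out-of-fold like everything else; the regulation
matrix's `known_mask` lets evaluation exclude them afterwards.

Degenerate cases are handled explicitly rather than silently: TFs with
fewer than `min_pos` positives (default 2) or positives confined to one
fold are skipped (flagged `NA` column) or, under the `all-data` policy,
scored in-sample by one model trained on everything; a fold whose training
split turns single-class borrows the nearest preceding valid fold's model
and logs the event.

Parallelism is deliberately boring: the canonical TF order is cut into at
most `n_workers` contiguous chunks with sizes differing by at most one,
workers are stateless forks that share only the result store, results are
collected keyed by TF id, and no random number is drawn inside a worker.
Consequently the decision-score matrix is *identical* — not merely close —
for any worker count, which the tests assert at 1e-10. Measured speedup,
efficiency $E = S/j$, redundancy $R = O_j/O_1$ and quality $Q = SE/R$ are
computed from recorded wall times and operation counts (number of SVM
trainings × training-set size², a proxy for the dominant kernel-arithmetic
cost); they describe the machine the run executed on and are therefore
reported, never asserted.

## The synthetic genome

Real benchmark compendia (DREAM-style expression + gold standards, STRING
interactions) are external downloads, so the package carries a seeded
generator that reproduces their *structure*: each TF has a latent activity
vector (standard normal over samples) and a uniform draw of target genes;
target expression is the weighted sum of its regulators' activities plus
Gaussian noise, with effect magnitudes uniform in [0.5, 1.5] and balanced
signs (the classifier is sign-agnostic, so balanced activation/repression
is the harder, honest case); non-targets are unit-variance noise. The PPI
graph links co-regulated pairs with probability `p_in = 0.3` and background
pairs with `p_out = 0.01`; the optional methylation channel is
$-0.5 \times$ expression plus unit noise for targets. A fraction
`frac_known = 0.6` of true edges (rounded per TF) is revealed as training
labels; the rest are hidden and serve as evaluation truth.

The default dimensions — 300 genes × 100 samples, 10 TFs × 20 targets,
noise SD 0.5, seed 7 — are the package's reference study conditions: small
enough that a full recovery experiment (generation, two kernels, fusion,
10-fold out-of-fold inference for all TFs, hidden-edge evaluation) runs in
seconds on one CPU, large enough that the class imbalance (≈ 4% positives
per TF) resembles the real problem.

What the generator does *not* emulate: transcriptional kinetics and
steady-state dynamics, realistic methylation beta-value distributions,
hub-dominated degree distributions, batch effects, or measurement dropout.
Passing recovery tests therefore demonstrate the pipeline's correctness and
its ability to exploit planted multi-modal signal — not performance on any
real genome.

One property of the construction deserves a caveat: because non-targets
have unit variance while targets carry signal *plus* noise, raising
`noise_sd` above 1 makes targets increasingly separable by variance alone.
Recovery is therefore only expected to improve monotonically with falling
noise within the `noise_sd <= 1` regime, and the monotonicity test operates
there.

## Evaluation

Per TF: precision, recall and F1 at a stated threshold (default 0, the SVM
decision boundary — the package prints the threshold because reported
metrics are meaningless without it), AUC as the tie-aware Mann–Whitney
statistic, and AUPR by rectangular integration over descending unique
thresholds (the conservative convention for PR curves; stated explicitly
because the trapezoidal variant differs). Report averages are unweighted
means over evaluable TFs. Two edge conventions: precision with no positive
predictions is reported as 1 with a `vacuous` flag (F1 still collapses to 0
through recall), and columns without both classes present are excluded and
counted rather than silently dropped.

## Interfaces and reproducibility

All on-disk formats are plain text: genes × samples TSV/CSV with gene ids
in the first column, 3-column gold-standard edge lists (`TF target 1`),
2/3-column PPI edge lists, ranked network TSVs and a JSON run manifest
(config snapshot, input digests, seed, per-TF timings, operation counts).
Gene identifier matching is exact-string and case-sensitive, and the
canonical gene order after universe intersection is lexicographic under C
collation — reproducibility must not depend on input file order or locale.
Missing expression values reject the row by default (with a warning); mean
imputation is available behind a flag. The `grnfuse` script under
`inst/exec/` exposes `simulate`, `infer`, `evaluate` and `perf` subcommands
over a single YAML configuration, with every error surfacing as a nonzero
exit status.

## Known limitations

* Only TFs with known targets can be scored; few-target TFs are skipped or
  scored in-sample, flagged either way.
* Scores carry no sign: an edge may be activation or repression.
* The kernel is dense: memory is quadratic in genes, which is comfortable
  to ~20k genes but rules out much larger universes without blocking.
* Training treats all unlisted genes as negatives; alternative
  negative-sampling schemes are a hook, not implemented.
* The p-norm weight learner is a heuristic alternation, not the exact
  semidefinite-programming MKL optimum.
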