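---
title: "Disease semantic similarity with an information-content contribution factor: models, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease semantic similarity with an information-content contribution factor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idssim)
```

## The problem

LncRNAs with similar functions tend to be associated with similar
diseases. Given a binary lncRNA–disease association matrix and a disease
vocabulary organised as a tree-numbered hierarchy (MeSH-style prefix
codes such as `C04.588.322`, where truncation at a dot yields the parent
node), this package quantifies lncRNA–lncRNA functional similarity and
uses it, together with disease–disease semantic similarity, to score
unobserved lncRNA–disease pairs.

The pipeline has four stages, each exposed as its own function family
and tied together by the `idssim()` fitting call:

1. **Vocabulary and DAGs.** Each disease $A$ induces a DAG
   $DAG_A = \{T_A, E_A\}$: the set $T_A$ of its ancestor terms
   (including itself) obtained by dot-truncating its tree numbers, with
   an edge for each adjacent pair of owned prefixes.
2. **Disease semantic similarity (DSS).** Per-term semantic values on
   the DAG, summed and compared between diseases.
3. **LncRNA functional similarity (FS).** Best-match aggregation of DSS
   over the two lncRNAs' disease groups.
4. **Prediction and evaluation.** WKNKN matrix pre-completion, repeated
   five-fold cross-validation with threshold-swept ROC/AUC, and
   extraction of the significant potential-association network.

## Semantic value models

All three models assign each term $t \in T_A$ a contribution
$SV_A(t)$ and set $SV(A) = \sum_{t \in T_A} SV_A(t)$.

**Plain decay** (`lncsim1`). $SV_A(A) = 1$ and, for $t \ne A$,
$SV_A(t) = \max\{\Delta \cdot SV_A(t') : t' \in C(t)\}$, where $C(t)$
are the children of $t$ *within* $DAG_A$ and $\Delta \in (0,1]$ is the
semantic contribution factor (default 0.5, the conventional choice).
Every term at a given layer decays identically, so two terms at the same
depth are indistinguishable no matter how specific they are.

**Information content** (`lncsim2`).
$SV_A(t) = -\log(Dags(t)/D)$, where $D$ is the number of diseases in
the vocabulary and $Dags(t)$ counts the disease DAGs containing $t$.
This captures specificity but ignores the hierarchy inside the DAG.

**Decay with IC contribution factor** (`idssim`, the default).
$SV_A(A) = 1$ and, for $t \ne A$,
$$SV_A(t) = \max\{(\Delta + P_t)\cdot SV_A(t') : t' \in C(t)\},
\qquad P_t = \frac{\max_k Dags(k) - Dags(t)}{D}.$$
$P_t \in [0, 1)$ is a rarity bonus: the most ubiquitous term gets 0,
rare terms approach 1. Two terms at the same layer now decay
differently, with the more specific one retaining more contribution.

The pairwise similarity is the shared-term contribution ratio
$$DSS(A,B) = \frac{\sum_{t \in T_A \cap T_B}\bigl(SV_A(t)+SV_B(t)\bigr)}
{SV(A)+SV(B)} \in [0,1].$$

```{r toy}
v0 <- mesh_vocab(list(R = "C01", X = "C01.100",
                      A = "C01.100.500", B = "C01.200"))
cnt <- corpus_counts(v0)
pa <- sv_idssim(build_dag(v0, "A"), cnt)
pb <- sv_idssim(build_dag(v0, "B"), cnt)
c(SV_A = pa$total, SV_B = pb$total, DSS_AB = dss(pa, pb))
```

### Numerical and structural choices

* $C(t)$ means children restricted to $E_A$, not all vocabulary
  children: that is the only reading under which the recursion is
  well-founded (children are strictly closer to $A$), and evaluation is
  a memoised recursion from $A$ outward. A cycle — possible only with
  pathological vocabularies in which one term owns interleaved prefix
  levels — raises a structural error.
* $P_t$ is indexed by the node being scored. The alternative reading,
  taking the child's factor, is available as `p_on_child = TRUE` but is
  not the default: the subscript on $P$ matches the scored node.
* $\Delta + P_t$ may exceed 1, so contributions can grow along a path;
  no clipping is applied. The DSS normalisation keeps scores in
  $[0,1]$ regardless, because the numerator sums over a subset of the
  denominator's summands.
* Diseases with several tree numbers get one DAG: the union of the
  prefix closures. A prefix with no owning term is skipped and the
  chain continues, since real vocabulary subsets are incomplete.
* The IC logarithm base defaults to $e$ and is configurable; the model
  definitions leave it open and DSS ratios are insensitive to it only
  within a model, not across models.
* Corpus counts default to the loaded vocabulary (so $D$ and $Dags$
  reflect whatever subset the user restricted to, e.g. via
  `tree_number_prefixes = "C"`); an explicit `corpus_counts` object can
  be supplied to score against a larger reference corpus.

## Functional similarity

With $DG(u)$ the disease group of lncRNA $u$ (the columns with a 1 in
its row), the best-match similarity of one disease into the other group
is $S(d, DG) = \max_{d' \in DG} DSS(d, d')$, and
$$FS(u,v) = \frac{\sum_{d \in DG(u)} S(d, DG(v)) +
\sum_{d \in DG(v)} S(d, DG(u))}{|DG(u)| + |DG(v)|}.$$

An lncRNA left with an empty disease group — routine after
cross-validation masking — receives 0 off-diagonal and 1 on the
diagonal instead of an error, reported via a single message, so the
evaluation loop never aborts. The explicit `qc_associations()` step
mirrors database curation (diseases without vocabulary matches dropped,
then lncRNAs without associations) and always reports what it removed.

## WKNKN prediction

WKNKN replaces unknown entries with similarity-weighted averages over
each side's $k$ nearest *known* neighbors (rows/columns with at least
one association, the query excluded), with geometric rank decay
$\eta^{i-1}$, the two side-estimates averaged and combined with the
input by entrywise max — so known positives are always preserved and
scores stay in $[0,1]$. Defaults $k = 5$, $\eta = 0.9$ follow the
method's original description; neighbor ties are broken by input index
order for reproducibility, and a query with no positive-similarity
neighbors receives 0 from that side.

## Evaluation protocol

All cells — positives and negatives — are partitioned uniformly into
five folds (sizes differ by at most one). Masking a fold turns its 1s
into 0s; the predictor then scores the masked matrix, and the fold's
ROC is computed *within the fold only*, positives being the cells that
were 1 in the original matrix. The threshold sweeps the fold's
predicted scores in descending order with a strict “greater than” rule,
so tied scores change state together and an all-tied fold contributes
the chance diagonal.

Fold curves are interpolated onto a fixed 1001-point FPR grid and
averaged pointwise over folds and repeats (default 10 repeats; repeat
$r$ is seeded `base_seed + r`); the AUC is the trapezoidal integral of
the averaged curve. Grid interpolation is one standard realisation of
“average the TPR/FPR values”; at the problem sizes used here the AUC is
insensitive to the alternative (rank-indexed averaging). Degenerate
folds with no positives or no negatives are excluded with a warning.
The population standard deviation (divisor $n$) is used in the
significant-network threshold $m(LDA) + 2\,sd(LDA)$, where $LDA$ are
the predicted scores of the cells with no known association; edges must
exceed the threshold strictly, so an all-tied score field yields an
empty network.

By default the FS matrix is recomputed from the *masked* matrix inside
each fold (`fs_from_masked = TRUE`): deriving FS from the full matrix
would leak the held-out associations into the similarity. Both options
exist because published evaluations of this family of models are
ambiguous on the point; the leakage-free choice is the default. DSS
does not depend on the association matrix and is computed once.

## The synthetic study fixture

`synth_vocab()` grows a random prefix-coded forest (defaults: 200
terms, 4 roots, depth 5, mean branching 3) and `synth_assoc()` plants
co-association blocks (defaults: 40 lncRNAs × 30 diseases, 4 blocks,
within-block density 0.6 against a 0.02 background). Block diseases are
drawn preferentially from DAG *sibling families* (terms sharing a
parent prefix), so semantic similarity genuinely carries information
about co-association — without that alignment no similarity-based
method could beat a popularity baseline on the fixture. All randomness
flows from explicit seeds; nothing touches the global RNG state.

What the generator emulates: the bipartite sparsity, the clustering of
associations around related diseases, and the prefix-coded hierarchy.
What it does not: literature-curation biases, research-heat effects
(heavily studied diseases accumulate associations), synonymous disease
names, and the depth/shape statistics of the real MeSH disease
category. Passing tests on the fixture therefore demonstrate
correctness of the computations and sensible calibration of the
protocol, not performance on curated databases.

Two controls bracket the pipeline on this fixture:

* `null_predictor(seed)` emits seeded random scores; the protocol must
  report AUC ≈ 0.5. This validates the fold bookkeeping and averaging.
* `shuffled_predictor(seed)` runs WKNKN on label-shuffled copies of
  *both* similarity matrices. Shuffling only the disease side would
  leave the unit diagonal aligned with identity, so exact-disease
  overlap between lncRNAs would still produce informative FS values;
  shuffling both sides removes exactly the similarity-derived
  information while preserving matrix structure such as disease
  popularity. The margin of the real pipeline over this control
  measures what the semantic similarity itself contributes.

Typical problem sizes in the test suite were chosen to exercise every
code path at desk scale: oracle comparisons use vocabularies of up to
30 terms (200 of them), the planted fixture runs the full 10-repeat
protocol, and the whole suite completes in a few minutes on one core.

## Known limitations

* Vocabulary parsing covers the descriptor ASCII dialect and a portable
  TSV; MeSH XML releases, qualifiers, supplementary concepts and entry
  terms (synonym resolution) are out of scope — irregular disease names
  must be resolved before QC.
* Reproducing published AUCs on curated lncRNA–disease snapshots
  requires those database snapshots and the corresponding MeSH release;
  with them, a user should see (for example) the Pancreatic Neoplasms
  DAG with 8 terms over 4 layers under the 2019 vocabulary, and AUCs of
  the same order as published — version drift across MeSH releases is
  expected, since $P_t$ changes with the corpus.
* The three semantic models score nearly identically on the synthetic
  fixture: the planted-block design rewards any faithful similarity,
  not the IC refinement specifically. Distinguishing the models
  empirically requires real curated data.
* WKNKN is the only predictor shipped; matrix-factorisation refinements
  and other association predictors are out of scope.
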