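# idssim

LncRNA functional similarity from an improved disease semantic
similarity, with association prediction and a full evaluation protocol.

## What it does and for whom

For researchers prioritising candidate lncRNA–disease associations: the
package takes a binary lncRNA–disease association matrix and a disease
vocabulary organised as a tree-numbered hierarchy (the MeSH disease
category, or any prefix-coded subset of it) and computes

* **disease semantic similarity (DSS)** on each disease's ancestor DAG,
  under three selectable per-term contribution models;
* **lncRNA functional similarity (FS)** by best-match aggregation of
  DSS over the two lncRNAs' disease groups;
* **predicted association scores** via WKNKN (weighted k nearest known
  neighbors) matrix pre-completion;
* **evaluation**: repeated five-fold cross-validation with
  threshold-swept ROC/AUC, a significant potential-association network
  (threshold `m + 2·sd` over the scores of unobserved pairs), and
  per-disease candidate rankings.

The default semantic model augments the classical per-edge decay Δ with
an information-content contribution factor

    P_t = (max_k Dags(k) − Dags(t)) / D

(`D` diseases in the vocabulary, `Dags(t)` the number of disease DAGs
containing term `t`), so the recursion

    SV_A(A) = 1,   SV_A(t) = max{ (Δ + P_t) · SV_A(t′) : t′ ∈ C(t) }

lets a rare, specific term retain more contribution than a ubiquitous
term at the same DAG layer. Pairwise similarity is the shared-term
ratio `DSS(A,B) = Σ_{t∈T_A∩T_B}(SV_A(t)+SV_B(t)) / (SV(A)+SV(B))`, and

    FS(u,v) = (Σ_{d∈DG(u)} max_{d′∈DG(v)} DSS(d,d′) +
               Σ_{d∈DG(v)} max_{d′∈DG(u)} DSS(d,d′))
              / (|DG(u)| + |DG(v)|).

The plain-decay (`lncsim1`) and pure information-content (`lncsim2`)
models are included for comparison.

## Worked example

```r
library(idssim)

vocab <- synth_vocab(n_terms = 200, seed = 7)   # prefix-coded hierarchy
assoc <- synth_assoc(vocab, seed = 8)           # planted-block associations

fit <- idssim(assoc, vocab)                     # model = "idssim", delta = 0.5
fit
#> lncRNA-disease similarity fit (model: idssim)
#>   40 lncRNAs x 30 diseases, 198 known associations
#>   significant potential network: 72 edge(s) above 0.4728

predict(fit, disease = colnames(assoc)[1], k = 5)
#>   rank  lncrna     score
#> 1    1 lnc_003 0.6603376
#> 2    2 lnc_008 0.6256913
#> 3    3 lnc_006 0.6114451
#> 4    4 lnc_002 0.5581445
#> 5    5 lnc_005 0.4362835

cross_validate(assoc, vocab, repeats = 10, base_seed = 7)
#> Cross-validation (10 x 5-fold, model idssim): AUC = 0.8245 over 50 fold curves
```

The fit holds the DSS, FS and prediction matrices (`fit$dss`, `fit$fs`,
`fit$pred`) and the significant network (`fit$network`). The ranking
lists the 5 highest-scoring lncRNAs with no known association to that
disease — the candidates one would screen first. The cross-validated
AUC of 0.82 says that a masked true association outranks a random
non-association about 82% of the time on this synthetic fixture; a
seeded random predictor scores 0.5 under the same protocol
(`predictor = null_predictor(seed)`).

Real data enter through `parse_mesh_ascii()` / `parse_vocab_tsv()` and
`read_assoc()`; `qc_associations()` reports which diseases and lncRNAs
survive name matching against the vocabulary.

A command-line interface wraps the same functions
(`exec/idssim`, subcommands `vocab`, `dss`, `fs`, `predict`,
`evaluate`, `network`, `rank`, `simulate`), writing labelled CSV/TSV
matrices with provenance headers.

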