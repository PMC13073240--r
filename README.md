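# sclocate

Supervised inference of the anatomical compartment an immune cell came from,
using only its single-cell RNA-seq transcriptome.

Long-resident tissue immune cells (e.g. kidney-resident macrophages) absorb
transcriptional cues from their microenvironment and thereby carry a
*positional fingerprint*. `sclocate` learns that fingerprint: it selects
highly variable genes (HVGs) per training dataset by dispersion binning,
merges them across datasets by union, trains an attention-gated multilayer
perceptron to classify cells into compartments (e.g. cortex / outer medulla
OM / inner medulla IM), and validates on external datasets with accuracy and
per-compartment one-vs-rest ROC/AUC. Around that core it provides the
comparison feature selectors (one-vs-rest Wilcoxon markers, recursive
feature elimination, mutual-information ranking, random control), a
seven-model baseline suite, repeated stratified holdout validation,
mouse–human signature harmonization through a homology table,
compartment-resolved downstream analytics (cell-count kinetics, gene-set
module scores, compartment-wise differential expression), and a
negative-binomial simulator of compartment-labeled counts so the entire
pipeline is testable offline.

## Model sketch

For cell *c* with log-normalized, per-gene standardized expression
*x<sub>c</sub>* over the signature genes, the classifier computes

    g = sigmoid(W_g x_c + b_g)          # learned per-gene attention gate
    h = MLP(x_c ⊙ g)                    # ReLU trunk, hidden sizes 128, 64
    p(compartment k | x_c) = softmax(h)_k

trained with cross-entropy, Adam (lr 1e-3), dropout 0.2, early stopping on a
stratified 10% split. HVGs are ranked by the dispersion (var/mean of
log-normalized expression) z-scored within 20 equal-frequency mean bins —
the classical mean/variability-plot selector. One-vs-rest AUC is the
Mann–Whitney statistic with ties counted ½; internal validation reports
median ± SEM over repeated stratified 80/20 holdouts.

## Worked example

Simulate two independent batches of compartment-labeled cells, select HVGs
on one, train, and validate on the other:

```r
library(sclocate)

sim <- simulate_positional(sim_config(seed = 7))      # 2 datasets, 3 compartments
lnA <- log_normalize(qc_filter(sim$datasets$ds1$matrix)$matrix)
lnB <- log_normalize(qc_filter(sim$datasets$ds2$matrix)$matrix)
annA <- align_annotation(sim$datasets$ds1$annotation, lnA)
annB <- align_annotation(sim$datasets$ds2$annotation, lnB)

hv    <- hvg_rank(lnA, n_top = 100)                   # dispersion-binned HVGs
model <- train_position_model(lnA, annA, hv$geneset,
                              training_config(seed = 7))
evaluate(predict(model, lnB), annB)
```

```
EvaluationReport: accuracy 0.9987 over 1500 cells
per-class AUC: cortex=1.000, OM=1.000, IM=1.000
```

The held-out batch is classified almost perfectly because the simulator
plants 30 signature genes per compartment at a natural-log effect of 1.5;
`hv$geneset` recovers ~94% of them. Accuracy is the fraction of external
cells assigned to their true compartment; each AUC treats one compartment
as positive, scored by its predicted probability.

The same workflow runs from a config file:

```r
run_pipeline(system.file("extdata", "quickstart.yaml", package = "sclocate"),
             out_dir = "quickstart_out")
```

which writes the gene set (GMT), the model archive, evaluation JSON,
confusion matrices, compartment-fraction tables and a manifest of content
hashes (reruns reproduce every hash). A thin CLI wrapper with subcommands
(`simulate`, `select`, `train`, `predict`, `evaluate`, `benchmark`,
`map-homologs`, `apply`, `run`) lives at `inst/cli/sclocate.R`.

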