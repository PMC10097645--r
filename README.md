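# panelselect

Differentiable gene-panel selection for targeted spatial transcriptomics.

FISH-based spatial methods (MERFISH, seqFISH and relatives) measure a
pre-defined panel of tens to a few hundred genes in intact tissue, so the
panel has to be chosen before the experiment — usually from a reference
scRNA-seq atlas of the same tissue. `panelselect` chooses that panel by
training a neural network to reconstruct the genome-wide expression
profile from a small, learned subset of binarized genes, and keeps the
subset that loses the least information. It is aimed at computational
biologists designing probe panels and at methodologists who want a
self-contained, fully tested R implementation of the underlying
machinery: stochastic relaxation layers for discrete feature selection, a
dropout-aware reconstruction loss, and the matching evaluation protocol.

## The model

**Inputs and targets.** The model input is binarized expression
(`count > 0`), which is robust to the scRNA-seq→FISH domain shift; the
reconstruction target is the CPM-`log1p` profile. Supervised variants
replace the target with cell-type labels (multiclass cross-entropy) or
continuous per-cell properties (mean squared error).

**Hurdle loss.** scRNA-seq zeros mix true silence with dropout, so
reconstruction error is scored by a two-part (hurdle) loss. For gene *i*
the predictor emits a point prediction ŷᵢ and a detection probability
p̂ᵢ, and

&nbsp;&nbsp;ℓ_γ⁽ⁱ⁾(p̂ᵢ, ŷᵢ, yᵢ) = (ŷᵢ − yᵢ)²/γ − log p̂ᵢ if yᵢ > 0, and
−log(1 − p̂ᵢ) if yᵢ = 0,

summed over genes and averaged over cells, with γ = 10 balancing the two
components.

**Selection layers.** Exactly *k* genes are selected by a *binary mask
layer*: *k* Concrete (Gumbel-Softmax) distributions Aᵢ ~ Concrete(αᵢ, τ)
over the *d* candidates, combined by an element-wise maximum and
multiplied into the input, with the temperature τ annealed geometrically
from 10.0 to 0.01 during training so the mask becomes effectively
discrete. Large candidate pools are first narrowed to roughly 500 genes
by a *binary gates layer* — one Binary-Concrete gate Bᵢ ~ BinConcrete(βᵢ, τ)
per gene with an L0-style penalty λ·1ᵀb whose coefficient is tuned
automatically by a secant search on the surviving-gene count. After
training, the mask panel is the argmax of each αᵢ and the gates keep
genes with βᵢ/(1+βᵢ) > ½. Optimisation uses Adam (10⁻³), minibatches of
128 cells, early stopping on validation loss, and 5 independent trials
with the best-validation panel reported.

**Evaluation.** Panels are scored by retraining downstream models:
explained variance of the CPM-log profile (1 − ΣMSE/ΣVar on held-out
cells), expressed-gene prediction accuracy for genes detected in 20–80%
of cells (probability > 0.5 rule), and cell-type accuracy of a
gradient-boosted tree classifier. Panel overlap statistics include the
exact hypergeometric probability that two random panels overlap by
chance — about 4.6×10⁻³ for two 32-gene panels from 10,000 candidates.

**Cross-technology binarization.** To apply a model trained on scRNA-seq
to FISH counts, per-gene thresholds are matched by quantile: the zero
fraction of each gene in the reference becomes the quantile of the
matched threshold in the target technology, which undoes any monotone
per-gene distortion.

A built-in synthetic generator (zero-inflated negative-binomial counts,
cell-type structure determined by a few planted genes, paired pseudo-FISH
matrix with a monotone per-gene shift) provides ground truth for every
test in the package.

## Worked example

```r
library(panelselect)

# simulate a reference scRNA-seq dataset: 600 cells, 30 genes, 3 cell
# types, 4 planted genes that determine every other gene's expression
sim  <- generate_scrnaseq(synthetic_config(seed = 1))
data <- prepare_dataset(sim$em, labels = paste0("T", sim$truth$cell_types),
                        seed = 1)

# select a 4-gene panel (5 trials, best validation loss wins)
cfg   <- train_config(max_epochs = 400, patience = 400,
                      hidden = c(64, 64), seed = 1)
panel <- select_panel(data, k = 4, trials = 5, cfg = cfg)
print(panel)
#> <panel_result> 4 genes (reconstruction mode), trial 1 of 5, val loss 16.6289
#> genes: gene002, gene004, gene003, gene001

generics::glance(panel)
#> # A tibble: 1 × 7
#>       k mode           trials chosen_trial best_val_loss median_val_loss  seed
#>   <int> <chr>           <int>        <int>         <dbl>           <dbl> <int>
#> 1     4 reconstruction      5            1          16.6            17.3     1
```

The selected panel is exactly the four planted genes. Scoring it:

```r
report <- evaluate_panel(data, panel,
                         cfg = train_config(max_epochs = 200, patience = 50,
                                            hidden = c(32, 32), seed = 1))
print(report)
#> <eval_report>
#>   explained variance:       0.2296
#>   expressed-gene accuracy:  0.8079
#>   cell-type accuracy:       0.9833
#>   panel: gene002, gene004, gene003, gene001
```

Four binarized genes explain 23% of the held-out expression variance
(the generator's noise bounds this well below 1), predict
detection of the mid-frequency genes at 81% accuracy, and let a GBDT
recover the cell type at 98% accuracy. Applying the same trained
detector to the paired pseudo-FISH matrix shows what quantile threshold
matching buys over naive zero-thresholding:

```r
fish <- generate_paired_fish(sim$em, synthetic_config(seed = 1))
evaluate_transfer(sim$em, fish, panel$genes,
                  cfg = train_config(max_epochs = 100, patience = 30,
                                     hidden = c(32, 32), seed = 1))
#> # A tibble: 1 × 4
#>   matched_accuracy raw_zero_accuracy reference_accuracy n_target_genes
#>              <dbl>             <dbl>              <dbl>          <int>
#> 1            0.795             0.681              0.797             18
```

Matched thresholds recover essentially the reference accuracy (0.795 vs
0.797); a raw zero threshold on the shifted FISH counts loses 11 points.
(During selection you may see warnings about Concrete slots collapsing
onto duplicate genes; the panel is then completed deterministically to
exactly *k* genes, as documented in `extract_mask_panel()`.)

A command-line interface wraps the same functions:

```sh
Rscript inst/scripts/panelselect simulate --n-cells 600 --n-genes 30 --seed 1 --out-dir data/
Rscript inst/scripts/panelselect select --input data/scrna.csv --panel-size 4 --seed 1 --out-dir run/
Rscript inst/scripts/panelselect evaluate --input data/scrna.csv --panel run/panel.tsv --out-dir run/
```

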