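# epitensor

Multi-scale deep tensor factorization for imputing epigenomic signal
tracks.

Epigenomic compendia are organized as a matrix of biosamples (cell lines,
primary cells, tissues) by assays (DNase-seq, histone-modification and
transcription-factor ChIP-seq, transcription), where each filled cell is a
genome-wide signal track. Most cells are empty — real compendia are ~88–99%
missing — because experiments are expensive. `epitensor` predicts the
missing tracks, for computational biologists who want a compendium-scale
imputation engine whose every component (model, training, extension
protocols, evaluation) is small enough to run, test, and understand on one
CPU.

## The model

The signal value of biosample $b$, assay $a$ at genomic bin $g$ (25 bp
bins, arcsinh-transformed) is modeled as

$$\hat y_{bag} = f\big(\,[\,\mathbf{u}_b;\ \mathbf{v}_a;\ \mathbf{w}^{25}_g;\
\mathbf{w}^{250}_{\lfloor g/10\rfloor};\ \mathbf{w}^{5k}_{\lfloor
g/200\rfloor}\,]\,\big)$$

where $\mathbf{u}_b$, $\mathbf{v}_a$ are biosample and assay latent
factors, the three $\mathbf{w}$ matrices are genomic factors at 25 bp,
250 bp, and 5 kbp resolution (adjacent bins share the coarser rows), and
$f$ is a two-hidden-layer ReLU network with a linear regression head,
trained with Adam on squared error. Training is two-stage: all parameters
jointly on a training-region subset of the genome, then the genomic factors
alone, chromosome by chromosome, with everything else frozen.

Around the model the package provides:

* **Extension protocols** for adding biosamples/assays to a trained model:
  the three-step freeze-and-fit (`add_axis_element()`, bit-identical to the
  original model everywhere else), `freeze_extend()`, `fine_tune()`, and
  `retrain_from_scratch()`.
* **Evaluation**: six MSE metrics (`mseGlobal`, top-1% `mse1obs`/`mse1imp`,
  promoter/gene-body/enhancer restrictions), the average-activity baseline,
  paired t tests, 200 bp/50 bp window aggregation with ambiguous-label
  filtering, average precision and the precision–recall break-even point,
  and a greedy counter-based cross-validation fold partitioner.
* **A seeded synthetic-compendium generator** with known latent structure,
  configurable missingness, biosample specificity, and novel-activity
  assays, so everything above is testable offline.
* **I/O**: bedGraph tracks, BED annotations, chrom-sizes grids, experiment
  manifests with replicate selection, and a thin command-line dispatcher
  (`inst/cli/epitensor.R`) with `simulate`, `train`, `impute`, `evaluate`,
  `partition-folds`, `add-biosample`, `add-assay`, and `extend`
  subcommands.

## Worked example

Simulate a compendium, train a model, and compare held-out imputations
against the average-activity baseline:

```r
library(epitensor)

study <- run_imputation_study(
  synthetic_spec(n_biosamples = 16, mixing = 0.7, seed = 61),  # 16 x 12 x 4000 bins
  stage1_epochs = 800, stage2_epochs = 400, seed = 62)

tidy(study$report)
#> # A tibble: 6 x 6
#>   metric     model baseline   p_value assays_model_wins n_assays
#>   <chr>      <dbl>    <dbl>     <dbl>             <int>    <int>
#> 1 mseGlobal 0.0478   0.109  0.000110                 10       12
#> 2 mse1obs   0.101    0.139  0.0554                    7       12
#> 3 mse1imp   0.0639   0.105  0.0454                   11       12
#> 4 mseProm   0.0611   0.0943 0.00312                  11       12
#> 5 mseGene   0.0511   0.111  0.0000887                10       12
#> 6 mseEnh    0.0577   0.116  0.000157                 10       12
```

Each row is one metric averaged over the 67 held-out tracks of a fivefold
cross-validation: `model` is the trained model's error, `baseline` the
average-activity predictor's, `p_value` a per-track paired t test, and the
final columns count the assays (of 12) where the model's assay-mean error
beats the baseline's. The model roughly halves the baseline's global error
(0.048 vs 0.109) and wins the per-assay comparison on 10 of 12 assays — the
signature of genuinely biosample-specific imputation, since the baseline
already captures everything that is shared across biosamples.

Impute and write one missing track:

```r
model <- local({
  comp <- study$compendium
  fit <- train_full(
    init_model(comp$tensor$biosamples, comp$tensor$assays, comp$grid,
               desk_config(), seed = 1),
    comp$tensor,
    train_config(epochs = 800, batch_size = 256, seed = 7),
    train_config(epochs = 400, batch_size = 256, seed = 8))
  fit$model
})
write_track(predict_track(model, "bio03", "assay07"),
            study$compendium$grid, "bio03_assay07_imputed.bedGraph")
```

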