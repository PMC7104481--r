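#' Cross-validated imputation study on a synthetic compendium
#'
#' Generates a compendium, partitions its experiments into folds with the
#' greedy counter, trains one two-stage model per fold on the remaining
#' folds, imputes every held-out track, and reports per-track metrics for
#' the model and the average-activity baseline.
#'
#' @param spec A [synthetic_spec()].
#' @param k Number of folds (default 5).
#' @param stage1_epochs,stage2_epochs,batch_size Desk-scale training budget
#'   (defaults 600 / 300 / 256).
#' @param seed Integer seed driving generation, folds, and training.
#' @return A list with `report` (a `metric_report` with baseline columns),
#'   `compendium`, and `folds`.
#' @export
run_imputation_study <- function(spec, k = 5, stage1_epochs = 600,
                                 stage2_epochs = 300, batch_size = 256,
                                 seed = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  comp <- generate_compendium(spec)
  folds <- greedy_fold_partition(comp$tensor$cells, k = k,
                                 seed = child_seed(seed, 1L))
  imputed <- crossval_impute(
    comp$tensor, comp$grid, folds, spec$model_cfg,
    train_config(epochs = stage1_epochs, batch_size = batch_size,
                 seed = child_seed(seed, 2L)),
    train_config(epochs = stage2_epochs, batch_size = batch_size,
                 seed = child_seed(seed, 3L)))
  report <- evaluate_compendium(comp$tensor, imputed,
                                annotations = comp$annotations,
                                grid = comp$grid, folds = folds)
  list(report = report, compendium = comp, folds = folds)
}

#' Compare protocols for incorporating additional experiments
#'
#' Reproduces, at desk scale, the comparison of three ways to extend a model
#' to additional experiments containing a novel activity type: retraining
#' from scratch on original + additional, fine-tuning a pre-trained model
#' (same total epoch budget, split 75/25), and freeze-extending (decoder and
#' genomic factors frozen, biosample/assay factors trained on the additional
#' experiments for 100 epochs). The original experiments are four of five
#' greedy folds of a synthetic core compendium; the additional experiments
#' come from [generate_sparse_additional()] and are split per assay into
#' fitting and test halves.
#'
#' @param spec Core-compendium [synthetic_spec()] (the study defaults to a
#'   12 x 14 core so the held-out original fold has enough tracks for a
#'   stable mean).
#' @param epochs Total stage-1 epoch budget per protocol (default 1000).
#' @param stage2_epochs,batch_size Stage-2 budget and batch size.
#' @param seed Integer seed.
#' @return A tibble with one row per (protocol, test set) and the MSE, where
#'   test sets are `additional`, `additional_wo_novel`, `novel_only`, and
#'   `original`.
#' @export
run_extension_study <- function(spec = synthetic_spec(n_biosamples = 12,
                                                      n_assays = 14),
                                epochs = 1000, stage2_epochs = 400,
                                batch_size = 256, seed = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  spec$seed <- child_seed(seed, 11L)
  core <- generate_compendium(spec)
  folds <- greedy_fold_partition(core$tensor$cells, k = 5,
                                 seed = child_seed(seed, 12L))
  fold_of <- dplyr::left_join(core$tensor$cells, folds,
                              by = c("biosample", "assay"))$fold
  orig_train <- subset_cells(core$tensor, fold_of != 5)
  orig_test <- subset_cells(core$tensor, fold_of == 5)
  add <- generate_sparse_additional(core, seed = child_seed(seed, 13L))
  is_train <- add$split$part == "train"
  add_train <- subset_cells(add$tensor, is_train)
  add_test <- subset_cells(add$tensor, !is_train)

  cfg <- function(e, k) train_config(epochs = e, batch_size = batch_size,
                                     seed = child_seed(seed, k))
  s2 <- cfg(stage2_epochs, 20L)
  models <- list(
    retrain = retrain_from_scratch(orig_train, add_train, core$grid,
                                   spec$model_cfg, cfg(epochs, 21L),
                                   stage2_config = s2,
                                   seed = child_seed(seed, 31L)),
    fine_tune = {
      # the two pre-trained protocols share one initialization and epoch
      # stream (the shorter pretrain is a prefix of the longer), so protocol
      # comparisons are not inflated by independent training noise
      pre <- train_full(init_model(core$tensor$biosamples,
                                   core$tensor$assays, core$grid,
                                   spec$model_cfg,
                                   seed = child_seed(seed, 32L)),
                        orig_train, cfg(round(0.75 * epochs), 22L), s2)$model
      fine_tune(pre, orig_train, add_train, cfg(round(0.25 * epochs), 23L),
                stage2_config = s2, seed = child_seed(seed, 33L))
    },
    freeze = {
      pre <- train_full(init_model(core$tensor$biosamples,
                                   core$tensor$assays, core$grid,
                                   spec$model_cfg,
                                   seed = child_seed(seed, 32L)),
                        orig_train, cfg(epochs, 22L), s2)$model
      freeze_extend(pre, add_train,
                    train_config(epochs = 100, batch_size = 512,
                                 seed = child_seed(seed, 25L)),
                    seed = child_seed(seed, 35L))
    })

  novel <- add_test$cells$assay %in% add$novel_assays
  mse_on <- function(model, tensor, keep = NULL) {
    cells <- tensor$cells
    vals <- tensor$values
    if (!is.null(keep)) {
      cells <- cells[keep, , drop = FALSE]
      vals <- vals[keep, , drop = FALSE]
    }
    mean((predict_cells(model, cells) - vals)^2)
  }
  purrr::imap_dfr(models, function(m, nm) {
    tibble::tibble(
      protocol = nm,
      test_set = c("additional", "additional_wo_novel", "novel_only",
                   "original"),
      mse = c(mse_on(m, add_test), mse_on(m, add_test, !novel),
              mse_on(m, add_test, novel), mse_on(m, orig_test)))
  })
}
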