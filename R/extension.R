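#' Add one new biosample or assay to a pre-trained model (three-step protocol)
#'
#' The three-step freeze-and-fit extension: the decoder and all five factor
#' matrices are frozen; a single new factor row is appended to the relevant
#' axis, initialized like any embedding row, and fit by Adam on squared error
#' using only the supplied fitting tracks restricted to the fit region
#' (default: the grid's training regions). Every pre-existing parameter —
#' and therefore every prediction for pre-existing cells — is bit-identical
#' afterwards.
#'
#' @param model A trained [init_model()] object.
#' @param mode `"add_biosample"` or `"add_assay"`.
#' @param new_id Identifier for the new axis element (must not exist yet).
#' @param fitting_tensor A [track_tensor()] whose observed cells all
#'   reference `new_id` on the new axis; the other axis labels must already
#'   exist on the model.
#' @param fit_epochs,fit_batch Epochs and batch size for the fit (defaults
#'   10 and 512).
#' @param fit_region Optional 0-based bin subset (default: training regions).
#' @param seed Integer seed (new-row initialization and epoch sampling).
#' @return The extended model; the fit loss log is attached as
#'   `attr(, "fit_log")` and the updated row as `attr(, "updated_rows")`.
#' @export
add_axis_element <- function(model, mode = c("add_biosample", "add_assay"),
                             new_id, fitting_tensor, fit_epochs = 10,
                             fit_batch = 512, fit_region = NULL, seed = 1) {
  stopifnot(inherits(model, "factor_model"),
            inherits(fitting_tensor, "track_tensor"))
  mode <- match.arg(mode)
  axis <- if (mode == "add_biosample") "biosample" else "assay"
  other <- if (mode == "add_biosample") "assay" else "biosample"
  if (new_id %in% model[[paste0(axis, "s")]])
    stop("identifier already on the ", axis, " axis: ", new_id)
  if (!all(fitting_tensor$cells[[axis]] == new_id))
    stop("every fitting track must reference the new ", axis)
  if (!all(fitting_tensor$cells[[other]] %in% model[[paste0(other, "s")]]))
    stop("fitting tracks reference unknown ", other, " labels")
  if (is.null(fit_region)) fit_region <- training_bins(model$grid)
  if (length(fit_region) == 0)
    stop("fit region is empty: fitting tracks have no overlap with it")

  d <- if (axis == "biosample") model$config$d_biosample else model$config$d_assay
  new_row <- withr::with_seed(child_seed(seed, 104729L), embed_init(1L, d))
  model[[paste0(axis, "s")]] <- c(model[[paste0(axis, "s")]], new_id)
  model$factors[[axis]] <- rbind(model$factors[[axis]], new_row)

  old_flags <- model$trainable
  model$trainable <- list(network = FALSE, biosample = axis == "biosample",
                          assay = axis == "assay", genome = FALSE)
  cfg <- train_config(epochs = fit_epochs, batch_size = fit_batch,
                      seed = child_seed(seed, 2L))
  fit <- fit_epochs(model, fitting_tensor, fit_region, cfg)
  model <- fit$model
  model$trainable <- old_flags
  attr(model, "fit_log") <- fit$log
  attr(model, "updated_rows") <- stats::setNames(list(new_id), axis)
  model
}

# append any axis labels present in `tensor` but absent from the model,
# initializing their factor rows like fresh embeddings (seeded)
extend_axes <- function(model, tensor, seed) {
  new_b <- setdiff(tensor$biosamples, model$biosamples)
  new_a <- setdiff(tensor$assays, model$assays)
  withr::with_seed(child_seed(seed, 15485863L), {
    if (length(new_b) > 0) {
      model$factors$biosample <- rbind(
        model$factors$biosample, embed_init(length(new_b), model$config$d_biosample))
      model$biosamples <- c(model$biosamples, new_b)
    }
    if (length(new_a) > 0) {
      model$factors$assay <- rbind(
        model$factors$assay, embed_init(length(new_a), model$config$d_assay))
      model$assays <- c(model$assays, new_a)
    }
  })
  model
}

#' Retrain a model from scratch on original plus additional experiments
#'
#' The comparator protocol for incorporating new experiments: a fresh model
#' over the pooled axes is trained with the full two-stage pipeline on the
#' union of the original and additional tensors.
#'
#' @param original,additional [track_tensor()] objects with disjoint cell
#'   sets over the same grid.
#' @param grid A [genomic_grid()] with training regions.
#' @param model_cfg A [model_config()].
#' @param config Stage-1 [train_config()].
#' @param stage2_config Optional stage-2 [train_config()] (as in
#'   [train_full()]).
#' @param seed Initialization seed.
#' @return The trained model.
#' @export
retrain_from_scratch <- function(original, additional, grid,
                                 model_cfg = desk_config(), config,
                                 stage2_config = NULL, seed = 1) {
  pooled <- pool_tensors(original, additional)
  model <- init_model(pooled$biosamples, pooled$assays, grid, model_cfg,
                      seed = seed)
  train_full(model, pooled, config, stage2_config)$model
}

#' Fine-tune a pre-trained model on original plus additional experiments
#'
#' New axis rows are initialized, then every parameter group is trained on
#' the pooled tensor: a joint pass on the training regions followed by a
#' chromosome-wise refresh of the genomic factors.
#'
#' @param model A model pre-trained on `original`.
#' @param original,additional [track_tensor()] objects with disjoint cells.
#' @param config Phase-2 [train_config()] (typically a fraction of the
#'   from-scratch epoch budget).
#' @param stage2_config Optional stage-2 [train_config()]; give the retrain
#'   comparator and the fine-tuned model the same stage-2 budget so they
#'   differ only in how the joint phase is split.
#' @param seed Seed for new-row initialization.
#' @return The fine-tuned model.
#' @export
fine_tune <- function(model, original, additional, config,
                      stage2_config = NULL, seed = 1) {
  stopifnot(inherits(model, "factor_model"))
  pooled <- pool_tensors(original, additional)
  model <- extend_axes(model, pooled, seed)
  model <- set_trainable(model, network = TRUE, biosample = TRUE,
                         assay = TRUE, genome = TRUE)
  if (config$epochs == 0) return(model)
  train_full(model, pooled, config, stage2_config)$model
}

#' Freeze-extend a pre-trained model using only additional experiments
#'
#' The frozen comparator protocol: the decoder and the genomic factors are
#' frozen, and the biosample and assay factor matrices (existing rows and
#' newly initialized rows alike) are trained on the additional experiments
#' only, for 100 epochs by default. Because the genomic factors and decoder
#' never saw the additional data, activity types absent from the original
#' training set cannot be represented well — the cost of this protocol.
#'
#' @param model A model pre-trained on the original experiments.
#' @param additional A [track_tensor()] of additional experiments.
#' @param config A [train_config()]; default 100 epochs.
#' @param region Optional 0-based bin subset for epoch sampling (default:
#'   all bins).
#' @param seed Seed for new-row initialization.
#' @return The extended model; `attr(, "updated_rows")` lists the biosample
#'   and assay labels whose rows were eligible for updates.
#' @export
freeze_extend <- function(model, additional,
                          config = train_config(epochs = 100, batch_size = 512),
                          region = NULL, seed = 1) {
  stopifnot(inherits(model, "factor_model"),
            inherits(additional, "track_tensor"))
  model <- extend_axes(model, additional, seed)
  old_flags <- model$trainable
  model$trainable <- list(network = FALSE, biosample = TRUE, assay = TRUE,
                          genome = FALSE)
  if (is.null(region)) region <- seq.int(0L, n_bins(model$grid) - 1L)
  fit <- fit_epochs(model, additional, region, config)
  model <- fit$model
  model$trainable <- old_flags
  attr(model, "fit_log") <- fit$log
  attr(model, "updated_rows") <- list(biosample = unique(additional$cells$biosample),
                                      assay = unique(additional$cells$assay))
  model
}
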