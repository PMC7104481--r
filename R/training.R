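#' Training configuration
#'
#' Full-scale defaults: Adam (step size 0.001, beta1 0.9, beta2 0.999,
#' epsilon 1e-7 — the standard toolkit defaults), 8000 epochs, batch size
#' 40,000, squared-error loss on the arcsinh scale. Desk-scale runs pass much
#' smaller `epochs` and `batch_size`.
#'
#' @param epochs Number of epochs; one epoch is one pass over the genomic
#'   axis, drawing a random observed experiment at each position.
#' @param batch_size Triples per gradient step; the final short batch of an
#'   epoch is kept.
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters.
#' @param seed Integer seed controlling epoch sampling.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 8000, batch_size = 40000,
                         learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-7, seed = 1) {
  if (epochs < 0 || batch_size <= 0) stop("epochs and batch_size must be positive")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, seed = as.integer(seed)),
            class = "train_config")
}

#' Set which parameter groups receive gradient updates
#'
#' Groups are `network` (the three decoder weight matrices and biases),
#' `biosample`, `assay`, and `genome` (all three genomic factor matrices).
#' Frozen groups are bit-identical before and after training.
#'
#' @param model A [init_model()] object.
#' @param network,biosample,assay,genome Logical flags; `NULL` leaves a flag
#'   unchanged.
#' @return The model with updated flags.
#' @export
set_trainable <- function(model, network = NULL, biosample = NULL,
                          assay = NULL, genome = NULL) {
  stopifnot(inherits(model, "factor_model"))
  for (nm in c("network", "biosample", "assay", "genome")) {
    v <- get(nm)
    if (!is.null(v)) model$trainable[[nm]] <- isTRUE(v)
  }
  model
}

#' Sample one training epoch of (biosample, assay, bin) triples
#'
#' One epoch is one pass over the genomic axis: exactly one triple per bin of
#' `region`, each paired with an observed cell drawn uniformly at random, the
#' whole sequence shuffled (bins are visited in a random permutation, i.e.
#' sampled without replacement).
#'
#' @param tensor A [track_tensor()].
#' @param region Integer vector of 0-based fine-bin indices.
#' @param seed Integer seed; identical seeds give identical sequences.
#' @return Tibble with columns `row` (cell row in the tensor), `bin`
#'   (0-based).
#' @export
sample_epoch <- function(tensor, region, seed) {
  stopifnot(inherits(tensor, "track_tensor"))
  if (length(region) == 0) stop("region is empty")
  if (nrow(tensor$cells) == 0) stop("tensor has no observed cells")
  withr::with_seed(seed, {
    bins <- sample(as.integer(region))
    rows <- sample.int(nrow(tensor$cells), length(bins), replace = TRUE)
  })
  tibble::tibble(row = rows, bin = bins)
}

# derive a bounded child seed (keeps values < 2^31)
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k) %% 2147483647)
}

# gradient of mean squared error for one batch; returns loss and per-group
# gradients. bi/ai are 1-based axis indices, bins 0-based.
batch_gradients <- function(model, bi, ai, bins, y) {
  cfg <- model$config
  rows <- bin_rows(model$grid, bins)
  X <- cbind(model$factors$biosample[bi, , drop = FALSE],
             model$factors$assay[ai, , drop = FALSE],
             model$factors$fine[rows$fine, , drop = FALSE],
             model$factors$mid[rows$mid, , drop = FALSE],
             model$factors$coarse[rows$coarse, , drop = FALSE])
  fp <- forward_pass(model$net, X)
  B <- length(y)
  resid <- fp$yhat - y
  loss <- mean(resid^2)
  d_yhat <- matrix(2 * resid / B, ncol = 1)
  g <- list()
  g$w_out <- crossprod(fp$H2, d_yhat)
  g$b_out <- sum(d_yhat)
  dZ2 <- (d_yhat %*% t(model$net$w_out)) * (fp$Z2 > 0)
  g$W2 <- crossprod(fp$H1, dZ2)
  g$b2 <- colSums(dZ2)
  dZ1 <- (dZ2 %*% t(model$net$W2)) * (fp$Z1 > 0)
  g$W1 <- crossprod(X, dZ1)
  g$b1 <- colSums(dZ1)
  dX <- dZ1 %*% t(model$net$W1)
  ends <- cumsum(c(cfg$d_biosample, cfg$d_assay, cfg$d_fine, cfg$d_mid,
                   cfg$d_coarse))
  starts <- c(1L, ends[-5] + 1L)
  idx <- list(biosample = bi, assay = ai, fine = rows$fine, mid = rows$mid,
              coarse = rows$coarse)
  for (k in seq_along(idx)) {
    nm <- names(idx)[k]
    gm <- matrix(0, nrow(model$factors[[nm]]), ncol(model$factors[[nm]]))
    acc <- rowsum(dX[, starts[k]:ends[k], drop = FALSE], group = idx[[k]])
    gm[as.integer(rownames(acc)), ] <- acc
    g[[nm]] <- gm
  }
  list(loss = loss, gradients = g)
}

adam_new <- function(params) {
  list(t = 0,
       m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_update <- function(state, params, grads, cfg) {
  state$t <- state$t + 1
  c1 <- 1 - cfg$beta1^state$t
  c2 <- 1 - cfg$beta2^state$t
  for (nm in names(params)) {
    gnm <- grads[[nm]]
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * gnm
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * gnm^2
    step <- cfg$learning_rate * (state$m[[nm]] / c1) /
      (sqrt(state$v[[nm]] / c2) + cfg$epsilon)
    params[[nm]] <- params[[nm]] - step
  }
  list(state = state, params = params)
}

trainable_param_names <- function(model) {
  nms <- character(0)
  if (model$trainable$network) nms <- c(nms, "W1", "b1", "W2", "b2", "w_out", "b_out")
  if (model$trainable$biosample) nms <- c(nms, "biosample")
  if (model$trainable$assay) nms <- c(nms, "assay")
  if (model$trainable$genome) nms <- c(nms, "fine", "mid", "coarse")
  nms
}

get_params <- function(model, nms) {
  all <- c(model$net, model$factors)
  all[nms]
}

set_params <- function(model, params) {
  for (nm in names(params)) {
    if (nm %in% names(model$net)) {
      p <- params[[nm]]
      if (nm %in% c("b1", "b2")) p <- as.vector(p)
      if (nm == "b_out") p <- as.vector(p)
      if (nm %in% c("W1", "W2", "w_out")) dim(p) <- dim(model$net[[nm]])
      model$net[[nm]] <- p
    } else {
      p <- params[[nm]]
      dim(p) <- dim(model$factors[[nm]])
      model$factors[[nm]] <- p
    }
  }
  model
}

# core mini-batch loop shared by all training entry points. A fresh Adam
# instance is created per call (optimizer state never carries across stages).
fit_epochs <- function(model, tensor, region, config, cells = NULL,
                       log_every = 1L) {
  if (config$epochs == 0)
    return(list(model = model, log = tibble::tibble(epoch = integer(0),
                                                    loss = numeric(0))))
  nms <- trainable_param_names(model)
  if (length(nms) == 0) stop("no trainable parameter groups")
  work <- if (is.null(cells)) tensor else subset_cells(tensor, cells)
  bi_all <- match(work$cells$biosample, model$biosamples)
  ai_all <- match(work$cells$assay, model$assays)
  if (anyNA(bi_all) || anyNA(ai_all))
    stop("tensor references labels not on the model's axes")
  params <- get_params(model, nms)
  opt <- adam_new(params)
  epoch_loss <- numeric(config$epochs)
  t0 <- proc.time()[["elapsed"]]
  for (ep in seq_len(config$epochs)) {
    triples <- sample_epoch(work, region, child_seed(config$seed, ep))
    n <- nrow(triples)
    starts <- seq.int(1L, n, by = config$batch_size)
    losses <- numeric(length(starts))
    sizes <- numeric(length(starts))
    for (k in seq_along(starts)) {
      s <- starts[k]; e <- min(s + config$batch_size - 1L, n)
      rows <- triples$row[s:e]; bins <- triples$bin[s:e]
      y <- work$values[cbind(rows, bins + 1L)]
      bg <- batch_gradients(model, bi_all[rows], ai_all[rows], bins, y)
      if (!is.finite(bg$loss))
        stop(sprintf("training diverged: non-finite loss at epoch %d, batch %d",
                     ep, k))
      upd <- adam_update(opt, params, bg$gradients[nms], config)
      opt <- upd$state
      params <- upd$params
      model <- set_params(model, params)
      losses[k] <- bg$loss; sizes[k] <- e - s + 1L
    }
    epoch_loss[ep] <- sum(losses * sizes) / sum(sizes)
  }
  log <- tibble::tibble(epoch = seq_len(config$epochs), loss = epoch_loss)
  attr(log, "wall_time") <- proc.time()[["elapsed"]] - t0
  attr(log, "seed") <- config$seed
  class(log) <- c("train_log", class(log))
  list(model = model, log = log)
}

#' Stage-1 training: jointly fit all parameters on the training regions
#'
#' All five factor matrices and the decoder are optimized together by
#' mini-batch Adam on squared error, with epochs sampled only from the grid's
#' training regions (the desk-scale analog of training on a small pilot
#' subset of the genome).
#'
#' @param model A [init_model()] object with all groups trainable.
#' @param tensor A [track_tensor()] of observed experiments.
#' @param config A [train_config()].
#' @return List with elements `model` (trained) and `log` (per-epoch loss
#'   tibble with `wall_time`/`seed` attributes).
#' @export
train_stage1 <- function(model, tensor, config) {
  stopifnot(inherits(model, "factor_model"), inherits(tensor, "track_tensor"))
  if (is.null(model$grid$training_regions))
    stop("stage 1 requires training regions on the grid")
  if (!all(unlist(model$trainable)))
    stop("stage 1 trains all parameter groups; unfreeze them first")
  fit_epochs(model, tensor, training_bins(model$grid), config)
}

#' Stage-2 training: fit genomic factors chromosome by chromosome
#'
#' With the decoder, assay, and biosample factors frozen after stage 1, only
#' the three genomic factor matrices are trained, on one chromosome at a
#' time (epochs pass over that chromosome's full bin range). Rows belonging
#' to other chromosomes, and all frozen groups, are bit-identical before and
#' after.
#'
#' @param model A stage-1-trained [init_model()] object.
#' @param tensor A [track_tensor()].
#' @param config A [train_config()].
#' @param chromosome Chromosome name to train.
#' @return List with `model` and `log`, as [train_stage1()].
#' @export
train_stage2 <- function(model, tensor, config, chromosome) {
  stopifnot(inherits(model, "factor_model"))
  model <- set_trainable(model, network = FALSE, biosample = FALSE,
                         assay = FALSE, genome = TRUE)
  fit_epochs(model, tensor, chromosome_bins(model$grid, chromosome), config)
}

#' Full two-stage training pipeline
#'
#' Runs [train_stage1()] on the training regions, then [train_stage2()] on
#' every chromosome in turn, and restores all-trainable flags.
#'
#' @param model A freshly initialized [init_model()] object.
#' @param tensor A [track_tensor()].
#' @param config Stage-1 [train_config()].
#' @param stage2_config Stage-2 [train_config()]; defaults to `config` with
#'   a derived seed.
#' @return List with `model` and `log` (stage-1 log).
#' @export
train_full <- function(model, tensor, config,
                       stage2_config = NULL) {
  s1 <- train_stage1(model, tensor, config)
  model <- s1$model
  if (is.null(stage2_config)) {
    stage2_config <- config
    stage2_config$seed <- child_seed(config$seed, 7919L)
  }
  for (chrom in model$grid$layout$chrom) {
    cfg <- stage2_config
    cfg$seed <- child_seed(stage2_config$seed, match(chrom, model$grid$layout$chrom))
    model <- train_stage2(model, tensor, cfg, chrom)$model
  }
  model <- set_trainable(model, network = TRUE, biosample = TRUE,
                         assay = TRUE, genome = TRUE)
  list(model = model, log = s1$log)
}

#' Mean squared training/evaluation loss of a model on observed cells
#' @param model A [init_model()] object.
#' @param tensor A [track_tensor()].
#' @param bins Optional 0-based bin subset (default all bins).
#' @return Mean squared error over all observed cells and requested bins.
#' @export
model_loss <- function(model, tensor, bins = NULL) {
  if (is.null(bins)) bins <- seq.int(0L, n_bins(model$grid) - 1L)
  pred <- predict_cells(model, tensor$cells, bins)
  mean((pred - tensor$values[, bins + 1L, drop = FALSE])^2)
}

#' @export
print.train_log <- function(x, ...) {
  cat(sprintf("<train_log> %d epochs; final loss %.5g (%.1fs)\n",
              nrow(x), x$loss[nrow(x)], attr(x, "wall_time") %||% NA))
  invisible(x)
}
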