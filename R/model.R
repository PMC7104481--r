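#' Model architecture configuration
#'
#' Sets the latent dimensionality of the five factor matrices and the width
#' of the decoder's two hidden layers. The full-scale defaults are 32 factors
#' per biosample, 256 per assay, 25 per fine (25 bp) genomic position, 40 per
#' mid (250 bp) block, and 45 per coarse (5 kbp) block, with 2048 hidden
#' units; [desk_config()] gives a small configuration suitable for tests and
#' simulation studies.
#'
#' @param d_biosample,d_assay,d_fine,d_mid,d_coarse Factor dimensions.
#' @param hidden Hidden layer width of the decoder.
#' @return A `model_config` list. The decoder input width is the sum of the
#'   five factor dimensions (398 at the full-scale defaults).
#' @export
model_config <- function(d_biosample = 32, d_assay = 256, d_fine = 25,
                         d_mid = 40, d_coarse = 45, hidden = 2048) {
  cfg <- list(d_biosample = as.integer(d_biosample),
              d_assay = as.integer(d_assay), d_fine = as.integer(d_fine),
              d_mid = as.integer(d_mid), d_coarse = as.integer(d_coarse),
              hidden = as.integer(hidden))
  if (any(unlist(cfg) <= 0)) stop("all dimensions must be positive integers")
  cfg$d_in <- with(cfg, d_biosample + d_assay + d_fine + d_mid + d_coarse)
  structure(cfg, class = "model_config")
}

#' Desk-scale model configuration
#'
#' A small architecture (4 + 8 + 5 + 4 + 3 factors, 32 hidden units) that
#' trains in seconds on one CPU; used throughout the test suite and the
#' simulation studies.
#'
#' @return A [model_config()].
#' @export
desk_config <- function() {
  model_config(d_biosample = 4, d_assay = 8, d_fine = 5, d_mid = 4,
               d_coarse = 3, hidden = 32)
}

#' Initialize a factor model
#'
#' Dense decoder weights are drawn Glorot-uniform (symmetric uniform with
#' limit `sqrt(6 / (fan_in + fan_out))`), biases are zero, and embedding
#' (factor) rows are small symmetric uniform on (-0.05, 0.05) — the standard
#' defaults of mainstream deep-learning toolkits. Identical seeds give
#' bit-identical parameters.
#'
#' @param biosamples,assays Ordered axis identifier vectors.
#' @param grid A [genomic_grid()]; fixes the number of fine/mid/coarse factor
#'   rows.
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return An object of class `factor_model` holding the five factor
#'   matrices, the decoder weights, the grid, axis labels, and trainability
#'   flags (all groups trainable initially).
#' @export
init_model <- function(biosamples, assays, grid, config = desk_config(),
                       seed = 1) {
  stopifnot(inherits(grid, "genomic_grid"), inherits(config, "model_config"))
  biosamples <- as.character(biosamples)
  assays <- as.character(assays)
  if (anyDuplicated(biosamples) || anyDuplicated(assays))
    stop("axis identifiers must be unique")
  lay <- grid$layout
  withr::with_seed(seed, {
    factors <- list(
      biosample = embed_init(length(biosamples), config$d_biosample),
      assay = embed_init(length(assays), config$d_assay),
      fine = embed_init(sum(lay$n_fine), config$d_fine),
      mid = embed_init(sum(lay$n_mid), config$d_mid),
      coarse = embed_init(sum(lay$n_coarse), config$d_coarse))
    net <- list(
      W1 = glorot(config$d_in, config$hidden),
      b1 = numeric(config$hidden),
      W2 = glorot(config$hidden, config$hidden),
      b2 = numeric(config$hidden),
      w_out = glorot(config$hidden, 1L),
      b_out = 0)
  })
  structure(list(config = config, biosamples = biosamples, assays = assays,
                 grid = grid, factors = factors, net = net,
                 trainable = list(network = TRUE, biosample = TRUE,
                                  assay = TRUE, genome = TRUE)),
            class = "factor_model")
}

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

embed_init <- function(n, d) {
  matrix(stats::runif(n * d, -0.05, 0.05), n, d)
}

#' @export
print.factor_model <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(c(x$factors, x$net), length, numeric(1)))
  cat(sprintf(
    "<factor_model> %d biosamples x %d assays, %d bins; %d+%d+%d+%d+%d factors, %d hidden units (%s parameters)\n",
    length(x$biosamples), length(x$assays), n_bins(x$grid),
    cfg$d_biosample, cfg$d_assay, cfg$d_fine, cfg$d_mid, cfg$d_coarse,
    cfg$hidden, format(np, big.mark = ",")))
  on <- names(Filter(isTRUE, x$trainable))
  cat("  trainable groups:", paste(on, collapse = ", "), "\n")
  invisible(x)
}

axis_index <- function(labels, axis, what) {
  if (is.numeric(labels)) {
    i <- as.integer(labels)
    if (any(i < 1 | i > length(axis))) stop(what, " index out of range")
    return(i)
  }
  i <- match(as.character(labels), axis)
  if (anyNA(i)) stop("unknown ", what, ": ",
                     paste(labels[is.na(i)], collapse = ", "))
  i
}

# 1-based factor-row indices for a vector of 0-based fine bins
bin_rows <- function(grid, bins) {
  ms <- multiscale_indices(bins, grid)
  list(fine = ms$fine + 1L, mid = ms$mid + 1L, coarse = ms$coarse + 1L)
}

#' Assemble decoder input vectors for (biosample, assay, bin) triples
#'
#' Concatenates the five factor rows in the fixed order (biosample, assay,
#' fine, mid, coarse). Two bins in the same mid/coarse block differ only in
#' their fine segment.
#'
#' @param model A [init_model()] object.
#' @param biosample,assay Identifiers (character) or 1-based axis indices;
#'   recycled against `bins`.
#' @param bins Integer vector of 0-based fine-bin indices.
#' @return Numeric matrix with one row per triple and `d_in` columns.
#' @export
embed_inputs <- function(model, biosample, assay, bins) {
  stopifnot(inherits(model, "factor_model"))
  bi <- axis_index(biosample, model$biosamples, "biosample")
  ai <- axis_index(assay, model$assays, "assay")
  n <- max(length(bi), length(ai), length(bins))
  bi <- rep_len(bi, n); ai <- rep_len(ai, n); bins <- rep_len(as.integer(bins), n)
  rows <- bin_rows(model$grid, bins)
  cbind(model$factors$biosample[bi, , drop = FALSE],
        model$factors$assay[ai, , drop = FALSE],
        model$factors$fine[rows$fine, , drop = FALSE],
        model$factors$mid[rows$mid, , drop = FALSE],
        model$factors$coarse[rows$coarse, , drop = FALSE])
}

# forward pass keeping intermediates for backprop
forward_pass <- function(net, X) {
  Z1 <- X %*% net$W1 + rep(net$b1, each = nrow(X))
  H1 <- pmax(Z1, 0)
  Z2 <- H1 %*% net$W2 + rep(net$b2, each = nrow(X))
  H2 <- pmax(Z2, 0)
  yhat <- as.vector(H2 %*% net$w_out) + net$b_out
  list(yhat = yhat, X = X, Z1 = Z1, H1 = H1, Z2 = Z2, H2 = H2)
}

#' Decoder forward pass
#'
#' `ReLU` on both hidden layers, linear output:
#' `y = w_out . ReLU(W2 . ReLU(W1 x + b1) + b2) + b_out`.
#'
#' @param model A [init_model()] object (or a bare decoder weight list with
#'   elements `W1`, `b1`, `W2`, `b2`, `w_out`, `b_out`).
#' @param X Input matrix (rows = triples, `d_in` columns) or a single input
#'   vector.
#' @return Numeric vector of predicted transformed signal values.
#' @export
decoder_forward <- function(model, X) {
  net <- if (inherits(model, "factor_model")) model$net else model
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != nrow(net$W1)) stop("input width does not match the decoder")
  forward_pass(net, X)$yhat
}

#' Predict an imputed track for one (biosample, assay) cell
#'
#' Applies the decoder to the embedded inputs at every requested bin. Output
#' is on the arcsinh scale (use [inverse_transform()] for the original
#' scale).
#'
#' @param model A [init_model()] object (typically trained).
#' @param biosample,assay Cell identifiers or 1-based indices.
#' @param bins Optional 0-based fine-bin subset; default all bins.
#' @return Numeric vector, one prediction per requested bin.
#' @export
predict_track <- function(model, biosample, assay, bins = NULL) {
  stopifnot(inherits(model, "factor_model"))
  if (is.null(bins)) bins <- seq.int(0L, n_bins(model$grid) - 1L)
  out <- numeric(length(bins))
  chunk <- 16384L
  for (s in seq.int(1L, length(bins), by = chunk)) {
    e <- min(s + chunk - 1L, length(bins))
    X <- embed_inputs(model, biosample, assay, bins[s:e])
    out[s:e] <- decoder_forward(model, X)
  }
  out
}

#' Predict every cell of a tensor's observed set (or arbitrary cells)
#' @param model A [init_model()] object.
#' @param cells Tibble with columns `biosample`, `assay`.
#' @param bins Optional 0-based bin subset.
#' @return Matrix with one row per cell.
#' @export
predict_cells <- function(model, cells, bins = NULL) {
  cells <- tibble::as_tibble(cells)
  do.call(rbind, purrr::map2(cells$biosample, cells$assay,
                             function(b, a) predict_track(model, b, a, bins)))
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single-file archive holding the five factor matrices,
#' decoder weights, configuration, grid, trainability flags, and the axis
#' label lists (authoritative for index-identifier mapping).
#'
#' @param model A [init_model()] object.
#' @param path Checkpoint file path.
#' @return `path` invisibly; `read_model()` returns the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "factor_model"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
read_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "factor_model")) stop("not a factor_model checkpoint")
  model
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy summary of a model's parameter groups
#' @param x A `factor_model`.
#' @param ... Unused.
#' @return Tibble with one row per parameter group: rows, columns, parameter
#'   count, trainability, and root-mean-square magnitude.
#' @method tidy factor_model
#' @export
tidy.factor_model <- function(x, ...) {
  groups <- c(x$factors, x$net[c("W1", "W2", "w_out")])
  trainable <- c(biosample = x$trainable$biosample, assay = x$trainable$assay,
                 fine = x$trainable$genome, mid = x$trainable$genome,
                 coarse = x$trainable$genome, W1 = x$trainable$network,
                 W2 = x$trainable$network, w_out = x$trainable$network)
  purrr::imap_dfr(groups, function(m, nm) {
    tibble::tibble(group = nm, rows = nrow(m), cols = ncol(m),
                   n_parameters = length(m),
                   trainable = unname(trainable[nm]),
                   rms = sqrt(mean(m^2)))
  })
}

#' One-row summary of a model
#' @param x A `factor_model`.
#' @param ... Unused.
#' @return One-row tibble: axis sizes, bin count, total parameter count.
#' @method glance factor_model
#' @export
glance.factor_model <- function(x, ...) {
  tibble::tibble(
    n_biosamples = length(x$biosamples), n_assays = length(x$assays),
    n_bins = n_bins(x$grid), hidden = x$config$hidden,
    d_in = x$config$d_in,
    n_parameters = sum(vapply(c(x$factors, x$net), length, numeric(1))))
}
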