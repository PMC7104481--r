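#' Average-activity baseline for one assay
#'
#' The positionwise mean signal of an assay across the observed tracks of
#' the (training) biosamples. Beating this baseline is the evidence that a
#' model captures biosample-specific signal, since the baseline makes the
#' same prediction for every biosample. The evaluated track's own biosample
#' must always be excluded.
#'
#' @param tensor A [track_tensor()].
#' @param assay Assay identifier.
#' @param exclude_biosamples Biosample identifiers to leave out (at minimum
#'   the biosample being evaluated).
#' @return Numeric per-bin vector.
#' @export
average_activity <- function(tensor, assay, exclude_biosamples = character(0)) {
  stopifnot(inherits(tensor, "track_tensor"))
  keep <- tensor$cells$assay == assay &
    !(tensor$cells$biosample %in% exclude_biosamples)
  if (!any(keep))
    stop("no eligible tracks for assay ", assay, " after exclusions")
  colMeans(tensor$values[keep, , drop = FALSE])
}

#' Global mean squared error between observed and imputed tracks
#' @param observed,imputed Equal-length numeric vectors (arcsinh scale).
#' @return Mean of squared differences.
#' @export
mse_global <- function(observed, imputed) {
  if (length(observed) != length(imputed)) stop("length mismatch")
  mean((observed - imputed)^2)
}

#' MSE at the positions carrying the top 1% of signal
#'
#' With `by = "observed"` this is a recall-like measure (can the imputation
#' reconstruct the strongest observed positions?); with `by = "imputed"` a
#' precision-like one (is the signal real where the imputation is
#' strongest?). The top set holds `ceiling(0.01 * n)` positions, ties broken
#' by position order.
#'
#' @param observed,imputed Equal-length numeric vectors with at least 100
#'   positions.
#' @param by Which vector selects the top positions.
#' @return MSE over the selected subset.
#' @export
mse_top1 <- function(observed, imputed, by = c("observed", "imputed")) {
  by <- match.arg(by)
  if (length(observed) != length(imputed)) stop("length mismatch")
  n <- length(observed)
  if (n < 100) stop("need at least 100 positions for a top-1% metric")
  sel <- if (by == "observed") observed else imputed
  m <- ceiling(0.01 * n)
  top <- order(sel, seq_len(n), decreasing = c(TRUE, FALSE), method = "radix")[seq_len(m)]
  mean((observed[top] - imputed[top])^2)
}

#' MSE restricted to an annotated set of bins
#' @param observed,imputed Equal-length numeric vectors.
#' @param mask Integer vector of 0-based bin indices (e.g. from
#'   [intervals_to_bin_mask()] on promoters, gene bodies, or enhancers).
#' @return MSE over the masked bins.
#' @export
mse_region <- function(observed, imputed, mask) {
  if (length(observed) != length(imputed)) stop("length mismatch")
  if (length(mask) == 0) stop("mask is empty")
  i <- as.integer(mask) + 1L
  if (min(i) < 1 || max(i) > length(observed)) stop("mask index out of range")
  mean((observed[i] - imputed[i])^2)
}

#' Paired t test on per-track metric values of two methods
#'
#' Standard paired t statistic on the differences, with the degenerate cases
#' handled explicitly: all-zero differences give `t = 0, p = 1`; identical
#' nonzero differences (zero variance, nonzero mean) give the limiting
#' `p = 0`.
#'
#' @param a,b Equal-length numeric vectors of a per-track metric under two
#'   methods, paired per track.
#' @return One-row tibble with `t`, `p_value`, `df`, `mean_difference`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  n <- length(a)
  if (n < 2) stop("need at least two pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(tibble::tibble(t = 0, p_value = 1, df = n - 1, mean_difference = 0))
    return(tibble::tibble(t = sign(mean(d)) * Inf, p_value = 0, df = n - 1,
                          mean_difference = mean(d)))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(t = unname(ht$statistic), p_value = ht$p.value,
                 df = unname(ht$parameter), mean_difference = mean(d))
}

#' Aggregate a per-bin vector to sliding windows
#'
#' Windows of `window` bp with stride `stride` bp, starting at position 0 of
#' a chromosome; each window's value is the mean of its constituent fine
#' bins (8 bins for 200 bp windows of 25 bp bins), truncated at the
#' chromosome end.
#'
#' @param values Numeric per-bin vector for one chromosome.
#' @param bin_size Fine bin width in bp (default 25).
#' @param window,stride Window width and stride in bp (defaults 200 and 50);
#'   both must be multiples of `bin_size`.
#' @return Numeric vector, one value per window; window k (0-based) covers
#'   `[k * stride, k * stride + window)`.
#' @export
aggregate_to_windows <- function(values, bin_size = 25, window = 200,
                                 stride = 50) {
  if (window < bin_size) stop("window smaller than a bin")
  if (window %% bin_size != 0 || stride %% bin_size != 0)
    stop("window and stride must be multiples of the bin size")
  wb <- window %/% bin_size
  sb <- stride %/% bin_size
  n <- length(values)
  starts <- seq.int(0L, n - 1L, by = sb)
  vapply(starts, function(s) {
    mean(values[(s + 1L):min(s + wb, n)])
  }, numeric(1))
}

#' Drop ambiguous windows from scores and labels
#'
#' Peak labels come in three classes — positive (bound), negative (unbound),
#' and ambiguous (peak flanks, irreproducible peaks) — and the ambiguous
#' class is excluded from precision-recall evaluation.
#'
#' @param scores Numeric vector of per-window prediction scores.
#' @param labels Character/factor vector aligned with `scores`, in
#'   `{"positive", "negative", "ambiguous"}` (the single-letter challenge
#'   codes `B`/`U`/`A` are also accepted).
#' @return List with `scores` and logical `labels` (`TRUE` = positive),
#'   ambiguous windows removed.
#' @export
filter_ambiguous <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  labels <- as.character(labels)
  map <- c(positive = "positive", negative = "negative",
           ambiguous = "ambiguous", B = "positive", U = "negative",
           A = "ambiguous")
  if (!all(labels %in% names(map))) stop("unrecognized label values")
  labels <- unname(map[labels])
  keep <- labels != "ambiguous"
  if (!any(keep)) stop("all windows are ambiguous")
  list(scores = scores[keep], labels = labels[keep] == "positive")
}

#' Average precision of a ranked prediction list
#'
#' The step-wise (non-interpolated) area under the precision-recall curve:
#' `AP = sum_k (R_k - R_{k-1}) * P_k` over the ranked list, with tied scores
#' grouped (all windows sharing a score enter the ranking together).
#'
#' @param scores Numeric prediction scores.
#' @param labels Logical (or 0/1) labels; needs at least one positive and
#'   one negative.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  P <- sum(labels)
  if (P == 0 || P == length(labels))
    stop("need at least one positive and one negative label")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp_end <- cumsum(rle(s)$lengths)   # last index of each tied score group
  tp <- cumsum(l)[grp_end]
  k <- grp_end
  prec <- tp / k
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Precision-recall break-even point (EPR)
#'
#' The precision of the top-P scored windows, where P is the number of
#' positive labels — the point on the precision-recall curve where precision
#' equals recall. Ties at the cutoff are, by default, included (precision is
#' computed over the enlarged set); set `ties = "exclude"` to truncate at
#' exactly P windows instead.
#'
#' @param scores Numeric prediction scores.
#' @param labels Logical (or 0/1) labels; needs at least one positive.
#' @param ties `"include"` (default) or `"exclude"`.
#' @return EPR in `[0, 1]`.
#' @export
epr <- function(scores, labels, ties = c("include", "exclude")) {
  ties <- match.arg(ties)
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  P <- sum(labels)
  if (P == 0) stop("need at least one positive label")
  ord <- order(scores, decreasing = TRUE)
  if (ties == "exclude") {
    top <- ord[seq_len(P)]
  } else {
    cutoff <- scores[ord[P]]
    top <- which(scores >= cutoff)
  }
  mean(labels[top])
}

#' Greedy counter-based fold partition of an experiment matrix
#'
#' Experiments are grouped by biosample; biosamples are visited in a seeded
#' random order, experiments within each biosample are shuffled, and each
#' experiment is dealt fold `counter mod k + 1`, the counter persisting
#' across biosamples. This balances fold sizes to within one experiment
#' while spreading each biosample's experiments across folds.
#'
#' @param experiments Data frame with columns `biosample` and `assay`, one
#'   row per experiment.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @param shuffle Shuffle biosample order and within-biosample experiment
#'   order (default TRUE; FALSE keeps input order, useful for worked
#'   examples).
#' @return Tibble with columns `biosample`, `assay`, `fold` (1..k); fold
#'   coverage counts are attached as `attr(, "coverage")`.
#' @export
greedy_fold_partition <- function(experiments, k = 5, seed = 1,
                                  shuffle = TRUE) {
  experiments <- tibble::as_tibble(experiments)
  stopifnot(all(c("biosample", "assay") %in% names(experiments)))
  if (k < 2) stop("k must be at least 2")
  bios <- unique(experiments$biosample)
  idx_by_bio <- split(seq_len(nrow(experiments)),
                      factor(experiments$biosample, levels = bios))
  order_idx <- withr::with_seed(seed, {
    bio_order <- if (shuffle) sample(bios) else bios
    unlist(lapply(bio_order, function(b) {
      i <- idx_by_bio[[b]]
      if (shuffle && length(i) > 1) sample(i) else i
    }), use.names = FALSE)
  })
  fold <- integer(nrow(experiments))
  fold[order_idx] <- (seq_along(order_idx) - 1L) %% k + 1L
  out <- dplyr::mutate(experiments, fold = fold)
  attr(out, "coverage") <- out |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(n = dplyr::n(),
                     n_biosamples = dplyr::n_distinct(.data$biosample),
                     n_assays = dplyr::n_distinct(.data$assay),
                     .groups = "drop")
  out
}

#' Per-track metric report for imputed experiments
#'
#' For each observed cell of `tensor` (or the given subset), computes the
#' six MSE metrics for the supplied imputations and, when `folds` is given,
#' for the average-activity baseline computed from that cell's training
#' complement (the evaluated biosample is always excluded).
#'
#' @param tensor A [track_tensor()] of observed experiments.
#' @param imputed Matrix of imputations aligned with
#'   `observed_cells(tensor)` rows (e.g. from [crossval_impute()] or
#'   [predict_cells()]).
#' @param annotations Optional list with elements `promoters`, `gene_bodies`,
#'   `enhancers`, each a `chrom`/`start`/`end` data frame.
#' @param grid A [genomic_grid()] (needed for region metrics).
#' @param folds Optional fold assignment from [greedy_fold_partition()]; if
#'   given, baseline columns (`baseline_*`) computed on each cell's training
#'   folds are added. A cell whose assay has no training-set counterpart is
#'   dropped with a warning.
#' @return A tibble with one row per evaluated track, of class
#'   `metric_report`.
#' @export
evaluate_compendium <- function(tensor, imputed, annotations = NULL,
                                grid = NULL, folds = NULL) {
  stopifnot(inherits(tensor, "track_tensor"))
  imputed <- as.matrix(imputed)
  if (nrow(imputed) != nrow(tensor$cells))
    stop("imputed matrix must align with the tensor's observed cells")
  masks <- NULL
  if (!is.null(annotations)) {
    if (is.null(grid)) stop("region metrics need the grid")
    masks <- lapply(annotations[c("promoters", "gene_bodies", "enhancers")],
                    intervals_to_bin_mask, grid = grid)
  }
  fold_of <- NULL
  if (!is.null(folds)) {
    fold_of <- dplyr::left_join(tensor$cells, tibble::as_tibble(folds),
                                by = c("biosample", "assay"))$fold
    if (anyNA(fold_of)) stop("folds must cover every observed cell")
  }
  rows <- purrr::map(seq_len(nrow(tensor$cells)), function(i) {
    obs <- tensor$values[i, ]
    imp <- imputed[i, ]
    row <- tibble::tibble(
      biosample = tensor$cells$biosample[i], assay = tensor$cells$assay[i],
      mseGlobal = mse_global(obs, imp),
      mse1obs = mse_top1(obs, imp, by = "observed"),
      mse1imp = mse_top1(obs, imp, by = "imputed"))
    if (!is.null(masks)) {
      row$mseProm <- mse_region(obs, imp, masks$promoters)
      row$mseGene <- mse_region(obs, imp, masks$gene_bodies)
      row$mseEnh <- mse_region(obs, imp, masks$enhancers)
    }
    if (!is.null(fold_of)) {
      train <- fold_of != fold_of[i]
      eligible <- train & tensor$cells$assay == tensor$cells$assay[i] &
        tensor$cells$biosample != tensor$cells$biosample[i]
      if (!any(eligible)) return(NULL)
      base <- colMeans(tensor$values[eligible, , drop = FALSE])
      row$baseline_mseGlobal <- mse_global(obs, base)
      row$baseline_mse1obs <- mse_top1(obs, base, by = "observed")
      row$baseline_mse1imp <- mse_top1(obs, base, by = "imputed")
      if (!is.null(masks)) {
        row$baseline_mseProm <- mse_region(obs, base, masks$promoters)
        row$baseline_mseGene <- mse_region(obs, base, masks$gene_bodies)
        row$baseline_mseEnh <- mse_region(obs, base, masks$enhancers)
      }
    }
    row
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    warning(dropped, " track(s) skipped: no training-set counterpart assay")
  out <- dplyr::bind_rows(rows)
  class(out) <- c("metric_report", class(out))
  out
}

#' Aggregate a metric report over tracks and against the baseline
#' @param x A `metric_report` from [evaluate_compendium()].
#' @param ... Unused.
#' @return Tibble with one row per metric: mean model value, mean baseline
#'   value (if present), paired-t p value, and the number of assays where
#'   the model's assay-mean beats the baseline's.
#' @method tidy metric_report
#' @export
tidy.metric_report <- function(x, ...) {
  metrics <- intersect(c("mseGlobal", "mse1obs", "mse1imp", "mseProm",
                         "mseGene", "mseEnh"), names(x))
  purrr::map_dfr(metrics, function(m) {
    row <- tibble::tibble(metric = m, model = mean(x[[m]]))
    bm <- paste0("baseline_", m)
    if (bm %in% names(x)) {
      row$baseline <- mean(x[[bm]])
      row$p_value <- paired_t(x[[m]], x[[bm]])$p_value
      by_assay <- x |>
        dplyr::group_by(.data$assay) |>
        dplyr::summarise(model = mean(.data[[m]]),
                         baseline = mean(.data[[bm]]), .groups = "drop")
      row$assays_model_wins <- sum(by_assay$model < by_assay$baseline)
      row$n_assays <- nrow(by_assay)
    }
    row
  })
}

#' Cross-validated imputation of every observed cell
#'
#' For each fold, a fresh model is trained with the two-stage pipeline on
#' the other folds' experiments and used to impute the held-out fold's
#' tracks.
#'
#' @param tensor A [track_tensor()].
#' @param grid A [genomic_grid()] with training regions.
#' @param folds Fold assignment from [greedy_fold_partition()] covering all
#'   observed cells.
#' @param model_cfg A [model_config()].
#' @param config Stage-1 [train_config()].
#' @param stage2_config Optional stage-2 [train_config()].
#' @return Matrix of imputations aligned with `observed_cells(tensor)`.
#' @export
crossval_impute <- function(tensor, grid, folds, model_cfg = desk_config(),
                            config, stage2_config = NULL) {
  fold_of <- dplyr::left_join(tensor$cells, tibble::as_tibble(folds),
                              by = c("biosample", "assay"))$fold
  if (anyNA(fold_of)) stop("folds must cover every observed cell")
  imputed <- matrix(NA_real_, nrow(tensor$cells), ncol(tensor$values))
  for (f in sort(unique(fold_of))) {
    train_tensor <- subset_cells(tensor, fold_of != f)
    model <- init_model(tensor$biosamples, tensor$assays, grid, model_cfg,
                        seed = child_seed(config$seed, f))
    cfg <- config; cfg$seed <- child_seed(config$seed, 100L + f)
    model <- train_full(model, train_tensor, cfg, stage2_config)$model
    held <- which(fold_of == f)
    imputed[held, ] <- predict_cells(model, tensor$cells[held, ])
  }
  imputed
}

#' Relative reduction between two error values, in percent
#'
#' `100 * (from - to) / from`: the headline way of summarising how much one
#' method's error improves on another's.
#'
#' @param from Reference (e.g. baseline) error.
#' @param to Improved error.
#' @return Percent reduction (positive when `to < from`).
#' @examples
#' relative_reduction(0.0807, 0.0653)  # ~19.1
#' @export
relative_reduction <- function(from, to) {
  if (any(from == 0)) stop("reference value must be nonzero")
  100 * (from - to) / from
}
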