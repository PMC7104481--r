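#' Construct a biosample x assay x position signal tensor
#'
#' A `track_tensor` holds the observed cells of the experiment matrix: each
#' observed (biosample, assay) pair carries one arcsinh-transformed signal
#' vector with one entry per fine bin of the grid. The set of observed cells
#' is the missingness mask; unobserved cells simply have no row.
#'
#' @param values Numeric matrix, one row per observed cell, one column per
#'   fine bin; or a named list of per-cell vectors (names ignored, use
#'   `cells` for identity).
#' @param cells Data frame with columns `biosample` and `assay`, one row per
#'   row of `values`.
#' @param biosamples,assays Ordered axis identifier vectors. Default: the
#'   unique values appearing in `cells`, in order of first appearance.
#' @param grid Optional [genomic_grid()]; if given, the bin count is checked.
#' @return An object of class `track_tensor`.
#' @export
track_tensor <- function(values, cells, biosamples = NULL, assays = NULL,
                         grid = NULL) {
  if (is.list(values) && !is.matrix(values)) {
    values <- do.call(rbind, values)
  }
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  cells <- tibble::as_tibble(cells)[, c("biosample", "assay")]
  cells$biosample <- as.character(cells$biosample)
  cells$assay <- as.character(cells$assay)
  if (nrow(cells) != nrow(values))
    stop("cells and values must have one row per observed track")
  if (anyDuplicated(cells)) stop("duplicate (biosample, assay) cells")
  if (any(!is.finite(values))) stop("signal values must be finite")
  if (is.null(biosamples)) biosamples <- unique(cells$biosample)
  if (is.null(assays)) assays <- unique(cells$assay)
  biosamples <- as.character(biosamples)
  assays <- as.character(assays)
  if (anyDuplicated(biosamples)) stop("biosample identifiers must be unique")
  if (anyDuplicated(assays)) stop("assay identifiers must be unique")
  if (!all(cells$biosample %in% biosamples))
    stop("cell references a biosample not on the axis")
  if (!all(cells$assay %in% assays))
    stop("cell references an assay not on the axis")
  if (!is.null(grid) && ncol(values) != n_bins(grid))
    stop("value vectors must have one entry per grid bin")
  structure(list(biosamples = biosamples, assays = assays,
                 cells = cells, values = values),
            class = "track_tensor")
}

#' @export
print.track_tensor <- function(x, ...) {
  ms <- missingness_summary(x)
  cat(sprintf(
    "<track_tensor> %d biosamples x %d assays x %d bins; %d observed cells (%.1f%% missing)\n",
    length(x$biosamples), length(x$assays), ncol(x$values),
    ms$observed, ms$percent_missing))
  invisible(x)
}

#' Observed cells of a tensor
#' @param tensor A [track_tensor()].
#' @return Tibble with columns `biosample`, `assay`, `row` (row in the value
#'   matrix).
#' @export
observed_cells <- function(tensor) {
  stopifnot(inherits(tensor, "track_tensor"))
  dplyr::mutate(tensor$cells, row = dplyr::row_number())
}

#' Summarise the missingness of an experiment matrix
#'
#' Capacity is `|biosamples| x |assays|`; the percent missing is
#' `100 * (1 - observed / capacity)`.
#'
#' @param tensor A [track_tensor()].
#' @return A one-row tibble with columns `capacity`, `observed`,
#'   `percent_missing`.
#' @examples
#' # 2 x 2 matrix with every cell observed: nothing missing
#' tt <- track_tensor(matrix(0, 4, 10),
#'                    expand.grid(biosample = c("b1", "b2"),
#'                                assay = c("a1", "a2")))
#' missingness_summary(tt)
#' @export
missingness_summary <- function(tensor) {
  stopifnot(inherits(tensor, "track_tensor"))
  if (length(tensor$biosamples) == 0 || length(tensor$assays) == 0)
    stop("tensor has an empty axis")
  capacity <- length(tensor$biosamples) * length(tensor$assays)
  observed <- nrow(tensor$cells)
  tibble::tibble(capacity = capacity, observed = observed,
                 percent_missing = 100 * (1 - observed / capacity))
}

#' Extract one observed track from a tensor
#' @param tensor A [track_tensor()].
#' @param biosample,assay Cell identifiers.
#' @return Numeric per-bin vector.
#' @export
get_track <- function(tensor, biosample, assay) {
  i <- cell_row(tensor, biosample, assay)
  if (is.na(i)) stop("cell (", biosample, ", ", assay, ") is not observed")
  tensor$values[i, ]
}

cell_row <- function(tensor, biosample, assay) {
  which(tensor$cells$biosample == biosample & tensor$cells$assay == assay)[1]
}

#' Pool two tensors into one (union of axes, disjoint cells)
#'
#' Used by the retraining and fine-tuning extension protocols, which train on
#' the original and additional experiments together.
#'
#' @param a,b [track_tensor()] objects over the same grid (same bin count).
#' @return A pooled [track_tensor()]; axis order is `a`'s axes followed by
#'   `b`'s new identifiers.
#' @export
pool_tensors <- function(a, b) {
  stopifnot(inherits(a, "track_tensor"), inherits(b, "track_tensor"))
  if (ncol(a$values) != ncol(b$values)) stop("tensors have different bin counts")
  shared <- dplyr::inner_join(a$cells, b$cells, by = c("biosample", "assay"))
  if (nrow(shared) > 0)
    stop("cell sets overlap: ", nrow(shared), " colliding (biosample, assay) cells")
  track_tensor(rbind(a$values, b$values),
               dplyr::bind_rows(a$cells, b$cells),
               biosamples = union(a$biosamples, b$biosamples),
               assays = union(a$assays, b$assays))
}

#' Restrict a tensor to a subset of its observed cells
#' @param tensor A [track_tensor()].
#' @param keep Logical or integer vector indexing rows of
#'   `observed_cells(tensor)`.
#' @param drop_axes If `TRUE`, drop axis identifiers that no longer have any
#'   observed cell; default keeps the full axes.
#' @return A [track_tensor()].
#' @export
subset_cells <- function(tensor, keep, drop_axes = FALSE) {
  stopifnot(inherits(tensor, "track_tensor"))
  cells <- tensor$cells[keep, , drop = FALSE]
  track_tensor(tensor$values[keep, , drop = FALSE], cells,
               biosamples = if (drop_axes) unique(cells$biosample) else tensor$biosamples,
               assays = if (drop_axes) unique(cells$assay) else tensor$assays)
}
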