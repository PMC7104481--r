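#' Define a binned genomic coordinate grid with three resolutions
#'
#' A `genomic_grid` fixes the coordinate system used by every other function
#' in the package: a set of ordered chromosomes, a fine bin size (25 bp by
#' default), and two coarser block sizes expressed as multiples of the fine
#' bin (250 bp and 5 kbp at the defaults). Genomic latent factors live at
#' these three resolutions, so adjacent fine bins share their mid- and
#' coarse-resolution factors. Blocks are aligned to chromosome starts and
#' never span chromosomes; a partial trailing block at a chromosome end gets
#' its own index.
#'
#' All coordinates are 0-based, half-open (the bedGraph/BED convention), and
#' bin indices exposed by the API are 0-based global fine-bin indices.
#'
#' @param chromosomes A data frame with columns `chrom` and `length` (bp), or
#'   a named numeric vector of chromosome lengths. Order is preserved.
#' @param bin_size Fine bin width in bp (default 25).
#' @param ratio_mid Fine bins per mid-resolution block (default 10 = 250 bp).
#' @param ratio_coarse Fine bins per coarse block (default 200 = 5 kbp);
#'   must be a multiple of `ratio_mid`.
#' @param training_regions Optional data frame with columns `chrom`, `start`,
#'   `end` (bp, half-open): the regions used for joint (stage-1) training,
#'   analogous to a small pilot subset of the genome. Must be sorted and
#'   non-overlapping within each chromosome.
#' @return An object of class `genomic_grid`.
#' @examples
#' grid <- genomic_grid(c(chr1 = 10000), bin_size = 25)
#' n_bins(grid)
#' @export
genomic_grid <- function(chromosomes, bin_size = 25, ratio_mid = 10,
                         ratio_coarse = 200, training_regions = NULL) {
  if (is.numeric(chromosomes) && !is.null(names(chromosomes))) {
    chromosomes <- tibble::tibble(chrom = names(chromosomes),
                                  length = unname(chromosomes))
  }
  chromosomes <- tibble::as_tibble(chromosomes)
  stopifnot(all(c("chrom", "length") %in% names(chromosomes)))
  if (nrow(chromosomes) == 0) stop("grid needs at least one chromosome")
  if (anyDuplicated(chromosomes$chrom)) stop("duplicate chromosome names")
  if (any(chromosomes$length <= 0)) stop("chromosome lengths must be positive")
  if (!(is.numeric(bin_size) && length(bin_size) == 1 && bin_size > 0 &&
        bin_size == as.integer(bin_size)))
    stop("bin_size must be a positive integer")
  for (r in list(ratio_mid, ratio_coarse)) {
    if (!(is.numeric(r) && length(r) == 1 && r > 0 && r == as.integer(r)))
      stop("resolution ratios must be positive integers")
  }
  if (ratio_coarse %% ratio_mid != 0)
    stop("ratio_coarse must be a multiple of ratio_mid")

  layout <- chromosomes
  layout$n_fine <- as.integer(ceiling(layout$length / bin_size))
  layout$n_mid <- as.integer(ceiling(layout$n_fine / ratio_mid))
  layout$n_coarse <- as.integer(ceiling(layout$n_fine / ratio_coarse))
  layout$fine_offset <- c(0L, cumsum(layout$n_fine)[-nrow(layout)])
  layout$mid_offset <- c(0L, cumsum(layout$n_mid)[-nrow(layout)])
  layout$coarse_offset <- c(0L, cumsum(layout$n_coarse)[-nrow(layout)])

  grid <- structure(
    list(layout = layout, bin_size = as.integer(bin_size),
         ratio_mid = as.integer(ratio_mid),
         ratio_coarse = as.integer(ratio_coarse),
         training_regions = NULL),
    class = "genomic_grid")
  if (!is.null(training_regions)) {
    grid$training_regions <- validate_regions(training_regions, grid)
  }
  grid
}

validate_regions <- function(regions, grid) {
  regions <- tibble::as_tibble(regions)
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  if (any(regions$start >= regions$end))
    stop("malformed interval: start must be < end")
  if (!all(regions$chrom %in% grid$layout$chrom))
    stop("interval chromosome not on the grid")
  len <- grid$layout$length[match(regions$chrom, grid$layout$chrom)]
  if (any(regions$start < 0) || any(regions$end > len))
    stop("interval outside chromosome bounds")
  regions <- dplyr::arrange(regions, match(.data$chrom, grid$layout$chrom),
                            .data$start)
  overlaps <- regions |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(bad = any(.data$start[-1] < .data$end[-length(.data$end)]),
                     .groups = "drop")
  if (any(overlaps$bad, na.rm = TRUE))
    stop("training regions must be non-overlapping within a chromosome")
  regions
}

#' @export
print.genomic_grid <- function(x, ...) {
  cat(sprintf(
    "<genomic_grid> %d chromosome(s), %d bins of %d bp (mid %d bp, coarse %d bp)\n",
    nrow(x$layout), n_bins(x), x$bin_size,
    x$bin_size * x$ratio_mid, x$bin_size * x$ratio_coarse))
  if (!is.null(x$training_regions))
    cat(sprintf("  training regions: %d interval(s), %d bins\n",
                nrow(x$training_regions), length(training_bins(x))))
  invisible(x)
}

#' Total number of fine bins on a grid
#' @param grid A [genomic_grid()].
#' @return Integer count of fine bins across all chromosomes.
#' @export
n_bins <- function(grid) {
  stopifnot(inherits(grid, "genomic_grid"))
  sum(grid$layout$n_fine)
}

#' Map fine-bin indices to their mid- and coarse-resolution block indices
#'
#' Block indices are computed per chromosome (blocks never span chromosome
#' boundaries): within a chromosome, the mid index is `floor(local / ratio_mid)`
#' and the coarse index `floor(local / ratio_coarse)`, each offset by the
#' chromosome's cumulative block counts.
#'
#' @param bins Integer vector of 0-based global fine-bin indices.
#' @param grid A [genomic_grid()].
#' @return A tibble with columns `fine`, `mid`, `coarse` (all 0-based).
#' @examples
#' grid <- genomic_grid(c(chr1 = 10000))
#' multiscale_indices(c(0, 9, 10, 200), grid)
#' @export
multiscale_indices <- function(bins, grid) {
  stopifnot(inherits(grid, "genomic_grid"))
  bins <- as.integer(bins)
  if (length(bins) > 0 && (anyNA(bins) || min(bins) < 0 || max(bins) >= n_bins(grid)))
    stop("bin index out of range")
  ci <- findInterval(bins, grid$layout$fine_offset)
  local <- bins - grid$layout$fine_offset[ci]
  tibble::tibble(
    fine = bins,
    mid = grid$layout$mid_offset[ci] + local %/% grid$ratio_mid,
    coarse = grid$layout$coarse_offset[ci] + local %/% grid$ratio_coarse)
}

#' Convert bp intervals to the set of fine bins they overlap
#'
#' A bin is included iff it overlaps an interval by at least 1 bp.
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open bp coordinates).
#' @param grid A [genomic_grid()].
#' @return Sorted integer vector of 0-based global fine-bin indices.
#' @export
intervals_to_bin_mask <- function(intervals, grid) {
  stopifnot(inherits(grid, "genomic_grid"))
  intervals <- tibble::as_tibble(intervals)
  if (nrow(intervals) == 0) return(integer(0))
  intervals <- validate_regions_loose(intervals, grid)
  bs <- grid$bin_size
  off <- grid$layout$fine_offset[match(intervals$chrom, grid$layout$chrom)]
  bins <- purrr::pmap(list(intervals$start, intervals$end, off),
                      function(s, e, o) {
                        seq.int(s %/% bs, (e - 1L) %/% bs) + o
                      })
  sort(unique(as.integer(unlist(bins))))
}

# like validate_regions but tolerates overlapping/unsorted input
validate_regions_loose <- function(intervals, grid) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$start >= intervals$end))
    stop("malformed interval: start must be < end")
  if (!all(intervals$chrom %in% grid$layout$chrom))
    stop("interval chromosome not on the grid")
  len <- grid$layout$length[match(intervals$chrom, grid$layout$chrom)]
  if (any(intervals$start < 0) || any(intervals$end > len))
    stop("interval outside chromosome bounds")
  intervals
}

#' Fine bins covered by the grid's training regions
#' @param grid A [genomic_grid()] with `training_regions` set.
#' @return Sorted integer vector of 0-based fine-bin indices.
#' @export
training_bins <- function(grid) {
  stopifnot(inherits(grid, "genomic_grid"))
  if (is.null(grid$training_regions))
    stop("grid has no training regions defined")
  intervals_to_bin_mask(grid$training_regions, grid)
}

#' Fine bins belonging to one chromosome
#' @param grid A [genomic_grid()].
#' @param chrom Chromosome name.
#' @return Integer vector of 0-based global fine-bin indices.
#' @export
chromosome_bins <- function(grid, chrom) {
  stopifnot(inherits(grid, "genomic_grid"))
  i <- match(chrom, grid$layout$chrom)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  seq.int(grid$layout$fine_offset[i],
          length.out = grid$layout$n_fine[i])
}

# 0-based mid/coarse row ranges for one chromosome (used by stage-2 freezing
# checks)
chromosome_blocks <- function(grid, chrom) {
  i <- match(chrom, grid$layout$chrom)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  list(
    fine = seq.int(grid$layout$fine_offset[i], length.out = grid$layout$n_fine[i]),
    mid = seq.int(grid$layout$mid_offset[i], length.out = grid$layout$n_mid[i]),
    coarse = seq.int(grid$layout$coarse_offset[i], length.out = grid$layout$n_coarse[i]))
}

#' Serialize a grid to plain-text files
#'
#' Writes a two-column chrom-sizes file, a JSON config block (bin size and
#' resolution ratios), and a BED3 file of training regions (if present).
#'
#' @param grid A [genomic_grid()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_grid <- function(grid, dir) {
  stopifnot(inherits(grid, "genomic_grid"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(grid$layout[, c("chrom", "length")],
                   file.path(dir, "chrom.sizes"), col_names = FALSE)
  jsonlite::write_json(
    list(bin_size = grid$bin_size, ratio_mid = grid$ratio_mid,
         ratio_coarse = grid$ratio_coarse),
    file.path(dir, "grid.json"), auto_unbox = TRUE)
  if (!is.null(grid$training_regions)) {
    readr::write_tsv(grid$training_regions[, c("chrom", "start", "end")],
                     file.path(dir, "training_regions.bed"), col_names = FALSE)
  }
  invisible(dir)
}

#' Read a grid serialized by [write_grid()]
#' @param dir Directory containing `chrom.sizes`, `grid.json`, and optionally
#'   `training_regions.bed`.
#' @return A [genomic_grid()].
#' @export
read_grid <- function(dir) {
  sizes <- readr::read_tsv(file.path(dir, "chrom.sizes"),
                           col_names = c("chrom", "length"),
                           col_types = "ci", progress = FALSE)
  cfg <- jsonlite::read_json(file.path(dir, "grid.json"), simplifyVector = TRUE)
  regions <- NULL
  bedfile <- file.path(dir, "training_regions.bed")
  if (file.exists(bedfile)) regions <- read_bed3(bedfile)
  genomic_grid(sizes, bin_size = cfg$bin_size, ratio_mid = cfg$ratio_mid,
               ratio_coarse = cfg$ratio_coarse, training_regions = regions)
}
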