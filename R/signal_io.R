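#' Read a bedGraph signal track
#'
#' Uses the standard bedGraph reader and returns the runs as a tibble in
#' 0-based half-open coordinates.
#'
#' @param path Path to a 4-column bedGraph file.
#' @return Tibble with columns `chrom`, `start`, `end`, `value`, sorted by
#'   chromosome and start.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1L,
                 end = GenomicRanges::end(gr),
                 value = as.numeric(gr$score)) |>
    dplyr::arrange(.data$chrom, .data$start)
}

# BED3 reader (regions, annotations)
read_bed3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1L,
                 end = GenomicRanges::end(gr))
}

write_bed3 <- function(regions, path) {
  readr::write_tsv(tibble::as_tibble(regions)[, c("chrom", "start", "end")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Choose which replicate of an experiment to use
#'
#' Prefers the pooled replicate when present; otherwise takes the second
#' replicate in submission (manifest) order; with a single candidate, that
#' one.
#'
#' @param available Character vector of replicate labels, in submission order.
#' @return The chosen label.
#' @examples
#' select_replicate(c("rep1", "pooled"))  # "pooled"
#' select_replicate(c("rep1", "rep2"))    # "rep2"
#' @export
select_replicate <- function(available) {
  available <- as.character(available)
  if (length(available) == 0) stop("no replicates available")
  if ("pooled" %in% available) return("pooled")
  if (length(available) >= 2) return(available[2])
  available[1]
}

#' Bin a raw signal track to the grid
#'
#' Each fine bin receives the base-pair-weighted mean of the run values
#' covering it; bases not covered by any run contribute value 0. A partial
#' trailing bin at a chromosome end averages over the bases that exist.
#'
#' @param track Tibble of runs with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open bp), non-overlapping within each chromosome, e.g.
#'   from [read_bedgraph()].
#' @param grid A [genomic_grid()].
#' @return Numeric vector with one entry per fine bin of the grid.
#' @export
bin_signal <- function(track, grid) {
  stopifnot(inherits(grid, "genomic_grid"))
  track <- tibble::as_tibble(track)
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(track)))
  if (!all(track$chrom %in% grid$layout$chrom))
    stop("track chromosome not on the grid")
  if (any(!is.finite(track$value))) stop("track values must be finite")
  if (any(track$start >= track$end)) stop("malformed run: start must be < end")
  len <- grid$layout$length[match(track$chrom, grid$layout$chrom)]
  if (any(track$start < 0) || any(track$end > len))
    stop("run exceeds chromosome length")
  ov <- track |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::summarise(bad = any(.data$start[-1] < .data$end[-length(.data$end)]),
                     .groups = "drop")
  if (any(ov$bad, na.rm = TRUE)) stop("runs overlap within a chromosome")

  bs <- grid$bin_size
  widths <- bin_widths(grid)
  out <- numeric(n_bins(grid))
  off <- grid$layout$fine_offset[match(track$chrom, grid$layout$chrom)]
  # accumulate value * (covered fraction of the bin); a bin fully covered by
  # a single run contributes exactly its value, so bin-aligned tracks
  # round-trip bit-for-bit
  for (i in seq_len(nrow(track))) {
    s <- track$start[i]; e <- track$end[i]; v <- track$value[i]; o <- off[i]
    b1 <- s %/% bs; b2 <- (e - 1L) %/% bs
    if (b1 == b2) {
      j <- o + b1 + 1L
      out[j] <- out[j] + v * ((e - s) / widths[j])
    } else {
      j1 <- o + b1 + 1L; j2 <- o + b2 + 1L
      out[j1] <- out[j1] + v * (((b1 + 1) * bs - s) / widths[j1])
      out[j2] <- out[j2] + v * ((e - b2 * bs) / widths[j2])
      if (b2 > b1 + 1) {
        mid <- (o + b1 + 2L):(o + b2)
        out[mid] <- out[mid] + v * (bs / widths[mid])
      }
    }
  }
  out
}

# bp width of every fine bin (trailing bins may be short)
bin_widths <- function(grid) {
  unlist(lapply(seq_len(nrow(grid$layout)), function(i) {
    nf <- grid$layout$n_fine[i]
    w <- rep(grid$bin_size, nf)
    w[nf] <- grid$layout$length[i] - (nf - 1) * grid$bin_size
    w
  }), use.names = FALSE)
}

#' Variance-stabilizing transform for binned signal
#'
#' The inverse hyperbolic sine, `ln(x + sqrt(x^2 + 1))`, applied elementwise.
#' It compresses the heavy right tail of epigenomic signal while being linear
#' near zero; the model trains and is evaluated on this scale.
#'
#' @param x Numeric vector of binned signal values.
#' @return Transformed vector.
#' @export
arcsinh_transform <- function(x) {
  if (any(!is.finite(x))) stop("input must be finite")
  asinh(x)
}

#' Inverse of [arcsinh_transform()]
#' @param y Numeric vector on the transformed scale.
#' @return Signal on the original scale, `sinh(y)`.
#' @export
inverse_transform <- function(y) {
  if (any(!is.finite(y))) stop("input must be finite")
  sinh(y)
}

#' Write a per-bin signal vector as a bedGraph track
#'
#' Adjacent equal-valued bins are run-length merged. Numeric values are
#' written with shortest round-trip formatting, so
#' `bin_signal(read_bedgraph(path), grid)` reproduces the input vector
#' exactly.
#'
#' @param values Numeric vector, one entry per fine bin of `grid`.
#' @param grid A [genomic_grid()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_track <- function(values, grid, path) {
  stopifnot(inherits(grid, "genomic_grid"))
  if (length(values) != n_bins(grid))
    stop("value vector length must equal the grid bin count")
  if (any(!is.finite(values))) stop("values must be finite")
  runs <- purrr::map_dfr(seq_len(nrow(grid$layout)), function(i) {
    nf <- grid$layout$n_fine[i]
    v <- values[grid$layout$fine_offset[i] + seq_len(nf)]
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths
    tibble::tibble(chrom = grid$layout$chrom[i],
                   start = starts_bin * grid$bin_size,
                   end = pmin(ends_bin * grid$bin_size, grid$layout$length[i]),
                   value = r$values)
  })
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(runs, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read an experiment manifest
#'
#' A manifest is a TSV with columns `biosample`, `assay`, `replicate`,
#' `path`, one row per available replicate track.
#'
#' @param path Path to the manifest TSV.
#' @return Tibble with those four columns.
#' @export
read_manifest <- function(path) {
  m <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  stopifnot(all(c("biosample", "assay", "replicate", "path") %in% names(m)))
  m
}

#' Load a signal tensor from a manifest of bedGraph tracks
#'
#' For each (biosample, assay) pair, one replicate is chosen with
#' [select_replicate()] (manifest order is submission order), its track is
#' binned to the grid, and the arcsinh transform is applied (binning first,
#' transform second).
#'
#' @param manifest Tibble from [read_manifest()], or a path to one. Relative
#'   track paths are resolved against the manifest's directory when a path is
#'   given.
#' @param grid A [genomic_grid()].
#' @param transform Apply [arcsinh_transform()] after binning (default TRUE).
#' @return A [track_tensor()].
#' @export
load_tensor <- function(manifest, grid, transform = TRUE) {
  base <- "."
  if (is.character(manifest) && length(manifest) == 1) {
    base <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  manifest <- tibble::as_tibble(manifest)
  chosen <- manifest |>
    dplyr::group_by(.data$biosample, .data$assay) |>
    dplyr::summarise(path = .data$path[match(select_replicate(.data$replicate),
                                             .data$replicate)],
                     .groups = "drop")
  vals <- purrr::map(chosen$path, function(p) {
    if (!file.exists(p)) p <- file.path(base, p)
    v <- bin_signal(read_bedgraph(p), grid)
    if (transform) arcsinh_transform(v) else v
  })
  track_tensor(do.call(rbind, vals), chosen[, c("biosample", "assay")],
               grid = grid)
}
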