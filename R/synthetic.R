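#' Specification for a synthetic epigenomic compendium
#'
#' The generator emulates the structure of a real compendium at desk scale:
#' arcsinh-scale non-negative signal with peak loci shared across biosamples
#' plus biosample-specific deviations (controlled by `mixing`), heavy-tailed
#' per-assay coverage counts in the observation mask, and a configurable
#' fraction of cells observed. Ground truth is produced by a known
#' ("teacher") decoder over latent factors, so model realizability and
#' parameter recovery can be tested exactly.
#'
#' @param n_biosamples,n_assays Axis sizes (defaults 10 and 12).
#' @param n_bins Total fine bins (default 4000 of 25 bp).
#' @param bin_size Fine bin width in bp.
#' @param n_chromosomes Number of equal-sized chromosomes (default 1).
#' @param model_cfg A [model_config()] giving the latent dimensions of the
#'   teacher (and, in `"matched"` mode, of the student).
#' @param decoder Teacher decoder: `"matched"` (same architecture as the
#'   package's model, non-negative output head — data exactly realizable by
#'   a model of the same configuration), `"mlp"` (independent MLP, rectified
#'   output), or `"linear"` (rectified linear map).
#' @param teacher_hidden Teacher hidden width (default 16; less than the
#'   student's so a matched student can fit it).
#' @param noise_sd Gaussian noise sd on the arcsinh scale (default 0.1).
#' @param observed_fraction Fraction of cells observed (default 0.35, i.e.
#'   65% missing; real compendia range from ~88.6% to ~99.7% missing, but a
#'   10 x 12 matrix needs denser observation to be trainable at all).
#' @param mixing Biosample-specificity weight in `[0, 1]`: 0 makes every
#'   biosample identical (the average-activity baseline is then the
#'   MSE-optimal predictor up to noise); 0.5 and above gives strongly
#'   biosample-specific tracks.
#' @param peak_rate Expected peaks per bin per fine latent dimension.
#' @param background Baseline arcsinh-scale signal level added everywhere
#'   (default 0.4), keeping ground truth strictly positive so that
#'   rectifying noisy observations at zero is a rare event.
#' @param signal_sd Target sd of the noiseless signal around the background.
#' @param training_fraction Fraction of each chromosome covered by the
#'   grid's training regions (default 0.25).
#' @param genome_occupancy Fraction of each genomic factor dimension the
#'   teacher actually uses (default 0.6; remaining columns are zero),
#'   mirroring the full-scale situation where latent dimensionalities are
#'   generous relative to the data's intrinsic structure.
#' @param seed Integer seed; everything is deterministic given it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_biosamples = 10, n_assays = 12, n_bins = 4000,
                           bin_size = 25, n_chromosomes = 1,
                           model_cfg = desk_config(),
                           decoder = c("matched", "mlp", "linear"),
                           teacher_hidden = 16, noise_sd = 0.1,
                           observed_fraction = 0.35, mixing = 0.5,
                           peak_rate = 0.004, background = 0.4,
                           signal_sd = 0.6, training_fraction = 0.25,
                           genome_occupancy = 0.6, seed = 1) {
  decoder <- match.arg(decoder)
  if (observed_fraction <= 0 || observed_fraction > 1)
    stop("observed_fraction must be in (0, 1]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (mixing < 0 || mixing > 1) stop("mixing must be in [0, 1]")
  if (n_biosamples <= 0 || n_assays <= 0 || n_bins <= 0)
    stop("all sizes must be positive")
  structure(as.list(environment()), class = "synthetic_spec")
}

# peak-structured genomic profile: sum of Gaussian bumps at random loci
peak_profile <- function(n, rate) {
  npk <- stats::rpois(1, n * rate)
  p <- numeric(n)
  if (npk == 0) return(p)
  centers <- stats::runif(npk, 1, n)
  widths <- stats::runif(npk, 2, 8)
  heights <- stats::runif(npk, 0.5, 2)
  x <- seq_len(n)
  for (k in seq_len(npk)) {
    lo <- max(1, floor(centers[k] - 4 * widths[k]))
    hi <- min(n, ceiling(centers[k] + 4 * widths[k]))
    p[lo:hi] <- p[lo:hi] +
      heights[k] * exp(-0.5 * ((x[lo:hi] - centers[k]) / widths[k])^2)
  }
  p
}

# evenly spaced training-region blocks covering `fraction` of each chromosome
default_training_regions <- function(layout, bin_size, fraction,
                                     blocks_per_chrom = 5) {
  purrr::map_dfr(seq_len(nrow(layout)), function(i) {
    nf <- layout$n_fine[i]
    block <- max(1L, floor(nf * fraction / blocks_per_chrom))
    starts <- floor(seq(0, nf - block, length.out = blocks_per_chrom))
    tibble::tibble(chrom = layout$chrom[i],
                   start = starts * bin_size,
                   end = pmin((starts + block) * bin_size, layout$length[i]))
  })
}

# the teacher occupies only `genome_occupancy` of each genomic factor
# dimension (remaining columns are zero): at full scale the model's genomic
# dimensionalities are deliberately generous relative to the latent
# structure of the data, and the spare directions are what lets a retrained
# model absorb new activity types without displacing the old ones
teacher_genome_factors <- function(spec, n_fine, n_mid, n_coarse) {
  cfg <- spec$model_cfg
  used <- function(d) max(1L, ceiling(d * spec$genome_occupancy))
  pad <- function(m, d) cbind(m, matrix(0, nrow(m), d - ncol(m)))
  fine <- vapply(seq_len(used(cfg$d_fine)),
                 function(j) peak_profile(n_fine, spec$peak_rate),
                 numeric(n_fine))
  mid <- matrix(stats::rnorm(n_mid * used(cfg$d_mid), 0, 0.5), n_mid)
  coarse <- matrix(stats::rnorm(n_coarse * used(cfg$d_coarse), 0, 0.5), n_coarse)
  list(fine = pad(fine, cfg$d_fine), mid = pad(mid, cfg$d_mid),
       coarse = pad(coarse, cfg$d_coarse))
}

teacher_decoder <- function(spec) {
  cfg <- spec$model_cfg
  th <- spec$teacher_hidden
  if (spec$decoder == "linear") {
    return(list(kind = "linear", w = stats::rnorm(cfg$d_in), scale = 1))
  }
  net <- list(W1 = glorot(cfg$d_in, th), b1 = numeric(th),
              W2 = glorot(th, th), b2 = numeric(th),
              w_out = glorot(th, 1L), b_out = 0)
  if (spec$decoder == "matched") net$w_out <- abs(net$w_out)
  list(kind = spec$decoder, net = net, scale = 1)
}

teacher_raw_output <- function(teacher, X) {
  if (teacher$kind == "linear") return(as.vector(X %*% teacher$w))
  forward_pass(teacher$net, X)$yhat
}

# ground-truth arcsinh signal for a set of cells given teacher latents;
# returns a cells x bins matrix
teacher_truth <- function(spec, teacher, bio_rows, assay_rows, G, bi, ai) {
  n <- length(bi)
  out <- matrix(0, n, nrow(G))
  for (i in seq_len(n)) {
    X <- cbind(matrix(bio_rows[bi[i], ], nrow(G), ncol(bio_rows), byrow = TRUE),
               matrix(assay_rows[ai[i], ], nrow(G), ncol(assay_rows), byrow = TRUE),
               G)
    out[i, ] <- teacher_raw_output(teacher, X)
  }
  out
}

# heavy-tailed per-assay coverage counts summing to `total`, each assay
# observed at least `min_per` times, none more than n_biosamples; the floor
# mirrors a core compendium's minimum-coverage inclusion rule
coverage_counts <- function(n_assays, n_biosamples, total, min_per = 3) {
  min_per <- max(1L, min(min_per, total %/% n_assays))
  w <- exp(stats::rnorm(n_assays, 0, 1))
  counts <- pmin(pmax(round(total * w / sum(w)), min_per), n_biosamples)
  # largest-remainder style fix-up to hit the exact total
  guard <- 0
  while (sum(counts) != total && guard < 10000) {
    if (sum(counts) > total) {
      i <- which(counts > min_per)
      i <- i[which.max(counts[i])]
      counts[i] <- counts[i] - 1L
    } else {
      i <- which(counts < n_biosamples)
      i <- i[which.min(counts[i])]
      counts[i] <- counts[i] + 1L
    }
    guard <- guard + 1
  }
  counts
}

#' Generate a synthetic compendium with known latent structure
#'
#' Deterministic given `spec$seed`. Ground truth is the teacher decoder
#' applied to teacher latents; observed values add Gaussian noise on the
#' arcsinh scale and are rectified at 0; the observation mask has
#' heavy-tailed per-assay coverage and matches the requested observed
#' fraction to the cell.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_compendium`:
#'   `tensor` (observed [track_tensor()]), `grid`, `truth` (noiseless full
#'   cells x bins matrix), `noisy` (noisy rectified full matrix),
#'   `cells_full` (cell order of the full matrices), `teacher` (latents and
#'   decoder), `annotations` (promoters / gene bodies / enhancers),
#'   `labels` (peak-label tibble for the aggregate profile), and `spec`.
#' @export
generate_compendium <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  per_chrom <- ceiling(spec$n_bins / spec$n_chromosomes)
  sizes <- rep(per_chrom, spec$n_chromosomes)
  sizes[spec$n_chromosomes] <- spec$n_bins - per_chrom * (spec$n_chromosomes - 1)
  chroms <- tibble::tibble(chrom = paste0("chrS", seq_len(spec$n_chromosomes)),
                           length = sizes * spec$bin_size)
  grid0 <- genomic_grid(chroms, bin_size = spec$bin_size)
  grid <- genomic_grid(chroms, bin_size = spec$bin_size,
                       training_regions = default_training_regions(
                         grid0$layout, spec$bin_size, spec$training_fraction))

  biosamples <- paste0("bio", sprintf("%02d", seq_len(spec$n_biosamples)))
  assays <- paste0("assay", sprintf("%02d", seq_len(spec$n_assays)))
  cfg <- spec$model_cfg
  n_cells <- spec$n_biosamples * spec$n_assays

  withr::with_seed(spec$seed, {
    gf <- teacher_genome_factors(spec, sum(grid$layout$n_fine),
                                 sum(grid$layout$n_mid),
                                 sum(grid$layout$n_coarse))
    base_row <- stats::rnorm(cfg$d_biosample, 0, 0.6)
    unique_rows <- matrix(stats::rnorm(spec$n_biosamples * cfg$d_biosample, 0, 0.6),
                          spec$n_biosamples)
    bio_rows <- matrix(base_row, spec$n_biosamples, cfg$d_biosample,
                       byrow = TRUE) + spec$mixing * unique_rows
    assay_rows <- matrix(stats::rnorm(spec$n_assays * cfg$d_assay, 0, 0.6),
                         spec$n_assays)
    teacher <- teacher_decoder(spec)

    rows <- bin_rows(grid, seq.int(0L, n_bins(grid) - 1L))
    G <- cbind(gf$fine[rows$fine, , drop = FALSE],
               gf$mid[rows$mid, , drop = FALSE],
               gf$coarse[rows$coarse, , drop = FALSE])
    cells_full <- tibble::tibble(
      biosample = rep(biosamples, each = spec$n_assays),
      assay = rep(assays, spec$n_biosamples))
    bi <- match(cells_full$biosample, biosamples)
    ai <- match(cells_full$assay, assays)
    raw <- teacher_truth(spec, teacher, bio_rows, assay_rows, G, bi, ai)
    s <- spec$signal_sd / stats::sd(raw)
    if (teacher$kind == "linear") {
      teacher$w <- teacher$w * s
    } else {
      teacher$net$w_out <- teacher$net$w_out * s
    }
    raw <- raw * s
    truth <- if (teacher$kind == "matched") raw + spec$background
             else pmax(raw, 0) + spec$background
    if (teacher$kind == "matched") teacher$net$b_out <- spec$background
    teacher$latents <- list(biosample = bio_rows, assay = assay_rows,
                            fine = gf$fine, mid = gf$mid, coarse = gf$coarse)
    teacher$base_biosample_row <- base_row

    noisy <- pmax(truth + matrix(stats::rnorm(length(truth), 0, spec$noise_sd),
                                 nrow(truth)), 0)

    total <- round(spec$observed_fraction * n_cells)
    if (total > n_cells) stop("requested observed cells exceed capacity")
    counts <- coverage_counts(spec$n_assays, spec$n_biosamples, total)
    # deal each assay's tracks to the currently least-covered biosamples
    # (random tie-breaking): per-assay counts stay heavy-tailed while
    # per-biosample coverage stays balanced, the desk-scale analog of a
    # core compendium's minimum-coverage rule
    per_bio <- integer(spec$n_biosamples)
    observed <- purrr::map(sample(seq_len(spec$n_assays)), function(a) {
      pref <- order(per_bio + stats::runif(spec$n_biosamples))
      b <- pref[seq_len(counts[a])]
      per_bio[b] <<- per_bio[b] + 1L
      (b - 1L) * spec$n_assays + a
    })
    obs_idx <- sort(unlist(observed))
  })

  tensor <- track_tensor(noisy[obs_idx, , drop = FALSE],
                         cells_full[obs_idx, ],
                         biosamples = biosamples, assays = assays, grid = grid)
  profile <- colMeans(truth)
  annotations <- derive_annotations(profile, grid)
  labels <- labels_from_signal(profile[chromosome_bins(grid, grid$layout$chrom[1]) + 1L],
                               bin_size = spec$bin_size)
  structure(list(tensor = tensor, grid = grid, truth = truth, noisy = noisy,
                 cells_full = cells_full, teacher = teacher,
                 annotations = annotations, labels = labels, spec = spec),
            class = "synthetic_compendium")
}

# promoters / gene bodies / enhancers derived from the aggregate profile:
# strongest merged peak intervals are promoters (with a downstream gene
# body), the next tier enhancers
derive_annotations <- function(profile, grid) {
  thr <- stats::quantile(profile, 0.96)
  hot <- which(profile > thr)
  if (length(hot) < 4) hot <- order(profile, decreasing = TRUE)[1:20]
  runs <- split(hot, cumsum(c(1, diff(hot) != 1)))
  strength <- vapply(runs, function(r) max(profile[r]), numeric(1))
  ord <- order(strength, decreasing = TRUE)
  half <- ceiling(length(ord) / 2)
  to_intervals <- function(run_list, extend = 0L) {
    purrr::map_dfr(run_list, function(r) {
      b0 <- min(r) - 1L; b1 <- max(r)   # 0-based half-open in bins
      ci <- findInterval(b0, grid$layout$fine_offset)
      lo <- grid$layout$fine_offset[ci]
      hi <- lo + grid$layout$n_fine[ci]
      b1 <- min(b1 + extend, hi)
      tibble::tibble(chrom = grid$layout$chrom[ci],
                     start = (b0 - lo) * grid$bin_size,
                     end = min((b1 - lo) * grid$bin_size,
                               grid$layout$length[ci]))
    })
  }
  proms <- runs[ord[seq_len(half)]]
  enhs <- runs[ord[setdiff(seq_along(ord), seq_len(half))]]
  if (length(enhs) == 0) enhs <- proms
  list(promoters = merge_intervals(to_intervals(proms)),
       gene_bodies = merge_intervals(to_intervals(proms, extend = 40L)),
       enhancers = merge_intervals(to_intervals(enhs)))
}

merge_intervals <- function(iv) {
  iv |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(grp = cumsum(.data$start > dplyr::lag(cummax(.data$end),
                                                        default = -1))) |>
    dplyr::group_by(.data$chrom, .data$grp) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop") |>
    dplyr::select("chrom", "start", "end")
}

#' Derive window peak labels from a signal track
#'
#' Windows (200 bp, 50 bp stride by default) whose aggregated signal exceeds
#' the given quantile are positive; non-positive windows within
#' `flank_windows` of a positive are ambiguous (emulating peak flanks); the
#' rest are negative.
#'
#' @param track Numeric per-bin vector for one chromosome (ground truth or
#'   observed signal).
#' @param bin_size,window,stride As in [aggregate_to_windows()].
#' @param threshold_quantile Quantile of window values defining positives
#'   (default 0.95); must be in (0, 1).
#' @param flank_windows Ambiguity flank width in windows (default 2).
#' @return Tibble with columns `start`, `end` (bp), `value` (window mean),
#'   `label` in `{"positive", "ambiguous", "negative"}`.
#' @export
labels_from_signal <- function(track, bin_size = 25, window = 200,
                               stride = 50, threshold_quantile = 0.95,
                               flank_windows = 2) {
  if (threshold_quantile <= 0 || threshold_quantile >= 1)
    stop("threshold_quantile must be in (0, 1)")
  agg <- aggregate_to_windows(track, bin_size, window, stride)
  thr <- stats::quantile(agg, threshold_quantile)
  positive <- agg > thr
  label <- rep("negative", length(agg))
  if (any(positive)) {
    near <- which(vapply(seq_along(agg), function(k) {
      any(positive[max(1, k - flank_windows):min(length(agg), k + flank_windows)])
    }, logical(1)))
    label[near] <- "ambiguous"
  }
  label[positive] <- "positive"
  starts <- (seq_along(agg) - 1L) * stride
  tibble::tibble(start = starts, end = starts + window, value = agg,
                 label = label)
}

#' Generate additional sparse experiments around a core compendium
#'
#' Adds new biosamples and new assays to a core synthetic compendium,
#' including `novel_assays` whose genomic signal comes from independent
#' latents — an activity type statistically unlike anything in the core set,
#' which a model with frozen genomic factors cannot represent. For each
#' assay the additional experiments' biosamples are evenly partitioned into
#' training and test halves.
#'
#' @param core A `synthetic_compendium` from [generate_compendium()].
#' @param n_new_biosamples,n_new_assays New axis element counts (defaults 8
#'   and 4).
#' @param novel_assays How many of the new assays carry novel activity
#'   (default 2): many of a sparse compendium's missing assays are
#'   knockdown-transcription style activity absent from the core set.
#' @param core_assays_per_biosample Size of the fixed panel of most-covered
#'   core assays observed in every new biosample (default 4) — the
#'   accessibility-like tracks every sparsely characterized biosample has.
#' @param biosamples_per_new_assay How many of the new biosamples each new
#'   assay is observed in (default 8).
#' @param seed Integer seed.
#' @return List with `tensor` (additional observed cells; axes = core axes
#'   plus new identifiers), `split` (per-cell `train`/`test` assignment),
#'   `novel_assays` (identifiers), `truth` (noiseless matrix aligned with
#'   the tensor's cells).
#' @export
generate_sparse_additional <- function(core, n_new_biosamples = 8,
                                       n_new_assays = 4, novel_assays = 2,
                                       core_assays_per_biosample = 4,
                                       biosamples_per_new_assay = 10,
                                       seed = 1) {
  stopifnot(inherits(core, "synthetic_compendium"))
  if (novel_assays > n_new_assays)
    stop("novel_assays cannot exceed n_new_assays")
  spec <- core$spec
  cfg <- spec$model_cfg
  teacher <- core$teacher
  grid <- core$grid
  nb <- length(core$tensor$biosamples)

  new_bios <- paste0("newbio", sprintf("%02d", seq_len(n_new_biosamples)))
  new_assays <- paste0("newassay", sprintf("%02d", seq_len(n_new_assays)))
  novel <- utils::head(new_assays, novel_assays)
  if (any(c(new_bios, new_assays) %in%
          c(core$tensor$biosamples, core$tensor$assays)))
    stop("identifier collision with the core compendium")

  all_bios <- c(core$tensor$biosamples, new_bios)
  all_assays <- c(core$tensor$assays, new_assays)

  withr::with_seed(child_seed(seed, 31L), {
    n_extra <- n_new_biosamples + min(biosamples_per_new_assay,
                                      n_new_biosamples)
    new_bio_rows <- matrix(teacher$base_biosample_row, n_extra,
                           cfg$d_biosample, byrow = TRUE) +
      spec$mixing * matrix(stats::rnorm(n_extra * cfg$d_biosample,
                                        0, 0.6), n_extra)
    new_assay_rows <- matrix(stats::rnorm(n_new_assays * cfg$d_assay, 0, 0.6),
                             n_new_assays)
    bio_rows <- rbind(teacher$latents$biosample, new_bio_rows)
    assay_rows <- rbind(teacher$latents$assay, new_assay_rows)

    # novel-activity profiles: independent peak structure per novel assay,
    # with a biosample-specific component at the same mixing weight; each
    # novel assay's track-level mean and sd are drawn from the core
    # compendium's empirical per-track statistics so the novelty is in
    # where the signal sits along the genome, not in its marginal scale
    novel_shared <- lapply(novel, function(a)
      peak_profile(n_bins(grid), spec$peak_rate * 3))
    novel_mean <- rep(stats::median(rowMeans(core$truth)), length(novel))
    novel_sd <- rep(stats::median(apply(core$truth, 1, stats::sd)),
                    length(novel))

    # new biosamples are characterized mostly by the heavily covered core
    # assays (the accessibility-like tracks every sparse biosample has);
    # new assays are observed in the new (sparse) biosamples only, so core
    # factor rows outside the touched assays receive no additional-data
    # gradient at all
    core_cov <- table(factor(core$tensor$cells$assay,
                             levels = core$tensor$assays))
    panel <- core$tensor$assays[order(as.numeric(core_cov),
                                      decreasing = TRUE)][
      seq_len(core_assays_per_biosample)]
    # ordinary new assays live on the panel-characterized new biosamples;
    # novel-activity assays live on a dedicated group of sparse biosamples
    # characterized only by those assays (the knockdown-transcription
    # pattern: a family of related sparse experiments on its own biosamples)
    ordinary <- setdiff(new_assays, novel)
    n_ded <- min(biosamples_per_new_assay, length(new_bios))
    ded_bios <- paste0("novelbio", sprintf("%02d", seq_len(n_ded)))
    all_bios <- c(all_bios, ded_bios)
    cells <- dplyr::bind_rows(
      purrr::map_dfr(new_bios, function(b) {
        tibble::tibble(biosample = b, assay = panel)
      }),
      purrr::map_dfr(ordinary, function(a) {
        b <- sample(new_bios, min(biosamples_per_new_assay, length(new_bios)))
        tibble::tibble(biosample = b, assay = a)
      }),
      purrr::map_dfr(novel, function(a) {
        tibble::tibble(biosample = ded_bios, assay = a)
      })) |>
      dplyr::distinct()

    rows <- bin_rows(grid, seq.int(0L, n_bins(grid) - 1L))
    G <- cbind(teacher$latents$fine[rows$fine, , drop = FALSE],
               teacher$latents$mid[rows$mid, , drop = FALSE],
               teacher$latents$coarse[rows$coarse, , drop = FALSE])
    bi <- match(cells$biosample, all_bios)
    ai <- match(cells$assay, all_assays)
    truth <- teacher_truth(spec, teacher, bio_rows, assay_rows, G, bi, ai)
    if (teacher$kind != "matched") truth <- pmax(truth, 0) + spec$background
    for (i in seq_len(nrow(cells))) {
      j <- match(cells$assay[i], novel)
      if (!is.na(j)) {
        specific <- peak_profile(n_bins(grid), spec$peak_rate * 3)
        p <- (1 - spec$mixing) * novel_shared[[j]] + spec$mixing * specific
        p <- (p - mean(p)) / max(stats::sd(p), 1e-8) * novel_sd[j] +
          novel_mean[j]
        truth[i, ] <- pmax(p, 0)
      }
    }
    noisy <- pmax(truth + matrix(stats::rnorm(length(truth), 0, spec$noise_sd),
                                 nrow(truth)), 0)
    # for each assay, its biosamples are evenly partitioned into the
    # fitting ("train") and test halves
    split <- cells |>
      dplyr::group_by(.data$assay) |>
      dplyr::mutate(part = {
        b <- sample(unique(.data$biosample))
        half <- ceiling(length(b) / 2)
        ifelse(.data$biosample %in% b[seq_len(half)], "train", "test")
      }) |>
      dplyr::ungroup()
  })

  tensor <- track_tensor(noisy, cells, biosamples = all_bios,
                         assays = all_assays, grid = grid)
  list(tensor = tensor, split = split, novel_assays = novel, truth = truth)
}

#' Write a synthetic compendium to plain-text fixture files
#'
#' Writes one bedGraph per observed track (arcsinh scale by default), a
#' manifest TSV, the grid files, BED annotations, and the peak-label table.
#'
#' @param compendium A `synthetic_compendium`.
#' @param dir Output directory.
#' @param raw Write tracks on the original (inverse-transformed) scale
#'   instead of the arcsinh scale.
#' @return The manifest path, invisibly.
#' @export
write_fixtures <- function(compendium, dir, raw = FALSE) {
  stopifnot(inherits(compendium, "synthetic_compendium"))
  dir.create(file.path(dir, "tracks"), recursive = TRUE, showWarnings = FALSE)
  tensor <- compendium$tensor
  grid <- compendium$grid
  paths <- character(nrow(tensor$cells))
  for (i in seq_len(nrow(tensor$cells))) {
    paths[i] <- file.path("tracks", sprintf("%s_%s.bedGraph",
                                            tensor$cells$biosample[i],
                                            tensor$cells$assay[i]))
    v <- tensor$values[i, ]
    if (raw) v <- inverse_transform(v)
    write_track(v, grid, file.path(dir, paths[i]))
  }
  manifest <- tibble::tibble(biosample = tensor$cells$biosample,
                             assay = tensor$cells$assay,
                             replicate = "pooled", path = paths)
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  write_grid(grid, dir)
  for (nm in names(compendium$annotations))
    write_bed3(compendium$annotations[[nm]], file.path(dir, paste0(nm, ".bed")))
  readr::write_tsv(compendium$labels, file.path(dir, "labels.tsv"))
  invisible(file.path(dir, "manifest.tsv"))
}
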