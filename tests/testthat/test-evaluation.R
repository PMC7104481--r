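test_that("average activity is the positionwise mean over eligible tracks", {
  tt <- track_tensor(rbind(c(1, 1), c(3, 5), c(9, 9)),
                     data.frame(biosample = c("b1", "b2", "b3"),
                                assay = c("h3k", "h3k", "other")))
  expect_equal(average_activity(tt, "h3k", exclude_biosamples = "b2"),
               c(1, 1))
  expect_equal(average_activity(tt, "h3k"), c(2, 3))
  expect_error(average_activity(tt, "h3k",
                                exclude_biosamples = c("b1", "b2")),
               "no eligible")
})

test_that("MSE metrics match brute-force oracles on randomized instances", {
  expect_equal(mse_global(c(0, 1), c(1, 1)), 0.5)
  expect_equal(mse_global(1:4, 1:4), 0)
  expect_error(mse_global(1:3, 1:4), "mismatch")
  withr::with_seed(21, {
    for (i in 1:100) {
      n <- sample(100:400, 1)
      obs <- rnorm(n); imp <- rnorm(n)
      expect_equal(mse_global(obs, imp), oracle_mse(obs, imp),
                   tolerance = 1e-12)
      expect_equal(mse_top1(obs, imp, "observed"),
                   oracle_mse_top1(obs, imp, obs), tolerance = 1e-12)
      expect_equal(mse_top1(obs, imp, "imputed"),
                   oracle_mse_top1(obs, imp, imp), tolerance = 1e-12)
      mask <- sample(0:(n - 1), sample(5:50, 1))
      expect_equal(mse_region(obs, imp, mask),
                   oracle_mse_mask(obs, imp, mask), tolerance = 1e-12)
    }
  })
})

test_that("top-1% selection takes ceil(n/100) positions, ties by position", {
  obs <- c(5, rep(0, 99)); imp <- rep(1, 100)
  expect_equal(mse_top1(obs, imp, "observed"), (5 - 1)^2)  # only position 1
  tied <- rep(1, 150)  # ceil(1.5) = 2 positions, earliest first
  imp2 <- c(0.5, 0.25, rep(1, 148))
  expect_equal(mse_top1(tied, imp2, "observed"), (0.25 + 0.5625) / 2)
  expect_equal(mse_top1(tied, tied, "observed"), 0)
  expect_error(mse_top1(rnorm(99), rnorm(99)), "at least 100")
})

test_that("region MSE over the full mask equals the global MSE", {
  withr::with_seed(22, { obs <- rnorm(300); imp <- rnorm(300) })
  expect_equal(mse_region(obs, imp, 0:299), mse_global(obs, imp))
  expect_equal(mse_region(obs, imp, 7), (obs[8] - imp[8])^2)
  expect_error(mse_region(obs, imp, integer(0)), "empty")
})

test_that("the paired t test matches the textbook formula and edge cases", {
  r <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p_value, 1)
  r <- paired_t(c(2, 4, 6), c(1, 2, 3))  # differences 1, 2, 3
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$t, 3.4641, tolerance = 1e-4)
  expect_equal(r$p_value, 2 * stats::pt(-3.4641016, 2), tolerance = 1e-6)
  r <- paired_t(c(2, 3, 4), c(1, 2, 3))  # constant nonzero differences
  expect_equal(r$p_value, 0)
  withr::with_seed(23, {
    for (i in 1:50) {
      a <- rnorm(sample(5:40, 1)); b <- rnorm(length(a))
      got <- paired_t(a, b)
      want <- oracle_paired_t(a, b)
      expect_equal(got$t, want$t, tolerance = 1e-12)
      expect_equal(got$p_value, want$p, tolerance = 1e-12)
    }
  })
})

test_that("window aggregation averages constituent bins with 200/50 layout", {
  expect_equal(aggregate_to_windows(1:8)[1], 4.5)
  const <- rep(2.5, 40)
  expect_true(all(aggregate_to_windows(const) == 2.5))
  # windows at offsets 0 and 50 bp share 6 of their 8 bins
  v <- rnorm(16)
  w <- aggregate_to_windows(v)
  expect_equal(w[1], mean(v[1:8]))
  expect_equal(w[2], mean(v[3:10]))
  expect_error(aggregate_to_windows(v, bin_size = 25, window = 10), "smaller")
  expect_error(aggregate_to_windows(v, bin_size = 25, window = 210),
               "multiples")
  withr::with_seed(24, {
    for (i in 1:20) {
      v <- rnorm(sample(20:200, 1))
      expect_equal(aggregate_to_windows(v), oracle_window_means(v, 8, 2))
    }
  })
})

test_that("ambiguous windows are dropped from both scores and labels", {
  s <- 1:10 / 10
  lab <- c("positive", "negative", "ambiguous", "negative", "ambiguous",
           "ambiguous", "positive", "ambiguous", "negative", "negative")
  f <- filter_ambiguous(s, lab)
  expect_length(f$scores, 6)
  expect_type(f$labels, "logical")
  expect_equal(sum(f$labels), 2)
  # challenge letter codes accepted
  f2 <- filter_ambiguous(c(0.9, 0.1, 0.5), c("B", "U", "A"))
  expect_equal(f2$labels, c(TRUE, FALSE))
  expect_identical(filter_ambiguous(s, rep(c("positive", "negative"), 5))$scores, s)
  expect_error(filter_ambiguous(1, "ambiguous"), "all windows")
  expect_error(filter_ambiguous(1, "weird"), "unrecognized")
})

test_that("average precision matches hand-worked and brute-force values", {
  expect_equal(average_precision(c(0.9, 0.8, 0.2), c(1, 1, 0)), 1.0)
  expect_equal(average_precision(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)),
               1 * 0.5 + (2 / 3) * 0.5)
  expect_error(average_precision(1:3, c(1, 1, 1)), "one positive and one")
  withr::with_seed(25, {
    for (i in 1:100) {
      n <- sample(20:120, 1)
      scores <- round(runif(n), sample(1:3, 1))  # coarse rounding forces ties
      labels <- runif(n) < 0.3
      if (!any(labels) || all(labels)) next
      expect_equal(average_precision(scores, labels),
                   oracle_average_precision(scores, labels),
                   tolerance = 1e-12)
    }
  })
})

test_that("the break-even point is the precision of the top-P windows", {
  expect_equal(epr(c(0.9, 0.8, 0.2), c(1, 1, 0)), 1.0)
  expect_equal(epr(c(0.9, 0.8, 0.1, 0.05), c(1, 0, 1, 0)), 0.5)
  expect_error(epr(1:3, c(0, 0, 0)), "positive")
  # tie policy: included by default, excluded behind the flag
  s <- c(1, 0.5, 0.5, 0.5); l <- c(1, 1, 0, 0)
  expect_equal(epr(s, l), 0.5)            # all ties enter: 2 pos of 4
  expect_equal(epr(s, l, ties = "exclude"), 1.0)  # exactly top-2
  withr::with_seed(26, {
    for (i in 1:100) {
      n <- sample(20:120, 1)
      scores <- round(runif(n), sample(1:3, 1))
      labels <- runif(n) < 0.4
      if (!any(labels)) next
      e <- epr(scores, labels)
      expect_equal(e, oracle_epr(scores, labels), tolerance = 1e-12)
      expect_lte(e, 1)
      expect_gte(e, 0)
    }
  })
})

test_that("AP and EPR are invariant under strictly monotone score maps", {
  withr::with_seed(27, {
    scores <- runif(80)
    labels <- runif(80) < 0.3
    labels[1] <- TRUE; labels[2] <- FALSE
    for (f in list(function(x) 2 * x + 1, exp, function(x) x^3)) {
      expect_equal(average_precision(f(scores), labels),
                   average_precision(scores, labels))
      expect_equal(epr(f(scores), labels), epr(scores, labels))
    }
  })
})

test_that("the greedy counter partition walks folds across biosamples", {
  exps <- data.frame(biosample = c("A", "A", "A", "B", "B"),
                     assay = paste0("x", 1:5))
  folds <- greedy_fold_partition(exps, k = 2, shuffle = FALSE)
  expect_equal(folds$fold, c(1, 2, 1, 2, 1))  # counter 0,1,2,3,4 mod 2, +1
  expect_equal(folds$fold, oracle_fold_walk(exps, 2))
  expect_error(greedy_fold_partition(exps, k = 1), "at least 2")
})

test_that("fold sizes balance to within one and assignment is seeded", {
  withr::with_seed(28, {
    for (i in 1:30) {
      n <- sample(8:60, 1)
      exps <- data.frame(
        biosample = sample(paste0("b", 1:6), n, TRUE),
        assay = sample(paste0("a", 1:8), n, TRUE))
      k <- sample(2:5, 1)
      f <- greedy_fold_partition(exps, k = k, seed = i)
      sizes <- tabulate(f$fold, k)
      expect_lte(max(sizes) - min(sizes), 1)
      expect_identical(f, greedy_fold_partition(exps, k = k, seed = i))
    }
  })
})

test_that("with enough experiments per label, every fold's training
           complement covers every biosample and assay", {
  # constructed instance: 6 biosamples x 5 assays, fully crossed
  exps <- expand.grid(biosample = paste0("b", 1:6), assay = paste0("a", 1:5),
                      stringsAsFactors = FALSE)
  f <- greedy_fold_partition(exps, k = 5, seed = 3)
  for (fold in 1:5) {
    train <- f[f$fold != fold, ]
    expect_setequal(unique(train$biosample), paste0("b", 1:6))
    expect_setequal(unique(train$assay), paste0("a", 1:5))
  }
  cov <- attr(f, "coverage")
  expect_equal(sum(cov$n), nrow(exps))
})

test_that("compendium evaluation is exact for identity and baseline models", {
  comp <- noiseless_compendium()
  tt <- comp$tensor
  folds <- greedy_fold_partition(tt$cells, k = 5, seed = 4)
  # model == observed data: every metric is zero
  rep0 <- evaluate_compendium(tt, tt$values, annotations = comp$annotations,
                              grid = comp$grid, folds = folds)
  for (m in c("mseGlobal", "mse1obs", "mse1imp", "mseProm", "mseGene",
              "mseEnh")) {
    expect_true(all(rep0[[m]] == 0))
  }
  # model == average activity of the training folds: equals baseline columns
  fold_of <- dplyr::left_join(tt$cells, folds,
                              by = c("biosample", "assay"))$fold
  base_pred <- t(vapply(seq_len(nrow(tt$cells)), function(i) {
    train <- fold_of != fold_of[i]
    keep <- train & tt$cells$assay == tt$cells$assay[i] &
      tt$cells$biosample != tt$cells$biosample[i]
    colMeans(tt$values[keep, , drop = FALSE])
  }, numeric(ncol(tt$values))))
  repb <- evaluate_compendium(tt, base_pred, annotations = comp$annotations,
                              grid = comp$grid, folds = folds)
  expect_equal(repb$mseGlobal, repb$baseline_mseGlobal)
  expect_equal(repb$mse1imp, repb$baseline_mse1imp)
  expect_equal(repb$mseEnh, repb$baseline_mseEnh)
  summ <- tidy(repb)
  expect_s3_class(summ, "tbl_df")
  expect_true(all(c("metric", "model", "baseline", "p_value") %in% names(summ)))
})

test_that("relative reduction reproduces headline percentages", {
  expect_equal(round(relative_reduction(0.0807, 0.0653), 1), 19.1)
  expect_equal(round(relative_reduction(0.115, 0.107)), 7)
  expect_error(relative_reduction(0, 1), "nonzero")
})
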