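test_that("three-step extension leaves every pre-existing parameter intact", {
  setup <- trained_setup()
  model <- setup$model
  comp <- setup$comp
  # synthesize one fitting track for a new biosample from the teacher family
  new_track <- matrix(colMeans(comp$tensor$values[
    comp$tensor$cells$assay == comp$tensor$assays[1], , drop = FALSE]), 1)
  fitting <- track_tensor(new_track,
                          data.frame(biosample = "fresh", assay =
                                       comp$tensor$assays[1]),
                          biosamples = "fresh",
                          assays = comp$tensor$assays)
  ext <- add_axis_element(model, "add_biosample", "fresh", fitting,
                          fit_epochs = 10, fit_batch = 512, seed = 3)
  expect_identical(ext$net, model$net)
  expect_identical(ext$factors$assay, model$factors$assay)
  expect_identical(ext$factors$fine, model$factors$fine)
  expect_identical(ext$factors$biosample[seq_len(nrow(model$factors$biosample)), ],
                   model$factors$biosample)
  expect_equal(nrow(ext$factors$biosample), nrow(model$factors$biosample) + 1)
  # predictions for all pre-existing cells bit-identical
  withr::with_seed(4, bins <- sample(0:(n_bins(comp$grid) - 1), 50))
  for (i in sample(nrow(comp$tensor$cells), 5)) {
    expect_identical(
      predict_track(ext, comp$tensor$cells$biosample[i],
                    comp$tensor$cells$assay[i], bins),
      predict_track(model, comp$tensor$cells$biosample[i],
                    comp$tensor$cells$assay[i], bins))
  }
  expect_equal(attr(ext, "updated_rows"), list(biosample = "fresh"))
  expect_error(add_axis_element(model, "add_biosample",
                                comp$tensor$biosamples[1], fitting),
               "already on")
})

test_that("zero fitting epochs leave the new row at its initialization", {
  setup <- trained_setup()
  comp <- setup$comp
  fitting <- track_tensor(comp$tensor$values[1, , drop = FALSE],
                          data.frame(biosample = "fresh",
                                     assay = comp$tensor$cells$assay[1]),
                          biosamples = "fresh", assays = comp$tensor$assays)
  e0 <- add_axis_element(setup$model, "add_biosample", "fresh", fitting,
                         fit_epochs = 0, seed = 11)
  e0b <- add_axis_element(setup$model, "add_biosample", "fresh", fitting,
                          fit_epochs = 0, seed = 11)
  new_row <- e0$factors$biosample[nrow(e0$factors$biosample), ]
  expect_identical(new_row, e0b$factors$biosample[nrow(e0b$factors$biosample), ])
  expect_true(all(abs(new_row) <= 0.05))  # untouched embedding-style init
})

test_that("a new biosample fit from one accessibility-like track beats the
           average-activity baseline on its held-out assays", {
  setup <- trained_setup()
  comp <- setup$comp
  spec <- comp$spec
  # generate one extra biosample from the same latent family
  withr::with_seed(55, {
    delta <- spec$mixing * rnorm(spec$model_cfg$d_biosample, 0, 0.6)
  })
  new_row <- comp$teacher$base_biosample_row + delta
  rows <- epitensor:::bin_rows(comp$grid, 0:(n_bins(comp$grid) - 1))
  G <- cbind(comp$teacher$latents$fine[rows$fine, ],
             comp$teacher$latents$mid[rows$mid, ],
             comp$teacher$latents$coarse[rows$coarse, ])
  truth <- vapply(seq_along(comp$tensor$assays), function(a) {
    X <- cbind(matrix(new_row, n_bins(comp$grid), length(new_row),
                      byrow = TRUE),
               matrix(comp$teacher$latents$assay[a, ], n_bins(comp$grid),
                      ncol(comp$teacher$latents$assay), byrow = TRUE), G)
    epitensor:::teacher_raw_output(comp$teacher, X)
  }, numeric(n_bins(comp$grid)))
  withr::with_seed(56, noisy <- pmax(truth + rnorm(length(truth),
                                                   0, spec$noise_sd), 0))
  # fit from the most-covered ("accessibility-like") assay only
  cov <- table(factor(comp$tensor$cells$assay, levels = comp$tensor$assays))
  fit_assay <- comp$tensor$assays[which.max(cov)]
  fit_idx <- match(fit_assay, comp$tensor$assays)
  fitting <- track_tensor(t(noisy[, fit_idx]),
                          data.frame(biosample = "fresh", assay = fit_assay),
                          biosamples = "fresh", assays = comp$tensor$assays)
  # a desk-scale epoch covers ~1000x fewer genomic positions than a
  # full-scale epoch, so the fitting budget is expressed in comparable
  # gradient-step counts rather than the full-scale epoch default
  ext <- add_axis_element(setup$model, "add_biosample", "fresh", fitting,
                          fit_epochs = 200, fit_batch = 128, seed = 57)
  held <- setdiff(seq_along(comp$tensor$assays), fit_idx)
  model_mse <- mean(vapply(held, function(a) {
    mean((predict_track(ext, "fresh", comp$tensor$assays[a]) - noisy[, a])^2)
  }, numeric(1)))
  base_mse <- mean(vapply(held, function(a) {
    base <- average_activity(comp$tensor, comp$tensor$assays[a])
    mean((base - noisy[, a])^2)
  }, numeric(1)))
  expect_lt(model_mse, base_mse)
})

test_that("adding two biosamples commutes at the prediction level", {
  setup <- trained_setup()
  comp <- setup$comp
  mk <- function(id, row) track_tensor(
    comp$tensor$values[row, , drop = FALSE],
    data.frame(biosample = id, assay = comp$tensor$cells$assay[row]),
    biosamples = id, assays = comp$tensor$assays)
  fa <- mk("extraA", 1); fb <- mk("extraB", 2)
  ab <- add_axis_element(add_axis_element(setup$model, "add_biosample",
                                          "extraA", fa, seed = 5),
                         "add_biosample", "extraB", fb, seed = 6)
  ba <- add_axis_element(add_axis_element(setup$model, "add_biosample",
                                          "extraB", fb, seed = 6),
                         "add_biosample", "extraA", fa, seed = 5)
  bins <- 0:99
  for (a in comp$tensor$assays[1:3]) {
    expect_identical(predict_track(ab, "extraA", a, bins),
                     predict_track(ba, "extraA", a, bins))
    expect_identical(predict_track(ab, "extraB", a, bins),
                     predict_track(ba, "extraB", a, bins))
  }
})

test_that("freeze-extension keeps the decoder and genomic factors bit-equal", {
  setup <- trained_setup()
  comp <- setup$comp
  add <- generate_sparse_additional(comp, seed = 77)
  fz <- freeze_extend(setup$model, add$tensor,
                      train_config(epochs = 5, batch_size = 512, seed = 78),
                      seed = 78)
  expect_identical(fz$net, setup$model$net)
  expect_identical(fz$factors$fine, setup$model$factors$fine)
  expect_identical(fz$factors$mid, setup$model$factors$mid)
  expect_identical(fz$factors$coarse, setup$model$factors$coarse)
  expect_false(identical(
    fz$factors$assay[seq_len(nrow(setup$model$factors$assay)), ],
    setup$model$factors$assay))
  upd <- attr(fz, "updated_rows")
  expect_setequal(upd$biosample, unique(add$tensor$cells$biosample))
  expect_setequal(upd$assay, unique(add$tensor$cells$assay))
})

test_that("retraining pools cells, is seed-deterministic, and fine-tuning
           with zero epochs just appends initialized rows", {
  setup <- trained_setup()
  comp <- setup$comp
  add <- generate_sparse_additional(comp, seed = 88)
  add_train <- subset_cells(add$tensor, add$split$part == "train")
  pooled <- pool_tensors(comp$tensor, add_train)
  expect_equal(nrow(pooled$cells),
               nrow(comp$tensor$cells) + nrow(add_train$cells))

  cfg <- train_config(epochs = 3, batch_size = 256, seed = 90)
  r1 <- retrain_from_scratch(comp$tensor, add_train, comp$grid,
                             desk_config(), cfg, seed = 91)
  r2 <- retrain_from_scratch(comp$tensor, add_train, comp$grid,
                             desk_config(), cfg, seed = 91)
  expect_identical(r1$factors, r2$factors)
  expect_identical(r1$net, r2$net)
  # sanity on a trained model: test error finite and below the raw variance
  # of the test signal (the no-information bound)
  r3 <- retrain_from_scratch(comp$tensor, add_train, comp$grid,
                             desk_config(),
                             train_config(epochs = 250, batch_size = 256,
                                          seed = 90),
                             stage2_config = train_config(epochs = 120,
                                                          batch_size = 256,
                                                          seed = 93),
                             seed = 91)
  add_test <- subset_cells(add$tensor, add$split$part == "test")
  mse <- mean((predict_cells(r3, add_test$cells) - add_test$values)^2)
  expect_true(is.finite(mse))
  expect_lt(mse, stats::var(as.vector(add_test$values)))

  ft0 <- fine_tune(setup$model, comp$tensor, add_train,
                   train_config(epochs = 0, batch_size = 256, seed = 92),
                   seed = 92)
  expect_identical(ft0$net, setup$model$net)
  expect_identical(
    ft0$factors$biosample[seq_len(nrow(setup$model$factors$biosample)), ],
    setup$model$factors$biosample)
  expect_true(all(c(add_train$biosamples) %in% ft0$biosamples))
})
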