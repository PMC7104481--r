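test_that("epoch sampling visits each region bin once with uniform cells", {
  tt <- random_cells_tensor(3, 3, 1, 20, seed = 1)
  ep <- sample_epoch(tt, 0:9, seed = 2)
  expect_equal(sort(ep$bin), 0:9)
  expect_true(all(ep$row == 1))

  tt4 <- random_cells_tensor(4, 4, 4, 5, seed = 3)
  big <- sample_epoch(tt4, 0:9999, seed = 4)
  counts <- tabulate(big$row, 4)
  sigma <- sqrt(10000 * 0.25 * 0.75)
  expect_true(all(abs(counts - 2500) < 3 * sigma))

  expect_identical(sample_epoch(tt4, 0:99, seed = 5),
                   sample_epoch(tt4, 0:99, seed = 5))
  expect_false(identical(sample_epoch(tt4, 0:99, seed = 5),
                         sample_epoch(tt4, 0:99, seed = 6)))
  expect_error(sample_epoch(tt4, integer(0), seed = 1), "empty")
})

test_that("zero-epoch training is the identity and loss is reproducible", {
  comp <- noiseless_compendium()
  m <- init_model(comp$tensor$biosamples, comp$tensor$assays, comp$grid,
                  desk_config(), seed = 1)
  out <- train_stage1(m, comp$tensor, train_config(epochs = 0,
                                                   batch_size = 64, seed = 1))
  expect_identical(out$model$factors, m$factors)
  expect_identical(out$model$net, m$net)

  cfg <- train_config(epochs = 3, batch_size = 128, seed = 42)
  f1 <- train_stage1(m, comp$tensor, cfg)
  f2 <- train_stage1(m, comp$tensor, cfg)
  expect_identical(f1$log$loss, f2$log$loss)
  expect_identical(f1$model$factors, f2$model$factors)
})

test_that("joint training fits a realizable compendium on the regions", {
  comp <- noiseless_compendium()
  setup <- trained_setup()  # default-noise compendium, full two-stage run
  m <- init_model(comp$tensor$biosamples, comp$tensor$assays, comp$grid,
                  desk_config(), seed = 1)
  region <- training_bins(comp$grid)
  init_mse <- model_loss(m, comp$tensor, region)
  fit <- train_stage1(m, comp$tensor,
                      train_config(epochs = 500, batch_size = 256, seed = 7))
  final <- model_loss(fit$model, comp$tensor, region)
  expect_lt(final, 0.05 * init_mse)
  # training loss decreases from initialization on the noisy setup as well
  expect_lt(setup$log$loss[nrow(setup$log)], setup$log$loss[1])
})

test_that("stage 2 touches only the chromosome's genomic factor rows", {
  spec <- synthetic_spec(n_bins = 2000, n_chromosomes = 2, noise_sd = 0,
                         seed = 33)
  comp <- generate_compendium(spec)
  m <- init_model(comp$tensor$biosamples, comp$tensor$assays, comp$grid,
                  desk_config(), seed = 2)
  s1 <- train_stage1(m, comp$tensor,
                     train_config(epochs = 200, batch_size = 256, seed = 3))
  m1 <- s1$model
  s2 <- train_stage2(m1, comp$tensor,
                     train_config(epochs = 150, batch_size = 256, seed = 4),
                     chromosome = "chrS2")
  m2 <- s2$model
  # frozen groups bit-identical
  expect_identical(m2$net, m1$net)
  expect_identical(m2$factors$biosample, m1$factors$biosample)
  expect_identical(m2$factors$assay, m1$factors$assay)
  # chromosome 1 genome rows untouched; chromosome 2 rows moved
  blocks1 <- epitensor:::chromosome_blocks(comp$grid, "chrS1")
  blocks2 <- epitensor:::chromosome_blocks(comp$grid, "chrS2")
  expect_identical(m2$factors$fine[blocks1$fine + 1, ],
                   m1$factors$fine[blocks1$fine + 1, ])
  expect_identical(m2$factors$mid[blocks1$mid + 1, ],
                   m1$factors$mid[blocks1$mid + 1, ])
  expect_false(identical(m2$factors$fine[blocks2$fine + 1, ],
                         m1$factors$fine[blocks2$fine + 1, ]))
  # stage-2 on the untrained chromosome brings its error down
  bins2 <- chromosome_bins(comp$grid, "chrS2")
  expect_lt(model_loss(m2, comp$tensor, bins2),
            model_loss(m1, comp$tensor, bins2))
  expect_error(train_stage2(m1, comp$tensor,
                            train_config(epochs = 1, batch_size = 64),
                            chromosome = "chrX"), "unknown")
})

test_that("trainability flags freeze exactly the requested groups", {
  comp <- noiseless_compendium()
  m <- init_model(comp$tensor$biosamples, comp$tensor$assays, comp$grid,
                  desk_config(), seed = 5)
  frozen <- set_trainable(m, network = FALSE, biosample = FALSE,
                          assay = FALSE, genome = FALSE)
  expect_error(
    epitensor:::fit_epochs(frozen, comp$tensor, training_bins(comp$grid),
                           train_config(epochs = 1, batch_size = 64,
                                        seed = 1)),
    "no trainable")

  only_assay <- set_trainable(m, network = FALSE, biosample = FALSE,
                              assay = TRUE, genome = FALSE)
  out <- epitensor:::fit_epochs(only_assay, comp$tensor,
                                training_bins(comp$grid),
                                train_config(epochs = 5, batch_size = 256,
                                             seed = 2))$model
  expect_identical(out$net, m$net)
  expect_identical(out$factors$biosample, m$factors$biosample)
  expect_identical(out$factors$fine, m$factors$fine)
  expect_false(identical(out$factors$assay, m$factors$assay))
})

test_that("with frozen genome and one observed track, predictions approach
           the track's conditional mean on a 2-bin toy", {
  grid <- genomic_grid(c(c1 = 50), bin_size = 25,
                       training_regions = data.frame(chrom = "c1", start = 0,
                                                     end = 50))
  m <- init_model("b", "a", grid, model_config(2, 2, 2, 2, 2, 8), seed = 3)
  m <- set_trainable(m, genome = FALSE)
  y <- c(1.0, 2.0)
  tt <- track_tensor(matrix(y, 1), data.frame(biosample = "b", assay = "a"))
  fit <- epitensor:::fit_epochs(m, tt, 0:1,
                                train_config(epochs = 400, batch_size = 2,
                                             seed = 4))$model
  pred <- predict_track(fit, "b", "a")
  # genome factors are near-identical across the two bins at init, so the
  # best achievable fit is (approximately) the track mean at both bins
  expect_equal(mean(pred), mean(y), tolerance = 0.05)
  expect_lt(abs(pred[1] - pred[2]), 0.2 * abs(y[1] - y[2]))
})

test_that("training errors out when asked for the impossible", {
  comp <- noiseless_compendium()
  m <- init_model(comp$tensor$biosamples, comp$tensor$assays, comp$grid,
                  desk_config(), seed = 1)
  m_nr <- set_trainable(m, network = FALSE)
  expect_error(train_stage1(m_nr, comp$tensor,
                            train_config(epochs = 1, batch_size = 64)),
               "all parameter groups")
  g <- genomic_grid(c(c1 = 1000))  # no training regions
  m2 <- init_model("b", "a", g, desk_config(), seed = 1)
  tt <- track_tensor(matrix(0, 1, n_bins(g)),
                     data.frame(biosample = "b", assay = "a"))
  expect_error(train_stage1(m2, tt, train_config(epochs = 1, batch_size = 8)),
               "training regions")
})
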