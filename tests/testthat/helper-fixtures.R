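# Shared fixtures. Expensive objects (a generated compendium and a trained
# model) are built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

tiny_grid <- function(len = 10000, bin_size = 25, ...) {
  genomic_grid(c(chrT = len), bin_size = bin_size, ...)
}

# a small noiseless matched compendium (shared, read-only)
noiseless_compendium <- function() {
  fixture("noiseless_compendium", function() {
    generate_compendium(synthetic_spec(noise_sd = 0, seed = 101))
  })
}

# default-noise compendium plus a model trained on it with the standard
# desk budget (shared by training / extension / cli tests); 16 biosamples
# at mixing 0.7 so the trained model has clear biosample-specific signal
trained_setup <- function() {
  fixture("trained_setup", function() {
    comp <- generate_compendium(synthetic_spec(n_biosamples = 16,
                                               mixing = 0.7, seed = 202))
    model <- init_model(comp$tensor$biosamples, comp$tensor$assays,
                        comp$grid, desk_config(), seed = 1)
    fit <- train_full(model, comp$tensor,
                      train_config(epochs = 600, batch_size = 256, seed = 7),
                      train_config(epochs = 300, batch_size = 256, seed = 8))
    list(comp = comp, model = fit$model, log = fit$log)
  })
}

random_cells_tensor <- function(n_bio, n_assay, n_obs, n_bins, seed) {
  withr::with_seed(seed, {
    bios <- paste0("b", seq_len(n_bio))
    assays <- paste0("a", seq_len(n_assay))
    all_cells <- expand.grid(biosample = bios, assay = assays,
                             stringsAsFactors = FALSE)
    pick <- sample(nrow(all_cells), n_obs)
    vals <- matrix(abs(rnorm(n_obs * n_bins)), n_obs)
    track_tensor(vals, all_cells[pick, ], biosamples = bios, assays = assays)
  })
}
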