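# Shared fixtures: a small synthetic study bundle and fast training configs.
# Everything is generated in code under fixed seeds.

tiny_spec <- function(...) {
  args <- utils::modifyList(list(
    n_proteins = 12, n_teacher_proteins = 15, length_range = c(30, 60),
    sites_per_protein = 3, teacher_sites_per_protein = 3,
    d = 8, n_layers = 2, sigma = 0.2, sigma_teacher = 0.5, seed = 42
  ), list(...))
  do.call(synthetic_spec, args)
}

fast_config <- function(...) {
  args <- utils::modifyList(list(
    hidden = c(16, 8), epochs = 60, lr = 0.01, batch_size = 64,
    weight_decay = 1e-4, validation_fraction = 0, patience = 0,
    finetune_epochs = 30
  ), list(...))
  do.call(regressor_config, args)
}

# one shared tiny bundle per test run
.fixture_env <- new.env(parent = emptyenv())
tiny_bundle <- function() {
  if (is.null(.fixture_env$bundle)) .fixture_env$bundle <- synthetic_bundle(tiny_spec())
  .fixture_env$bundle
}

write_temp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  readr::write_csv(df, path)
  path
}
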