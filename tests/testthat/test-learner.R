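test_that("a member recovers a constant target function", {
  withr::with_seed(1, X <- matrix(rnorm(50 * 8), 50, 8))
  cfg <- regressor_config(hidden = 8, epochs = 600, lr = 0.01, batch_size = 64,
                          weight_decay = 1e-3, validation_fraction = 0, patience = 0)
  m <- train_member(X, rep(1.3, 50), cfg, seed = 3)
  expect_lt(max(abs(predict(m, X) - 1.3)), 0.05)
})

test_that("a member fits a noise-free linear map near the least-squares oracle", {
  withr::with_seed(2, {
    X <- matrix(rnorm(500 * 16), 500, 16)
    beta <- rnorm(16)
  })
  y <- drop(X %*% beta)
  # independent oracle: exact least squares reaches zero residual
  ls <- lm.fit(cbind(1, X), y)
  expect_lt(sqrt(mean(ls$residuals^2)), 1e-10)
  cfg <- regressor_config(hidden = c(32, 16), epochs = 600, lr = 0.01,
                          batch_size = 500, weight_decay = 0,
                          validation_fraction = 0, patience = 0)
  m <- train_member(X, y, cfg, seed = 4)
  expect_lt(sqrt(mean((predict(m, X) - y)^2)), 0.05)
})

test_that("training is deterministic and the loss decreases from initialization", {
  withr::with_seed(5, X <- matrix(rnorm(80 * 6), 80, 6))
  y <- drop(X[, 1]) + 0.5
  cfg <- fast_config(epochs = 50)
  m1 <- train_member(X, y, cfg, seed = 11)
  m2 <- train_member(X, y, cfg, seed = 11)
  expect_identical(m1$W, m2$W)               # bit-for-bit reproducible
  expect_identical(m1$b, m2$b)
  m3 <- train_member(X, y, cfg, seed = 12)
  expect_false(identical(m1$W, m3$W))        # different seed, different member
  expect_lt(m1$train_mse[length(m1$train_mse)], m1$train_mse[1])
})

test_that("degenerate and divergent training inputs raise informative errors", {
  X <- matrix(rnorm(16), 8, 2)
  expect_error(train_member(X[1, , drop = FALSE], 1, fast_config(), seed = 1),
               "at least 2")
  Xb <- X; Xb[1, 1] <- NA
  expect_error(train_member(Xb, rnorm(8), fast_config(), seed = 1), "finite")
  expect_error(train_member(X, rnorm(8), fast_config()), "seed")
  withr::with_seed(2, X2 <- matrix(rnorm(100 * 4), 100, 4))
  cfg <- regressor_config(hidden = c(8, 8), epochs = 10, lr = 1e200,
                          batch_size = 100, validation_fraction = 0, patience = 0)
  expect_error(train_member(X2, rnorm(100), cfg, seed = 1), "epoch")
})

test_that("pretraining bookkeeping: member seeds, metadata, degenerate M = 1", {
  b <- tiny_bundle()
  cfg <- fast_config(epochs = 25)
  expect_warning(
    ens <- pretrain_ensemble(b$teacher, b$sequences, b$backend, "acid",
                             layer = 1, n_members = 5, config = cfg, seed = 100),
    "not in the acid channel")
  expect_equal(ens$n_members, 5)
  expect_true(ens$pretrained)
  expect_false(ens$finetuned)
  expect_match(ens$pretrain_hash, "^[0-9a-f]+$")
  expect_equal(tidy(ens)$seed, 101:105)

  # M = 1 reduces to a single train_member call with seed + 1
  ens1 <- pretrain_ensemble(b$teacher, b$sequences, b$backend, "acid",
                            layer = 1, n_members = 1, config = cfg, seed = 100,
                            quiet = TRUE)
  acid <- b$teacher[channel_of(b$teacher$aa) == "acid", ]
  X <- seqpka:::gather_features(acid, b$sequences, b$backend, 1)
  direct <- train_member(X, pka_shift(acid$pka, acid$aa), cfg, seed = 101)
  expect_identical(ens1$members[[1]]$W, direct$W)

  # two runs with the same seeds give identical ensembles
  ens2 <- pretrain_ensemble(b$teacher, b$sequences, b$backend, "acid",
                            layer = 1, n_members = 5, config = cfg, seed = 100,
                            quiet = TRUE)
  expect_identical(lapply(ens$members, `[[`, "W"),
                   lapply(ens2$members, `[[`, "W"))
})

test_that("fine-tuning updates weights; zero epochs is the identity", {
  b <- tiny_bundle()
  cfg <- fast_config(epochs = 25)
  ens <- pretrain_ensemble(b$teacher, b$sequences, b$backend, "base",
                           layer = 1, n_members = 2, config = cfg, seed = 7,
                           quiet = TRUE)
  cfg0 <- fast_config(epochs = 25, finetune_epochs = 0)
  same <- finetune_ensemble(ens, b$experimental, b$sequences, b$backend,
                            config = cfg0, quiet = TRUE)
  expect_identical(same$members, ens$members)

  tuned <- finetune_ensemble(ens, b$experimental, b$sequences, b$backend,
                             config = cfg, quiet = TRUE)
  expect_true(tuned$finetuned)
  expect_false(identical(tuned$members[[1]]$W, ens$members[[1]]$W))

  # width mismatch between model and backend is a configuration error
  spec_wide <- tiny_spec(d = 6)
  wide <- planted_backend(spec_wide, generate_corpus(spec_wide))
  expect_error(finetune_ensemble(ens, b$experimental, b$sequences, wide,
                                 config = cfg, quiet = TRUE), "width")
})

test_that("fine-tuning on the pretraining distribution does not hurt held-out error", {
  # 5 seeded replicates; compare pretrained-only vs fine-tuned on data drawn
  # from the same generative process, evaluated on held-out proteins
  deltas <- vapply(1:5, function(s) {
    spec <- synthetic_spec(n_proteins = 40, n_teacher_proteins = 150,
                           length_range = c(30, 60), sites_per_protein = 3,
                           teacher_sites_per_protein = 3, d = 8, n_layers = 1,
                           sigma = 0.3, sigma_teacher = 0.3, seed = 300 + s)
    b <- synthetic_bundle(spec)
    cfg <- fast_config(epochs = 60, finetune_epochs = 60,
                       validation_fraction = 0.2, patience = 8)
    test_ids <- sprintf("P%04d", 31:40)
    train <- b$experimental[!(b$experimental$protein_id %in% test_ids), ]
    test <- b$experimental[b$experimental$protein_id %in% test_ids, ]
    pre <- pretrain_ensemble(b$teacher, b$sequences, b$backend, "acid",
                             layer = 1, n_members = 5, config = cfg,
                             seed = s, quiet = TRUE)
    tuned <- finetune_ensemble(pre, train, b$sequences, b$backend,
                               config = cfg, quiet = TRUE)
    acid_test <- test[channel_of(test$aa) == "acid", ]
    X <- seqpka:::gather_features(acid_test, b$sequences, b$backend, 1)
    truth <- pka_shift(acid_test$pka, acid_test$aa)
    rmse <- function(model) sqrt(mean((predict(model, X)$shift - truth)^2))
    rmse(tuned) - rmse(pre)
  }, numeric(1))
  # not worse within one standard error over the replicates
  expect_lt(mean(deltas), sd(deltas) / sqrt(length(deltas)))
})

test_that("ensemble predictions: mean, stderr and member-order invariance", {
  b <- tiny_bundle()
  cfg <- fast_config(epochs = 30)
  ens <- train_channel(b$experimental, b$sequences, b$backend, "acid",
                       layer = 1, n_members = 4, config = cfg, seed = 50,
                       quiet = TRUE)
  acid <- b$experimental[channel_of(b$experimental$aa) == "acid", ]
  X <- seqpka:::gather_features(acid, b$sequences, b$backend, 1)
  p <- predict(ens, X)
  expect_true(all(p$stderr >= 0))
  # permuting members leaves the mean unchanged
  perm <- ens
  perm$members <- rev(perm$members)
  expect_equal(predict(perm, X)$shift, p$shift)
  # an ensemble of identical members has zero spread
  clone <- ens
  clone$members <- rep(ens$members[1], 4)
  expect_equal(predict(clone, X)$stderr, rep(0, nrow(X)))
})

test_that("train_channel composes the stages and defaults to 200 members", {
  b <- tiny_bundle()
  cfg <- fast_config(epochs = 25)
  # without a teacher the ensemble trains from random initialization
  scratch <- train_channel(b$experimental, b$sequences, b$backend, "acid",
                           layer = 1, n_members = 2, config = cfg, seed = 9,
                           quiet = TRUE)
  expect_false(scratch$pretrained)
  staged <- train_channel(b$experimental, b$sequences, b$backend, "acid",
                          layer = 1, teacher = b$teacher, n_members = 2,
                          config = cfg, seed = 9, quiet = TRUE)
  expect_true(staged$pretrained)
  expect_true(staged$finetuned)
  expect_equal(formals(train_channel)$n_members, 200)
  g <- glance(staged)
  expect_equal(g$n_members, 2)
  expect_equal(g$channel, "acid")
})

test_that("site prediction routes channels correctly with uncertainty", {
  b <- tiny_bundle()
  cfg <- fast_config(epochs = 30)
  acid <- train_channel(b$experimental, b$sequences, b$backend, "acid",
                        layer = 1, n_members = 2, config = cfg, seed = 1,
                        quiet = TRUE)
  base <- train_channel(b$experimental, b$sequences, b$backend, "base",
                        layer = 1, n_members = 2, config = cfg, seed = 2,
                        quiet = TRUE)
  pred <- predict_pka(NULL, b$sequences[1:3], b$backend,
                      list(acid = acid, base = base))
  expect_true(all(pred$channel[pred$aa %in% c("ASP", "GLU", "CYS", "TYR")] == "acid"))
  expect_true(all(pred$channel[pred$aa %in% c("HIS", "LYS")] == "base"))
  # pka reconstructs from shift exactly
  expect_equal(pred$pka, pka_from_shift(pred$shift, pred$aa), tolerance = 1e-12)
  # acid sites get the acid model's output (routing, not just labels)
  acid_sites <- pred[pred$channel == "acid", c("protein_id", "position", "aa")]
  Xa <- seqpka:::gather_features(acid_sites, b$sequences, b$backend, 1)
  expect_equal(pred$shift[pred$channel == "acid"], predict(acid, Xa)$shift)
  # a missing sequence is a lookup error
  expect_error(
    predict_pka(tibble::tibble(protein_id = "ghost", position = 1, aa = "ASP"),
                b$sequences, b$backend, list(acid = acid, base = base)),
    "ghost")
})

test_that("model archives round-trip through write/read with manifest checks", {
  b <- tiny_bundle()
  cfg <- fast_config(epochs = 20)
  ens <- train_channel(b$experimental, b$sequences, b$backend, "base",
                       layer = 2, n_members = 2, config = cfg, seed = 77,
                       quiet = TRUE)
  dir <- withr::local_tempdir()
  write_ensemble(ens, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_ensemble(dir)
  expect_equal(back$layer, 2)
  expect_equal(back$backend_id, ens$backend_id)
  base <- b$experimental[channel_of(b$experimental$aa) == "base", ]
  X <- seqpka:::gather_features(base, b$sequences, b$backend, 2)
  expect_identical(predict(back, X), predict(ens, X))
  expect_error(read_ensemble(withr::local_tempdir()), "not an ensemble archive")
})
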