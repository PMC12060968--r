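# independent loop-based re-implementation used as the metric oracle
brute_metrics <- function(true, pred) {
  n <- length(true)
  ss <- 0
  mx <- 0
  for (i in seq_len(n)) {
    r <- pred[i] - true[i]
    ss <- ss + r * r
    if (abs(r) > mx) mx <- abs(r)
  }
  mt <- sum(true) / n
  mp <- sum(pred) / n
  num <- 0; dt <- 0; dp <- 0
  for (i in seq_len(n)) {
    num <- num + (true[i] - mt) * (pred[i] - mp)
    dt <- dt + (true[i] - mt)^2
    dp <- dp + (pred[i] - mp)^2
  }
  list(rmse = sqrt(ss / n), pcc = num / sqrt(dt * dp), maxe = mx)
}

test_that("regression metrics match hand-computed and worked examples", {
  perfect <- regression_metrics(c(2, 4, 6), c(2, 4, 6))
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$pcc, 1)
  expect_equal(perfect$maxe, 0)

  m <- regression_metrics(c(0, 0), c(1, 1))
  expect_equal(m$rmse, 1)
  expect_equal(m$maxe, 1)
  expect_true(is.na(m$pcc))  # zero-variance truth: undefined, not 0

  m2 <- regression_metrics(c(1, 2, 3), c(1, 2, 5))
  expect_equal(m2$rmse, sqrt(4 / 3))
  expect_equal(m2$maxe, 2)
  expect_equal(m2$pcc, 0.9607689, tolerance = 1e-6)  # frozen from brute-force oracle

  expect_error(regression_metrics(1:3, 1:2), "length")
})

test_that("regression metrics agree with an independent loop implementation", {
  withr::with_seed(101, {
    for (i in 1:25) {
      n <- sample(3:60, 1)
      true <- rnorm(n, 7, 2)
      pred <- true + rnorm(n, 0, 0.7)
      got <- regression_metrics(true, pred)
      want <- brute_metrics(true, pred)
      expect_equal(got$rmse, want$rmse, tolerance = 1e-10)
      expect_equal(got$pcc, want$pcc, tolerance = 1e-10)
      expect_equal(got$maxe, want$maxe, tolerance = 1e-10)
    }
  })
})

test_that("critical errors count only protonated<->deprotonated corner cells", {
  # representative pKa per class at default thresholds
  rep_pka <- c(deprotonated = 5, titrating = 7, protonated = 9)
  lev <- protonation_classes()
  # exhaustive check over all 9 (true, predicted) class patterns
  for (tc in lev) {
    for (pc in lev) {
      cm <- classification_metrics(rep_pka[[tc]], rep_pka[[pc]])
      critical <- (tc == "protonated" && pc == "deprotonated") ||
                  (tc == "deprotonated" && pc == "protonated")
      expect_equal(cm$cer_count, as.integer(critical))
      expect_equal(cm$confusion[tc, pc], 1L, ignore_attr = TRUE)
      expect_equal(sum(cm$confusion), 1)
    }
  }

  # worst case: both sites critically flipped
  worst <- classification_metrics(c(9, 5), c(5, 9))
  expect_equal(worst$cer_count, 2)
  expect_equal(worst$n, 2)

  # 10 sites, one prot->dep flip and two prot->titrating flips:
  # only the corner flip is critical
  true <- c(rep(9, 5), rep(5, 3), 7, 7)
  pred <- c(5, 7, 7, 9, 9, 5, 5, 5, 7, 7)
  cm <- classification_metrics(true, pred)
  expect_equal(cm$cer_count, 1)
  expect_equal(cm$n, 10)

  # all-correct: CER 0, precision/recall 1 for occupied classes
  ok <- classification_metrics(true, true)
  expect_equal(ok$cer_count, 0)
  occupied <- ok$by_class[ok$by_class$n_true > 0, ]
  expect_true(all(occupied$precision == 1))
  expect_true(all(occupied$recall == 1))
})

test_that("hold-out splits are protein-grouped, seeded and leak-free", {
  withr::with_seed(1, {
    ds <- tibble::tibble(
      protein_id = rep(sprintf("p%02d", 1:10), each = 4),
      position = rep(1:4, 10),
      aa = sample(titratable_aas(), 40, replace = TRUE),
      pka = runif(40, 2, 12)
    )
  })
  sp <- make_holdout_splits(ds, n_splits = 6, test_fraction = 0.2, seed = 5)
  expect_equal(nrow(sp), 6)
  for (i in 1:6) {
    expect_length(sp$test[[i]], 2)          # 10 proteins x 0.2
    expect_length(intersect(sp$train[[i]], sp$test[[i]]), 0)
    expect_setequal(c(sp$train[[i]], sp$test[[i]]), unique(ds$protein_id))
    # no residue of a test protein in the training rows
    train_rows <- ds[ds$protein_id %in% sp$train[[i]], ]
    expect_false(any(train_rows$protein_id %in% sp$test[[i]]))
  }
  sp2 <- make_holdout_splits(ds, n_splits = 6, test_fraction = 0.2, seed = 5)
  expect_identical(sp, sp2)
  expect_error(make_holdout_splits(ds, test_fraction = 1.2), "test_fraction")
  expect_error(make_holdout_splits(ds[1:4, ], test_fraction = 0.5), "at least 2")
})

test_that("hold-out evaluation aggregates splits and conserves counts", {
  b <- tiny_bundle()
  cfg <- fast_config(epochs = 30)
  ev <- run_holdout_evaluation(b$experimental, b$sequences, b$backend, layer = 1,
                               n_splits = 3, test_fraction = 0.25, seed = 1,
                               n_members = 2, config = cfg)
  expect_s3_class(ev, "pka_holdout_eval")
  expect_equal(nrow(tidy(ev)), 3)
  g <- glance(ev)
  expect_equal(g$n_splits, 3)
  expect_gte(g$rmse, 0)
  # MAXE of each split bounds its RMSE
  expect_true(all(tidy(ev)$maxe >= tidy(ev)$rmse))
  # accumulated confusion equals the sum over per-split tables (conservation)
  per_split_sum <- sum(vapply(unique(ev$predictions$split), function(s) {
    p <- ev$predictions[ev$predictions$split == s, ]
    classification_metrics(p$pka_true, p$pka_pred)$n
  }, numeric(1)))
  expect_equal(ev$classification$n, per_split_sum)
  expect_equal(ev$classification$n, nrow(ev$predictions))
  # per-aa breakdown conserves the site count
  expect_equal(sum(ev$per_aa$n), nrow(ev$predictions))

  # single split: stderr is flagged missing
  ev1 <- run_holdout_evaluation(b$experimental, b$sequences, b$backend, layer = 1,
                                n_splits = 1, test_fraction = 0.25, seed = 1,
                                n_members = 2, config = cfg)
  expect_true(is.na(glance(ev1)$rmse_se))
})

test_that("ablation arms share identical splits and pooled arms train one model", {
  b <- tiny_bundle()
  cfg <- fast_config(epochs = 25)
  ab <- run_ablation(b$experimental, b$sequences, b$backend, layer = 1,
                     teacher = b$teacher, n_splits = 2, test_fraction = 0.25,
                     seed = 3, n_members = 2, config = cfg)
  expect_equal(nrow(tidy(ab)), 4)
  expect_setequal(tidy(ab)$arm, c("baseline", "PT", "AB", "PT+AB"))
  hashes <- vapply(ab$reports, function(r) r$meta$split_hash, character(1))
  expect_length(unique(hashes), 1)           # paired comparison
  expect_identical(unique(hashes), ab$split_hash)
  # the no-AB arms trained pooled models, the AB arms split channels
  expect_false(ab$reports$baseline$meta$split_channels)
  expect_true(ab$reports$`PT+AB`$meta$split_channels)
  expect_true(ab$reports$PT$meta$pretrained)
  expect_false(ab$reports$AB$meta$pretrained)
  expect_error(run_ablation(b$experimental, b$sequences, b$backend, layer = 1,
                            teacher = NULL), "teacher")
})

test_that("a single-layer sweep reduces to a plain hold-out evaluation", {
  b <- tiny_bundle()
  cfg <- fast_config(epochs = 25)
  sw <- layer_sweep(b$experimental, b$sequences, b$backend, layers = 2,
                    n_splits = 2, test_fraction = 0.25, seed = 4,
                    n_members = 2, config = cfg)
  expect_equal(nrow(tidy(sw)), 1)
  ev <- run_holdout_evaluation(b$experimental, b$sequences, b$backend, layer = 2,
                               n_splits = 2, test_fraction = 0.25, seed = 4,
                               n_members = 2, config = cfg)
  expect_equal(tidy(sw)$rmse, glance(ev)$rmse)
  expect_equal(sw$best_layer, 2L)
  expect_error(layer_sweep(b$experimental, b$sequences, b$backend,
                           layers = c(1, 99)), "layers")
})

test_that("plot methods return ggplot objects", {
  b <- tiny_bundle()
  cfg <- fast_config(epochs = 20)
  ev <- run_holdout_evaluation(b$experimental, b$sequences, b$backend, layer = 1,
                               n_splits = 2, test_fraction = 0.25, seed = 2,
                               n_members = 2, config = cfg)
  expect_s3_class(autoplot(ev), "ggplot")
  sw <- layer_sweep(b$experimental, b$sequences, b$backend, layers = 1:2,
                    n_splits = 2, test_fraction = 0.25, seed = 2,
                    n_members = 2, config = cfg)
  expect_s3_class(autoplot(sw), "ggplot")
  withr::with_seed(8, {
    hist_tbl <- tibble::tibble(aa = rep(c("ASP", "HIS"), each = 20),
                               pka = c(rnorm(20, 3.7, 0.5), rnorm(20, 6.5, 0.5)))
  })
  expect_s3_class(plot_pka_histograms(hist_tbl), "ggplot")
})
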