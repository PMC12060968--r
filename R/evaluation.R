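# Evaluation protocol: regression and protonation-state classification
# metrics, repeated protein-grouped hold-out tests, the pretraining /
# channel-separation ablation, and the transformer layer sweep.

#' Regression metrics for pKa prediction
#'
#' Root-mean-square error, Pearson correlation coefficient and maximum
#' absolute error between experimental and predicted pKa values. The PCC of
#' a zero-variance vector is undefined and reported as `NA`, never coerced
#' to 0.
#'
#' @param true,pred Numeric vectors of equal length.
#' @return A one-row tibble with columns `rmse`, `pcc`, `maxe`, `n`.
#' @export
#' @examples
#' regression_metrics(c(1, 2, 3), c(1, 2, 5))
regression_metrics <- function(true, pred) {
  stopifnot(length(true) == length(pred), all(is.finite(true)),
            all(is.finite(pred)))
  if (length(true) == 0) abort("empty metric input")
  resid <- pred - true
  pcc <- if (length(true) >= 2 && sd(true) > 0 && sd(pred) > 0) {
    cor(true, pred)
  } else {
    NA_real_
  }
  tibble(rmse = sqrt(mean(resid^2)), pcc = pcc, maxe = max(abs(resid)),
         n = length(true))
}

#' Protonation-state classification metrics
#'
#' Classifies experimental and predicted pKa values into the three
#' protonation states at the reference pH and tabulates a 3x3 confusion
#' table (rows = true class, columns = predicted class). The critical error
#' rate (CER) is the fraction of predictions that misclassify protonated as
#' deprotonated or vice versa -- confusions involving the titrating class
#' are never critical. Precision and recall are reported per class from the
#' accumulated counts.
#'
#' @param true_pka,pred_pka Numeric vectors of equal length.
#' @param thresholds A [state_thresholds()].
#' @return A list of class `pka_class_metrics`: `confusion` (3x3 matrix),
#'   `by_class` (tibble of precision/recall), `cer_count`, `n`, `cer`.
#' @export
classification_metrics <- function(true_pka, pred_pka,
                                   thresholds = state_thresholds()) {
  stopifnot(length(true_pka) == length(pred_pka))
  lev <- protonation_classes()
  tc <- classify_state(true_pka, thresholds)
  pc <- classify_state(pred_pka, thresholds)
  confusion <- table(true = tc, pred = pc)
  confusion <- unclass(confusion)[lev, lev]
  class_metrics_from_confusion(confusion)
}

# precision/recall/CER from an accumulated 3x3 confusion table
class_metrics_from_confusion <- function(confusion) {
  lev <- protonation_classes()
  stopifnot(identical(dim(confusion), c(3L, 3L)))
  n <- sum(confusion)
  cer_count <- confusion["protonated", "deprotonated"] +
    confusion["deprotonated", "protonated"]
  by_class <- tibble(
    class = lev,
    precision = vapply(lev, function(k) {
      tot <- sum(confusion[, k])
      if (tot == 0) NA_real_ else confusion[k, k] / tot
    }, numeric(1)),
    recall = vapply(lev, function(k) {
      tot <- sum(confusion[k, ])
      if (tot == 0) NA_real_ else confusion[k, k] / tot
    }, numeric(1)),
    n_true = rowSums(confusion)[lev]
  )
  structure(
    list(confusion = confusion, by_class = by_class,
         cer_count = unname(cer_count), n = n,
         cer = if (n > 0) unname(cer_count) / n else NA_real_),
    class = "pka_class_metrics"
  )
}

#' @export
print.pka_class_metrics <- function(x, ...) {
  cat(sprintf("<pka_class_metrics> n = %d | CER %d/%d (%.3f)\n",
              x$n, x$cer_count, x$n, x$cer))
  print(x$confusion)
  invisible(x)
}

#' Protein-grouped hold-out splits
#'
#' Draws `n_splits` independent random partitions of the dataset's proteins
#' into train and test groups. Splitting at the protein level (never the
#' residue level) prevents near-identical embeddings of the same protein
#' from leaking between train and test. Split `i` uses seed `seed + i`, so
#' the collection is deterministic and the same splits can be shared across
#' ablation arms or layer sweeps for paired comparisons.
#'
#' @param data A pKa records tibble.
#' @param n_splits Number of independent splits (default 20).
#' @param test_fraction Fraction of proteins held out, in (0, 1).
#' @param seed Integer base seed.
#' @return A tibble with columns `split`, `seed`, `train` and `test`
#'   (list-columns of protein ids).
#' @export
make_holdout_splits <- function(data, n_splits = 20, test_fraction = 0.1,
                                seed = 0) {
  if (!(test_fraction > 0 && test_fraction < 1)) {
    abort("test_fraction must be in (0, 1)")
  }
  proteins <- sort(unique(data$protein_id))
  if (length(proteins) < 2) abort("need at least 2 proteins to split")
  n_test <- max(1L, round(length(proteins) * test_fraction))
  if (n_test >= length(proteins)) n_test <- length(proteins) - 1L
  rows <- purrr::map(seq_len(n_splits), function(i) {
    test <- withr::with_seed(as.integer(seed) + i,
                             sort(sample(proteins, n_test)))
    tibble(split = i, seed = as.integer(seed) + i,
           train = list(setdiff(proteins, test)), test = list(test))
  })
  bind_rows(rows)
}

# Train per-split models and predict the split's test sites.
# Returns list(predictions = tibble, models = list) for one split.
fit_and_predict_split <- function(records, sequences, backend, layer,
                                  train_ids, test_ids, teacher,
                                  teacher_sequences, split_channels,
                                  n_members, config, seed, solution) {
  train <- records[records$protein_id %in% train_ids, , drop = FALSE]
  test <- records[records$protein_id %in% test_ids, , drop = FALSE]
  stopifnot(nrow(train) > 0, nrow(test) > 0)
  # leakage guard: teacher proteins appearing in this split's test set are
  # excluded from pretraining
  teacher_use <- NULL
  if (!is.null(teacher)) {
    teacher_use <- teacher[!(teacher$protein_id %in% test_ids), , drop = FALSE]
  }
  channels <- if (split_channels) c("acid", "base") else "combined"
  models <- list()
  for (ch in channels) {
    models[[ch]] <- train_channel(
      train, sequences, backend, channel = ch, layer = layer,
      teacher = teacher_use, teacher_sequences = teacher_sequences,
      n_members = n_members, config = config,
      seed = stream_seed(seed, paste0("channel-", ch)), solution = solution,
      quiet = TRUE
    )
  }
  pred <- predict_pka(test[, c("protein_id", "position", "aa")],
                      sequences, backend, models, solution = solution)
  pred <- left_join(pred, test[, c("protein_id", "position", "pka")],
                    by = c("protein_id", "position"))
  names(pred)[names(pred) == "pka.x"] <- "pka_pred"
  names(pred)[names(pred) == "pka.y"] <- "pka_true"
  list(predictions = pred, models = models)
}

#' Repeated hold-out evaluation
#'
#' The full evaluation protocol: for each protein-grouped hold-out split,
#' train the channel model(s) on the training proteins (optionally with
#' teacher pretraining) and predict the held-out sites. Regression metrics
#' (RMSE, PCC, MAXE) are reported per split and aggregated as mean +/-
#' standard error (`sd / sqrt(n_splits)`); classification metrics are
#' computed from the confusion counts accumulated over all splits, not
#' averaged per split. A per-amino-acid breakdown is computed from the
#' accumulated residuals, with the CER suppressed for residue types whose
#' accumulated protonated + deprotonated truth count falls below
#' `min_class_count` (tiny test sets make the rate meaningless).
#'
#' @param data Experimental pKa records tibble.
#' @param sequences Named character vector of sequences.
#' @param backend A `pka_backend`.
#' @param layer Embedding layer used for training and prediction.
#' @param teacher Optional teacher records (enables pretraining).
#' @param teacher_sequences Sequences for teacher records.
#' @param splits Optional precomputed [make_holdout_splits()] table (shared
#'   splits give paired comparisons); otherwise drawn here.
#' @param n_splits,test_fraction,seed Split parameters when `splits` is
#'   `NULL`.
#' @param split_channels `TRUE` trains separate acid/base models; `FALSE`
#'   trains one pooled model.
#' @param n_members Ensemble size per model.
#' @param config A [regressor_config()].
#' @param solution,thresholds References for shift reconstruction and
#'   classification.
#' @param min_class_count Minimum accumulated protonated+deprotonated truth
#'   count for a per-aa CER to be reported.
#' @return An object of class `pka_holdout_eval`; see [tidy()] / [glance()].
#' @export
run_holdout_evaluation <- function(data, sequences, backend, layer,
                                   teacher = NULL,
                                   teacher_sequences = sequences,
                                   splits = NULL, n_splits = 20,
                                   test_fraction = 0.1, seed = 0,
                                   split_channels = TRUE, n_members = 200,
                                   config = regressor_config(),
                                   solution = solution_pka(),
                                   thresholds = state_thresholds(),
                                   min_class_count = 5) {
  stopifnot(nrow(data) > 0)
  if (is.null(splits)) {
    splits <- make_holdout_splits(data, n_splits, test_fraction, seed)
  }
  split_results <- vector("list", nrow(splits))
  for (i in seq_len(nrow(splits))) {
    res <- fit_and_predict_split(
      data, sequences, backend, layer,
      splits$train[[i]], splits$test[[i]],
      teacher, teacher_sequences, split_channels, n_members, config,
      seed = splits$seed[[i]], solution = solution
    )
    res$predictions$split <- splits$split[[i]]
    split_results[[i]] <- res$predictions
  }
  predictions <- bind_rows(split_results)

  per_split <- predictions |>
    group_by(.data$split) |>
    dplyr::group_modify(~ regression_metrics(.x$pka_true, .x$pka_pred)) |>
    ungroup()
  agg <- function(v) {
    m <- mean(v, na.rm = TRUE)
    se <- if (length(v) > 1) sd(v, na.rm = TRUE) / sqrt(length(v)) else NA_real_
    c(m, se)
  }
  aggregate <- tibble(
    metric = c("rmse", "pcc", "maxe"),
    mean = c(agg(per_split$rmse)[1], agg(per_split$pcc)[1], agg(per_split$maxe)[1]),
    stderr = c(agg(per_split$rmse)[2], agg(per_split$pcc)[2], agg(per_split$maxe)[2])
  )
  cls <- classification_metrics(predictions$pka_true, predictions$pka_pred,
                                thresholds)
  per_aa <- predictions |>
    group_by(.data$aa) |>
    dplyr::group_modify(function(x, key) {
      rm <- regression_metrics(x$pka_true, x$pka_pred)
      cm <- classification_metrics(x$pka_true, x$pka_pred, thresholds)
      n_crit_classes <- sum(cm$confusion["protonated", ]) +
        sum(cm$confusion["deprotonated", ])
      rm$cer <- if (n_crit_classes >= min_class_count) cm$cer else NA_real_
      rm
    }) |>
    ungroup()

  structure(
    list(splits = splits, per_split = per_split, aggregate = aggregate,
         classification = cls, per_aa = per_aa, predictions = predictions,
         meta = list(layer = layer, split_channels = split_channels,
                     pretrained = !is.null(teacher), n_members = n_members,
                     backend_id = backend$backend_id, seed = seed,
                     thresholds = thresholds,
                     split_hash = rlang::hash(splits[c("split", "train", "test")]))),
    class = "pka_holdout_eval"
  )
}

#' @export
print.pka_holdout_eval <- function(x, ...) {
  r <- x$aggregate
  fmt <- function(m) {
    i <- which(r$metric == m)
    if (is.na(r$stderr[i])) sprintf("%.3f", r$mean[i])
    else sprintf("%.3f +/- %.3f", r$mean[i], r$stderr[i])
  }
  cat(sprintf("<pka_holdout_eval> %d split(s) | RMSE %s | PCC %s | MAXE %s | CER %d/%d\n",
              nrow(x$per_split), fmt("rmse"), fmt("pcc"), fmt("maxe"),
              x$classification$cer_count, x$classification$n))
  invisible(x)
}

#' @describeIn tidy-seqpka Per-split regression metrics of a hold-out
#'   evaluation.
#' @export
tidy.pka_holdout_eval <- function(x, ...) x$per_split

#' @describeIn tidy-seqpka One-row aggregate of a hold-out evaluation
#'   (metric means +/- stderr over splits, accumulated CER).
#' @export
glance.pka_holdout_eval <- function(x, ...) {
  a <- x$aggregate
  g <- function(m, col) a[[col]][a$metric == m]
  tibble(
    rmse = g("rmse", "mean"), rmse_se = g("rmse", "stderr"),
    pcc = g("pcc", "mean"), pcc_se = g("pcc", "stderr"),
    maxe = g("maxe", "mean"), maxe_se = g("maxe", "stderr"),
    cer = x$classification$cer, cer_count = x$classification$cer_count,
    n_sites = x$classification$n, n_splits = nrow(x$per_split)
  )
}

#' Pretraining / channel-separation ablation
#'
#' Runs four complete hold-out evaluations on identical splits: (1) the
#' baseline with neither pretraining (PT) nor acid/base channel separation
#' (AB); (2) PT only; (3) AB only; (4) PT and AB. Sharing the split table
#' across arms makes the comparison paired.
#'
#' @inheritParams run_holdout_evaluation
#' @param teacher Teacher records (required for the PT arms).
#' @return An object of class `pka_ablation`: `arms` tibble (arm, pt, ab,
#'   rmse, stderr) and `reports` (the four `pka_holdout_eval`s).
#' @export
run_ablation <- function(data, sequences, backend, layer, teacher,
                         teacher_sequences = sequences, splits = NULL,
                         n_splits = 20, test_fraction = 0.1, seed = 0,
                         n_members = 200, config = regressor_config(),
                         solution = solution_pka(),
                         thresholds = state_thresholds()) {
  if (is.null(teacher)) abort("the PT arms require a teacher dataset")
  if (is.null(splits)) {
    splits <- make_holdout_splits(data, n_splits, test_fraction, seed)
  }
  arms <- tibble(
    arm = c("baseline", "PT", "AB", "PT+AB"),
    pt = c(FALSE, TRUE, FALSE, TRUE),
    ab = c(FALSE, FALSE, TRUE, TRUE)
  )
  reports <- purrr::pmap(arms, function(arm, pt, ab) {
    run_holdout_evaluation(
      data, sequences, backend, layer,
      teacher = if (pt) teacher else NULL,
      teacher_sequences = teacher_sequences,
      splits = splits, seed = seed, split_channels = ab,
      n_members = n_members, config = config, solution = solution,
      thresholds = thresholds
    )
  })
  names(reports) <- arms$arm
  arms$rmse <- vapply(reports, function(r) glance(r)$rmse, numeric(1))
  arms$stderr <- vapply(reports, function(r) glance(r)$rmse_se, numeric(1))
  structure(list(arms = arms, reports = reports,
                 split_hash = rlang::hash(splits[c("split", "train", "test")])),
            class = "pka_ablation")
}

#' @export
print.pka_ablation <- function(x, ...) {
  cat("<pka_ablation> overall hold-out RMSE by arm\n")
  print(as.data.frame(x$arms))
  invisible(x)
}

#' @describeIn tidy-seqpka Arm-level RMSE table of an ablation.
#' @export
tidy.pka_ablation <- function(x, ...) x$arms

#' Transformer layer sweep
#'
#' Trains and evaluates dedicated models on each layer's embeddings with one
#' shared set of hold-out splits, reporting the overall and per-amino-acid
#' RMSE per layer and the argmin layer of each curve. This probes which
#' depth of the representation encodes the titratable-site environment best.
#'
#' @inheritParams run_holdout_evaluation
#' @param layers Integer vector of layers to evaluate.
#' @return An object of class `pka_layer_sweep`: `by_layer` tibble (layer,
#'   rmse, stderr), `per_aa` tibble (layer, aa, rmse, n), `best_layer`,
#'   `best_layer_per_aa`, `reports`.
#' @export
layer_sweep <- function(data, sequences, backend, layers, teacher = NULL,
                        teacher_sequences = sequences, splits = NULL,
                        n_splits = 20, test_fraction = 0.1, seed = 0,
                        split_channels = TRUE, n_members = 200,
                        config = regressor_config(),
                        solution = solution_pka(),
                        thresholds = state_thresholds()) {
  layers <- as.integer(layers)
  stopifnot(length(layers) >= 1, all(layers >= 1), all(layers <= backend$n_layers))
  if (is.null(splits)) {
    splits <- make_holdout_splits(data, n_splits, test_fraction, seed)
  }
  reports <- lapply(layers, function(l) {
    run_holdout_evaluation(
      data, sequences, backend, layer = l, teacher = teacher,
      teacher_sequences = teacher_sequences, splits = splits, seed = seed,
      split_channels = split_channels, n_members = n_members, config = config,
      solution = solution, thresholds = thresholds
    )
  })
  names(reports) <- as.character(layers)
  by_layer <- tibble(
    layer = layers,
    rmse = unname(vapply(reports, function(r) glance(r)$rmse, numeric(1))),
    stderr = unname(vapply(reports, function(r) glance(r)$rmse_se, numeric(1)))
  )
  per_aa <- bind_rows(lapply(seq_along(layers), function(i) {
    mutate(reports[[i]]$per_aa, layer = layers[i])
  }))
  best_per_aa <- per_aa |>
    group_by(.data$aa) |>
    dplyr::slice_min(.data$rmse, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("aa", "layer", "rmse")
  structure(
    list(by_layer = by_layer, per_aa = per_aa,
         best_layer = by_layer$layer[which.min(by_layer$rmse)],
         best_layer_per_aa = best_per_aa, reports = reports),
    class = "pka_layer_sweep"
  )
}

#' @export
print.pka_layer_sweep <- function(x, ...) {
  cat(sprintf("<pka_layer_sweep> %d layer(s) | best overall layer = %d\n",
              nrow(x$by_layer), x$best_layer))
  print(as.data.frame(x$by_layer))
  invisible(x)
}

#' @describeIn tidy-seqpka Layer-level RMSE table of a sweep.
#' @export
tidy.pka_layer_sweep <- function(x, ...) x$by_layer
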