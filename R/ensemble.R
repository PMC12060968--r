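# Channel ensembles: pretraining on a teacher corpus, fine-tuning on
# experimental records, and uncertainty-bearing prediction.

new_pka_ensemble <- function(channel, members, backend_id, layer, d, config,
                             base_seed, pretrained, finetuned,
                             pretrain_hash = NA_character_,
                             finetune_hash = NA_character_) {
  stopifnot(length(members) >= 1)
  structure(
    list(channel = channel, members = members, n_members = length(members),
         backend_id = backend_id, layer = as.integer(layer), d = as.integer(d),
         config = config, base_seed = as.integer(base_seed),
         pretrained = pretrained, finetuned = finetuned,
         pretrain_hash = pretrain_hash, finetune_hash = finetune_hash),
    class = "pka_ensemble"
  )
}

#' @export
print.pka_ensemble <- function(x, ...) {
  stage <- paste(c(if (x$pretrained) "pretrained", if (x$finetuned) "fine-tuned",
                   if (!x$pretrained && !x$finetuned) "from-scratch"), collapse = " + ")
  cat(sprintf("<pka_ensemble> %s channel | %d member(s) | %s | backend %s layer %d (d = %d)\n",
              x$channel, x$n_members, stage, x$backend_id, x$layer, x$d))
  invisible(x)
}

channel_records <- function(records, channel, quiet = FALSE) {
  if (channel == "combined") return(records)
  keep <- channel_of(records$aa) == channel
  if (!quiet && any(!keep)) {
    warn(sprintf("rejected %d record(s) not in the %s channel", sum(!keep), channel))
  }
  records[keep, , drop = FALSE]
}

#' Pretrain a channel ensemble on a teacher dataset
#'
#' Trains `n_members` shift regressors on teacher-labelled pKa records (for
#' instance, the predictions of a prior structure-based model over a large
#' corpus). Member `m` is trained with seed `seed + m`, so ensembles are
#' reproducible and member diversity comes from initialization and data
#' order. Records outside the requested channel are rejected with a count.
#'
#' @param teacher Teacher pKa records tibble (`source = "teacher"`).
#' @param sequences Named character vector of sequences covering the records.
#' @param backend An embedding backend.
#' @param channel `"acid"`, `"base"`, or `"combined"` (pooled).
#' @param layer Backend layer used for the features.
#' @param n_members Ensemble size (default 200).
#' @param config A [regressor_config()].
#' @param seed Integer base seed.
#' @param solution Solution pKa reference, see [solution_pka()].
#' @param quiet Suppress the channel-mismatch rejection warning (used by
#'   evaluation loops that filter by design).
#' @return A `pka_ensemble` with `pretrained = TRUE`.
#' @export
pretrain_ensemble <- function(teacher, sequences, backend,
                              channel = c("acid", "base", "combined"),
                              layer, n_members = 200,
                              config = regressor_config(), seed = 0,
                              solution = solution_pka(), quiet = FALSE) {
  channel <- match.arg(channel)
  recs <- channel_records(teacher, channel, quiet)
  if (nrow(recs) == 0) abort("empty teacher set for channel after filtering")
  X <- gather_features(recs, sequences, backend, layer)
  shifts <- pka_shift(recs$pka, recs$aa, solution)
  members <- lapply(seq_len(n_members), function(m) {
    train_member(X, shifts, config, seed = as.integer(seed) + m)
  })
  new_pka_ensemble(channel, members, backend$backend_id, layer, backend$d,
                   config, seed, pretrained = TRUE, finetuned = FALSE,
                   pretrain_hash = rlang::hash(recs))
}

#' Fine-tune a pretrained ensemble on experimental records
#'
#' Continues optimization of every member's weights on the experimental
#' records at the reduced fine-tuning learning rate. With
#' `config$finetune_epochs = 0` the model is returned unchanged (apart from
#' metadata remaining as-is).
#'
#' @param model A `pka_ensemble`.
#' @inheritParams pretrain_ensemble
#' @param experimental Experimental pKa records tibble.
#' @return A new `pka_ensemble` with `finetuned = TRUE` when any update ran.
#' @export
finetune_ensemble <- function(model, experimental, sequences, backend,
                              config = model$config, seed = model$base_seed,
                              solution = solution_pka(), quiet = FALSE) {
  stopifnot(inherits(model, "pka_ensemble"))
  if (backend$d != model$d) {
    abort(sprintf("backend width %d does not match model width %d", backend$d, model$d))
  }
  recs <- channel_records(experimental, model$channel, quiet)
  if (nrow(recs) == 0) abort("no experimental records in the model's channel")
  if (config$finetune_epochs == 0) return(model)
  X <- gather_features(recs, sequences, backend, model$layer)
  shifts <- pka_shift(recs$pka, recs$aa, solution)
  # distinct stream from pretraining: offset the member seeds
  model$members <- lapply(seq_along(model$members), function(m) {
    finetune_member(model$members[[m]], X, shifts, config,
                    seed = stream_seed(as.integer(seed) + m, "finetune"))
  })
  model$finetuned <- TRUE
  model$finetune_hash <- rlang::hash(recs)
  model$config <- config
  model
}

#' Train one channel end to end
#'
#' Orchestrates the two-stage protocol for a single channel: optional
#' pretraining on a teacher corpus followed by fine-tuning on experimental
#' records. Without a teacher set the ensemble is trained from random
#' initialization directly on the experimental records (the full learning
#' rate and epoch budget). `channel = "combined"` pools acidic and basic
#' residues into one model (the no-channel-separation mode of the ablation).
#'
#' @inheritParams pretrain_ensemble
#' @param experimental Experimental pKa records used for (fine-)tuning.
#' @param teacher Optional teacher records; enables pretraining.
#' @param teacher_sequences Sequences for the teacher records (defaults to
#'   `sequences`).
#' @return A `pka_ensemble`.
#' @export
train_channel <- function(experimental, sequences, backend,
                          channel = c("acid", "base", "combined"), layer,
                          teacher = NULL, teacher_sequences = sequences,
                          n_members = 200, config = regressor_config(),
                          seed = 0, solution = solution_pka(), quiet = FALSE) {
  channel <- match.arg(channel)
  if (!is.null(teacher)) {
    model <- pretrain_ensemble(teacher, teacher_sequences, backend, channel,
                               layer, n_members, config, seed, solution, quiet)
    return(finetune_ensemble(model, experimental, sequences, backend,
                             config, seed, solution, quiet))
  }
  recs <- channel_records(experimental, channel, quiet)
  if (nrow(recs) == 0) abort("no experimental records in the requested channel")
  X <- gather_features(recs, sequences, backend, layer)
  shifts <- pka_shift(recs$pka, recs$aa, solution)
  members <- lapply(seq_len(n_members), function(m) {
    train_member(X, shifts, config, seed = as.integer(seed) + m)
  })
  new_pka_ensemble(channel, members, backend$backend_id, layer, backend$d,
                   config, seed, pretrained = FALSE, finetuned = FALSE,
                   finetune_hash = rlang::hash(recs))
}

#' Ensemble shift predictions with uncertainty
#'
#' @param object A `pka_ensemble`.
#' @param features `n x d` matrix.
#' @param ... Unused.
#' @return A tibble with columns `shift` (member mean) and `stderr`
#'   (member sample standard deviation / sqrt(M)); the ensemble mean is
#'   invariant to member order.
#' @export
predict.pka_ensemble <- function(object, features, ...) {
  stopifnot(is.matrix(features))
  if (nrow(features) == 0) return(tibble(shift = numeric(0), stderr = numeric(0)))
  P <- vapply(object$members, function(m) predict(m, features),
              numeric(nrow(features)))
  if (!is.matrix(P)) P <- matrix(P, nrow = nrow(features))
  M <- ncol(P)
  tibble(
    shift = rowMeans(P),
    stderr = if (M > 1) apply(P, 1, sd) / sqrt(M) else rep(0, nrow(P))
  )
}

#' @describeIn tidy-seqpka Per-member summary of an ensemble.
#' @export
tidy.pka_ensemble <- function(x, ...) {
  tibble(
    member = seq_len(x$n_members),
    seed = vapply(x$members, function(m) m$seed, integer(1)),
    epochs_run = vapply(x$members, function(m) as.integer(m$epochs_run), integer(1)),
    final_train_mse = vapply(x$members, function(m) m$train_mse[length(m$train_mse)],
                             numeric(1))
  )
}

#' @describeIn tidy-seqpka One-row provenance summary of an ensemble.
#' @export
glance.pka_ensemble <- function(x, ...) {
  tibble(
    channel = x$channel, n_members = x$n_members, d = x$d, layer = x$layer,
    backend_id = x$backend_id, pretrained = x$pretrained,
    finetuned = x$finetuned, base_seed = x$base_seed
  )
}

#' Tidiers for seqpka model and evaluation objects
#'
#' [generics::tidy()] returns per-component tibbles (ensemble members,
#' hold-out splits, ablation arms, sweep layers); [generics::glance()]
#' returns one-row summaries.
#'
#' @param x A seqpka object.
#' @param ... Unused.
#' @name tidy-seqpka
NULL

# ---- serialization -------------------------------------------------------

#' Save and load ensemble model archives
#'
#' An archive is a directory holding `manifest.json` (channel, member count,
#' backend id, layer, width, seeds, dataset hashes, package version) and
#' `weights.rds` (the member parameters). `read_ensemble()` validates the
#' manifest against the weights before returning a usable model.
#'
#' @param model A `pka_ensemble`.
#' @param dir Archive directory (created if needed).
#' @return `write_ensemble()`: `dir` invisibly; `read_ensemble()`: the model.
#' @export
write_ensemble <- function(model, dir) {
  stopifnot(inherits(model, "pka_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format_version = 1L,
    package_version = as.character(utils::packageVersion("seqpka")),
    channel = model$channel, n_members = model$n_members,
    backend_id = model$backend_id, layer = model$layer, d = model$d,
    base_seed = model$base_seed, pretrained = model$pretrained,
    finetuned = model$finetuned, pretrain_hash = model$pretrain_hash,
    finetune_hash = model$finetune_hash,
    member_seeds = vapply(model$members, function(m) m$seed, integer(1))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(list(members = model$members, config = model$config),
          file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  wf <- file.path(dir, "weights.rds")
  if (!file.exists(mf) || !file.exists(wf)) {
    abort(sprintf("'%s' is not an ensemble archive (manifest.json + weights.rds expected)", dir))
  }
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (is.null(manifest$format_version) || manifest$format_version > 1) {
    abort("unsupported archive format version")
  }
  payload <- readRDS(wf)
  if (length(payload$members) != manifest$n_members) {
    abort("archive corrupt: member count disagrees with manifest")
  }
  new_pka_ensemble(manifest$channel, payload$members, manifest$backend_id,
                   manifest$layer, manifest$d, payload$config,
                   manifest$base_seed, manifest$pretrained, manifest$finetuned,
                   manifest$pretrain_hash %||% NA_character_,
                   manifest$finetune_hash %||% NA_character_)
}
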