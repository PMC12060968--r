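# Site-level pKa prediction: route each titratable site to its channel
# model, reconstruct absolute pKa from the predicted shift, and classify the
# protonation state.

#' List the titratable sites of a set of sequences
#'
#' @param sequences Named character vector of one-letter sequences.
#' @return A tibble with columns `protein_id`, `position`, `aa` (three-letter),
#'   ordered by `(protein_id, position)`.
#' @export
find_titratable_sites <- function(sequences) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  rows <- purrr::map(names(sequences), function(pid) {
    letters1 <- strsplit(toupper(sequences[[pid]]), "")[[1]]
    pos <- which(letters1 %in% TITRATABLE_LETTERS)
    tibble(protein_id = pid, position = pos,
           aa = unname(AA_ONE_TO_THREE[letters1[pos]]))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(protein_id = character(), position = integer(), aa = character()))
  }
  arrange(out, .data$protein_id, .data$position)
}

#' Predict pKa values for titratable sites
#'
#' The central prediction step: each site is embedded by the backend at the
#' layer its channel model was trained on, routed to the matching ensemble
#' (acidic channel for Asp/Glu/Cys/Tyr, basic for His/Lys, or a single
#' pooled model), and receives a predicted shift with an ensemble standard
#' error. The absolute pKa is the solution reference plus the shift, and the
#' protonation state is classified at the reference pH.
#'
#' Sequences longer than the backend maximum produce a per-protein warning
#' and their sites are dropped; other proteins are still processed.
#'
#' @param sites Tibble of sites (`protein_id`, `position`, `aa`); `NULL`
#'   predicts every titratable site in `sequences`.
#' @param sequences Named character vector of sequences.
#' @param backend A `pka_backend`, or a named list
#'   `list(acid = ..., base = ...)` when the channels use different backends.
#' @param models Named list of `pka_ensemble`s: `acid` and `base`, or a
#'   single `combined` pooled model.
#' @param solution Solution pKa reference.
#' @param thresholds A [state_thresholds()] for the protonation class.
#' @return A tibble ordered by `(protein_id, position)` with columns
#'   `protein_id`, `position`, `aa`, `channel`, `shift`, `stderr`, `pka`,
#'   `class`.
#' @export
predict_pka <- function(sites = NULL, sequences, backend, models,
                        solution = solution_pka(),
                        thresholds = state_thresholds()) {
  stopifnot(is.list(models))
  if (!is.null(models$combined)) {
    stopifnot(inherits(models$combined, "pka_ensemble"))
  } else if (!(inherits(models$acid, "pka_ensemble") &&
               inherits(models$base, "pka_ensemble"))) {
    abort("models must be list(acid=, base=) ensembles or list(combined=)")
  }
  if (is.null(sites)) sites <- find_titratable_sites(sequences)
  empty <- tibble(protein_id = character(), position = integer(),
                  aa = character(), channel = character(), shift = numeric(),
                  stderr = numeric(), pka = numeric(),
                  class = factor(character(), levels = protonation_classes()))
  if (nrow(sites) == 0) return(empty)
  sites <- as_tibble(sites)
  sites$aa <- normalize_aa(sites$aa)
  sites$channel <- channel_of(sites$aa)

  missing <- setdiff(unique(sites$protein_id), names(sequences))
  if (length(missing) > 0) {
    abort(sprintf("no sequence available for protein(s): %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  backend_for <- function(ch) {
    if (inherits(backend, "pka_backend")) backend else backend[[ch]]
  }
  # drop sites on over-length sequences, keep processing the rest
  parts <- list()
  for (ch in intersect(c("acid", "base"), unique(sites$channel))) {
    model <- models[[ch]] %||% models$combined
    bk <- backend_for(ch)
    part <- sites[sites$channel == ch, , drop = FALSE]
    lens <- nchar(sequences[unique(part$protein_id)])
    over <- names(lens)[lens > bk$max_len]
    if (length(over) > 0) {
      warn(sprintf("dropping %d protein(s) longer than the backend maximum %d: %s",
                   length(over), bk$max_len, paste(head(over, 5), collapse = ", ")))
      part <- part[!(part$protein_id %in% over), , drop = FALSE]
    }
    if (nrow(part) == 0) next
    X <- gather_features(part, sequences, bk, model$layer)
    pred <- predict(model, X)
    part$shift <- pred$shift
    part$stderr <- pred$stderr
    parts[[ch]] <- part
  }
  if (length(parts) == 0) return(empty)
  out <- bind_rows(parts)
  out$pka <- pka_from_shift(out$shift, out$aa, solution)
  out$class <- classify_state(out$pka, thresholds)
  arrange(out, .data$protein_id, .data$position)
}
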