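# Embedding backend contract: sequence -> per-residue feature matrix at a
# chosen transformer layer. Real protein-language-model adapters plug in
# through the same contract as the synthetic planted-signal backend.

#' Construct an embedding backend
#'
#' A backend converts an amino-acid sequence into an `L x d` matrix of
#' per-residue feature vectors at a chosen layer. The contract:
#' deterministic (identical `(sequence, layer)` calls yield identical
#' matrices), one row per residue positionally aligned to the sequence
#' (1-based), all entries finite, layers numbered `1..n_layers` with the
#' final layer equal to the advertised depth, and sequences of length
#' greater than `max_len` rejected rather than truncated.
#'
#' @param backend_id Opaque identifier recorded in model provenance.
#' @param d Embedding width (columns).
#' @param n_layers Number of available layers.
#' @param embed_fn `function(sequence, layer)` returning an `L x d` matrix;
#'   may attach a `protein_id` attribute when it can identify the sequence.
#' @param max_len Maximum accepted sequence length (default 1022).
#' @param subclass Optional extra S3 class.
#' @param ... Additional fields stored on the backend.
#' @return An object of class `pka_backend`.
#' @export
new_pka_backend <- function(backend_id, d, n_layers, embed_fn,
                            max_len = 1022L, subclass = character(), ...) {
  stopifnot(is.function(embed_fn), d >= 1, n_layers >= 1, max_len >= 1)
  structure(
    list(backend_id = backend_id, d = as.integer(d),
         n_layers = as.integer(n_layers), max_len = as.integer(max_len),
         embed_fn = embed_fn, ...),
    class = c(subclass, "pka_backend")
  )
}

#' @export
print.pka_backend <- function(x, ...) {
  cat(sprintf("<pka_backend> %s | d = %d | layers 1..%d | max length %d\n",
              x$backend_id, x$d, x$n_layers, x$max_len))
  invisible(x)
}

#' Embed a sequence at a given layer
#'
#' Runs the backend and enforces the embedding contract: the result has one
#' row per residue (row i corresponds to residue i, 1-based) and `d` finite
#' columns. Over-length sequences and out-of-range layers are errors; unknown
#' residue letters are embedded by the backend's unknown-token convention and
#' flagged via the `"flagged_positions"` attribute.
#'
#' @param backend A [new_pka_backend()] object.
#' @param sequence One-letter amino-acid string.
#' @param layer Layer index in `1..backend$n_layers`.
#' @return An `L x d` numeric matrix with attributes `protein_id` (may be
#'   `NA`), `layer` and `backend_id`.
#' @export
embed_sequence <- function(backend, sequence, layer) {
  stopifnot(inherits(backend, "pka_backend"), is.character(sequence),
            length(sequence) == 1)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L > backend$max_len) {
    abort(sprintf("sequence length %d exceeds backend maximum %d (no silent truncation)",
                  L, backend$max_len))
  }
  layer <- as.integer(layer)
  if (length(layer) != 1 || is.na(layer) || layer < 1 || layer > backend$n_layers) {
    abort(sprintf("layer must be in 1..%d", backend$n_layers))
  }
  letters1 <- strsplit(sequence, "")[[1]]
  unknown <- which(!(letters1 %in% names(AA_ONE_TO_THREE)))
  em <- backend$embed_fn(sequence, layer)
  if (!is.matrix(em) || nrow(em) != L || ncol(em) != backend$d) {
    abort(sprintf("backend '%s' violated the contract: expected %d x %d matrix",
                  backend$backend_id, L, backend$d))
  }
  if (!all(is.finite(em))) {
    abort(sprintf("backend '%s' returned non-finite embedding entries", backend$backend_id))
  }
  if (length(unknown) > 0) {
    warn(sprintf("sequence contains %d non-standard residue letter(s) at position(s) %s; embedded by the backend's unknown-token convention",
                 length(unknown), paste(head(unknown, 5), collapse = ", ")))
    attr(em, "flagged_positions") <- unknown
  }
  if (is.null(attr(em, "protein_id"))) attr(em, "protein_id") <- NA_character_
  attr(em, "layer") <- layer
  attr(em, "backend_id") <- backend$backend_id
  em
}

#' Gather the feature rows of specific residue sites
#'
#' Selects the rows of an embedding matrix corresponding to a set of sites,
#' preserving the order of `sites`. Permuting the requested sites permutes
#' the output rows identically.
#'
#' @param em An embedding matrix from [embed_sequence()].
#' @param sites A tibble with columns `protein_id` and `position`.
#' @return A `nrow(sites) x d` matrix.
#' @export
select_residue_vectors <- function(em, sites) {
  stopifnot(is.matrix(em), is.data.frame(sites),
            all(c("protein_id", "position") %in% names(sites)))
  pid <- attr(em, "protein_id")
  if (nrow(sites) == 0) return(em[0, , drop = FALSE])
  if (!is.na(pid)) {
    mism <- sites$protein_id != pid
    if (any(mism)) {
      abort(sprintf("site protein_id(s) %s do not match embedding protein_id '%s'",
                    paste(unique(sites$protein_id[mism]), collapse = ", "), pid))
    }
  }
  over <- sites$position < 1 | sites$position > nrow(em)
  if (any(over)) {
    abort(sprintf("site position(s) out of range for %s: %s",
                  pid, paste(sites$position[over], collapse = ", ")))
  }
  em[sites$position, , drop = FALSE]
}

# ---- backend registry ----------------------------------------------------

.backend_registry <- new.env(parent = emptyenv())

#' Backend plug-in registry
#'
#' Backends are registered under a name so configurations can refer to them
#' as strings (e.g. `"planted"`). `register_backend()` stores a constructor;
#' `get_backend()` calls it with `...`; `list_backends()` names the entries.
#'
#' @param name Registry key.
#' @param constructor Function returning a `pka_backend`.
#' @export
register_backend <- function(name, constructor) {
  stopifnot(is.character(name), is.function(constructor))
  assign(name, constructor, envir = .backend_registry)
  invisible(name)
}

#' @rdname register_backend
#' @param ... Passed to the registered constructor.
#' @export
get_backend <- function(name, ...) {
  if (!exists(name, envir = .backend_registry, inherits = FALSE)) {
    abort(sprintf("no backend registered under '%s' (available: %s)",
                  name, paste(list_backends(), collapse = ", ")))
  }
  get(name, envir = .backend_registry)(...)
}

#' @rdname register_backend
#' @export
list_backends <- function() ls(.backend_registry)

#' Memoize a backend's embeddings on disk
#'
#' Real protein-language-model backends are expensive; this wrapper caches
#' each `(backend_id, layer, sequence)` result under `dir` as an RDS array
#' with a JSON sidecar describing its provenance, and replays it on repeat
#' calls. The wrapped backend satisfies the same contract.
#'
#' @param backend A `pka_backend`.
#' @param dir Cache directory (created if absent).
#' @return A caching `pka_backend` with the same id, width and depth.
#' @export
with_embedding_cache <- function(backend, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  inner <- backend
  embed_cached <- function(sequence, layer) {
    key <- rlang::hash(list(inner$backend_id, as.integer(layer), sequence))
    rds <- file.path(dir, paste0(key, ".rds"))
    if (file.exists(rds)) return(readRDS(rds))
    em <- embed_sequence(inner, sequence, layer)
    saveRDS(em, rds)
    jsonlite::write_json(
      list(backend_id = inner$backend_id, layer = as.integer(layer),
           sequence_hash = rlang::hash(sequence), n_residues = nrow(em),
           d = ncol(em)),
      file.path(dir, paste0(key, ".json")), auto_unbox = TRUE)
    em
  }
  new_pka_backend(backend$backend_id, backend$d, backend$n_layers,
                  embed_cached, max_len = backend$max_len,
                  subclass = "pka_cached_backend")
}

# Embed every needed protein once and gather feature rows for `records`.
# Returns a nrow(records) x d matrix aligned to the records.
gather_features <- function(records, sequences, backend, layer) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  missing <- setdiff(unique(records$protein_id), names(sequences))
  if (length(missing) > 0) {
    abort(sprintf("no sequence available for protein(s): %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  X <- matrix(NA_real_, nrow(records), backend$d)
  for (pid in unique(records$protein_id)) {
    idx <- which(records$protein_id == pid)
    em <- embed_sequence(backend, sequences[[pid]], layer)
    attr(em, "protein_id") <- pid  # backend may not know the id
    X[idx, ] <- select_residue_vectors(em, records[idx, c("protein_id", "position")])
  }
  X
}
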