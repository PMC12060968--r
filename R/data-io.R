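# Reading, validating and summarising pKa record tables (PKAD-style CSV).

#' Read a pKa table in the package CSV schema
#'
#' Parses a CSV of per-residue pKa observations. The required columns are
#' `protein_id`, `position` (1-based), `aa` (one- or three-letter) and `pka`
#' (pH units); real database exports with different headers can be adapted
#' with `col_map` instead of editing the file. Rows that violate the record
#' invariants (non-titratable residue, position < 1, non-numeric pKa) are
#' rejected with row-numbered warnings; duplicated `(protein_id, position)`
#' keys keep the first occurrence.
#'
#' @param path Path to a UTF-8, comma-separated file with a header row.
#' @param kind `"experimental"` for measured values or `"teacher"` for values
#'   predicted by a prior model (used for pretraining).
#' @param col_map Optional named character vector mapping the schema names to
#'   the file's column names, e.g. `c(protein_id = "PDB ID", pka = "pKa")`.
#' @return A tibble with columns `protein_id`, `position`, `aa`, `pka`,
#'   `source`.
#' @export
read_pka_table <- function(path, kind = c("experimental", "teacher"),
                           col_map = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (!col_map[[std]] %in% names(raw)) {
        abort(sprintf("col_map names column '%s' which is absent from %s", col_map[[std]], path))
      }
      names(raw)[names(raw) == col_map[[std]]] <- std
    }
  }
  as_pka_table(raw, kind = kind)
}

#' Validate an in-memory data frame as a pKa records table
#'
#' Applies the same row-level validation as [read_pka_table()]: titratable
#' residue types only, 1-based positions, finite pKa (with a soft warning
#' outside the physical 0-16 range), first-wins de-duplication on
#' `(protein_id, position)`.
#'
#' @param data A data frame with columns `protein_id`, `position`, `aa`, `pka`.
#' @inheritParams read_pka_table
#' @return A validated tibble with a `source` column.
#' @export
as_pka_table <- function(data, kind = c("experimental", "teacher")) {
  kind <- match.arg(kind)
  required <- c("protein_id", "position", "aa", "pka")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort(sprintf("pKa table is missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  df <- as_tibble(data)[required]
  df$protein_id <- as.character(df$protein_id)
  df$aa <- normalize_aa(df$aa)
  df$pka <- suppressWarnings(as.numeric(df$pka))
  df$position <- suppressWarnings(as.integer(df$position))
  df$.row <- seq_len(nrow(df))

  bad_aa <- !(df$aa %in% TITRATABLE_AAS)
  bad_pos <- is.na(df$position) | df$position < 1L
  bad_pka <- !is.finite(df$pka)
  bad <- bad_aa | bad_pos | bad_pka
  if (any(bad)) {
    reasons <- dplyr::case_when(
      bad_aa[bad]  ~ "non-titratable residue",
      bad_pos[bad] ~ "position must be a 1-based integer",
      TRUE         ~ "non-numeric or non-finite pKa"
    )
    warn(sprintf(
      "rejected %d row(s): %s", sum(bad),
      paste(sprintf("row %d (%s)", df$.row[bad], reasons), collapse = "; ")
    ))
  }
  df <- df[!bad, ]
  if (nrow(df) == 0) abort("no valid rows remain after validation")

  dup <- duplicated(df[c("protein_id", "position")])
  if (any(dup)) {
    warn(sprintf("dropping %d duplicated (protein_id, position) row(s); keeping first occurrence",
                 sum(dup)))
    df <- df[!dup, ]
  }
  outside <- df$pka <= 0 | df$pka >= 16
  if (any(outside)) {
    warn(sprintf("%d pKa value(s) outside the typical physical range (0, 16)", sum(outside)))
  }
  df$source <- kind
  df$.row <- NULL
  df
}

#' Check pKa records against their sequences
#'
#' Asserts that every record's position falls inside its protein sequence and
#' that the sequence letter at that position matches the record's residue
#' type. Records whose protein has no sequence in `sequences` are skipped.
#'
#' @param data A pKa records tibble.
#' @param sequences Named character vector of one-letter sequences.
#' @return `data`, invisibly; errors describe the offending records.
#' @export
validate_pka_table <- function(data, sequences) {
  have <- data$protein_id %in% names(sequences)
  d <- data[have, ]
  if (nrow(d) == 0) return(invisible(data))
  len <- nchar(sequences[d$protein_id])
  over <- d$position > len
  if (any(over)) {
    abort(sprintf("record position beyond sequence length for: %s",
                  paste(sprintf("%s:%d", d$protein_id[over], d$position[over]), collapse = ", ")))
  }
  letter <- substr(sequences[d$protein_id], d$position, d$position)
  want <- unname(AA_THREE_TO_ONE[d$aa])
  mism <- letter != want
  if (any(mism)) {
    abort(sprintf("sequence letter does not match record residue for: %s",
                  paste(sprintf("%s:%d (%s != %s)", d$protein_id[mism], d$position[mism],
                                letter[mism], want[mism]), collapse = ", ")))
  }
  invisible(data)
}

#' Summarise a pKa records table
#'
#' Counts records per titratable amino acid, the grand total, and the number
#' of distinct proteins. The total always equals the sum of the six per-type
#' counts.
#'
#' @param data A pKa records tibble (possibly empty).
#' @return A one-row tibble with columns `n_ASP`, `n_GLU`, `n_HIS`, `n_CYS`,
#'   `n_TYR`, `n_LYS`, `n_total`, `n_proteins`.
#' @export
summarize_pka_table <- function(data) {
  counts <- vapply(TITRATABLE_AAS, function(a) sum(data$aa == a), integer(1))
  out <- as_tibble(as.list(stats::setNames(counts, paste0("n_", TITRATABLE_AAS))))
  out$n_total <- sum(counts)
  out$n_proteins <- length(unique(data$protein_id))
  out
}

#' Write a pKa records or predictions table as CSV
#'
#' @param data A tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pka_table <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Read and write FASTA sequence files
#'
#' Thin wrappers around Biostrings that move between FASTA files and the
#' named character vectors used throughout this package.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: a named character vector of upper-case one-letter
#'   sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' @rdname read_fasta
#' @param sequences Named character vector of sequences.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(!is.null(names(sequences)))
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
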