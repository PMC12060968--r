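# Solution (model-peptide) pKa reference values and shift arithmetic.

the <- new.env(parent = emptyenv())

#' Solution pKa reference table
#'
#' Reference pKa values of the six titratable amino acids measured in short
#' model peptides, where the protein environment is absent. The packaged
#' defaults are the alanine pentapeptide (Ala-Ala-X-Ala-Ala) values of
#' Thurlkill et al. (2006) Protein Sci 15:1214. The shift of a residue in a
#' protein is defined against these values: `shift = pka - solution_pka(aa)`.
#'
#' All six values are configurable: pass `path` to load an alternative
#' reference CSV with columns `aa`, `solution_pka` and optionally `peptide`.
#'
#' @param path Optional path to a replacement reference CSV.
#' @return A tibble with columns `aa` (three-letter), `solution_pka`
#'   (pH units) and `peptide` (provenance label).
#' @export
#' @examples
#' solution_pka()
solution_pka <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(the$solution_pka)) {
      path <- system.file("extdata", "solution_pka.csv", package = "seqpka")
      the$solution_pka <- load_solution_table(path)
    }
    return(the$solution_pka)
  }
  load_solution_table(path)
}

load_solution_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("aa", "solution_pka") %in% names(tab))) {
    abort("solution pKa reference must have columns 'aa' and 'solution_pka'")
  }
  tab$aa <- normalize_aa(tab$aa)
  if (!("peptide" %in% names(tab))) tab$peptide <- NA_character_
  missing <- setdiff(TITRATABLE_AAS, tab$aa)
  if (length(missing) > 0) {
    abort(sprintf(
      "solution pKa reference is missing titratable types: %s",
      paste(missing, collapse = ", ")
    ))
  }
  his <- tab$solution_pka[tab$aa == "HIS"][1]
  if (his < 6.4 || his > 6.6) {
    warn(sprintf("His solution pKa %.2f lies outside the expected ~6.5 range [6.4, 6.6]", his))
  }
  as_tibble(tab[tab$aa %in% TITRATABLE_AAS, c("aa", "solution_pka", "peptide")])
}

# named numeric lookup aa -> solution pKa
solution_vector <- function(solution = solution_pka()) {
  stats::setNames(solution$solution_pka, solution$aa)
}

#' pKa shifts relative to solution values
#'
#' `pka_shift()` converts absolute pKa values to shifts relative to the
#' model-peptide solution reference (positive = upshifted); `pka_from_shift()`
#' is its exact inverse. `add_pka_shift()` is the data-frame verb: it appends
#' a `shift` column to a pKa records table.
#'
#' @param pka,shift Numeric vectors in pH units.
#' @param aa Amino-acid codes, recycled against `pka`/`shift`.
#' @param solution Solution reference table, see [solution_pka()].
#' @return Numeric vector (`pka_shift`, `pka_from_shift`) or tibble with a
#'   `shift` column (`add_pka_shift`).
#' @export
#' @examples
#' pka_shift(8.54, "HIS")  # +2 relative to the 6.54 reference
pka_shift <- function(pka, aa, solution = solution_pka()) {
  aa <- normalize_aa(aa)
  sol <- solution_vector(solution)
  bad <- setdiff(unique(aa), names(sol))
  if (length(bad) > 0) {
    abort(sprintf("no solution pKa configured for: %s", paste(bad, collapse = ", ")))
  }
  pka - unname(sol[aa])
}

#' @rdname pka_shift
#' @export
pka_from_shift <- function(shift, aa, solution = solution_pka()) {
  aa <- normalize_aa(aa)
  sol <- solution_vector(solution)
  bad <- setdiff(unique(aa), names(sol))
  if (length(bad) > 0) {
    abort(sprintf("no solution pKa configured for: %s", paste(bad, collapse = ", ")))
  }
  shift + unname(sol[aa])
}

#' @rdname pka_shift
#' @param data A pKa records tibble with columns `aa` and `pka`.
#' @export
add_pka_shift <- function(data, solution = solution_pka()) {
  stopifnot(is.data.frame(data), all(c("aa", "pka") %in% names(data)))
  dplyr::mutate(as_tibble(data), shift = pka_shift(.data$pka, .data$aa, solution))
}
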