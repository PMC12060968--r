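# Per-amino-acid summaries of batch predictions (solution reference, modal
# and mean predicted pKa, residue counts).

#' Summarise a predictions table per amino acid
#'
#' For each titratable type: the solution (model-peptide) reference value,
#' the histogram mode of the predicted pKa (midpoint of the most populated
#' bin; ties resolved toward the lowest bin), the mean, and the residue
#' count. Bins are anchored at 0 with the given width, so summaries are
#' deterministic. The per-type counts always sum to the number of input
#' rows.
#'
#' @param predictions A predictions tibble with columns `aa` and `pka`
#'   (the [predict_pka()] output schema).
#' @param bin_width Histogram bin width in pH units (default 0.1).
#' @param solution Solution pKa reference.
#' @return A tibble with columns `aa`, `sol`, `mode`, `mean`, `n`.
#' @export
summarize_predictions <- function(predictions, bin_width = 0.1,
                                  solution = solution_pka()) {
  stopifnot(is.data.frame(predictions), bin_width > 0)
  if (nrow(predictions) == 0) {
    warn("empty predictions table; returning empty summary")
    return(tibble(aa = character(), sol = numeric(), mode = numeric(),
                  mean = numeric(), n = integer()))
  }
  stopifnot(all(c("aa", "pka") %in% names(predictions)))
  sol_vec <- solution_vector(solution)
  predictions |>
    mutate(aa = normalize_aa(.data$aa)) |>
    group_by(.data$aa) |>
    summarise(
      sol = unname(sol_vec[.data$aa[1]]),
      mode = {
        bin <- floor(.data$pka / bin_width)
        counts <- table(bin)
        best <- as.numeric(names(counts)[which.max(counts)])
        (best + 0.5) * bin_width
      },
      mean = mean(.data$pka),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    arrange(.data$aa)
}
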