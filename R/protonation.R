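# Henderson-Hasselbalch protonation probabilities and the three-class
# discretization (protonated / titrating / deprotonated) used in evaluation.

#' Protonated fraction of a titratable site
#'
#' Henderson-Hasselbalch relation for a single independent site:
#' `f = 1 / (1 + 10^(pH - pKa))`. The fraction increases with pKa at fixed pH
#' and decreases with pH at fixed pKa.
#'
#' @param pka pKa value(s), pH units.
#' @param pH Solvent pH (default 7.0).
#' @return Protonated fraction(s) in `[0, 1]`.
#' @export
#' @examples
#' protonated_fraction(7.0, 7.0)   # 0.5 at the midpoint
#' protonated_fraction(6.52, 7.0)  # ~0.25
protonated_fraction <- function(pka, pH = 7.0) {
  stopifnot(all(is.finite(pka)), all(is.finite(pH)))
  1 / (1 + 10^(pH - pka))
}

#' pKa boundaries of the titrating class
#'
#' Inverts the Henderson-Hasselbalch relation at the two probability
#' thresholds: `pka = pH - log10((1 - prob) / prob)`. At the defaults
#' (pH 7, probabilities 0.25/0.75) the boundaries are 6.52 and 7.48 after
#' rounding to two decimals. When `prob_hi = 1 - prob_lo` the boundaries are
#' symmetric about the reference pH.
#'
#' @param pH Reference pH.
#' @param prob_lo,prob_hi Protonation-probability thresholds,
#'   `0 < prob_lo < prob_hi < 1`.
#' @return Named numeric vector `c(pka_lo, pka_hi)` with
#'   `protonated_fraction(pka_lo, pH) == prob_lo`.
#' @export
#' @examples
#' round(class_boundaries(7.0, 0.25, 0.75), 2)
class_boundaries <- function(pH = 7.0, prob_lo = 0.25, prob_hi = 0.75) {
  if (!(prob_lo > 0 && prob_hi < 1 && prob_lo < prob_hi)) {
    abort("need 0 < prob_lo < prob_hi < 1")
  }
  c(pka_lo = pH - log10((1 - prob_lo) / prob_lo),
    pka_hi = pH - log10((1 - prob_hi) / prob_hi))
}

#' Protonation-state thresholds
#'
#' Bundles the reference pH and the two protonation-probability cutoffs and
#' derives the corresponding pKa class boundaries. Sites whose protonated
#' fraction at the reference pH lies inside the closed interval
#' `[prob_lo, prob_hi]` are "titrating"; above it "protonated"; below it
#' "deprotonated". The boundaries are recomputed from `pH`/`prob_*`, never
#' stored stale.
#'
#' @inheritParams class_boundaries
#' @return An object of class `pka_thresholds`.
#' @export
state_thresholds <- function(pH = 7.0, prob_lo = 0.25, prob_hi = 0.75) {
  b <- class_boundaries(pH, prob_lo, prob_hi)
  structure(
    list(pH = pH, prob_lo = prob_lo, prob_hi = prob_hi,
         pka_lo = unname(b["pka_lo"]), pka_hi = unname(b["pka_hi"])),
    class = "pka_thresholds"
  )
}

#' @export
print.pka_thresholds <- function(x, ...) {
  cat(sprintf(
    "<pka_thresholds> pH %.2f | titrating: %.2f <= Prob <= %.2f, %.2f <= pKa <= %.2f\n",
    x$pH, x$prob_lo, x$prob_hi, x$pka_lo, x$pka_hi))
  invisible(x)
}

#' Protonation classes
#'
#' @return The class labels in increasing-pKa order.
#' @export
protonation_classes <- function() c("deprotonated", "titrating", "protonated")

#' Classify protonation state at a reference pH
#'
#' Discretizes pKa values into `deprotonated` / `titrating` / `protonated`
#' by comparing the protonated fraction at the reference pH with the
#' probability thresholds. Low pKa relative to the pH means the site is
#' mostly deprotonated (e.g. a down-shifted, nucleophilic Cys thiolate);
#' high pKa means protonated (e.g. an up-shifted His cation). Exact boundary
#' values fall in the closed titrating interval.
#'
#' @param pka Numeric pKa value(s).
#' @param thresholds A [state_thresholds()] object.
#' @return Factor with levels `deprotonated < titrating < protonated`.
#' @export
#' @examples
#' classify_state(c(5, 7, 9), state_thresholds())
classify_state <- function(pka, thresholds = state_thresholds()) {
  stopifnot(inherits(thresholds, "pka_thresholds"))
  cls <- rep("titrating", length(pka))
  cls[pka < thresholds$pka_lo] <- "deprotonated"
  cls[pka > thresholds$pka_hi] <- "protonated"
  factor(cls, levels = protonation_classes(), ordered = TRUE)
}
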