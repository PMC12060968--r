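# Synthetic study generator: sequences with titratable sites, per-residue
# embeddings carrying a planted shift signal, experimental-style pKa tables
# and a noisy teacher labelling of a larger corpus. Every downstream stage
# (embedding contract, ensembles, evaluation harness) is exercised on this
# generator without any download.

# per-aa sampling weights mirroring the composition of the experimental
# database (330 Asp, 382 Glu, 219 His, 60 Cys, 39 Tyr, 137 Lys)
AA_SITE_WEIGHTS <- c(ASP = 330, GLU = 382, HIS = 219, CYS = 60, TYR = 39, LYS = 137) / 1167

#' Specification of a synthetic pKa study
#'
#' Defines the generative model behind the synthetic corpus. Each titratable
#' position carries a latent true shift `s` drawn from its channel's
#' distribution: acidic residues from a two-component mixture with an
#' enriched positive-shift mode (buried carboxylates are predominantly
#' upshifted), basic residues from a roughly symmetric normal. Embedding
#' rows for titratable sites are `s * gain(channel) * w + noise` with a unit
#' planted direction `w` shared by both channels and opposite gains
#' (+1 acid, -1 base): the same micro-environment feature shifts acids and
#' bases in opposite directions, which is exactly why separately trained
#' channels help. Non-titratable rows are pure isotropic noise.
#'
#' Experimental observations add `N(0, sigma)` measurement noise to
#' `solution(aa) + s`; the teacher table adds the larger `N(0, sigma_teacher)`
#' labelling noise over a disjoint, larger protein pool.
#'
#' Defaults are a desk-scale stand-in for the real study: 300 proteins with
#' ~1,200 experimental sites, and 2,000 teacher proteins with ~6,000
#' teacher-labelled sites.
#'
#' @param n_proteins Proteins in the experimental pool.
#' @param n_teacher_proteins Proteins in the (disjoint) teacher pool.
#' @param length_range Sequence length range (uniform draw, inclusive).
#' @param titratable_density Per-position probability of a titratable
#'   residue.
#' @param sites_per_protein Experimental sites sampled per protein (capped at
#'   the available titratable positions).
#' @param teacher_sites_per_protein Teacher sites sampled per teacher
#'   protein.
#' @param d Embedding width.
#' @param n_layers Layers advertised by the planted backend.
#' @param signal_layers Layers in which the planted signal is present
#'   (`NULL` = all layers); other layers carry pure noise, which supports
#'   layer-sweep tests.
#' @param acid_shift Acid-channel shift distribution:
#'   `(1 - mix) * N(mu0, sd0) + mix * N(mu1, sd1)`.
#' @param base_shift Base-channel shift distribution `N(mu, sd)`.
#' @param emb_noise Isotropic embedding noise standard deviation.
#' @param sigma Experimental observation noise sd (pH units).
#' @param sigma_teacher Teacher labelling noise sd (pH units).
#' @param seed Master seed; all draws derive purpose-keyed streams from it.
#' @return An object of class `synthetic_pka_spec`.
#' @export
synthetic_spec <- function(n_proteins = 300, n_teacher_proteins = 2000,
                           length_range = c(60, 200),
                           titratable_density = 0.25,
                           sites_per_protein = 4,
                           teacher_sites_per_protein = 3,
                           d = 32, n_layers = 3, signal_layers = NULL,
                           acid_shift = list(mix = 0.25, mu0 = 0, sd0 = 1,
                                             mu1 = 2, sd1 = 0.7),
                           base_shift = list(mu = 0, sd = 1),
                           emb_noise = 0.1, sigma = 0.3, sigma_teacher = 0.7,
                           seed = 1) {
  stopifnot(n_proteins >= 1, n_teacher_proteins >= 0,
            length(length_range) == 2, length_range[1] >= 10,
            length_range[1] <= length_range[2],
            titratable_density > 0, titratable_density <= 1,
            d >= 2, n_layers >= 1, emb_noise >= 0, sigma >= 0,
            sigma_teacher >= 0)
  if (is.null(signal_layers)) signal_layers <- seq_len(n_layers)
  stopifnot(all(signal_layers >= 1), all(signal_layers <= n_layers))
  structure(
    list(n_proteins = as.integer(n_proteins),
         n_teacher_proteins = as.integer(n_teacher_proteins),
         length_range = as.integer(length_range),
         titratable_density = titratable_density,
         sites_per_protein = as.integer(sites_per_protein),
         teacher_sites_per_protein = as.integer(teacher_sites_per_protein),
         d = as.integer(d), n_layers = as.integer(n_layers),
         signal_layers = as.integer(signal_layers),
         acid_shift = acid_shift, base_shift = base_shift,
         emb_noise = emb_noise, sigma = sigma, sigma_teacher = sigma_teacher,
         seed = as.integer(seed)),
    class = "synthetic_pka_spec"
  )
}

# the planted unit direction shared by both channels
planted_direction <- function(spec) {
  withr::with_seed(stream_seed(spec$seed, "direction"), {
    w <- rnorm(spec$d)
  })
  w / sqrt(sum(w^2))
}

channel_gain <- function(channel) ifelse(channel == "acid", 1, -1)

draw_shifts <- function(channel, n, spec) {
  out <- numeric(n)
  is_acid <- channel == "acid"
  n_a <- sum(is_acid)
  if (n_a > 0) {
    p <- spec$acid_shift
    comp <- runif(n_a) < p$mix
    out[is_acid] <- ifelse(comp, rnorm(n_a, p$mu1, p$sd1), rnorm(n_a, p$mu0, p$sd0))
  }
  if (n_a < n) {
    p <- spec$base_shift
    out[!is_acid] <- rnorm(n - n_a, p$mu, p$sd)
  }
  out
}

#' Generate a synthetic protein corpus
#'
#' Draws sequences for the experimental pool (ids `P0001...`) and the
#' disjoint teacher pool (ids `T0001...`), and assigns every titratable
#' position a latent true shift from its channel's distribution. Sequence
#' letters and latent shifts come from separate purpose-keyed random
#' streams, so the corpus is fully deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `pka_corpus`: `sequences` (named character
#'   vector) and `sites` (tibble `protein_id`, `position`, `aa`, `channel`,
#'   `pool`, `true_shift`).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_pka_spec"))
  ids <- c(sprintf("P%04d", seq_len(spec$n_proteins)),
           if (spec$n_teacher_proteins > 0)
             sprintf("T%04d", seq_len(spec$n_teacher_proteins)))
  pools <- c(rep("experimental", spec$n_proteins),
             rep("teacher", spec$n_teacher_proteins))
  non_tit <- setdiff(unname(AA_THREE_TO_ONE), TITRATABLE_LETTERS)
  tit_w <- AA_SITE_WEIGHTS[TITRATABLE_AAS]

  sequences <- character(length(ids))
  site_rows <- vector("list", length(ids))
  withr::with_seed(stream_seed(spec$seed, "sequences"), {
    for (i in seq_along(ids)) {
      L <- sample(spec$length_range[1]:spec$length_range[2], 1)
      is_tit <- runif(L) < spec$titratable_density
      letters1 <- character(L)
      letters1[!is_tit] <- sample(non_tit, sum(!is_tit), replace = TRUE)
      letters1[is_tit] <- sample(TITRATABLE_LETTERS, sum(is_tit),
                                 replace = TRUE, prob = tit_w)
      sequences[i] <- paste(letters1, collapse = "")
      pos <- which(is_tit)
      site_rows[[i]] <- tibble(
        protein_id = ids[i], position = pos,
        aa = unname(AA_ONE_TO_THREE[letters1[pos]]), pool = pools[i]
      )
    }
  })
  names(sequences) <- ids
  sites <- bind_rows(site_rows)
  sites$channel <- channel_of(sites$aa)
  withr::with_seed(stream_seed(spec$seed, "signal"), {
    sites$true_shift <- draw_shifts(sites$channel, nrow(sites), spec)
  })
  structure(list(sequences = sequences,
                 sites = sites[, c("protein_id", "position", "aa", "channel",
                                   "pool", "true_shift")]),
            class = "pka_corpus")
}

#' @export
print.pka_corpus <- function(x, ...) {
  cat(sprintf("<pka_corpus> %d sequence(s), %d titratable site(s)\n",
              length(x$sequences), nrow(x$sites)))
  invisible(x)
}

#' Planted-signal embedding backend
#'
#' An embedding backend satisfying the full contract whose feature rows
#' carry the corpus's latent shifts: for a titratable site with true shift
#' `s`, the row at a signal layer is `s * gain(channel) * w + N(0, emb_noise)`
#' with `w` the unit planted direction (`backend$w`); all other rows (and
#' all rows at non-signal layers) are pure noise. Determinism is keyed on
#' the sequence content, the layer and the spec seed, so identical calls are
#' bitwise identical, including for sequences the backend has never seen
#' (which embed as pure noise).
#'
#' @param spec A [synthetic_spec()].
#' @param corpus The matching [generate_corpus()] result.
#' @return A `pka_backend` with extra fields `w` (planted direction) and
#'   `spec`.
#' @export
planted_backend <- function(spec, corpus) {
  stopifnot(inherits(spec, "synthetic_pka_spec"), inherits(corpus, "pka_corpus"))
  w <- planted_direction(spec)
  seq_to_id <- stats::setNames(names(corpus$sequences),
                               unname(corpus$sequences))
  sites_by_protein <- split(corpus$sites, corpus$sites$protein_id)
  backend_id <- sprintf("planted-d%d-seed%d", spec$d, spec$seed)

  embed_fn <- function(sequence, layer) {
    L <- nchar(sequence)
    noise_seed <- hash_seed(backend_id, layer, sequence)
    em <- withr::with_seed(noise_seed, {
      matrix(rnorm(L * spec$d, 0, spec$emb_noise), L, spec$d)
    })
    pid <- seq_to_id[sequence]
    if (!is.na(pid) && layer %in% spec$signal_layers) {
      st <- sites_by_protein[[pid]]
      if (!is.null(st) && nrow(st) > 0) {
        em[st$position, ] <- em[st$position, , drop = FALSE] +
          (st$true_shift * channel_gain(st$channel)) %o% w
      }
    }
    attr(em, "protein_id") <- unname(pid)
    em
  }
  new_pka_backend(backend_id, spec$d, spec$n_layers, embed_fn,
                  max_len = 1022L, subclass = "pka_planted_backend",
                  w = w, spec = spec)
}

# deterministic small seed from arbitrary values
hash_seed <- function(...) {
  strtoi(substr(rlang::hash(list(...)), 1, 7), base = 16L)
}

#' Generate experimental, teacher and truth tables for a corpus
#'
#' Samples per-protein site subsets and attaches noisy observations:
#' experimental pKa = `solution(aa) + s + N(0, sigma)` over the experimental
#' pool; teacher pKa = `solution(aa) + s + N(0, sigma_teacher)` over the
#' larger teacher pool. The truth table carries the latent shift and the
#' noise-free pKa of every sampled site for parameter-recovery tests. Site
#' sampling and the two noise sources use separate purpose-keyed streams, so
#' changing `sigma` alone never moves which sites are observed.
#'
#' @param spec A [synthetic_spec()].
#' @param corpus The matching [generate_corpus()] result.
#' @param solution Solution pKa reference.
#' @return A list of class `pka_truth`: `experimental` and `teacher` pKa
#'   record tibbles, `truth` (with `true_shift`, `true_pka`), and
#'   `sequences`.
#' @export
generate_truth_tables <- function(spec, corpus, solution = solution_pka()) {
  stopifnot(inherits(spec, "synthetic_pka_spec"), inherits(corpus, "pka_corpus"))
  pick <- function(sites, k) {
    withr::with_seed(stream_seed(spec$seed, "site-sampling"), {
      out <- sites |>
        group_by(.data$protein_id) |>
        dplyr::slice_sample(n = k) |>
        ungroup()
    })
    arrange(out, .data$protein_id, .data$position)
  }
  exp_sites <- pick(corpus$sites[corpus$sites$pool == "experimental", ],
                    spec$sites_per_protein)
  tea_sites <- pick(corpus$sites[corpus$sites$pool == "teacher", ],
                    spec$teacher_sites_per_protein)
  sol <- solution_vector(solution)

  make_records <- function(sites, noise_sd, stream, kind) {
    noise <- withr::with_seed(stream_seed(spec$seed, stream),
                              rnorm(nrow(sites), 0, noise_sd))
    tibble(protein_id = sites$protein_id, position = sites$position,
           aa = sites$aa,
           pka = unname(sol[sites$aa]) + sites$true_shift + noise,
           source = kind)
  }
  experimental <- make_records(exp_sites, spec$sigma, "noise-experimental",
                               "experimental")
  teacher <- if (nrow(tea_sites) > 0) {
    make_records(tea_sites, spec$sigma_teacher, "noise-teacher", "teacher")
  } else {
    experimental[0, ]
  }
  truth <- bind_rows(exp_sites, tea_sites)
  truth$true_pka <- unname(sol[truth$aa]) + truth$true_shift
  structure(
    list(experimental = experimental, teacher = teacher,
         truth = truth[, c("protein_id", "position", "aa", "channel", "pool",
                           "true_shift", "true_pka")],
         sequences = corpus$sequences),
    class = "pka_truth"
  )
}

#' @export
print.pka_truth <- function(x, ...) {
  cat(sprintf("<pka_truth> %d experimental, %d teacher record(s) over %d sequence(s)\n",
              nrow(x$experimental), nrow(x$teacher), length(x$sequences)))
  invisible(x)
}

#' Generate a complete synthetic study bundle
#'
#' Convenience wrapper running [generate_corpus()], [planted_backend()] and
#' [generate_truth_tables()] in one call.
#'
#' @inheritParams generate_truth_tables
#' @return A list of class `pka_bundle` with `spec`, `corpus`, `backend`,
#'   `experimental`, `teacher`, `truth`, `sequences`.
#' @export
synthetic_bundle <- function(spec = synthetic_spec(), solution = solution_pka()) {
  corpus <- generate_corpus(spec)
  truth <- generate_truth_tables(spec, corpus, solution)
  structure(
    list(spec = spec, corpus = corpus, backend = planted_backend(spec, corpus),
         experimental = truth$experimental, teacher = truth$teacher,
         truth = truth$truth, sequences = corpus$sequences),
    class = "pka_bundle"
  )
}
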