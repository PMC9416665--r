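.NEUTRAL_AA <- setdiff(.AA20, c(.POSITIVE_AA, .NEGATIVE_AA))

#' Random IDR-like sequence of controlled charge composition
#'
#' Draws a sequence with a fixed number of positive (K/R), negative (D/E)
#' and neutral residues, shuffled into random positions. Counts are
#' `round(length * fraction)`, so the realized composition matches the
#' request to within rounding. Optional motifs (e.g. a basic stretch)
#' overwrite the draw at given positions. Deterministic given `seed`.
#'
#' Defaults emulate the charge content typical of membrane-binding IDRs:
#' about 15% positive and 15% negative residues.
#'
#' @param length sequence length (>= 1).
#' @param fraction_positive,fraction_negative requested fractions
#'   (>= 0, summing to <= 1).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param motifs optional named list/character vector of motifs, names
#'   giving 1-based start positions, e.g. `c("5" = "KRKK")`.
#' @return A single amino-acid string.
#' @examples
#' random_idr_sequence(50, 0.2, 0.1, seed = 7)
#' @export
random_idr_sequence <- function(length, fraction_positive = 0.15,
                                fraction_negative = 0.15, seed = NULL,
                                motifs = NULL) {
  if (length < 1L || length != as.integer(length)) {
    stop("`length` must be a positive integer")
  }
  if (fraction_positive < 0 || fraction_negative < 0) {
    stop("fractions must be >= 0")
  }
  n_pos <- round(length * fraction_positive)
  n_neg <- round(length * fraction_negative)
  if (n_pos + n_neg > length) {
    stop("infeasible composition: requested charge counts exceed the length")
  }
  n_neu <- length - n_pos - n_neg
  draw <- function() {
    letters1 <- c(sample(.POSITIVE_AA, n_pos, replace = TRUE),
                  sample(.NEGATIVE_AA, n_neg, replace = TRUE),
                  sample(.NEUTRAL_AA, n_neu, replace = TRUE))
    paste(sample(letters1), collapse = "")
  }
  seq1 <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (!is.null(motifs)) {
    chars <- strsplit(seq1, "", fixed = TRUE)[[1]]
    starts <- as.integer(names(motifs))
    if (any(is.na(starts))) stop("`motifs` must be named by start position")
    for (k in seq_along(motifs)) {
      m <- strsplit(toupper(motifs[[k]]), "", fixed = TRUE)[[1]]
      pos <- starts[k] + seq_along(m) - 1L
      if (starts[k] < 1L || max(pos) > length) {
        stop(sprintf("motif %d does not fit in the sequence", k))
      }
      chars[pos] <- m
    }
    seq1 <- paste(chars, collapse = "")
  }
  seq1
}

#' Model-derived noisy contact profile
#'
#' Generates an observed-looking contact profile from the partition
#' function itself: `C_n = clip(c * w_n / w_max + eps_n, 0, 1)` with
#' independent Gaussian noise per residue. With `noise_sd = 0` the profile
#' is exactly the model propensity, which makes noise-free parameter
#' recovery an exact round trip. Deterministic given `seed`.
#'
#' @param sequence amino-acid string.
#' @param params generating [model_params()].
#' @param scale per-protein scale `c` in (0, 1].
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param termini passed to [classify_residues()].
#' @return Numeric vector of contact probabilities in \[0, 1\].
#' @export
synthetic_contact_profile <- function(sequence,
                                      params = preset_params("disordered"),
                                      scale = 0.8, noise_sd = 0.02,
                                      seed = NULL, termini = "free") {
  if (scale <= 0 || scale > 1) stop("`scale` must be in (0, 1]")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  classes <- classify_residues(sequence, termini = termini)
  w <- statistical_weights(classes, params)
  clean <- scale * w / max(w)
  if (noise_sd == 0) return(clean)
  draw <- function() stats::rnorm(length(clean), sd = noise_sd)
  eps <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  pmin(pmax(clean + eps, 0), 1)
}

#' Synthetic training set
#'
#' Convenience generator pairing [random_idr_sequence()] with
#' [synthetic_contact_profile()] for several proteins, each with its own
#' scale drawn uniformly in `scale_range` and its own noise stream. One
#' integer seed drives all substreams (per-protein seeds are derived by
#' small offsets, kept well below 2^31).
#'
#' @param n_proteins number of proteins.
#' @param length residues per protein.
#' @param params generating [model_params()].
#' @param scale_range range the per-protein scales are drawn from.
#' @param noise_sd Gaussian noise sd shared by all proteins.
#' @param seed integer seed (required, for a reproducible world).
#' @param fraction_positive,fraction_negative composition passed through.
#' @param termini passed through.
#' @return A [training_set()] with ids `synth1`, `synth2`, ...
#' @export
synthetic_training_set <- function(n_proteins = 5L, length = 100L,
                                   params = preset_params("disordered"),
                                   scale_range = c(0.4, 0.9),
                                   noise_sd = 0.02, seed = 1L,
                                   fraction_positive = 0.15,
                                   fraction_negative = 0.15,
                                   termini = "free") {
  stopifnot(n_proteins >= 1L, is.numeric(seed), length(seed) == 1L)
  seed <- as.integer(seed) %% 1000000L
  scales <- withr::with_seed(seed, {
    stats::runif(n_proteins, scale_range[1], scale_range[2])
  })
  entries <- lapply(seq_len(n_proteins), function(i) {
    seq_i <- random_idr_sequence(length, fraction_positive, fraction_negative,
                                 seed = seed + 1000L * i)
    obs_i <- synthetic_contact_profile(seq_i, params, scale = scales[i],
                                       noise_sd = noise_sd,
                                       seed = seed + 1000L * i + 500L,
                                       termini = termini)
    training_entry(paste0("synth", i), seq_i, obs_i, termini = termini)
  })
  training_set(entries)
}
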