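#' Distance-attenuated contributing factor
#'
#' The multiplicative factor a site of a given charge class contributes to
#' the statistical weight of a residue `d` positions away along the
#' sequence:
#' \deqn{q(d) = 1 + (q_0 - 1) / (1 + a d + b d^2)}
#' where `q_0` is the class amplitude at `d = 0`. Charged classes use
#' `a_pm`/`b_pm`; neutral uses `a_zero` with `b = 0`. The factor decays
#' monotonically toward 1 with increasing `d`, so it always lies strictly
#' between `min(1, q_0)` and `max(1, q_0)` (inclusive of `q_0` at d = 0).
#'
#' @param class `"positive"`, `"negative"` or `"neutral"`.
#' @param d non-negative integer sequence distance(s); vectorized.
#' @param params a [model_params()] object.
#' @return Numeric vector of factors, same length as `d`.
#' @examples
#' distance_factor("positive", 10, preset_params("disordered"))  # ~1.625
#' @export
distance_factor <- function(class, d, params) {
  stopifnot(inherits(params, "memprop_params"))
  class <- match.arg(class, .CLASS_LEVELS)
  if (any(!is.finite(d)) || any(d < 0)) stop("`d` must be finite and >= 0")
  q0 <- switch(class, positive = params$q_plus, negative = params$q_minus,
               neutral = params$q_zero)
  a <- if (class == "neutral") params$a_zero else params$a_pm
  b <- if (class == "neutral") 0 else params$b_pm
  1 + (q0 - 1) / (1 + a * d + b * d^2)
}

# log contributing factors for one class at distances 0..dmax, as a
# lookup vector indexed by d + 1.
.log_factor_table <- function(class, dmax, params) {
  log(distance_factor(class, 0:dmax, params))
}

#' Statistical weights of every residue in a sequence
#'
#' The membrane-association statistical weight of residue `n` is the
#' product, over all sites `i` of the sequence (including `i = n` and any
#' terminal pseudo-sites), of the distance-attenuated contributing factors
#' \eqn{w_n = \prod_i q_{i;|i-n|}}. Computed as a sum of log factors then
#' exponentiated, so long sequences neither underflow nor overflow; all
#' factors are strictly positive for valid parameters, so the logs are
#' finite.
#'
#' @param classes a [classify_residues()] object.
#' @param params a [model_params()] object.
#' @param log if `TRUE`, return log weights.
#' @return Numeric vector `w_n`, one per residue.
#' @export
statistical_weights <- function(classes, params, log = FALSE) {
  stopifnot(inherits(classes, "residue_classes"),
            inherits(params, "memprop_params"))
  n_res <- length(classes$classes)
  tables <- lapply(stats::setNames(.CLASS_LEVELS, .CLASS_LEVELS),
                   .log_factor_table, dmax = n_res - 1L, params = params)
  pos <- seq_len(n_res)
  logw <- numeric(n_res)
  for (cls in .CLASS_LEVELS) {
    idx <- which(classes$classes == cls)
    if (length(idx) == 0L) next
    tab <- tables[[cls]]
    # distance matrix restricted to sites of this class, summed over sites
    for (i in idx) logw <- logw + tab[abs(i - pos) + 1L]
  }
  if (classes$n_term_site) logw <- logw + tables[["positive"]][abs(1L - pos) + 1L]
  if (classes$c_term_site) logw <- logw + tables[["negative"]][abs(n_res - pos) + 1L]
  if (log) logw else exp(logw)
}

#' Statistical weight of a single residue
#'
#' @param n 1-based residue index within the sequence.
#' @inheritParams statistical_weights
#' @return Scalar weight `w_n`.
#' @export
statistical_weight <- function(n, classes, params) {
  stopifnot(inherits(classes, "residue_classes"))
  n_res <- length(classes$classes)
  if (length(n) != 1L || n != as.integer(n) || n < 1L || n > n_res) {
    stop(sprintf("residue index must be an integer in 1..%d", n_res))
  }
  statistical_weights(classes, params)[n]
}

#' Per-residue membrane-association propensity profile
#'
#' Normalizes the statistical weights to propensities
#' \eqn{P_n = c \, w_n / w_{max}}, where `w_max` is the sequence maximum of
#' `w_n` and `c` is a per-protein scale factor (default 1, so propensities
#' are relative on (0, 1]; `c` is only meaningful when estimated against an
#' observed profile). The profile is 1-based over the supplied sequence; an
#' integer `offset` shifts the reported index into author/UniProt numbering
#' (reported index = position + offset).
#'
#' @inheritParams statistical_weights
#' @param scale per-protein scale factor `c` (> 0).
#' @param offset integer added to the 1-based position for reporting.
#' @return A data frame of class `propensity_profile` with columns
#'   `index`, `residue`, `class`, `weight`, `propensity`, and attributes
#'   `w_max`, `scale`, `offset`.
#' @examples
#' cls <- classify_residues("GGGGKGGGG", termini = "capped")
#' pp <- propensity_profile(cls, preset_params("disordered"))
#' pp$index[which.max(pp$propensity)]  # the central K
#' @export
propensity_profile <- function(classes, params = preset_params("disordered"),
                               scale = 1, offset = 0L) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0) {
    stop("`scale` must be a single positive number")
  }
  if (offset != as.integer(offset)) stop("`offset` must be an integer")
  w <- statistical_weights(classes, params)
  w_max <- max(w)
  out <- data.frame(
    index = seq_along(w) + as.integer(offset),
    residue = strsplit(classes$sequence, "", fixed = TRUE)[[1]],
    class = classes$classes,
    weight = w,
    propensity = scale * w / w_max,
    stringsAsFactors = FALSE
  )
  structure(out, w_max = w_max, scale = scale, offset = as.integer(offset),
            class = c("propensity_profile", "data.frame"))
}

#' @export
print.propensity_profile <- function(x, ...) {
  cat(sprintf("propensity_profile: %d residues, w_max = %.6g, scale c = %g\n",
              nrow(x), attr(x, "w_max"), attr(x, "scale")))
  peak <- x$index[which.max(x$propensity)]
  cat(sprintf("  peak propensity %.4g at index %d\n", max(x$propensity), peak))
  NextMethod()
}
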