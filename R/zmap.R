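#' Constants of the tip-height to contact-probability map
#'
#' The smooth map from a side chain's mean tip height above the membrane
#' phosphate plane, `z_tip` (Å), to a contact probability was calibrated
#' against raw 3.5-Å heavy-atom contact fractions; the published constants
#' are z0 = 6.9 Å, L1 = 3.2 Å, L0 = 1.2 Å, Lm = 5.0 Å, Lw = 0.5 Å.
#'
#' @param z0 midpoint height (Å) where the contact probability is 1/2.
#' @param l1,l0 asymptotic softness lengths (Å) far above / below the
#'   membrane; must satisfy `l1 > l0 > 0`.
#' @param lm,lw midpoint (Å) and width (Å, > 0) of the sigmoid that
#'   interpolates the softness length between `l0` and `l1`.
#' @return An object of class `smooth_map_params`.
#' @export
smooth_map_params <- function(z0 = 6.9, l1 = 3.2, l0 = 1.2, lm = 5.0, lw = 0.5) {
  vals <- c(z0, l1, l0, lm, lw)
  if (!all(is.finite(vals))) stop("all map constants must be finite")
  if (!(l1 > l0 && l0 > 0)) stop("require L1 > L0 > 0")
  if (lw <= 0) stop("require Lw > 0")
  structure(list(z0 = z0, l1 = l1, l0 = l0, lm = lm, lw = lw),
            class = "smooth_map_params")
}

# logistic with exponent clamped to +-700: exp(710) overflows double, and
# beyond +-700 the probability is 0/1 to machine precision anyway.
.safe_logistic <- function(x) {
  1 / (1 + exp(pmin(pmax(x, -700), 700)))
}

#' Height-dependent softness length L(z_tip)
#'
#' \deqn{L(z) = L_1 - (L_1 - L_0) / (1 + \exp[(z - L_m)/L_w])}
#' Strictly between `L0` and `L1` for finite input; equals their mean at
#' `z = Lm`.
#'
#' @param z_tip tip height(s) in Å; vectorized.
#' @param params a [smooth_map_params()] object.
#' @return Numeric vector of lengths (Å).
#' @export
length_scale <- function(z_tip, params = smooth_map_params()) {
  stopifnot(inherits(params, "smooth_map_params"))
  if (any(!is.finite(z_tip))) stop("`z_tip` must be finite")
  params$l1 - (params$l1 - params$l0) *
    .safe_logistic((z_tip - params$lm) / params$lw)
}

#' Contact probability from tip height
#'
#' \deqn{C(z) = 1 / (1 + \exp[(z - z_0)/L(z)])}
#' with the softness length itself varying smoothly with height via
#' [length_scale()]. Strictly decreasing in `z_tip`; bounded in (0, 1) for
#' finite input, overflow-guarded for extreme arguments.
#'
#' @inheritParams length_scale
#' @return Contact probabilities in (0, 1), same length/order as `z_tip`.
#' @examples
#' contact_from_ztip(6.9)  # 0.5 at the midpoint
#' @export
contact_from_ztip <- function(z_tip, params = smooth_map_params()) {
  stopifnot(inherits(params, "smooth_map_params"))
  if (any(!is.finite(z_tip))) stop("`z_tip` must be finite")
  .safe_logistic((z_tip - params$z0) / length_scale(z_tip, params))
}
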