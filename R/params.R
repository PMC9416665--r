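#' Partition-function model parameters
#'
#' Container for the six constants of the sequence-based partition function:
#' the three amplitudes `q_plus`, `q_minus`, `q_zero` (contributing factor of
#' a positive, negative or neutral site at sequence distance zero) and the
#' three distance-attenuation coefficients. The attenuation follows
#' \deqn{q(d) = 1 + (q_0 - 1) / (1 + a d + b d^2)}
#' with `a = a_pm`, `b = b_pm` for charged sites and `a = a_zero`, `b = 0`
#' for neutral sites. The attenuation coefficients are inherited constants
#' and are held fixed during fitting; only the amplitudes are trained.
#'
#' @param q_plus,q_minus,q_zero strictly positive dimensionless amplitudes.
#' @param a_pm,b_pm attenuation coefficients (per residue, per residue
#'   squared) shared by the charged classes; non-negative.
#' @param a_zero attenuation coefficient for neutral sites; non-negative.
#' @return An object of class `memprop_params`.
#' @seealso [preset_params()] for the two published parameter sets.
#' @examples
#' p <- model_params(2.43, 0.26, 0.59)
#' distance_factor("neutral", 0, p)   # 0.59
#' @export
model_params <- function(q_plus, q_minus, q_zero,
                         a_pm = 0.0982, b_pm = 0.00305, a_zero = 0.521) {
  amps <- c(q_plus = q_plus, q_minus = q_minus, q_zero = q_zero)
  if (!all(is.finite(amps)) || any(amps <= 0)) {
    stop("amplitudes q_plus, q_minus, q_zero must be finite and > 0")
  }
  att <- c(a_pm = a_pm, b_pm = b_pm, a_zero = a_zero)
  if (!all(is.finite(att)) || any(att < 0)) {
    stop("attenuation coefficients a_pm, b_pm, a_zero must be finite and >= 0")
  }
  structure(
    list(q_plus = q_plus, q_minus = q_minus, q_zero = q_zero,
         a_pm = a_pm, b_pm = b_pm, a_zero = a_zero),
    class = "memprop_params"
  )
}

#' Published amplitude sets
#'
#' The two trained amplitude sets: `"disordered"` (fit to fully disordered
#' IDRs; q+ = 2.43, q- = 0.26, q0 = 0.59) and `"helix"` (fit to IDRs
#' containing membrane-bound amphipathic helices; q+ = 2.29, q- = 0.64,
#' q0 = 1.17). Both share the inherited attenuation constants
#' a± = 0.0982, b± = 0.00305, a0 = 0.521. The mode is user-selected;
#' nothing in the package auto-detects helix content.
#'
#' @param mode `"disordered"` (default) or `"helix"`.
#' @return A `memprop_params` object.
#' @export
preset_params <- function(mode = c("disordered", "helix")) {
  mode <- match.arg(mode)
  switch(mode,
    disordered = model_params(2.43, 0.26, 0.59),
    helix      = model_params(2.29, 0.64, 1.17)
  )
}

#' @export
print.memprop_params <- function(x, ...) {
  cat("Partition-function parameters\n")
  cat(sprintf("  amplitudes : q+ = %g, q- = %g, q0 = %g\n",
              x$q_plus, x$q_minus, x$q_zero))
  cat(sprintf("  attenuation: a+- = %g, b+- = %g, a0 = %g (b0 = 0)\n",
              x$a_pm, x$b_pm, x$a_zero))
  invisible(x)
}
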