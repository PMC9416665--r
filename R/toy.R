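#' Moving-average-charge baseline
#'
#' A deliberately simple comparator for the partition-function score: each
#' residue carries a charge of +1 (K, R), -1 (D, E) or 0 (all other), with
#' `termini = "free"` adding +1 at position 1 and -1 at position N for the
#' free termini, and the profile value at residue `n` is the mean charge
#' over a centered window (default seven residues). Windows are truncated
#' at the sequence edges and the mean is taken over the positions actually
#' in range, so every residue has a defined value interpretable as a mean
#' charge in [-1, 1].
#'
#' @param sequence amino-acid string, normalized as in
#'   [classify_residues()].
#' @param window odd window width >= 1 (default 7). `window = 1` returns
#'   the raw charge sequence.
#' @param termini `"free"` (default) or `"capped"`.
#' @return Numeric vector of per-residue mean charges.
#' @examples
#' moving_average_charge("KGDGK", window = 7, termini = "capped")
#' @export
moving_average_charge <- function(sequence, window = 7L,
                                  termini = c("free", "capped")) {
  if (length(window) != 1L || window != as.integer(window) ||
      window < 1L || window %% 2L == 0L) {
    stop("`window` must be an odd integer >= 1")
  }
  classes <- classify_residues(sequence, termini = match.arg(termini))
  ch <- residue_charges(classes)
  n <- length(ch)
  half <- (as.integer(window) - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(ch[lo:hi])
  }, numeric(1))
}

#' Ordinary least-squares comparator
#'
#' Fits `y = slope * x + intercept` by ordinary least squares and reports
#' the coefficient of determination `R^2 = 1 - SSres/SStot`. Used to score
#' the moving-average-charge profile against an observed contact profile.
#' A constant `y` (zero total sum of squares) is reported as `r_squared = 0`
#' (the regression explains nothing); a constant `x` is an error, since the
#' slope is undefined.
#'
#' @param x predictor profile (e.g. mean charge per residue).
#' @param y observed profile of the same length (>= 3 points).
#' @return A list of class `memprop_lm` with `slope`, `intercept`,
#'   `r_squared`, `n_points`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3L) stop("need at least 3 points")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  if (stats::var(x) == 0) stop("zero variance in x: slope undefined")
  fit <- stats::lm(y ~ x)
  coefs <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  structure(
    list(slope = unname(coefs["x"]), intercept = unname(coefs["(Intercept)"]),
         r_squared = r2, n_points = length(x)),
    class = "memprop_lm"
  )
}

#' @export
print.memprop_lm <- function(x, ...) {
  cat(sprintf("OLS fit: y = %.4g x + %.4g, R^2 = %.3f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}
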