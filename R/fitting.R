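#' Assemble a training set of sequences and observed contact profiles
#'
#' @param ... entries created by [training_entry()].
#' @return A list of class `training_set`.
#' @export
training_set <- function(...) {
  entries <- list(...)
  if (length(entries) == 1L && is.list(entries[[1]]) &&
      !inherits(entries[[1]], "training_entry")) {
    entries <- entries[[1]]
  }
  if (length(entries) < 1L) stop("training set needs at least one entry")
  ok <- vapply(entries, inherits, logical(1), what = "training_entry")
  if (!all(ok)) stop("all entries must be created by training_entry()")
  ids <- vapply(entries, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate protein ids in training set")
  names(entries) <- ids
  structure(entries, class = "training_set")
}

#' One protein of a training set
#'
#' @param id protein identifier.
#' @param sequence amino-acid string (or a pre-built
#'   [classify_residues()] object).
#' @param observed per-residue observed contact probabilities in \[0, 1\],
#'   same length as the sequence.
#' @param group label for grouped leave-one-out; proteins sharing a label
#'   are held out together (default: the id, i.e. each protein its own
#'   group).
#' @param termini passed to [classify_residues()] when `sequence` is a
#'   string.
#' @return A list of class `training_entry`.
#' @export
training_entry <- function(id, sequence, observed, group = id,
                           termini = "free") {
  classes <- if (inherits(sequence, "residue_classes")) sequence
             else classify_residues(sequence, termini = termini)
  observed <- as.numeric(observed)
  if (length(observed) != length(classes$classes)) {
    stop(sprintf("'%s': profile length %d != sequence length %d",
                 id, length(observed), length(classes$classes)))
  }
  if (any(!is.finite(observed)) || any(observed < 0) || any(observed > 1)) {
    stop(sprintf("'%s': observed probabilities must be finite and in [0, 1]", id))
  }
  structure(list(id = as.character(id), classes = classes,
                 observed = observed, group = as.character(group)),
            class = "training_entry")
}

#' Closed-form least-squares scale factor
#'
#' Given relative weights `r_n = w_n / w_max` and an observed profile
#' `C_n`, the per-protein scale minimizing the sum of squared residuals of
#' `c * r_n` is \eqn{c = \sum C_n r_n / \sum r_n^2}, clipped to be
#' non-negative. This is the scale profiled out inside the fitting
#' objective, so the optimizer only searches amplitude space.
#'
#' @param r relative weights (some > 0).
#' @param observed observed contact probabilities, same length.
#' @return Scalar `c >= 0`.
#' @export
optimal_scale <- function(r, observed) {
  if (length(r) != length(observed)) stop("length mismatch")
  if (all(r == 0)) stop("all relative weights are zero")
  max(sum(observed * r) / sum(r^2), 0)
}

#' Root-mean-square error between profiles
#' @param predicted,observed equal-length numeric profiles.
#' @return \eqn{\sqrt{\mathrm{mean}((pred - obs)^2)}}.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  sqrt(mean((predicted - observed)^2))
}

#' Pooled coefficient of determination about the parity line
#'
#' \eqn{R_0^2 = 1 - \sum (pred - obs)^2 / SS_{tot}}, pooled over all
#' residues of all proteins, measuring how tightly predictions hug the
#' y = x line. By default `SStot` is taken about the observed mean (the
#' standard R-squared denominator); `center = "zero"` uses the raw sum of
#' squares of the observations instead, for comparison.
#'
#' @param predicted,observed pooled equal-length numeric profiles.
#' @param center `"mean"` (default) or `"zero"`.
#' @return Scalar; 1 for a perfect prediction, can be negative.
#' @export
r0_squared <- function(predicted, observed, center = c("mean", "zero")) {
  center <- match.arg(center)
  if (length(predicted) != length(observed)) stop("length mismatch")
  ss_tot <- switch(center,
    mean = sum((observed - mean(observed))^2),
    zero = sum(observed^2))
  if (ss_tot == 0) {
    stop("zero variance in observations: coefficient of determination undefined")
  }
  1 - sum((predicted - observed)^2) / ss_tot
}

# pooled sum of squared residuals with the per-protein scale profiled out;
# logq = log(q_plus, q_minus, q_zero)
.fit_objective <- function(logq, training, dist) {
  q <- exp(logq)
  params <- model_params(q[1], q[2], q[3],
                         a_pm = dist$a_pm, b_pm = dist$b_pm,
                         a_zero = dist$a_zero)
  total <- 0
  for (entry in training) {
    w <- statistical_weights(entry$classes, params)
    r <- w / max(w)
    cc <- optimal_scale(r, entry$observed)
    total <- total + sum((cc * r - entry$observed)^2)
  }
  total
}

# which amplitudes are constrained by the data: a class (counting the
# terminal pseudo-sites) absent from every training sequence leaves its
# amplitude in a flat objective direction.
.identifiable_amplitudes <- function(training) {
  counts <- c(positive = 0, negative = 0, neutral = 0)
  for (entry in training) {
    tab <- table(factor(entry$classes$classes, levels = .CLASS_LEVELS))
    counts <- counts + as.numeric(tab)
    if (entry$classes$n_term_site) counts["positive"] <- counts["positive"] + 1
    if (entry$classes$c_term_site) counts["negative"] <- counts["negative"] + 1
  }
  stats::setNames(counts > 0, c("q_plus", "q_minus", "q_zero"))
}

#' Fit the amplitude parameters against observed contact profiles
#'
#' Minimizes the pooled per-residue sum of squared residuals between
#' predicted propensities `c_p * w_n / w_max` and the observed contact
#' probabilities, over the three amplitudes (q+, q-, q0). Each protein's
#' scale `c_p` is solved in closed form inside the objective
#' ([optimal_scale()]), so the optimizer searches only amplitude space; the
#' distance-attenuation constants stay frozen at their inherited values.
#' Optimization runs L-BFGS-B on log amplitudes (so the positivity bounds
#' become box constraints) from `n_starts` seeded initial points and keeps
#' the best converged result; non-convergence of the best run is flagged in
#' the result, never silent. Amplitudes whose charge class never occurs in
#' the training sequences are reported as non-identifiable.
#'
#' @param training a [training_set()].
#' @param init initial amplitudes `(q+, q-, q0)`; also the first start.
#' @param lower,upper box bounds on each amplitude (default \[0.01, 20\]).
#' @param n_starts number of multi-start points (default 10); starts after
#'   the first are drawn log-uniformly within the bounds.
#' @param seed integer seed making the extra starts reproducible.
#' @param distance_params `memprop_params` supplying the frozen
#'   attenuation constants (amplitudes in it are ignored).
#' @return An object of class `memprop_fit`: fitted `params`, `amplitudes`,
#'   per-protein `scales` and `rmse`, pooled `r0_squared`, `objective`,
#'   `converged`, `identifiable`, optimizer diagnostics.
#' @export
fit_amplitudes <- function(training, init = c(1, 1, 1),
                           lower = 0.01, upper = 20, n_starts = 10L,
                           seed = NULL,
                           distance_params = preset_params("disordered")) {
  stopifnot(inherits(training, "training_set"))
  init <- as.numeric(init)
  if (length(init) != 3L || any(!is.finite(init)) ||
      any(init < lower) || any(init > upper)) {
    stop("`init` must be three amplitudes within [lower, upper]")
  }
  if (!(lower > 0 && upper > lower)) stop("bounds must satisfy 0 < lower < upper")
  dist <- distance_params

  starts <- matrix(log(init), nrow = 1L)
  if (n_starts > 1L) {
    draw <- function() matrix(stats::runif(3L * (n_starts - 1L),
                                           log(lower), log(upper)),
                              ncol = 3L)
    extra <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    starts <- rbind(starts, extra)
  }

  runs <- apply(starts, 1L, function(p0) {
    stats::optim(p0, .fit_objective, training = training, dist = dist,
                 method = "L-BFGS-B",
                 lower = rep(log(lower), 3L), upper = rep(log(upper), 3L),
                 control = list(factr = 1e4, maxit = 500L))
  })
  values <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(values)]]

  q <- exp(best$par)
  params <- model_params(q[1], q[2], q[3], a_pm = dist$a_pm,
                         b_pm = dist$b_pm, a_zero = dist$a_zero)
  pred_all <- numeric(0); obs_all <- numeric(0)
  scales <- rmses <- stats::setNames(numeric(length(training)), names(training))
  for (id in names(training)) {
    entry <- training[[id]]
    w <- statistical_weights(entry$classes, params)
    r <- w / max(w)
    scales[id] <- optimal_scale(r, entry$observed)
    pred <- scales[id] * r
    rmses[id] <- rmse(pred, entry$observed)
    pred_all <- c(pred_all, pred); obs_all <- c(obs_all, entry$observed)
  }
  identifiable <- .identifiable_amplitudes(training)
  if (!all(identifiable)) {
    warning("non-identifiable amplitude(s): ",
            paste(names(identifiable)[!identifiable], collapse = ", "),
            " (charge class absent from training sequences)")
  }
  structure(
    list(params = params,
         amplitudes = stats::setNames(q, c("q_plus", "q_minus", "q_zero")),
         scales = scales, rmse = rmses,
         r0_squared = r0_squared(pred_all, obs_all),
         objective = best$value,
         converged = best$convergence == 0L,
         convergence_code = best$convergence,
         identifiable = identifiable,
         n_starts = nrow(starts), seed = seed,
         n_residues = length(obs_all)),
    class = "memprop_fit"
  )
}

#' @export
print.memprop_fit <- function(x, ...) {
  cat("Amplitude fit\n")
  cat(sprintf("  q+ = %.4g, q- = %.4g, q0 = %.4g%s\n",
              x$amplitudes[1], x$amplitudes[2], x$amplitudes[3],
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  pooled R0^2 = %.3f over %d residues (%d proteins)\n",
              x$r0_squared, x$n_residues, length(x$scales)))
  for (id in names(x$rmse)) {
    cat(sprintf("  %-12s c = %.3f, RMSE = %.4f\n", id, x$scales[id], x$rmse[id]))
  }
  if (!all(x$identifiable)) {
    cat("  non-identifiable:",
        paste(names(x$identifiable)[!x$identifiable], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Grouped leave-one-out robustness analysis
#'
#' Refits the amplitudes with each group of proteins held out in turn
#' (proteins sharing a group label — e.g. sequence-similar pairs — leave
#' together) and summarizes the spread of each amplitude across folds as
#' mean +/- standard deviation. Stable amplitudes across folds indicate the
#' fit is not dominated by any single protein.
#'
#' @inheritParams fit_amplitudes
#' @param ... further arguments passed to [fit_amplitudes()]
#'   (`init`, bounds, `n_starts`, `seed`, `distance_params`).
#' @return An object of class `memprop_loo`: `fits` (one `memprop_fit` per
#'   held-out group, named by that group) and `summary` (data frame with
#'   columns `amplitude`, `mean`, `sd`).
#' @export
leave_one_out <- function(training, ...) {
  stopifnot(inherits(training, "training_set"))
  groups <- vapply(training, `[[`, character(1), "group")
  uniq <- unique(groups)
  if (length(uniq) < 2L) stop("grouped leave-one-out needs at least 2 groups")
  fits <- lapply(uniq, function(g) {
    kept <- training[groups != g]
    fit_amplitudes(training_set(kept), ...)
  })
  names(fits) <- uniq
  amps <- t(vapply(fits, `[[`, numeric(3), "amplitudes"))
  summary <- data.frame(
    amplitude = c("q_plus", "q_minus", "q_zero"),
    mean = colMeans(amps),
    sd = apply(amps, 2L, stats::sd),
    row.names = NULL
  )
  structure(list(fits = fits, summary = summary), class = "memprop_loo")
}

#' @export
print.memprop_loo <- function(x, ...) {
  cat(sprintf("Leave-one-out over %d folds\n", length(x$fits)))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-8s %.3g +/- %.2g\n", x$summary$amplitude[i],
                x$summary$mean[i], x$summary$sd[i]))
  }
  invisible(x)
}
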