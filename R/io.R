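#' Read amino-acid sequences from FASTA
#'
#' @param path FASTA file, possibly multi-record; record descriptions
#'   become names, in input order.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) {
                    stop(sprintf("malformed FASTA '%s': %s", path,
                                 conditionMessage(e)))
                  })
  if (length(set) == 0L) stop(sprintf("no records in FASTA '%s'", path))
  stats::setNames(as.character(set), names(set))
}

#' Write a per-residue profile as TSV
#'
#' Tab-separated, '.' decimal, with a single '#'-prefixed header line
#' naming the columns; numeric columns are formatted to `digits`
#' significant digits (default 6, the package's diff-friendly dialect;
#' use 15 for a lossless round trip).
#'
#' @param profile a data frame (e.g. a [propensity_profile()]).
#' @param path output file, or `""` for stdout.
#' @param digits significant digits for numeric columns.
#' @export
write_profile <- function(profile, path, digits = 6L) {
  stopifnot(is.data.frame(profile))
  df <- as.data.frame(profile)
  fmt <- function(col) {
    if (is.double(col)) sprintf(paste0("%.", digits, "g"), col) else as.character(col)
  }
  lines <- c(paste0("#", paste(names(df), collapse = "\t")),
             do.call(paste, c(lapply(df, fmt), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

# shared TSV reader: '#'-prefixed header, numbered error messages
.read_tsv_profile <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  header_idx <- which(startsWith(lines, "#") & keep)
  data_idx <- which(!startsWith(lines, "#") & keep)
  if (length(data_idx) == 0L) stop(sprintf("no data rows in '%s'", path))
  cols <- if (length(header_idx) > 0L) {
    strsplit(sub("^#", "", lines[header_idx[1]]), "\t", fixed = TRUE)[[1]]
  } else NULL
  rows <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  n_col <- length(rows[[1]])
  bad <- which(lengths(rows) != n_col)
  if (length(bad) > 0L) {
    stop(sprintf("malformed TSV '%s': line %d has %d fields, expected %d",
                 path, data_idx[bad[1]], lengths(rows)[bad[1]], n_col))
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  if (!is.null(cols) && length(cols) == n_col) names(df) <- cols
  attr(df, "source_lines") <- data_idx
  df
}

#' Read an observed contact-probability profile from TSV
#'
#' Expects columns index, optional residue, and a final numeric value
#' column with probabilities; values outside \[0, 1\] are an error naming
#' the offending line.
#'
#' @param path TSV file ('#'-prefixed header optional).
#' @return Data frame with columns `index`, optionally `residue`, `value`.
#' @export
read_profile <- function(path) {
  df <- .read_tsv_profile(path)
  src <- attr(df, "source_lines")
  out <- data.frame(index = as.integer(df[[1]]), stringsAsFactors = FALSE)
  value_col <- ncol(df)
  if (ncol(df) >= 3L) out$residue <- df[[2]]
  out$value <- suppressWarnings(as.numeric(df[[value_col]]))
  bad <- which(is.na(out$index) | is.na(out$value))
  if (length(bad) > 0L) {
    stop(sprintf("malformed TSV '%s': non-numeric field on line %d",
                 path, src[bad[1]]))
  }
  oor <- which(out$value < 0 | out$value > 1)
  if (length(oor) > 0L) {
    stop(sprintf("'%s': probability %g out of [0, 1] on line %d",
                 path, out$value[oor[1]], src[oor[1]]))
  }
  out
}

#' Read a per-residue tip-height profile from TSV
#'
#' Like [read_profile()] but the value column holds z_tip heights in
#' Ångström, unconstrained in sign.
#'
#' @inheritParams read_profile
#' @return Data frame with columns `index`, `value` (Å).
#' @export
read_ztip <- function(path) {
  df <- .read_tsv_profile(path)
  src <- attr(df, "source_lines")
  out <- data.frame(index = as.integer(df[[1]]),
                    value = suppressWarnings(as.numeric(df[[ncol(df)]])))
  bad <- which(is.na(out$index) | is.na(out$value))
  if (length(bad) > 0L) {
    stop(sprintf("malformed TSV '%s': non-numeric field on line %d",
                 path, src[bad[1]]))
  }
  out
}

#' Composite amide chemical-shift perturbation
#'
#' The standard composite of backbone amide proton and nitrogen shift
#' changes, \eqn{\Delta\delta_{NH} = \sqrt{\Delta\delta_H^2 + k \,
#' \Delta\delta_N^2}}, with the nitrogen weight `k` scaling the broader
#' nitrogen dispersion down to proton units (common choices: 0.154 or
#' 0.2). Values below `floor` (ppm) are set to 0, the convention used to
#' suppress perturbations within experimental error (e.g. 0.005 ppm).
#'
#' @param delta_h,delta_n amide proton and nitrogen shift changes (ppm);
#'   vectorized, equal length.
#' @param nitrogen_weight positive dimensionless nitrogen weight.
#' @param floor values below this (ppm) are zeroed; default 0 (no floor).
#' @return Composite perturbations (ppm), >= 0.
#' @examples
#' combined_shift_perturbation(0.03, 0.1)  # ~0.0494
#' @export
combined_shift_perturbation <- function(delta_h, delta_n,
                                        nitrogen_weight = 0.154, floor = 0) {
  if (length(nitrogen_weight) != 1L || !is.finite(nitrogen_weight) ||
      nitrogen_weight <= 0) {
    stop("`nitrogen_weight` must be a single positive number")
  }
  if (length(delta_h) != length(delta_n)) stop("length mismatch")
  if (any(!is.finite(delta_h)) || any(!is.finite(delta_n))) {
    stop("shift changes must be finite")
  }
  out <- sqrt(delta_h^2 + nitrogen_weight * delta_n^2)
  out[out < floor] <- 0
  out
}
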