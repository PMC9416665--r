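.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.POSITIVE_AA <- c("K", "R")
.NEGATIVE_AA <- c("D", "E")
.CLASS_LEVELS <- c("positive", "negative", "neutral")

#' Classify residues into charge classes
#'
#' Assigns each residue of an amino-acid sequence to one of three charge
#' classes: positive (K, R), negative (D, E) or neutral (everything else,
#' including H). With `termini = "free"` the charged chain termini are
#' modeled as two additional pseudo-sites co-located with residues 1
#' (positive, the free amino group) and N (negative, the free carboxylate);
#' the terminal residues keep their own classes. `termini = "capped"`
#' drops both pseudo-sites, as for an IDR excised from a longer chain.
#'
#' Input is normalized before validation: whitespace is stripped and
#' letters are upper-cased. `X` is accepted as an unknown residue and
#' classed neutral with a warning; any other non-standard letter is an
#' error naming its position.
#'
#' @param sequence one-letter amino-acid string (length >= 1).
#' @param termini `"free"` (default) or `"capped"`.
#' @return An object of class `residue_classes`: a list with `sequence`
#'   (normalized string), `classes` (character vector, one of
#'   `"positive"`, `"negative"`, `"neutral"` per residue), `n_term_site`
#'   and `c_term_site` (logicals).
#' @examples
#' classify_residues("KRDEG", termini = "capped")$classes
#' @export
classify_residues <- function(sequence, termini = c("free", "capped")) {
  termini <- match.arg(termini)
  if (length(sequence) != 1L || !is.character(sequence) || is.na(sequence)) {
    stop("`sequence` must be a single character string")
  }
  seq_norm <- toupper(gsub("[[:space:]]", "", sequence))
  if (nchar(seq_norm) == 0L) stop("empty sequence")
  letters1 <- strsplit(seq_norm, "", fixed = TRUE)[[1]]
  bad <- which(!(letters1 %in% c(.AA20, "X")))
  if (length(bad) > 0L) {
    stop(sprintf("invalid residue '%s' at position %d (standard amino acids or X only)",
                 letters1[bad[1]], bad[1]))
  }
  if (any(letters1 == "X")) {
    warning(sprintf("%d 'X' residue(s) treated as neutral", sum(letters1 == "X")))
  }
  classes <- rep("neutral", length(letters1))
  classes[letters1 %in% .POSITIVE_AA] <- "positive"
  classes[letters1 %in% .NEGATIVE_AA] <- "negative"
  structure(
    list(sequence = seq_norm, classes = classes,
         n_term_site = termini == "free", c_term_site = termini == "free"),
    class = "residue_classes"
  )
}

#' @export
print.residue_classes <- function(x, ...) {
  n <- length(x$classes)
  cat(sprintf("residue_classes: %d residues (%d +, %d -, %d neutral)\n",
              n, sum(x$classes == "positive"), sum(x$classes == "negative"),
              sum(x$classes == "neutral")))
  cat(sprintf("  termini: N pseudo-site %s, C pseudo-site %s\n",
              if (x$n_term_site) "on" else "off",
              if (x$c_term_site) "on" else "off"))
  invisible(x)
}

# Per-residue integer charges (+1/-1/0). With free termini the terminal
# charges are additive: +1 at position 1 and -1 at position N on top of the
# residues' own charges (the toy-model convention).
residue_charges <- function(classes) {
  stopifnot(inherits(classes, "residue_classes"))
  ch <- c(positive = 1, negative = -1, neutral = 0)[classes$classes]
  names(ch) <- NULL
  n <- length(ch)
  if (classes$n_term_site) ch[1] <- ch[1] + 1
  if (classes$c_term_site) ch[n] <- ch[n] - 1
  ch
}
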