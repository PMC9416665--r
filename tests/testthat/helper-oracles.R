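# Independent oracles kept deliberately naive: direct products, no log
# space, no vectorization tricks. They must stay independent of the code
# paths they check.

naive_factor <- function(cls, d, params) {
  q0 <- switch(cls, positive = params$q_plus, negative = params$q_minus,
               neutral = params$q_zero)
  a <- if (cls == "neutral") params$a_zero else params$a_pm
  b <- if (cls == "neutral") 0 else params$b_pm
  1 + (q0 - 1) / (1 + a * d + b * d^2)
}

naive_statistical_weight <- function(n, classes, params) {
  n_res <- length(classes$classes)
  w <- 1
  for (i in seq_len(n_res)) {
    w <- w * naive_factor(classes$classes[i], abs(i - n), params)
  }
  if (classes$n_term_site) w <- w * naive_factor("positive", abs(1 - n), params)
  if (classes$c_term_site) w <- w * naive_factor("negative", abs(n_res - n), params)
  w
}

# mixed-composition random sequences for property tests
random_test_sequence <- function(len) {
  paste(sample(c("A", "G", "S", "P", "Q", "L", "K", "R", "D", "E", "H", "Y"),
               len, replace = TRUE), collapse = "")
}

disordered <- memprop::preset_params("disordered")
helix_set <- memprop::preset_params("helix")
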