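test_that("classify_residues assigns the three charge classes", {
  cls <- classify_residues("KRDEG", termini = "capped")
  expect_equal(cls$classes,
               c("positive", "positive", "negative", "negative", "neutral"))
  expect_false(cls$n_term_site)
  expect_false(cls$c_term_site)

  free <- classify_residues("GGG", termini = "free")
  expect_equal(free$classes, rep("neutral", 3))
  expect_true(free$n_term_site)
  expect_true(free$c_term_site)

  # H is neutral in the three-class scheme
  expect_equal(classify_residues("H", "capped")$classes, "neutral")
})

test_that("classify_residues normalizes case and whitespace", {
  a <- classify_residues("kr de g", termini = "capped")
  b <- classify_residues("KRDEG", termini = "capped")
  expect_identical(a, b)
})

test_that("classify_residues rejects bad input and warns on X", {
  expect_error(classify_residues(""), "empty")
  expect_error(classify_residues("   "), "empty")
  expect_error(classify_residues("AGZB"), "position 3")
  expect_warning(cls <- classify_residues("AXG", "capped"), "X")
  expect_equal(cls$classes[2], "neutral")
})

test_that("distance_factor reproduces hand-evaluated values", {
  expect_equal(distance_factor("neutral", 0, disordered), 0.59)
  expect_equal(distance_factor("positive", 0, disordered), 2.43)
  expect_equal(distance_factor("negative", 0, helix_set), 0.64)
  # d = 10, charged: 1 + 1.43 / (1 + 0.982 + 0.305)
  expect_equal(distance_factor("positive", 10, disordered),
               1 + 1.43 / (1 + 0.982 + 0.305), tolerance = 1e-12)
  # d = 1, neutral: 1 - 0.41 / 1.521
  expect_equal(distance_factor("neutral", 1, disordered),
               1 - 0.41 / 1.521, tolerance = 1e-12)
  expect_equal(distance_factor("positive", 1e6, disordered), 1, tolerance = 1e-5)
})

test_that("distance_factor attenuates monotonically toward 1", {
  d <- 0:500
  for (cls in c("positive", "negative", "neutral")) {
    f <- distance_factor(cls, d, disordered)
    q0 <- distance_factor(cls, 0, disordered)
    if (q0 > 1) expect_true(all(diff(f) < 0)) else expect_true(all(diff(f) > 0))
    expect_true(all(f >= min(1, q0) & f <= max(1, q0)))
  }
})

test_that("statistical weights match the naive product oracle", {
  p <- disordered
  # frozen oracle values
  cls5 <- classify_residues("GGGGG", "capped")
  f <- function(d) naive_factor("neutral", d, p)
  expect_equal(statistical_weight(3, cls5, p), 0.59 * f(1)^2 * f(2)^2,
               tolerance = 1e-12)
  expect_equal(statistical_weight(3, cls5, p), 0.201, tolerance = 1e-3)
  expect_equal(statistical_weight(1, classify_residues("G", "capped"), p), 0.59)
  # free termini put a positive and a negative pseudo-site on a lone K
  expect_equal(statistical_weight(1, classify_residues("K", "free"), p),
               2.43 * 2.43 * 0.26, tolerance = 1e-12)

  # random sequences, both parameter sets and termini conventions
  set.seed(101)
  for (k in 1:50) {
    params <- if (k %% 2) disordered else helix_set
    term <- if (k %% 3) "free" else "capped"
    cls <- classify_residues(random_test_sequence(sample(1:30, 1)), term)
    w <- statistical_weights(cls, params)
    w_naive <- vapply(seq_along(w), naive_statistical_weight, numeric(1),
                      classes = cls, params = params)
    expect_equal(w, w_naive, tolerance = 1e-10)
    expect_true(all(w > 0))
  }
})

test_that("statistical_weight validates the index", {
  cls <- classify_residues("GAG", "capped")
  expect_error(statistical_weight(0, cls, disordered), "1..3")
  expect_error(statistical_weight(4, cls, disordered), "1..3")
})

test_that("capped palindromic sequences have mirror-symmetric weights", {
  for (s in c("KGDGK", "EAKAE", "GGRGG", "KRGRK")) {
    cls <- classify_residues(s, "capped")
    w <- statistical_weights(cls, disordered)
    expect_equal(w, rev(w), tolerance = 1e-12)
  }
})

test_that("replacing a neutral residue with K never lowers any weight", {
  set.seed(202)
  for (k in 1:20) {
    s <- random_test_sequence(25)
    chars <- strsplit(s, "")[[1]]
    neutral_at <- which(!(chars %in% c("K", "R", "D", "E")))
    if (length(neutral_at) == 0) next
    i <- sample(neutral_at, 1)
    chars2 <- chars; chars2[i] <- "K"
    w1 <- statistical_weights(classify_residues(s, "free"), disordered)
    w2 <- statistical_weights(classify_residues(paste(chars2, collapse = ""),
                                                "free"), disordered)
    expect_true(all(w2 >= w1))
  }
})

test_that("propensity profiles are normalized to the scale factor", {
  p <- disordered
  set.seed(303)
  for (k in 1:10) {
    cls <- classify_residues(random_test_sequence(sample(5:40, 1)), "free")
    sc <- stats::runif(1, 0.2, 1.5)
    pp <- propensity_profile(cls, p, scale = sc)
    expect_equal(max(pp$propensity), sc, tolerance = 1e-12)
    expect_equal(pp$propensity, sc * pp$weight / attr(pp, "w_max"),
                 tolerance = 1e-12)
  }
})

test_that("a lone basic residue is the propensity peak", {
  pp <- propensity_profile(classify_residues("GGGGKGGGG", "capped"), disordered)
  expect_equal(pp$index[which.max(pp$propensity)], 5)
})

test_that("homopolymer interior is near-flat and mirror-symmetric", {
  # translational symmetry is exact only for an infinite chain: the slowly
  # decaying (1/d) edge attenuation leaves a few-percent bow in a finite
  # one, shrinking as the chain grows
  pp60 <- propensity_profile(classify_residues(strrep("G", 60), "capped"),
                             disordered)
  interior60 <- pp60$propensity[25:35]
  expect_lt(diff(range(interior60)) / mean(interior60), 0.05)
  expect_equal(pp60$propensity, rev(pp60$propensity), tolerance = 1e-12)
  pp300 <- propensity_profile(classify_residues(strrep("G", 300), "capped"),
                              disordered)
  interior300 <- pp300$propensity[145:155]
  expect_lt(diff(range(interior300)) / mean(interior300),
            diff(range(interior60)) / mean(interior60))
})

test_that("numbering offset shifts reported indices only", {
  cls <- classify_residues("GGKGG", "capped")
  a <- propensity_profile(cls, disordered, offset = 0)
  b <- propensity_profile(cls, disordered, offset = 580)
  expect_equal(b$index, a$index + 580)
  expect_equal(b$propensity, a$propensity)
})

test_that("long sequences neither under- nor overflow", {
  s <- paste(rep(c("K", "G", "E", "R", "A", "D"), length.out = 2000),
             collapse = "")
  w <- statistical_weights(classify_residues(s, "free"), disordered)
  expect_true(all(is.finite(w)) && all(w > 0))
})

test_that("parameter constructors enforce invariants", {
  expect_error(model_params(0, 0.3, 0.6), "> 0")
  expect_error(model_params(2, -0.3, 0.6), "> 0")
  expect_error(model_params(2, 0.3, 0.6, a_pm = -1), ">= 0")
  expect_equal(preset_params("helix")$q_zero, 1.17)
})
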