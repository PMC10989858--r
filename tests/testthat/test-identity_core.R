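test_that("frequency validation accepts well-formed and rejects degenerate input", {
  v <- validate_frequencies(c(A = 0.6, B = 0.3, C = 0.1))
  expect_s3_class(v, "allele_freqs")
  expect_equal(as.numeric(v), c(0.6, 0.3, 0.1))
  expect_equal(names(v), c("A", "B", "C"))
  expect_error(validate_frequencies(c(A = 0.5, B = 0.6)), "sum")
  expect_error(validate_frequencies(c(A = 1)), "monomorphic")
  expect_error(validate_frequencies(c(A = 0.5, B = -0.5, C = 1.0)), "positive")
  expect_error(validate_frequencies(numeric(0)), "empty")
})

test_that("pure Jacquard modes map to the expected coefficient values", {
  z <- jacquard_to_coefficients(delta_null)
  expect_equal(as.numeric(unclass(z)), rep(0, 8))
  one <- jacquard_to_coefficients(jacquard(c(1, rep(0, 8))))
  expect_equal(as.numeric(unclass(one)), rep(1, 8))
  d7 <- jacquard_to_coefficients(jacquard(c(0, 0, 0, 0, 0, 0, 1, 0, 0)))
  expect_equal(unclass(d7),
               c(F_A = 0, F_B = 0, R = 0.5, G_A = 0, G_B = 0,
                 F_AB = 0, R_AB = 0.5, H = 0))
})

test_that("Delta7 coefficients reproduce direct identity-class probabilities", {
  # substituting the Delta7 coefficient set into the class model must give
  # the direct enumeration values f_iiii = p^2 and f_ijij = 2 p_i p_j
  th <- jacquard_to_coefficients(jacquard(c(0, 0, 0, 0, 0, 0, 1, 0, 0)))
  for (pp in list(p3, p3b)) {
    expect_equal(quartet_class_probability(pp, th, "iiii", c(i = 1)),
                 as.numeric(pp[1])^2, tolerance = 1e-14)
    expect_equal(quartet_class_probability(pp, th, "ijij", c(i = 1, j = 2)),
                 2 * as.numeric(pp[1]) * as.numeric(pp[2]), tolerance = 1e-14)
  }
})

test_that("coefficient map is a bijection with its inverse", {
  set.seed(41)
  for (i in 1:50) {
    d <- rand_delta()
    th <- jacquard_to_coefficients(d)
    expect_equal(as.numeric(coefficients_to_jacquard(th)), as.numeric(d),
                 tolerance = 1e-12)
  }
})

test_that("ordering inequalities hold across the Delta simplex", {
  set.seed(42)
  for (i in 1:2000) {
    th <- jacquard_to_coefficients(rand_delta())
    expect_length(coefficient_consistency_report(th), 0)
  }
  expect_match(coefficient_consistency_report(rel_coefs(H = 0.5, G_A = 0.1)),
               "H <= G_A violated", all = FALSE)
  expect_length(coefficient_consistency_report(rel_coefs()), 0)
})

test_that("normalization constants match their closed forms and the Bernoulli cumulant", {
  expect_equal(normalization_constant(2, 0.2), 0.16)
  expect_equal(normalization_constant(3, 0.5), 0)
  expect_equal(normalization_constant(4, 0.5), -0.125)
  expect_error(normalization_constant(5, 0.2), "order")
  # order-4 constant equals the fourth cumulant of a Bernoulli(p) indicator,
  # computed independently by enumeration over the two outcomes
  for (p in seq(0.02, 0.98, length.out = 50)) {
    mu4c <- p * (1 - p)^4 + (1 - p) * p^4
    sigma2 <- p * (1 - p)
    expect_equal(normalization_constant(4, p), mu4c - 3 * sigma2^2,
                 tolerance = 1e-12)
  }
})

test_that("cumulants equal central moments through order 3 and differ at order 4", {
  # Gaussian: mu4c = 3 sigma^4 so k4 = 0
  g <- central_moments_to_cumulants(mu2 = 2, mu4 = 12)
  expect_equal(g$k4, 0)
  # Bernoulli(0.5) by enumeration: mu4c = 0.0625
  b <- central_moments_to_cumulants(mu2 = 0.25, mu3 = 0, mu4 = 0.0625)
  expect_equal(b$k4, -0.125)
  expect_equal(b$k3, 0)
  # four independent variates: all cross-covariances zero
  iv <- central_moments_to_cumulants(
    mu2 = c(s12 = 0, s13 = 0, s14 = 0, s23 = 0, s24 = 0, s34 = 0), mu4 = 0)
  expect_equal(unname(iv$k1234), 0)
  expect_error(central_moments_to_cumulants(mu2 = 0.2), "fourth")
})

test_that("mixture moments reduce correctly and match the enumeration oracle", {
  # identical components: no across-component variance
  same <- mixture_model(list(c(0.3, 0.7), c(0.3, 0.7)))
  mm0 <- mixture_moments(same)
  expect_equal(mm0$var_homozygosity, 0)
  expect_equal(mm0$cov_indicator, 0)
  # p +- a components: Var(p_m^2) by direct two-component enumeration
  p <- 0.3; a <- 0.1
  mm <- mixture_moments(mixture_two_pop(p, a))
  oracle <- ((p + a)^4 + (p - a)^4) / 2 - (((p + a)^2 + (p - a)^2) / 2)^2
  expect_equal(mm$var_homozygosity, oracle, tolerance = 1e-14)
  expect_equal(mm$var_homozygosity, 4 * a^2 * p^2, tolerance = 1e-12)
  # pooled frequency of the symmetric mixture is p
  expect_equal(unname(mm$pooled_p[1]), p)
})

test_that("effective selfing rate follows 2R - G and flags out-of-range values", {
  expect_equal(as.numeric(effective_selfing(0, 0)), 0)
  expect_equal(as.numeric(effective_selfing(0.5, 0)), 1)
  expect_warning(s <- effective_selfing(0.1, 0.5), "outside")
  expect_equal(as.numeric(s), -0.3)
  expect_true(attr(s, "out_of_range"))
})
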