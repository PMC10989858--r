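test_that("estimate_R inverts the forward model and handles trivial spectra", {
  sp0 <- class_spectrum(p3b, 0, n_genes = 2)
  expect_equal(unname(estimate_R(sp0, p3b)$estimates["R"]), 0, tolerance = 1e-12)
  sp1 <- class_spectrum(p3b, 1, n_genes = 2)
  expect_equal(unname(estimate_R(sp1, p3b)$estimates["R"]), 1, tolerance = 1e-12)
  sp <- class_spectrum(p3b, 0.25, n_genes = 2)
  e <- estimate_R(sp, p3b)
  expect_equal(unname(e$estimates["R"]), 0.25, tolerance = 1e-12)
  expect_equal(sum(e$weights), 1, tolerance = 1e-12)
  expect_equal(unname(e$weights), c(0.2, 0.35, 0.45))
})

test_that("estimate_G inverts the three-gene model given F and R", {
  set.seed(13)
  for (i in 1:20) {
    frg <- rand_FRG()
    sp <- class_spectrum(p4, as.list(frg), n_genes = 3)
    e <- estimate_G(sp, p4, F = frg[["F"]], R = frg[["R"]])
    expect_equal(unname(e$estimates["G"]), frg[["G"]], tolerance = 1e-10)
  }
  sp0 <- class_spectrum(p4, list(F = 0, R = 0, G = 0), n_genes = 3)
  expect_equal(unname(estimate_G(sp0, p4, 0, 0)$estimates["G"]), 0,
               tolerance = 1e-12)
})

test_that("half-frequency alleles are flagged non-estimable, never zero-filled", {
  sp <- class_spectrum(p3, list(F = 0.1, R = 0.1, G = 0.05), n_genes = 3)
  e <- estimate_G(sp, p3, F = 0.1, R = 0.1)
  expect_true(is.na(e$components$G[[1]]))
  expect_match(e$flags, "non-estimable", all = FALSE)
  expect_equal(unname(e$estimates["G"]), 0.05, tolerance = 1e-10)
  expect_equal(unname(e$weights[1]), 0)
})

test_that("joint H/F_AB solver inverts its forward system and flags singularities", {
  set.seed(17)
  for (i in 1:20) {
    H <- runif(1, 0, 0.2); FAB <- runif(1, 0, 0.3)
    f <- joint_class_freqs(0.4, 0.3, H = H, F_AB = FAB)
    e <- estimate_H_Fab(f["AAAA"], f["AaAa"], 0.4, 0.3)
    expect_equal(unname(e$estimates), c(H, FAB), tolerance = 1e-10)
  }
  f0 <- joint_class_freqs(0.4, 0.3)
  e0 <- estimate_H_Fab(f0["AAAA"], f0["AaAa"], 0.4, 0.3)
  expect_equal(unname(e0$estimates), c(0, 0), tolerance = 1e-12)
  expect_match(estimate_H_Fab(0.1, 0.1, 0.5, 0.3)$flags, "p = 1/2", all = FALSE)
  expect_match(estimate_H_Fab(0.1, 0.1, 0.6, 0.4)$flags, "third allele", all = FALSE)
})

test_that("joint H/F_AB/R_AB solver inverts exactly and is singular at p = 1/3", {
  set.seed(19)
  for (i in 1:20) {
    th <- runif(3, 0, 0.25)
    f <- joint_class_freqs(0.4, 0.3, H = th[1], F_AB = th[2], R_AB = th[3])
    e <- estimate_H_F_R(f["AAAA"], f["AaAa"], f["AAaa"], 0.4, 0.3)
    expect_equal(unname(e$estimates), th, tolerance = 1e-10)
  }
  f0 <- joint_class_freqs(0.4, 0.3)
  expect_equal(unname(estimate_H_F_R(f0["AAAA"], f0["AaAa"], f0["AAaa"],
                                     0.4, 0.3)$estimates),
               c(0, 0, 0), tolerance = 1e-12)
  expect_match(estimate_H_F_R(0.1, 0.1, 0.1, 1/3, 0.3)$flags,
               "1/3", all = FALSE)
})

test_that("four-gene closed forms are singular exactly at p = 1/3 on a fine grid", {
  # determinant of the 3x3 joint system changes sign only through p = 1/3
  dets <- vapply(seq(0.01, 0.6, by = 0.01), function(p) {
    M <- relquartet:::.joint_rows(p, 0.3, c("AAAA", "AaAa", "AAaa"),
                                  c("H", "F_AB", "R_AB"))
    det(M)
  }, 0)
  ps <- seq(0.01, 0.6, by = 0.01)
  near_third <- abs(ps - 1/3) < 0.005
  expect_true(all(abs(dets[!near_third]) > 1e-12))
  Msing <- relquartet:::.joint_rows(1/3, 0.3, c("AAAA", "AaAa", "AAaa"),
                                    c("H", "F_AB", "R_AB"))
  expect_lt(abs(det(Msing)), 1e-16)
})

test_that("three-gene components are non-estimable exactly at p = 1/2", {
  for (pi in seq(0.05, 0.95, by = 0.01)) {
    p <- validate_frequencies(c(pi, (1 - pi) * 0.6, (1 - pi) * 0.4))
    v <- exact_estimator_variance("G_A", p, weighting = "focal")
    if (abs(pi - 0.5) < 1e-9) expect_false(v$estimable[[1]])
    else expect_true(v$estimable[[1]])
  }
})

test_that("Weir-style identity disequilibrium estimator uses the printed coefficients", {
  w <- weir_identity_disequilibrium(0, 0, 0.2, 0.3)
  expect_equal(w$extra$abc$a, 2.16)
  expect_equal(w$extra$abc$b, 0.64)
  expect_equal(w$extra$abc$c, 0.072, tolerance = 1e-12)
  expect_equal(unname(w$estimates["R_AB"]), 0)
  expect_match(weir_identity_disequilibrium(0.1, 0.1, 1/3, 0.3)$flags,
               "singular", all = FALSE)
})

test_that("the eight-coefficient linear solve recovers Delta-derived truth", {
  d <- jacquard(c(0.05, 0.1, 0.05, 0.1, 0.05, 0.1, 0.2, 0.15, 0.2))
  th <- jacquard_to_coefficients(d)
  sp <- class_spectrum(p4, th, n_genes = 4)
  e <- estimate_all_eight(sp, p4)
  expect_equal(unname(e$estimates), unname(unclass(th)), tolerance = 1e-10)
  expect_true(is.finite(e$extra$condition_number))
  # null expectations give all zeros
  sp0 <- class_spectrum(p4, rel_coefs(), n_genes = 4)
  expect_equal(unname(estimate_all_eight(sp0, p4)$estimates), rep(0, 8),
               tolerance = 1e-12)
  set.seed(23)
  for (i in 1:20) {
    d <- rand_delta()
    th <- jacquard_to_coefficients(d)
    sp <- class_spectrum(p4, th, n_genes = 4)
    e <- estimate_all_eight(sp, p4)
    expect_equal(unname(e$estimates), unname(unclass(th)), tolerance = 1e-10)
  }
  # degenerate class system is flagged, not silently solved
  eq <- validate_frequencies(c(0.25, 0.25, 0.5))
  sp <- class_spectrum(eq, rel_coefs(), n_genes = 4)
  expect_match(estimate_all_eight(sp, eq)$flags, "singular", all = FALSE)
})

test_that("minimum-variance weights reproduce closed forms and sum to one", {
  w <- allele_weights(c(0.6, 0.3, 0.1), target = "R")
  expect_equal(unname(w$weights), c(0.2, 0.35, 0.45), tolerance = 1e-10)
  w2 <- allele_weights(c(0.3, 0.7), target = "R")
  expect_equal(unname(w2$weights), c(0.7, 0.3), tolerance = 1e-10)
  set.seed(29)
  for (i in 1:5) {
    k <- sample(2:4, 1)
    p <- validate_frequencies(local({ x <- rexp(k) + 0.2; x / sum(x) }))
    for (tg in c("R", "F", "H")) {
      w <- allele_weights(p, target = tg)$weights
      expect_equal(sum(w, na.rm = TRUE), 1, tolerance = 1e-10)
    }
  }
})

test_that("estimators are unbiased over the exact observation distribution", {
  # E[estimate] over the enumeration, weighted by model probabilities,
  # equals the true parameter (linearity makes this exact)
  set.seed(31)
  for (i in 1:20) {
    R <- runif(1, 0, 0.9)
    v <- exact_estimator_variance("R", p3b, truth = rel_coefs(R = R))
    expect_equal(v$mean, R, tolerance = 1e-10)
  }
  for (i in 1:10) {
    frg <- rand_FRG()
    v <- exact_estimator_variance("G_A", p4,
      truth = rel_coefs(F_A = frg[["F"]], R = frg[["R"]], G_A = frg[["G"]]))
    expect_equal(v$mean, frg[["G"]], tolerance = 1e-10)
  }
})

test_that("estimates serialize to JSON with components and weights", {
  sp <- class_spectrum(p3b, 0.25, n_genes = 2)
  e <- estimate_R(sp, p3b)
  js <- jsonlite::fromJSON(estimate_to_json(e))
  expect_equal(js$estimates$R, 0.25, tolerance = 1e-10)
  expect_equal(length(js$weights), 3)
})
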